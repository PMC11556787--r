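new_position_freqs <- function(df, n_reads, n_peptides,
                               sample_label = NA_character_) {
  df <- as_tibble(df)[, c("amino_acid", "position", "frequency")]
  attr(df, "n_reads") <- n_reads
  attr(df, "n_peptides") <- n_peptides
  attr(df, "sample_label") <- sample_label
  class(df) <- c("position_freqs", class(df))
  df
}

#' Position-wise amino-acid frequencies of a peptide count table
#'
#' For every position `p`, `freq(aa, p)` is the read-weighted fraction of
#' peptides carrying `aa` at `p`: the summed counts of peptides with `aa` at
#' `p` divided by the total read count (each read counts once). Set
#' `weight = "peptide"` for a unique-sequence-weighted tally instead. Columns
#' sum to 1 at each position.
#'
#' @param counts A `peptide_counts` tibble (see [peptide_counts()]).
#' @param include_stops Keep stop-containing peptides and tally `"*"` as a
#'   21st symbol. By default stop-containing peptides are excluded (with a
#'   message if any are present).
#' @param weight `"read"` (default; each read counts once) or `"peptide"`
#'   (each distinct peptide counts once).
#' @return A tibble of class `position_freqs` with columns `amino_acid`,
#'   `position`, `frequency`, and attributes `n_reads`, `n_peptides`,
#'   `sample_label`.
#' @export
position_frequencies <- function(counts, include_stops = FALSE,
                                 weight = c("read", "peptide")) {
  weight <- match.arg(weight)
  stopifnot(is.data.frame(counts),
            all(c("peptide", "count") %in% names(counts)))
  df <- as_tibble(counts)[, c("peptide", "count")]
  has_stop <- grepl("*", df$peptide, fixed = TRUE)
  if (!include_stops && any(has_stop)) {
    rlang::inform(sprintf(
      "Excluding %d stop-containing peptide(s) from the frequency matrix.",
      sum(has_stop)))
    df <- df[!has_stop, , drop = FALSE]
  }
  if (nrow(df) == 0L || sum(df$count) == 0L) {
    abort("No peptides (with nonzero counts) to tally.",
          class = "degronscan_insufficient_data")
  }
  P <- unique(nchar(df$peptide))
  if (length(P) != 1L) {
    abort("All peptides must have the same length.",
          class = "degronscan_config_error")
  }
  w <- if (weight == "read") df$count else rep(1L, nrow(df))
  symbols <- aa_alphabet(include_stop = include_stops)
  per_pos <- lapply(seq_len(P), function(p) {
    letter <- factor(substr(df$peptide, p, p), levels = symbols)
    tot <- tapply(w, letter, sum, default = 0)
    tibble(amino_acid = symbols, position = p,
           frequency = as.numeric(tot) / sum(w))
  })
  new_position_freqs(bind_rows(per_pos),
                     n_reads = sum(df$count), n_peptides = nrow(df),
                     sample_label = attr(counts, "sample_label") %||% NA_character_)
}

#' Assemble a frequency matrix from externally computed values
#'
#' Useful for feeding published per-position frequencies (e.g. a supplementary
#' tally) into the enrichment functions without raw counts.
#'
#' @param df Data frame with columns `amino_acid`, `position`, `frequency`.
#' @param n_reads,n_peptides Optional tally sizes (needed for pseudocount
#'   smoothing).
#' @param sample_label Sample label.
#' @return A `position_freqs` tibble.
#' @export
as_position_freqs <- function(df, n_reads = NA_real_, n_peptides = NA_real_,
                              sample_label = NA_character_) {
  df <- as_tibble(df)
  if (!all(c("amino_acid", "position", "frequency") %in% names(df))) {
    abort("`df` needs columns amino_acid, position, frequency.",
          class = "degronscan_config_error")
  }
  if (any(df$frequency < 0)) {
    abort("Frequencies must be non-negative.",
          class = "degronscan_config_error")
  }
  new_position_freqs(df, n_reads, n_peptides, sample_label)
}

new_enrichment_matrix <- function(df, reference, pseudocount) {
  df <- as_tibble(df)[, c("amino_acid", "position", "fold")]
  attr(df, "reference") <- reference
  attr(df, "pseudocount") <- pseudocount
  class(df) <- c("enrichment_matrix", class(df))
  df
}

# pseudocount smoothing of frequencies: (count + pc) / (n + n_symbols * pc)
smooth_frequency <- function(freq, n, pseudocount, n_symbols) {
  if (pseudocount == 0) return(freq)
  if (is.na(n)) {
    abort("Pseudocount smoothing needs the tally size (n_reads attribute).",
          class = "degronscan_config_error")
  }
  (freq * n + pseudocount) / (n + n_symbols * pseudocount)
}

#' Fold enrichment relative to the degenerate-codon null
#'
#' `fold(aa, p) = freq(aa, p) / null(aa)`: the observed position-wise
#' amino-acid frequency divided by the frequency expected from the number of
#' codons encoding that amino acid in the library's degenerate-codon scheme.
#' With the screen's printed position-1 numbers — isoleucine observed at
#' 17.7% against a 3/64 (4.7%) expectation — this is the 3.8-fold enrichment
#' readout; leucine at 14.8% against 6/64 (9.4%) gives 1.6-fold.
#'
#' @param freqs A `position_freqs` tibble.
#' @param null An `aa_distribution` from [position_null_distribution()]; must
#'   give every tallied amino acid nonzero probability.
#' @param pseudocount Reads added per (amino acid, position) cell before
#'   frequency computation; 0 (the default) reproduces raw printed ratios.
#' @return A tibble of class `enrichment_matrix` with columns `amino_acid`,
#'   `position`, `fold` and attributes `reference = "codon_null"`,
#'   `pseudocount`.
#' @export
enrichment_vs_null <- function(freqs,
                               null = position_null_distribution(codon_scheme("NNN")),
                               pseudocount = 0) {
  stopifnot(inherits(freqs, "position_freqs"),
            inherits(null, "aa_distribution"))
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  aas <- unique(freqs$amino_acid)
  null_p <- setNames(null$probability, null$symbol)[aas]
  if (anyNA(null_p) || any(null_p <= 0)) {
    abort("Null distribution must give every tallied symbol probability > 0.",
          class = "degronscan_config_error")
  }
  n <- attr(freqs, "n_reads") %||% NA_real_
  f <- smooth_frequency(freqs$frequency, n, pseudocount, length(aas))
  new_enrichment_matrix(
    tibble(amino_acid = freqs$amino_acid, position = freqs$position,
           fold = f / unname(null_p[freqs$amino_acid])),
    reference = "codon_null", pseudocount = pseudocount)
}

#' Fold enrichment of a sorted bin relative to the input library
#'
#' `fold(aa, p) = bin_freq(aa, p) / input_freq(aa, p)`. Both matrices are
#' pseudocount-smoothed (default 0.5 reads per cell) so that amino acids
#' absent from the finite input tally cannot blow up the ratio; pass
#' `pseudocount = 0` for raw ratios on large counts.
#'
#' @param bin_freqs,input_freqs `position_freqs` tibbles with identical
#'   dimensions.
#' @param pseudocount Smoothing reads per (amino acid, position) cell.
#' @return A tibble of class `enrichment_matrix` with
#'   `reference = "input_library"`.
#' @export
enrichment_vs_input <- function(bin_freqs, input_freqs, pseudocount = 0.5) {
  stopifnot(inherits(bin_freqs, "position_freqs"),
            inherits(input_freqs, "position_freqs"))
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  if (nrow(bin_freqs) != nrow(input_freqs) ||
      !identical(bin_freqs$amino_acid, input_freqs$amino_acid) ||
      !identical(bin_freqs$position, input_freqs$position)) {
    abort("Bin and input frequency matrices must share dimensions and order.",
          class = "degronscan_shape_error")
  }
  n_sym <- length(unique(bin_freqs$amino_acid))
  fb <- smooth_frequency(bin_freqs$frequency,
                         attr(bin_freqs, "n_reads") %||% NA_real_,
                         pseudocount, n_sym)
  fi <- smooth_frequency(input_freqs$frequency,
                         attr(input_freqs, "n_reads") %||% NA_real_,
                         pseudocount, n_sym)
  if (any(fi == 0)) {
    abort("Input frequencies contain zeros; use a positive pseudocount.",
          class = "degronscan_config_error")
  }
  new_enrichment_matrix(
    tibble(amino_acid = bin_freqs$amino_acid, position = bin_freqs$position,
           fold = fb / fi),
    reference = "input_library", pseudocount = pseudocount)
}

#' Rank candidate peptides by additive log-fold score
#'
#' Scores every observed peptide by the sum over positions of the log fold
#' enrichment of its residues, `score = sum_p log fold(aa_p, p)`, then
#' returns the `top_k` peptides (ties broken by read count, then
#' alphabetically). The score is an explicitly heuristic summary of how well
#' a peptide matches the screen's positional enrichment trends — the screens
#' this models chose candidates by eye.
#'
#' @param counts A `peptide_counts` tibble.
#' @param enr An `enrichment_matrix`.
#' @param top_k Number of candidates to return.
#' @return Tibble `rank`, `peptide`, `count`, `score`.
#' @export
rank_candidates <- function(counts, enr, top_k = 20L) {
  stopifnot(is.data.frame(counts), inherits(enr, "enrichment_matrix"))
  assert_scalar_number(top_k, "top_k", lower = 1)
  if (nrow(counts) == 0L) {
    return(tibble(rank = integer(0), peptide = character(0),
                  count = integer(0), score = numeric(0)))
  }
  P <- max(enr$position)
  log_fold <- setNames(log(enr$fold), paste0(enr$amino_acid, enr$position))
  score_cols <- vapply(seq_len(P), function(p) {
    log_fold[paste0(substr(counts$peptide, p, p), p)]
  }, numeric(nrow(counts)))
  score <- rowSums(matrix(score_cols, nrow = nrow(counts)))
  out <- tibble(peptide = counts$peptide, count = as.integer(counts$count),
                score = score)
  out <- out[order(-out$score, -out$count, out$peptide), ]
  out <- head(out, top_k)
  tibble(rank = seq_len(nrow(out)), out)
}

#' Export an enrichment matrix as a heatmap TSV (and figure)
#'
#' Writes a wide TSV of log2 fold values — amino-acid rows in fixed
#' alphabetical one-letter order, columns `P1..Pn` — plus, optionally, a
#' diverging-scale heatmap figure rendered with [autoplot.enrichment_matrix()].
#'
#' @param enr An `enrichment_matrix`.
#' @param tsv_path Output TSV path.
#' @param figure_path Optional figure path (extension selects the device,
#'   e.g. `.png`, `.svg`, `.pdf`).
#' @return Invisibly, the TSV path.
#' @export
export_heatmap <- function(enr, tsv_path, figure_path = NULL) {
  stopifnot(inherits(enr, "enrichment_matrix"))
  wide <- tidyr::pivot_wider(
    tibble(amino_acid = enr$amino_acid,
           position = paste0("P", enr$position),
           log2_fold = log2(enr$fold)),
    names_from = "position", values_from = "log2_fold")
  ord <- match(aa_alphabet(include_stop = TRUE), wide$amino_acid)
  wide <- wide[ord[!is.na(ord)], ]
  header <- sprintf("# reference=%s pseudocount=%s",
                    attr(enr, "reference"), attr(enr, "pseudocount"))
  body <- readr::format_tsv(wide)
  readr::write_lines(c(header, sub("\n$", "", body)), tsv_path)
  if (!is.null(figure_path)) {
    ggplot2::ggsave(figure_path, autoplot(enr), width = 4.5, height = 6,
                    dpi = 150)
  }
  invisible(tsv_path)
}

#' Read an enrichment heatmap TSV back into an `enrichment_matrix`
#'
#' Inverse of [export_heatmap()]; the round-trip preserves the matrix.
#'
#' @param path TSV path written by [export_heatmap()].
#' @return An `enrichment_matrix` tibble.
#' @export
read_enrichment_tsv <- function(path) {
  lines <- readr::read_lines(path)
  reference <- NA_character_
  pseudocount <- NA_real_
  if (length(lines) > 0 && startsWith(lines[1], "# reference=")) {
    reference <- sub("^# reference=(\\S+).*$", "\\1", lines[1])
    pseudocount <- as.numeric(sub("^.*pseudocount=(\\S+)$", "\\1", lines[1]))
    lines <- lines[-1]
  }
  wide <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                          show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, -"amino_acid",
                              names_to = "position", values_to = "log2_fold")
  new_enrichment_matrix(
    tibble(amino_acid = long$amino_acid,
           position = as.integer(sub("^P", "", long$position)),
           fold = 2^long$log2_fold),
    reference = reference, pseudocount = pseudocount)
}

#' Heatmap of an enrichment matrix
#'
#' Diverging-scale tile plot of log2 fold enrichment: amino acids (fixed
#' order) by position.
#'
#' @param object An `enrichment_matrix`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot enrichment_matrix
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  df <- tibble(
    amino_acid = factor(object$amino_acid,
                        levels = rev(aa_alphabet(include_stop = TRUE))),
    position = factor(paste0("P", object$position),
                      levels = paste0("P", sort(unique(object$position)))),
    log2_fold = log2(object$fold))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$amino_acid,
                                   fill = .data$log2_fold)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  name = expression(log[2] ~ fold)) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = sprintf("Enrichment vs %s",
                                     attr(object, "reference"))) +
    ggplot2::theme_minimal(base_size = 11)
}

#' Effective sample size of a weighted peptide tally
#'
#' Reads from one library member are not independent draws of a peptide:
#' the sampling unit behind a position-frequency estimate is the distinct
#' peptide, weighted by its read count. The Kish effective sample size
#' `(sum w)^2 / sum(w^2)` quantifies how many equally weighted peptides the
#' tally is worth, and is the right `n` for binomial noise envelopes on
#' frequencies and folds.
#'
#' @param counts A `peptide_counts` tibble (or any data frame with a `count`
#'   column).
#' @return A single number, between 1 and the number of distinct peptides.
#' @export
effective_sample_size <- function(counts) {
  stopifnot(is.data.frame(counts), "count" %in% names(counts))
  w <- as.numeric(counts$count)
  w <- w[w > 0]
  if (length(w) == 0L) {
    abort("No nonzero counts.", class = "degronscan_insufficient_data")
  }
  sum(w)^2 / sum(w^2)
}

#' Bootstrap confidence interval for one fold-enrichment cell
#'
#' Percentile bootstrap for `fold(aa, p)` of a sorted bin relative to the
#' input library. Resampling is clustered on distinct peptides (rows of the
#' count tables, carrying their read counts), since reads of one library
#' member are not independent observations of its sequence.
#'
#' @param bin_counts,input_counts `peptide_counts` tibbles.
#' @param amino_acid,position The matrix cell to bootstrap.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param pseudocount Smoothing passed to the frequency ratio.
#' @param seed Optional RNG seed.
#' @return A one-row tibble: `amino_acid`, `position`, `fold`, `lower`,
#'   `upper`, `n_boot`, `conf`.
#' @export
bootstrap_fold_ci <- function(bin_counts, input_counts, amino_acid, position,
                              n_boot = 200L, conf = 0.95, pseudocount = 0.5,
                              seed = NULL) {
  stopifnot(is.data.frame(bin_counts), is.data.frame(input_counts))
  assert_scalar_number(n_boot, "n_boot", lower = 2)
  assert_scalar_number(conf, "conf", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  letter_b <- substr(bin_counts$peptide, position, position) == amino_acid
  letter_i <- substr(input_counts$peptide, position, position) == amino_acid
  wb <- as.numeric(bin_counts$count)
  wi <- as.numeric(input_counts$count)
  fold_of <- function(ib, ii) {
    fb <- (sum(wb[ib][letter_b[ib]]) + pseudocount) /
      (sum(wb[ib]) + 20 * pseudocount)
    fi <- (sum(wi[ii][letter_i[ii]]) + pseudocount) /
      (sum(wi[ii]) + 20 * pseudocount)
    fb / fi
  }
  point <- fold_of(seq_along(wb), seq_along(wi))
  boots <- with_optional_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      fold_of(sample.int(length(wb), replace = TRUE),
              sample.int(length(wi), replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
  tibble(amino_acid = amino_acid, position = as.integer(position),
         fold = point, lower = ci[1], upper = ci[2],
         n_boot = as.integer(n_boot), conf = conf)
}
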