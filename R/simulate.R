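# Default amplicon flanks: fixed arbitrary sequences satisfying the 217-bp
# geometry (101 + 15 + 101). Real screens supply their own layout; everything
# downstream is anchored on configurable subsequences of these.
default_upstream_flank <- function() {
  paste0("AAAGTGTATGGGGTCTAGAGCTGGGTGCTGAATTGTAGCAGGGAACCGGTA",
         "CCTAAGTCGGCTTGAACATCGGTTCATAGATAGAGCAATAAACCTCCCGT")
}
default_downstream_flank <- function() {
  paste0("GGGGACCCGCGCCGCAGTCCTTTGCTGACCCGAACCTAACCGCAGCGTTCC",
         "AATTGCACAATCGCGCAAAATGTTGTGTTGACGGTGAGAACGAAAGGCGT")
}

#' Tandem-fluorescent-timer (tFT) readout parameters
#'
#' The reporter fuses a fast-maturing GFP to a slow-maturing mCherry; since
#' degradation removes both fluorophores but immature mCherry has not yet
#' become visible, faster turnover lowers the mature mCherry/GFP ratio.
#' Defaults take maturation half-times of 6 min (superfast GFP) and 40 min
#' (mCherry).
#'
#' @param m_gfp,m_cherry First-order maturation rates (1/min);
#'   `m_cherry < m_gfp` is required (mCherry is the slow partner).
#' @param cell_noise_cv Standard deviation of the per-cell log mCherry/GFP
#'   ratio around its variant mean (coefficient of variation of the ratio).
#' @param nonfluorescent_fraction,dead_fraction Probabilities that a cell
#'   fails the "mCherry-GFP positive" or "live" cytometry gates.
#' @return An object of class `tft_params`.
#' @export
tft_params <- function(m_gfp = log(2) / 6, m_cherry = log(2) / 40,
                       cell_noise_cv = 0.3,
                       nonfluorescent_fraction = 0.1, dead_fraction = 0.05) {
  assert_scalar_number(m_gfp, "m_gfp", lower = 0, strict_lower = TRUE)
  assert_scalar_number(m_cherry, "m_cherry", lower = 0, strict_lower = TRUE)
  if (m_cherry >= m_gfp) {
    abort("`m_cherry` must be smaller than `m_gfp` (slow-maturing partner).",
          class = "degronscan_config_error")
  }
  assert_scalar_number(cell_noise_cv, "cell_noise_cv", lower = 0)
  assert_scalar_number(nonfluorescent_fraction, "nonfluorescent_fraction",
                       lower = 0, upper = 1, strict_upper = TRUE)
  assert_scalar_number(dead_fraction, "dead_fraction",
                       lower = 0, upper = 1, strict_upper = TRUE)
  structure(list(m_gfp = m_gfp, m_cherry = m_cherry,
                 cell_noise_cv = cell_noise_cv,
                 nonfluorescent_fraction = nonfluorescent_fraction,
                 dead_fraction = dead_fraction),
            class = "tft_params")
}

#' Steady-state tFT ratio as a function of degradation rate
#'
#' Under constant synthesis, first-order maturation (rates `m_gfp`,
#' `m_cherry`) and first-order degradation at rate `k`, the steady-state
#' mature-fluorophore ratio, normalized so that a non-degraded protein reads
#' 1, is
#' \deqn{R(k) = \frac{m_c (m_g + k)}{m_g (m_c + k)}.}
#' R is strictly decreasing in `k` whenever `m_cherry < m_gfp`, with limit
#' `m_cherry / m_gfp` as `k` grows: the lower the ratio, the more unstable
#' the protein.
#'
#' @param k_deg Degradation rate(s), 1/min, non-negative (`Inf` allowed).
#' @param params A [tft_params()] object.
#' @return Numeric vector of normalized mCherry/GFP ratios in
#'   (`m_cherry/m_gfp`, 1].
#' @examples
#' tft_ratio(0)            # 1
#' tft_ratio(log(2) / 30)  # < 1
#' @export
tft_ratio <- function(k_deg, params = tft_params()) {
  stopifnot(inherits(params, "tft_params"))
  if (!is.numeric(k_deg) || anyNA(k_deg) || any(k_deg < 0)) {
    abort("`k_deg` must be non-negative.", class = "degronscan_domain_error")
  }
  mc <- params$m_cherry
  mg <- params$m_gfp
  out <- (mc * (mg + k_deg)) / (mg * (mc + k_deg))
  out[is.infinite(k_deg)] <- mc / mg
  out
}

#' Sort configuration
#'
#' @param unstable_bin_fraction Fraction of gated cells collected into the
#'   low-ratio "unstable" bin (0.04 in the screen this package models).
#' @param n_cells Number of cells drawn from the library.
#' @param seed Optional RNG seed for the cell draw.
#' @return An object of class `sort_config`.
#' @export
sort_config <- function(unstable_bin_fraction = 0.04, n_cells = 1e6,
                        seed = NULL) {
  assert_scalar_number(unstable_bin_fraction, "unstable_bin_fraction",
                       lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(n_cells, "n_cells", lower = 1)
  structure(list(unstable_bin_fraction = unstable_bin_fraction,
                 n_cells = as.integer(n_cells), seed = seed),
            class = "sort_config")
}

#' Simulate a degenerate-codon peptide library with planted ground truth
#'
#' Draws `n_variants` DNA inserts i.i.d. per position from the scheme's
#' nucleotide alphabets, translates them, assigns each variant a degradation
#' rate from the stability rule, and gives the pool uneven pre-sort
#' abundances (lognormal by default, mimicking uneven transformation).
#'
#' In `exhaustive` mode the function instead enumerates every peptide class
#' the scheme can encode (one representative insert each) with abundance
#' proportional to its codon multiplicity — the analytic limit of infinite
#' sampling, used for oracle checks.
#'
#' @param n_variants Number of library members to draw.
#' @param scheme A [codon_scheme()].
#' @param rule A [stability_rule()].
#' @param abundance `"lognormal"`, `"dirichlet"`, or `"uniform"`.
#' @param abundance_param `sdlog` of the lognormal or the Dirichlet
#'   concentration.
#' @param exhaustive Enumerate all peptide classes instead of sampling.
#' @param seed Optional RNG seed.
#' @param code Genetic code.
#' @return A tibble with one row per variant: `variant_id`, `dna_insert`,
#'   `peptide`, `k_deg`, `input_abundance` (sums to 1).
#' @export
sample_library <- function(n_variants, scheme = codon_scheme("NNN"),
                           rule = stability_rule(),
                           abundance = c("lognormal", "dirichlet", "uniform"),
                           abundance_param = 1, exhaustive = FALSE,
                           seed = NULL, code = standard_genetic_code()) {
  abundance <- match.arg(abundance)
  stopifnot(inherits(scheme, "codon_scheme"), inherits(rule, "stability_rule"))
  if (exhaustive) {
    return(exhaustive_library(scheme, rule, code))
  }
  assert_scalar_number(n_variants, "n_variants", lower = 1)
  n_variants <- as.integer(n_variants)
  with_optional_seed(seed, {
    n_nt <- 3L * scheme$num_codon_positions
    cols <- lapply(seq_len(n_nt), function(j) {
      alph <- scheme$position_alphabets[[(j - 1L) %% 3L + 1L]]
      if (length(alph) == 1L) rep(alph, n_variants)
      else alph[sample.int(length(alph), n_variants, replace = TRUE)]
    })
    dna <- do.call(paste0, cols)
    w <- switch(abundance,
      lognormal = rlnorm(n_variants, meanlog = 0, sdlog = abundance_param),
      dirichlet = rgamma(n_variants, shape = abundance_param, rate = 1),
      uniform = rep(1, n_variants))
    pep <- translate_dna(dna, code)
    tibble(variant_id = sprintf("v%07d", seq_len(n_variants)),
           dna_insert = dna,
           peptide = pep,
           k_deg = degradation_rate(rule, pep),
           input_abundance = w / sum(w))
  })
}

# Enumerate all peptide classes of a scheme, weighted by codon multiplicity.
exhaustive_library <- function(scheme, rule, code) {
  aa <- code[scheme$codons]
  mult <- table(aa)
  symbols <- names(mult)
  # representative codon per symbol (first in enumeration order)
  rep_codon <- scheme$codons[!duplicated(aa)]
  names(rep_codon) <- aa[!duplicated(aa)]
  P <- scheme$num_codon_positions
  grid <- do.call(expand.grid,
                  c(rep(list(seq_along(symbols)), P),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  pep_cols <- lapply(seq_len(P), function(p) symbols[grid[[p]]])
  pep <- do.call(paste0, pep_cols)
  dna <- do.call(paste0, lapply(seq_len(P), function(p) {
    unname(rep_codon[symbols[grid[[p]]]])
  }))
  w <- Reduce(`*`, lapply(seq_len(P), function(p) {
    as.numeric(mult)[grid[[p]]]
  }))
  tibble(variant_id = sprintf("v%07d", seq_len(nrow(grid))),
         dna_insert = dna,
         peptide = pep,
         k_deg = degradation_rate(rule, pep),
         input_abundance = w / sum(w))
}

#' Simulate per-cell flow-cytometry observations of a library
#'
#' Draws cells from the library in proportion to input abundance, gives each
#' a noisy observed log mCherry/GFP ratio centered on the steady-state tFT
#' ratio for its variant, and flags cells that fail the live and
#' fluorescence-positive gates. Only gated cells (`gated == TRUE`) are
#' eligible for sorting.
#'
#' @param library Tibble from [sample_library()].
#' @param params A [tft_params()].
#' @param sort A [sort_config()]; supplies `n_cells` and (optionally) `seed`.
#' @return Tibble with one row per cell: `cell_id`, `variant_id`, `k_deg`,
#'   `log_ratio`, `live`, `fluorescent`, `gated`.
#' @export
simulate_cells <- function(library, params = tft_params(),
                           sort = sort_config()) {
  stopifnot(is.data.frame(library), nrow(library) > 0,
            inherits(params, "tft_params"), inherits(sort, "sort_config"))
  n <- sort$n_cells
  with_optional_seed(sort$seed, {
    idx <- sample.int(nrow(library), n, replace = TRUE,
                      prob = library$input_abundance)
    mu <- log(tft_ratio(library$k_deg[idx], params))
    noise <- if (params$cell_noise_cv > 0) {
      rnorm(n, 0, params$cell_noise_cv)
    } else 0
    live <- runif(n) >= params$dead_fraction
    fluorescent <- runif(n) >= params$nonfluorescent_fraction
    tibble(cell_id = seq_len(n),
           variant_id = library$variant_id[idx],
           k_deg = library$k_deg[idx],
           log_ratio = mu + noise,
           live = live,
           fluorescent = fluorescent,
           gated = live & fluorescent)
  })
}

#' Sort the unstable (low-ratio) bin from a simulated cell table
#'
#' The unstable bin is the `unstable_bin_fraction` quantile tail of observed
#' log mCherry/GFP ratio among gated cells: the `round(fraction * n_gated)`
#' cells with the lowest ratios. The input pool is the full gated population.
#'
#' @param cells Tibble from [simulate_cells()].
#' @param sort A [sort_config()].
#' @return A list with tibbles `unstable` (the sorted bin) and `input` (all
#'   gated cells), each a multiset of cells carrying `variant_id`.
#' @export
sort_unstable_bin <- function(cells, sort = sort_config()) {
  stopifnot(is.data.frame(cells), inherits(sort, "sort_config"))
  gated <- dplyr::filter(cells, .data$gated)
  f <- sort$unstable_bin_fraction
  if (nrow(gated) < 1 / f) {
    abort(sprintf(
      "Too few gated cells (%d) for a bin fraction of %g.", nrow(gated), f),
      class = "degronscan_insufficient_data")
  }
  k <- round(f * nrow(gated))
  ord <- order(gated$log_ratio)
  list(unstable = gated[ord[seq_len(k)], , drop = FALSE],
       input = gated)
}

#' Amplicon read-simulation configuration
#'
#' Reads are the variable region embedded in constant flanks (default
#' geometry: 101 + 15 + 101 = 217 bp), with i.i.d. substitution sequencing
#' errors and Phred+33 qualities drawn per read from a clamped normal model.
#'
#' @param upstream_flank,downstream_flank Constant DNA flanks.
#' @param variable_length Length of the randomized region (nt).
#' @param amplicon_length Total read length; must equal
#'   `nchar(upstream_flank) + variable_length + nchar(downstream_flank)`.
#' @param reads_per_sample Reads to emit per sample.
#' @param substitution_error_rate Per-base substitution probability.
#' @param quality_mean,quality_sd Per-read Phred quality model (clamped to
#'   \[2, 40\]).
#' @param seed Optional RNG seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(upstream_flank = default_upstream_flank(),
                            downstream_flank = default_downstream_flank(),
                            variable_length = 15L,
                            amplicon_length = nchar(upstream_flank) +
                              variable_length + nchar(downstream_flank),
                            reads_per_sample = 5e5,
                            substitution_error_rate = 0.001,
                            quality_mean = 35, quality_sd = 3,
                            seed = NULL) {
  assert_dna_string(upstream_flank, "upstream_flank")
  assert_dna_string(downstream_flank, "downstream_flank")
  assert_scalar_number(variable_length, "variable_length", lower = 3)
  assert_scalar_number(reads_per_sample, "reads_per_sample", lower = 0)
  assert_scalar_number(substitution_error_rate, "substitution_error_rate",
                       lower = 0, upper = 1, strict_upper = TRUE)
  assert_scalar_number(quality_mean, "quality_mean", lower = 2, upper = 40)
  assert_scalar_number(quality_sd, "quality_sd", lower = 0)
  if (nchar(upstream_flank) + variable_length + nchar(downstream_flank) !=
      amplicon_length) {
    abort("Flank lengths + variable_length must equal amplicon_length.",
          class = "degronscan_config_error")
  }
  structure(list(upstream_flank = upstream_flank,
                 downstream_flank = downstream_flank,
                 variable_length = as.integer(variable_length),
                 amplicon_length = as.integer(amplicon_length),
                 reads_per_sample = as.integer(reads_per_sample),
                 substitution_error_rate = substitution_error_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 seed = seed),
            class = "read_sim_config")
}

# apply i.i.d. substitution errors to equal-length reads, vectorized by
# error rank so duplicate assignments to one read cannot collide
apply_substitutions <- function(reads, width, rate) {
  if (rate == 0 || length(reads) == 0L) return(reads)
  n_err <- rbinom(length(reads), width, rate)
  max_err <- max(n_err)
  if (max_err == 0L) return(reads)
  bases <- c("A", "C", "G", "T")
  for (r in seq_len(max_err)) {
    i <- which(n_err >= r)
    pos <- sample.int(width, length(i), replace = TRUE)
    cur <- substr(reads[i], pos, pos)
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3L, length(i), replace = TRUE)
    new <- bases[(match(cur, bases) - 1L + shift) %% 4L + 1L]
    stringr::str_sub(reads[i], pos, pos) <- new
  }
  reads
}

#' Emit amplicon FASTQ reads for a variant multiset
#'
#' Each read is `upstream_flank + insert + downstream_flank` with i.i.d.
#' substitution errors and per-read Phred+33 qualities. A ground-truth TSV
#' mapping read id to variant id (and true peptide) can be written alongside.
#' An empty multiset yields a valid empty FASTQ with a warning.
#'
#' @param variants Tibble with columns `variant_id` and `dna_insert`; one row
#'   per sorted cell (reads are resampled from these rows with replacement).
#' @param cfg A [read_sim_config()].
#' @param fastq_path Output FASTQ path (`.gz` supported).
#' @param truth_path Optional ground-truth TSV path.
#' @param read_prefix Prefix for read identifiers.
#' @return `fastq_path`, invisibly.
#' @export
emit_amplicon_reads <- function(variants, cfg = read_sim_config(),
                                fastq_path, truth_path = NULL,
                                read_prefix = "read") {
  stopifnot(is.data.frame(variants), inherits(cfg, "read_sim_config"))
  if (!all(c("variant_id", "dna_insert") %in% names(variants))) {
    abort("`variants` needs columns variant_id and dna_insert.",
          class = "degronscan_config_error")
  }
  if (any(nchar(variants$dna_insert) != cfg$variable_length)) {
    abort("All inserts must match cfg$variable_length.",
          class = "degronscan_config_error")
  }
  n <- if (nrow(variants) == 0L) 0L else cfg$reads_per_sample
  if (n == 0L) {
    warn(sprintf("Writing empty FASTQ to %s (no reads requested or empty multiset).",
                 fastq_path))
    readr::write_lines(character(0), fastq_path)
    if (!is.null(truth_path)) {
      readr::write_tsv(tibble(read_id = character(0), variant_id = character(0)),
                       truth_path)
    }
    return(invisible(fastq_path))
  }
  with_optional_seed(cfg$seed, {
    rows <- sample.int(nrow(variants), n, replace = TRUE)
    reads <- paste0(cfg$upstream_flank, variants$dna_insert[rows],
                    cfg$downstream_flank)
    reads <- apply_substitutions(reads, cfg$amplicon_length,
                                 cfg$substitution_error_rate)
    q <- round(rnorm(n, cfg$quality_mean, cfg$quality_sd))
    q <- pmin(pmax(q, 2L), 40L)
    qual_chars <- vapply(2:40, function(s) intToUtf8(s + 33L), "")
    quals <- strrep(qual_chars[q - 1L], cfg$amplicon_length)
    ids <- paste0(read_prefix, seq_len(n))
    out <- character(4L * n)
    out[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
    out[seq(2L, by = 4L, length.out = n)] <- reads
    out[seq(3L, by = 4L, length.out = n)] <- "+"
    out[seq(4L, by = 4L, length.out = n)] <- quals
    readr::write_lines(out, fastq_path)
    if (!is.null(truth_path)) {
      readr::write_tsv(tibble(read_id = ids,
                              variant_id = variants$variant_id[rows]),
                       truth_path)
    }
  })
  invisible(fastq_path)
}
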