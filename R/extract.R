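#' Amplicon layout for variable-region extraction
#'
#' Describes where the randomized region sits in a read: the constant anchor
#' sequences immediately flanking it, its length, the Hamming-distance
#' tolerance for anchor matching, and the read-level mean-quality filter.
#' Anchor matching is substitution-only at fixed spacing (no indel
#' alignment): reads carrying indels fail the spacing constraint and are
#' dropped, matching the substitution-only error model.
#'
#' @param upstream_anchor,downstream_anchor DNA strings immediately flanking
#'   the variable region.
#' @param variable_length Variable-region length in nucleotides (a positive
#'   multiple of 3).
#' @param max_anchor_mismatches Maximum Hamming mismatches tolerated per
#'   anchor.
#' @param min_mean_quality Minimum read mean Phred quality.
#' @return An object of class `amplicon_layout`.
#' @export
amplicon_layout <- function(upstream_anchor, downstream_anchor,
                            variable_length = 15L,
                            max_anchor_mismatches = 1L,
                            min_mean_quality = 20) {
  assert_dna_string(upstream_anchor, "upstream_anchor")
  assert_dna_string(downstream_anchor, "downstream_anchor")
  assert_scalar_number(variable_length, "variable_length", lower = 3)
  if (variable_length %% 3 != 0) {
    abort("`variable_length` must be a multiple of 3.",
          class = "degronscan_config_error")
  }
  assert_scalar_number(max_anchor_mismatches, "max_anchor_mismatches", lower = 0)
  assert_scalar_number(min_mean_quality, "min_mean_quality", lower = 0)
  structure(list(upstream_anchor = upstream_anchor,
                 downstream_anchor = downstream_anchor,
                 variable_length = as.integer(variable_length),
                 max_anchor_mismatches = as.integer(max_anchor_mismatches),
                 min_mean_quality = min_mean_quality),
            class = "amplicon_layout")
}

#' Default layout matching the simulator's read geometry
#'
#' Anchors on the `anchor_length` nucleotides of constant flank immediately
#' adjacent to the variable region.
#'
#' @param cfg A [read_sim_config()].
#' @param anchor_length Anchor length in nucleotides.
#' @param ... Passed on to [amplicon_layout()].
#' @return An [amplicon_layout()].
#' @export
default_layout <- function(cfg = read_sim_config(), anchor_length = 20L, ...) {
  up <- cfg$upstream_flank
  dn <- cfg$downstream_flank
  amplicon_layout(
    upstream_anchor = substr(up, nchar(up) - anchor_length + 1L, nchar(up)),
    downstream_anchor = substr(dn, 1L, anchor_length),
    variable_length = cfg$variable_length, ...)
}

#' Locate the variable region in reads by flank anchoring
#'
#' Finds, per read, the unique placement where both anchors match within
#' `max_anchor_mismatches` (Hamming distance) and are separated by exactly
#' `variable_length` nucleotides. Reads with zero or multiple candidate
#' placements are anchor failures. Coordinates are 1-based inclusive on the
#' read (the R string convention used throughout the package).
#'
#' @param reads Character vector or `Biostrings::DNAStringSet`.
#' @param layout An [amplicon_layout()].
#' @return Tibble with one row per read: `read_index`, `var_start`,
#'   `var_end` (NA when anchoring failed) and `n_candidates`.
#' @export
locate_flanks <- function(reads, layout) {
  stopifnot(inherits(layout, "amplicon_layout"))
  subj <- if (is.character(reads)) {
    if (length(reads) > 0 && any(grepl("[^ACGTN]", reads))) {
      abort("Reads may only contain A, C, G, T, N.",
            class = "degronscan_alphabet_error")
    }
    Biostrings::DNAStringSet(reads)
  } else {
    methods::as(reads, "DNAStringSet")
  }
  n <- length(subj)
  if (n == 0L) {
    return(tibble(read_index = integer(0), var_start = integer(0),
                  var_end = integer(0), n_candidates = integer(0)))
  }
  lu <- nchar(layout$upstream_anchor)
  vl <- layout$variable_length
  mm <- layout$max_anchor_mismatches
  mU <- Biostrings::vmatchPattern(layout$upstream_anchor, subj,
                                  max.mismatch = mm, fixed = TRUE)
  mD <- Biostrings::vmatchPattern(layout$downstream_anchor, subj,
                                  max.mismatch = mm, fixed = TRUE)
  sU <- Biostrings::startIndex(mU)
  sD <- Biostrings::startIndex(mD)
  lenU <- lengths(sU)
  lenD <- lengths(sD)
  # encode (read, position) pairs as integer keys; positions < 10^4 assumed
  keymul <- 10000
  readU <- rep.int(seq_len(n), lenU)
  posU <- unlist(sU, use.names = FALSE)
  keysD <- rep.int(seq_len(n), lenD) * keymul + unlist(sD, use.names = FALSE)
  ok <- ((readU * keymul) + posU + lu + vl) %in% keysD
  n_cand <- tabulate(readU[ok], nbins = n)
  var_start <- rep(NA_integer_, n)
  uniq <- which(n_cand == 1L)
  hit_reads <- readU[ok]
  hit_pos <- posU[ok]
  first_hit <- hit_pos[match(uniq, hit_reads)]
  var_start[uniq] <- first_hit + lu
  tibble(read_index = seq_len(n),
         var_start = var_start,
         var_end = var_start + vl - 1L,
         n_candidates = n_cand)
}

new_peptide_counts <- function(df, sample_label = NA_character_) {
  df <- as_tibble(df)
  stopifnot(all(c("peptide", "count") %in% names(df)))
  df <- df[order(-df$count, df$peptide), c("peptide", "count")]
  df$count <- as.integer(df$count)
  attr(df, "sample_label") <- sample_label
  class(df) <- c("peptide_counts", class(df))
  df
}

#' Build a peptide count table
#'
#' Constructor for the `peptide_counts` tibble used throughout the
#' enrichment module: one row per distinct peptide with its read count,
#' sorted by descending count then peptide, with a `sample_label` attribute.
#'
#' @param peptide Character vector of peptides (equal length).
#' @param count Non-negative integer read counts.
#' @param sample_label Label of the sample the counts came from.
#' @return A `peptide_counts` tibble.
#' @export
peptide_counts <- function(peptide, count, sample_label = NA_character_) {
  if (length(peptide) != length(count)) {
    abort("`peptide` and `count` must have equal length.",
          class = "degronscan_config_error")
  }
  if (length(peptide) > 0 && length(unique(nchar(peptide))) > 1L) {
    abort("All peptides must have the same length.",
          class = "degronscan_config_error")
  }
  if (any(count < 0) || any(count != round(count))) {
    abort("Counts must be non-negative integers.",
          class = "degronscan_config_error")
  }
  if (anyDuplicated(peptide)) {
    agg <- tapply(count, peptide, sum)
    peptide <- names(agg)
    count <- as.integer(agg)
  }
  new_peptide_counts(tibble(peptide = peptide, count = count), sample_label)
}

read_fastq_records <- function(path) {
  # Returns list(seq = character, mean_quality = numeric). Uses Biostrings for
  # parsing (handles gzip); an empty file yields zero records.
  if (!file.exists(path)) {
    abort(sprintf("FASTQ file not found: %s", path),
          class = "degronscan_io_error")
  }
  reads <- tryCatch(
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        # benign notice about dropping (unused) mcols during parsing
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) {
      abort(sprintf("Malformed FASTQ %s: %s", path, conditionMessage(e)),
            class = "degronscan_parse_error")
    })
  if (length(reads) == 0L) {
    return(list(seq = character(0), mean_quality = numeric(0)))
  }
  qints <- methods::as(Biostrings::quality(reads), "IntegerList")
  # as.character drops the (unused) quality metadata; silence that notice
  seqs <- suppressWarnings(unname(as.character(reads)))
  list(seq = seqs,
       mean_quality = unname(BiocGenerics::mean(qints)))
}

#' Extract, translate and classify amplicon reads
#'
#' The full read-to-peptide accounting: reads failing the mean-quality filter
#' are dropped first; survivors are anchored with [locate_flanks()]; variable
#' regions containing non-ACGT bases are dropped as ambiguous; the remainder
#' are translated. Peptides containing a stop are tallied separately from the
#' main (sense-only) count table. The report categories are disjoint and sum
#' to the number of input reads — no read silently vanishes.
#'
#' @param fastq Path to a FASTQ file (Phred+33; plain or gzip), or a
#'   character vector of read sequences (then no quality filtering applies).
#' @param layout An [amplicon_layout()].
#' @param code Genetic code.
#' @param sample_label Label recorded on the count tables (defaults to the
#'   FASTQ file name).
#' @return A list with elements `counts` (a `peptide_counts` tibble of
#'   sense peptides), `stop_counts` (same shape, stop-containing peptides)
#'   and `report` (one-row tibble: `n_reads`, `n_quality_fail`,
#'   `n_anchor_fail`, `n_ambiguous_base`, `n_stop_containing`, `n_valid`).
#' @export
extract_and_classify <- function(fastq, layout, code = standard_genetic_code(),
                                 sample_label = NULL) {
  stopifnot(inherits(layout, "amplicon_layout"))
  if (is.character(fastq) && length(fastq) == 1L &&
      (file.exists(fastq) || grepl("\\.(fastq|fq)(\\.gz)?$", fastq))) {
    rec <- read_fastq_records(fastq)
    seqs <- rec$seq
    meanq <- rec$mean_quality
    if (is.null(sample_label)) {
      sample_label <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
    }
  } else {
    seqs <- as.character(fastq)
    meanq <- rep(Inf, length(seqs))
    if (is.null(sample_label)) sample_label <- NA_character_
  }
  n_reads <- length(seqs)
  quality_ok <- meanq >= layout$min_mean_quality
  n_quality_fail <- sum(!quality_ok)

  qseqs <- seqs[quality_ok]
  loc <- locate_flanks(qseqs, layout)
  anchored <- !is.na(loc$var_start)
  n_anchor_fail <- sum(!anchored)

  var <- substr(qseqs[anchored], loc$var_start[anchored], loc$var_end[anchored])
  ambiguous <- grepl("[^ACGT]", var)
  n_ambiguous <- sum(ambiguous)

  pep <- if (any(!ambiguous)) translate_dna(var[!ambiguous], code) else character(0)
  has_stop <- grepl("*", pep, fixed = TRUE)
  n_stop <- sum(has_stop)
  n_valid <- sum(!has_stop)

  tally <- function(x) {
    if (length(x) == 0L) {
      return(new_peptide_counts(tibble(peptide = character(0),
                                       count = integer(0)), sample_label))
    }
    tt <- table(x)
    new_peptide_counts(tibble(peptide = names(tt), count = as.integer(tt)),
                       sample_label)
  }
  report <- tibble(sample_label = sample_label,
                   n_reads = n_reads,
                   n_quality_fail = n_quality_fail,
                   n_anchor_fail = n_anchor_fail,
                   n_ambiguous_base = n_ambiguous,
                   n_stop_containing = n_stop,
                   n_valid = n_valid)
  list(counts = tally(pep[!has_stop]),
       stop_counts = tally(pep[has_stop]),
       report = report)
}

#' Write / read peptide count tables as TSV
#'
#' The TSV round-trip is lossless: a `# sample_label=` comment line carries
#' the label, rows are sorted by descending count then peptide, and
#' [read_counts()] validates peptide length and count integrity, reporting
#' the offending line number on failure.
#'
#' @param counts A `peptide_counts` tibble.
#' @param path TSV path.
#' @return `path` (write) or a `peptide_counts` tibble (read).
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "peptide_counts"))
  label <- attr(counts, "sample_label") %||% NA_character_
  header <- sprintf("# sample_label=%s", label)
  readr::write_lines(c(header, "peptide\tcount",
                       sprintf("%s\t%d", counts$peptide, counts$count)), path)
  invisible(path)
}

#' @rdname write_counts
#' @param expected_length Required peptide length (default 5, the
#'   pentapeptide screen); `NULL` only requires a uniform length.
#' @export
read_counts <- function(path, expected_length = 5L) {
  if (!file.exists(path)) {
    abort(sprintf("Counts file not found: %s", path),
          class = "degronscan_io_error")
  }
  lines <- readr::read_lines(path)
  label <- NA_character_
  body_start <- 1L
  if (length(lines) > 0 && startsWith(lines[1], "# sample_label=")) {
    label <- sub("^# sample_label=", "", lines[1])
    if (label == "NA") label <- NA_character_
    body_start <- 2L
  }
  if (length(lines) < body_start || lines[body_start] != "peptide\tcount") {
    abort(sprintf("%s: missing 'peptide\\tcount' header.", path),
          class = "degronscan_parse_error")
  }
  data_lines <- lines[seq.int(body_start + 1L, length.out = length(lines) - body_start)]
  if (length(data_lines) == 0L) {
    return(new_peptide_counts(tibble(peptide = character(0), count = integer(0)),
                              label))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: expected 2 tab-separated fields.",
                  path, body_start + bad[1]),
          class = "degronscan_parse_error")
  }
  pep <- vapply(parts, `[[`, "", 1L)
  cnt <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(cnt) | cnt < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: count is not a non-negative integer.",
                  path, body_start + bad[1]),
          class = "degronscan_parse_error")
  }
  plen <- nchar(pep)
  ref_len <- if (is.null(expected_length)) plen[1] else expected_length
  bad <- which(plen != ref_len |
                 grepl(sprintf("[^%s*]", paste(aa_alphabet(), collapse = "")), pep))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: malformed peptide '%s'.",
                  path, body_start + bad[1], pep[bad[1]]),
          class = "degronscan_parse_error")
  }
  new_peptide_counts(tibble(peptide = pep, count = cnt), label)
}
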