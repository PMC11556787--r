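nnn_null <- position_null_distribution(codon_scheme("NNN"))

test_that("position frequencies are read-weighted occurrence fractions", {
  single <- peptide_counts("IHPYW", 3L)
  f <- position_frequencies(single)
  get <- function(aa, p) f$frequency[f$amino_acid == aa & f$position == p]
  expect_identical(get("I", 1), 1)
  expect_identical(get("H", 2), 1)
  expect_identical(sum(f$frequency), 5)  # columns each sum to 1

  two <- peptide_counts(c("IAAAA", "LAAAA"), c(1L, 1L))
  f2 <- position_frequencies(two)
  get2 <- function(aa, p) f2$frequency[f2$amino_acid == aa & f2$position == p]
  expect_identical(get2("I", 1), 0.5)
  expect_identical(get2("L", 1), 0.5)
  expect_identical(get2("A", 2), 1)

  # read weighting vs unique-peptide weighting
  skewed <- peptide_counts(c("IAAAA", "LAAAA"), c(3L, 1L))
  fr <- position_frequencies(skewed)
  fp <- position_frequencies(skewed, weight = "peptide")
  expect_identical(fr$frequency[fr$amino_acid == "I" & fr$position == 1], 0.75)
  expect_identical(fp$frequency[fp$amino_acid == "I" & fp$position == 1], 0.5)

  expect_error(position_frequencies(peptide_counts(character(0), integer(0))),
               class = "degronscan_insufficient_data")
})

test_that("exhaustive NNN library frequencies equal the codon null", {
  sch <- codon_scheme("NNN", num_codon_positions = 2L)
  lib <- sample_library(1, scheme = sch, exhaustive = TRUE)
  # integer codon-multiplicity weights: 64^2 total
  counts <- peptide_counts(lib$peptide,
                           as.integer(round(lib$input_abundance * 64^2)))
  suppressMessages(f <- position_frequencies(counts, include_stops = TRUE))
  null_p <- setNames(nnn_null$probability, nnn_null$symbol)
  for (p in 1:2) {
    col <- f[f$position == p, ]
    expect_equal(setNames(col$frequency, col$amino_acid)[names(null_p)],
                 null_p, tolerance = 1e-12)
  }
})

test_that("enrichment vs null reproduces the screen's printed worked examples", {
  # P1 frequencies as printed: Ile 17.7%, Leu 14.8%; null 3/64 and 6/64
  freqs <- as_position_freqs(tibble::tibble(
    amino_acid = c("I", "L"), position = 1L, frequency = c(0.177, 0.148)))
  enr <- enrichment_vs_null(freqs, nnn_null, pseudocount = 0)
  fold <- setNames(enr$fold, enr$amino_acid)
  expect_equal(round(fold[["I"]], 1), 3.8)
  expect_equal(round(fold[["L"]], 1), 1.6)
})

test_that("enrichment identities and the reconstruction invariant hold", {
  lib <- sample_library(300, seed = 61)
  counts <- peptide_counts(lib$peptide[!grepl("*", lib$peptide, fixed = TRUE)],
                           rep(1L, sum(!grepl("*", lib$peptide, fixed = TRUE))))
  f <- position_frequencies(counts)
  # freq equal to null everywhere -> all folds 1
  null_as_freqs <- as_position_freqs(tidyr::crossing(
    position = 1:5,
    tibble::tibble(amino_acid = nnn_null$symbol,
                   frequency = nnn_null$probability)) |>
      dplyr::filter(amino_acid != "*"))
  enr_id <- enrichment_vs_null(null_as_freqs, nnn_null, pseudocount = 0)
  expect_equal(enr_id$fold, rep(1, nrow(enr_id)))
  # sum over amino acids of fold * null = sum freq = 1 (pseudocount 0)
  enr <- enrichment_vs_null(f, nnn_null, pseudocount = 0)
  null_p <- setNames(nnn_null$probability, nnn_null$symbol)
  recon <- tapply(enr$fold * null_p[enr$amino_acid], enr$position, sum)
  expect_equal(as.numeric(recon), rep(1, 5), tolerance = 1e-9)
  # input against itself is identically 1
  self <- enrichment_vs_input(f, f, pseudocount = 0.5)
  expect_equal(self$fold, rep(1, nrow(self)))
  # forced arithmetic
  bin <- as_position_freqs(tibble::tibble(amino_acid = "I", position = 1L,
                                          frequency = 0.2))
  inp <- as_position_freqs(tibble::tibble(amino_acid = "I", position = 1L,
                                          frequency = 0.1))
  expect_identical(enrichment_vs_input(bin, inp, pseudocount = 0)$fold, 2)
  # dimension mismatch
  expect_error(enrichment_vs_input(f, bin), class = "degronscan_shape_error")
})

test_that("hard-threshold selection enrichment matches the analytic oracle", {
  # Selection: keep exactly the peptides with I or L at P1 (noise-free rule).
  # Analytic fold vs input for I at P1 is P(I|sel)/P(I) computed from class
  # probabilities over sense peptides; the pipeline estimate from counts must
  # agree within binomial sampling error.
  set.seed(71)
  lib <- sample_library(20000, rule = planted_ile_leu_rule(), seed = 72,
                        abundance = "uniform")
  lib <- dplyr::filter(lib, !grepl("*", peptide, fixed = TRUE))
  sel <- substr(lib$peptide, 1, 1) %in% c("I", "L")
  counts_in <- peptide_counts(lib$peptide, rep(1L, nrow(lib)))
  counts_bin <- peptide_counts(lib$peptide[sel], rep(1L, sum(sel)))
  f_in <- position_frequencies(counts_in)
  f_bin <- position_frequencies(counts_bin)
  enr <- enrichment_vs_input(f_bin, f_in, pseudocount = 0)
  p_I <- f_in$frequency[f_in$amino_acid == "I" & f_in$position == 1]
  p_L <- f_in$frequency[f_in$amino_acid == "L" & f_in$position == 1]
  oracle_I <- (p_I / (p_I + p_L))  / p_I
  got_I <- enr$fold[enr$amino_acid == "I" & enr$position == 1]
  expect_equal(got_I, oracle_I, tolerance = 1e-9)  # same finite sample: exact
  # positions 2-5 are untouched by the selection
  off <- enr$fold[enr$position > 1 & is.finite(enr$fold)]
  n_bin <- sum(sel)
  # folds at untouched positions deviate from 1 only by resampling noise;
  # here bin is a strict subset so deviation is hypergeometric, bounded by
  # binomial SE on the bin tally
  for (p in 2:5) {
    for (aa in unique(enr$amino_acid)) {
      fb <- f_bin$frequency[f_bin$amino_acid == aa & f_bin$position == p]
      fi <- f_in$frequency[f_in$amino_acid == aa & f_in$position == p]
      if (fi > 0.005) {
        se <- sqrt(fi * (1 - fi) / n_bin)
        expect_lt(abs(fb - fi), 5 * se)
      }
    }
  }
})

test_that("candidate ranking follows the additive log-fold score", {
  # two-position toy: I enriched 4x at P1, everything else flat
  grid <- tidyr::crossing(amino_acid = c("I", "L", "A"), position = 1:2)
  grid$fold <- ifelse(grid$amino_acid == "I" & grid$position == 1, 4, 1)
  enr <- structure(grid, class = c("enrichment_matrix", class(grid)),
                   reference = "input_library", pseudocount = 0)
  counts <- peptide_counts(c("IA", "LA", "AA"), c(1L, 10L, 10L))
  ranked <- rank_candidates(counts, enr, top_k = 3)
  expect_identical(ranked$peptide[1], "IA")
  expect_equal(ranked$score[1], log(4))
  # all folds 1 -> ranking reduces to count order then lexicographic
  enr$fold <- 1
  ranked_flat <- rank_candidates(counts, enr, top_k = 3)
  expect_identical(ranked_flat$peptide, c("AA", "LA", "IA"))
  expect_equal(ranked_flat$score, rep(0, 3))
})

test_that("heatmap TSV export round-trips and has the contracted shape", {
  lib <- sample_library(200, seed = 81)
  sense <- !grepl("*", lib$peptide, fixed = TRUE)
  counts <- peptide_counts(lib$peptide[sense], rep(1L, sum(sense)))
  enr <- enrichment_vs_null(position_frequencies(counts), nnn_null,
                            pseudocount = 0)
  tsv <- tempfile(fileext = ".tsv")
  export_heatmap(enr, tsv)
  lines <- readLines(tsv)
  expect_identical(length(lines), 22L)  # comment + header + 20 aa rows
  expect_identical(strsplit(lines[2], "\t")[[1]],
                   c("amino_acid", paste0("P", 1:5)))
  back <- read_enrichment_tsv(tsv)
  m_orig <- enr[order(enr$amino_acid, enr$position), ]
  m_back <- back[order(back$amino_acid, back$position), ]
  expect_equal(m_back$fold, m_orig$fold, tolerance = 1e-9)
  expect_identical(attr(back, "reference"), "codon_null")
  # identity folds -> all-zero log2 TSV
  enr1 <- enr
  enr1$fold <- 1
  export_heatmap(enr1, tsv)
  vals <- as.matrix(readr::read_tsv(tsv, skip = 1,
                                    show_col_types = FALSE)[, -1])
  expect_true(all(vals == 0))
})
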