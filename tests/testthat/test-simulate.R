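test_that("tft_ratio obeys its closed form, limits and monotonicity", {
  expect_identical(tft_ratio(0), 1)
  p <- tft_params(m_gfp = 0.1, m_cherry = 0.01, cell_noise_cv = 0)
  k <- log(2) / 30
  expect_equal(tft_ratio(k, p), (0.01 * (0.1 + k)) / (0.1 * (0.01 + k)))
  expect_equal(tft_ratio(Inf, p), 0.01 / 0.1)
  expect_error(tft_ratio(-1, p), class = "degronscan_domain_error")
  # strict monotone decrease in k whenever m_cherry < m_gfp
  set.seed(11)
  for (rep in 1:50) {
    rates <- sort(runif(2, 0.001, 1))
    pp <- tft_params(m_gfp = rates[2], m_cherry = rates[1])
    ks <- sort(runif(20, 0, 5))
    expect_true(all(diff(tft_ratio(ks, pp)) < 0))
  }
})

test_that("tft_params enforces the slow-maturing mCherry partner", {
  expect_error(tft_params(m_gfp = 0.01, m_cherry = 0.1),
               class = "degronscan_config_error")
})

test_that("sampled libraries are reproducible and respect the rule", {
  rule <- stability_rule(base_rate = 0.01, stop_rate = 0.05)
  lib1 <- sample_library(500, rule = rule, seed = 3)
  lib2 <- sample_library(500, rule = rule, seed = 3)
  expect_identical(lib1, lib2)
  expect_equal(sum(lib1$input_abundance), 1, tolerance = 1e-9)
  expect_identical(lib1$peptide, translate_dna(lib1$dna_insert))
  # neutral rule: every sense peptide sits at base rate, stops in their class
  sense <- !grepl("*", lib1$peptide, fixed = TRUE)
  expect_true(all(lib1$k_deg[sense] == 0.01))
  expect_true(all(lib1$k_deg[!sense] == 0.05))
})

test_that("planted rule multiplies rates for Ile/Leu at position 1", {
  rule <- planted_ile_leu_rule(base_rate = 0.002, factor = 8)
  peps <- c("IHPYW", "LAAAA", "AIAAA", "GNRWG", "A*AAA")
  k <- degradation_rate(rule, peps)
  expect_equal(k, c(0.016, 0.016, 0.002, 0.002, 0.016))
})

test_that("exhaustive library reproduces codon multiplicities exactly", {
  sch <- codon_scheme("NNN", num_codon_positions = 2L)
  lib <- sample_library(1, scheme = sch, exhaustive = TRUE)
  expect_identical(nrow(lib), 441L)  # 21^2 peptide classes
  expect_identical(lib$peptide, translate_dna(lib$dna_insert))
  # Ile marginal at each position is exactly 3/64 (stop mass included)
  for (p in 1:2) {
    ile <- substr(lib$peptide, p, p) == "I"
    expect_equal(sum(lib$input_abundance[ile]), 3 / 64)
  }
  expect_equal(sum(lib$input_abundance), 1, tolerance = 1e-12)
})

test_that("simulate_cells honors noise, gates, and determinism", {
  lib <- sample_library(50, rule = stability_rule(base_rate = 0.01),
                        seed = 5, abundance = "uniform")
  # zero noise + neutral rule: every gated sense-variant cell shares one ratio
  p0 <- tft_params(cell_noise_cv = 0, dead_fraction = 0,
                   nonfluorescent_fraction = 0)
  sense_lib <- dplyr::filter(lib, !grepl("*", peptide, fixed = TRUE))
  sense_lib$input_abundance <- sense_lib$input_abundance /
    sum(sense_lib$input_abundance)
  cells0 <- simulate_cells(sense_lib, p0, sort_config(n_cells = 500, seed = 2))
  expect_identical(length(unique(cells0$log_ratio)), 1L)
  # dead fraction: gated count within binomial 99.9% interval
  pd <- tft_params(dead_fraction = 0.5, nonfluorescent_fraction = 0)
  cells <- simulate_cells(lib, pd, sort_config(n_cells = 1e5, seed = 9))
  expect_gt(sum(cells$gated), qbinom(5e-4, 1e5, 0.5))
  expect_lt(sum(cells$gated), qbinom(1 - 5e-4, 1e5, 0.5))
  # determinism
  c1 <- simulate_cells(lib, tft_params(), sort_config(n_cells = 1000, seed = 4))
  c2 <- simulate_cells(lib, tft_params(), sort_config(n_cells = 1000, seed = 4))
  expect_identical(c1, c2)
})

test_that("sort_unstable_bin takes the exact low-ratio tail", {
  lib <- sample_library(100, seed = 8)
  scfg <- sort_config(unstable_bin_fraction = 0.04, n_cells = 10000, seed = 1)
  cells <- simulate_cells(lib, tft_params(dead_fraction = 0,
                                          nonfluorescent_fraction = 0), scfg)
  bins <- sort_unstable_bin(cells, scfg)
  expect_identical(nrow(bins$unstable), 400L)
  expect_identical(nrow(bins$input), 10000L)
  expect_lte(max(bins$unstable$log_ratio),
             min(setdiff(bins$input$log_ratio, bins$unstable$log_ratio)))
  # median split: bin mean strictly below complement mean
  half <- sort_config(unstable_bin_fraction = 0.5, n_cells = 10000, seed = 1)
  bins2 <- sort_unstable_bin(cells, half)
  comp <- dplyr::anti_join(bins2$input, bins2$unstable, by = "cell_id")
  expect_lt(mean(bins2$unstable$log_ratio), mean(comp$log_ratio))
  # too few gated cells
  few <- cells[1:10, ]
  expect_error(sort_unstable_bin(few, scfg),
               class = "degronscan_insufficient_data")
})

test_that("noise-free hard selection collects exactly the planted class", {
  # only Ile-at-P1 peptides are destabilized; with zero noise and the bin
  # fraction set to that class's empirical prevalence, the bin is pure
  rule <- planted_ile_leu_rule(factor = 8)
  rule$position_effects <- rule$position_effects[1, ]  # Ile only
  lib <- sample_library(400, rule = rule, seed = 21, abundance = "uniform")
  lib <- dplyr::filter(lib, !grepl("*", peptide, fixed = TRUE))
  lib$input_abundance <- lib$input_abundance / sum(lib$input_abundance)
  p0 <- tft_params(cell_noise_cv = 0, dead_fraction = 0,
                   nonfluorescent_fraction = 0)
  scfg <- sort_config(unstable_bin_fraction = 0.5, n_cells = 20000, seed = 3)
  cells <- simulate_cells(lib, p0, scfg)
  prevalence <- mean(substr(cells$variant_id |>
    (\(v) lib$peptide[match(v, lib$variant_id)])(), 1, 1) == "I")
  scfg2 <- sort_config(unstable_bin_fraction = prevalence,
                       n_cells = 20000, seed = 3)
  bins <- sort_unstable_bin(cells, scfg2)
  bin_peps <- lib$peptide[match(bins$unstable$variant_id, lib$variant_id)]
  expect_true(all(substr(bin_peps, 1, 1) == "I"))
})

test_that("amplicon reads carry the variant insert and planted error rate", {
  lib <- sample_library(20, seed = 12)
  cfg0 <- tiny_read_cfg(reads_per_sample = 500L)
  fq <- tempfile(fileext = ".fastq")
  truth <- tempfile(fileext = ".tsv")
  emit_amplicon_reads(lib, cfg0, fq, truth)
  lines <- readLines(fq)
  expect_identical(length(lines), 2000L)
  seqs <- lines[seq(2, length(lines), 4)]
  expect_true(all(nchar(seqs) == cfg0$amplicon_length))
  # error rate 0: every read's variable region translates to its peptide
  tt <- readr::read_tsv(truth, show_col_types = FALSE)
  var <- substr(seqs, nchar(cfg0$upstream_flank) + 1,
                nchar(cfg0$upstream_flank) + 15)
  expect_identical(translate_dna(var),
                   lib$peptide[match(tt$variant_id, lib$variant_id)])

  # substitution rate: mean mutated bases per read near binomial expectation
  cfg1 <- tiny_read_cfg(reads_per_sample = 2000L,
                        substitution_error_rate = 0.01, seed = 13)
  emit_amplicon_reads(lib, cfg1, fq, truth)
  lines <- readLines(fq)
  seqs <- lines[seq(2, length(lines), 4)]
  tt <- readr::read_tsv(truth, show_col_types = FALSE)
  clean <- paste0(cfg1$upstream_flank,
                  lib$dna_insert[match(tt$variant_id, lib$variant_id)],
                  cfg1$downstream_flank)
  n_mut <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, seqs, clean)
  expected <- cfg1$amplicon_length * 0.01
  se <- sqrt(cfg1$amplicon_length * 0.01 * 0.99 / length(seqs))
  expect_lt(abs(mean(n_mut) - expected), 4 * se)
})

test_that("an empty multiset yields a valid empty FASTQ with a warning", {
  fq <- tempfile(fileext = ".fastq")
  empty <- tibble::tibble(variant_id = character(0), dna_insert = character(0))
  expect_warning(emit_amplicon_reads(empty, tiny_read_cfg(), fq))
  expect_true(file.exists(fq))
  expect_identical(length(readLines(fq)), 0L)
})
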