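test_that("locate_flanks anchors exactly, tolerates mismatches, rejects indels", {
  layout <- tiny_layout()
  up <- layout$upstream_anchor
  dn <- layout$downstream_anchor
  insert <- "ATTCATCCGTATTGG"
  clean <- paste0("GG", up, insert, dn, "CC")
  loc <- locate_flanks(clean, layout)
  expect_identical(loc$var_start, 2L + nchar(up) + 1L)
  expect_identical(loc$var_end, loc$var_start + 14L)
  expect_identical(loc$n_candidates, 1L)

  # one mismatch in the upstream anchor, within tolerance
  up_mm <- up
  substr(up_mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(up, 5, 5))[1]
  loc_mm <- locate_flanks(paste0("GG", up_mm, insert, dn, "CC"), layout)
  expect_identical(loc_mm$var_start, loc$var_start)

  # a 1-nt deletion in the upstream anchor breaks the spacing constraint
  up_del <- paste0(substr(up, 1, 4), substr(up, 6, nchar(up)))
  loc_del <- locate_flanks(paste0("GG", up_del, insert, dn, "CC"), layout)
  expect_identical(loc_del$n_candidates, 0L)
  expect_true(is.na(loc_del$var_start))
})

test_that("extraction reproduces a noiseless single-variant sample", {
  cfg <- tiny_read_cfg(reads_per_sample = 1000L)
  layout <- tiny_layout(cfg)
  lib <- tibble::tibble(variant_id = "v1", dna_insert = "ATTCATCCGTATTGG")
  fq <- tempfile(fileext = ".fastq")
  emit_amplicon_reads(lib, cfg, fq)
  res <- extract_and_classify(fq, layout)
  expect_identical(res$counts$peptide, "IHPYW")
  expect_identical(res$counts$count, 1000L)
  expect_identical(res$report$n_valid, 1000L)
  expect_identical(res$report$n_quality_fail, 0L)
  expect_identical(res$report$n_anchor_fail, 0L)
})

test_that("stop-containing variable regions are routed to the stop map", {
  layout <- tiny_layout()
  read <- paste0(layout$upstream_anchor, "TAACATCCGTATTGG",
                 layout$downstream_anchor)
  res <- extract_and_classify(write_tiny_fastq(read), layout)
  expect_identical(nrow(res$counts), 0L)
  expect_identical(res$stop_counts$peptide, "*HPYW")
  expect_identical(res$stop_counts$count, 1L)
  expect_identical(res$report$n_stop_containing, 1L)
})

test_that("report categories are disjoint and conserve every read", {
  cfg <- tiny_read_cfg(reads_per_sample = 400L, substitution_error_rate = 0.03,
                       seed = 31)
  layout <- tiny_layout(cfg)
  lib <- sample_library(30, seed = 32)
  fq <- tempfile(fileext = ".fastq")
  emit_amplicon_reads(lib, cfg, fq)
  # add a low-quality read and an ambiguous-base read by hand
  lowq <- paste0(cfg$upstream_flank, "ATTCATCCGTATTGG", cfg$downstream_flank)
  ambig <- paste0(cfg$upstream_flank, "ATTCATCCGTNTTGG", cfg$downstream_flank)
  extra <- tempfile(fileext = ".fastq")
  writeLines(c("@lowq", lowq, "+", strrep("#", nchar(lowq)),
               "@ambig", ambig, "+", strrep("I", nchar(ambig))), extra)
  file.append(fq, extra)
  res <- extract_and_classify(fq, layout)
  rep <- res$report
  expect_identical(rep$n_reads, 402L)
  expect_identical(rep$n_quality_fail + rep$n_anchor_fail +
                     rep$n_ambiguous_base + rep$n_stop_containing + rep$n_valid,
                   rep$n_reads)
  expect_identical(rep$n_quality_fail, 1L)
  expect_gte(rep$n_ambiguous_base, 1L)
  expect_identical(sum(res$counts$count), rep$n_valid)
  expect_identical(sum(res$stop_counts$count), rep$n_stop_containing)
})

test_that("noiseless extraction equals ground-truth counts exactly", {
  cfg <- tiny_read_cfg(reads_per_sample = 2000L, seed = 41)
  layout <- tiny_layout(cfg)
  lib <- sample_library(100, seed = 42)
  fq <- tempfile(fileext = ".fastq")
  truth <- tempfile(fileext = ".tsv")
  emit_amplicon_reads(lib, cfg, fq, truth)
  res <- extract_and_classify(fq, layout)
  tt <- readr::read_tsv(truth, show_col_types = FALSE)
  true_peps <- lib$peptide[match(tt$variant_id, lib$variant_id)]
  sense <- !grepl("*", true_peps, fixed = TRUE)
  oracle_sense <- sort(table(true_peps[sense]), decreasing = TRUE)
  got <- setNames(res$counts$count, res$counts$peptide)
  expect_identical(sum(res$counts$count), sum(sense))
  expect_identical(unname(got[names(oracle_sense)]),
                   as.integer(oracle_sense))
  oracle_stop <- table(true_peps[!sense])
  got_stop <- setNames(res$stop_counts$count, res$stop_counts$peptide)
  expect_identical(unname(got_stop[names(oracle_stop)]),
                   as.integer(oracle_stop))
})

test_that("corrupted-read fraction matches the analytic substitution model", {
  err <- 0.02
  cfg <- tiny_read_cfg(reads_per_sample = 5000L,
                       substitution_error_rate = err, seed = 51)
  layout <- tiny_layout(cfg)
  lib <- tibble::tibble(variant_id = "v1", dna_insert = "ATTCATCCGTATTGG")
  fq <- tempfile(fileext = ".fastq")
  emit_amplicon_reads(lib, cfg, fq)
  res <- extract_and_classify(fq, layout)
  observed_clean <- res$counts$count[res$counts$peptide == "IHPYW"] /
    res$report$n_reads
  # a read reports the true peptide iff both anchors pass (<=1 mismatch each)
  # and the variable region is error-free at the DNA or synonymous level;
  # bound the check with the no-error-anywhere-in-window probability
  la <- nchar(layout$upstream_anchor)
  p_anchor <- (1 - err)^la + la * err * (1 - err)^(la - 1)
  p_clean_var <- (1 - err)^15
  p_true_lower <- p_anchor^2 * p_clean_var
  n <- res$report$n_reads
  se <- sqrt(p_true_lower * (1 - p_true_lower) / n)
  expect_gt(observed_clean, p_true_lower - 4 * se)
  # synonymous substitutions make the observed rate slightly higher
  expect_lt(observed_clean, p_true_lower + 0.02 + 4 * se)
})

test_that("counts TSV round-trips losslessly with deterministic order", {
  counts <- peptide_counts(c("IHPYW", "AAAAA", "GNRWG", "CCCCC"),
                           c(5L, 5L, 10L, 1L), sample_label = "demo")
  expect_identical(counts$peptide, c("GNRWG", "AAAAA", "IHPYW", "CCCCC"))
  path <- tempfile(fileext = ".tsv")
  write_counts(counts, path)
  back <- read_counts(path)
  expect_identical(as.data.frame(back), as.data.frame(counts))
  expect_identical(attr(back, "sample_label"), "demo")
})

test_that("malformed count tables are rejected with a line number", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# sample_label=x", "peptide\tcount", "IHPY\t3"), path)
  expect_error(read_counts(path), "line 3", class = "degronscan_parse_error")
  writeLines(c("# sample_label=x", "peptide\tcount", "IHPYW\t-3"), path)
  expect_error(read_counts(path), class = "degronscan_parse_error")
  writeLines(c("# sample_label=x", "peptide\tcount", "IHPYW\t3\textra"), path)
  expect_error(read_counts(path), class = "degronscan_parse_error")
})

test_that("empty FASTQ gives empty counts and an all-zero report", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  res <- extract_and_classify(fq, tiny_layout())
  expect_identical(nrow(res$counts), 0L)
  expect_identical(res$report$n_reads, 0L)
  expect_identical(res$report$n_valid, 0L)
})
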