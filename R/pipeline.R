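#' Pipeline configuration
#'
#' Bundles every stage's parameters — library size, codon scheme, planted
#' stability rule, tFT readout, sort, read simulation, extraction layout,
#' enrichment options — with one top-level seed that is fanned out
#' deterministically to the per-stage RNGs. The configuration hash recorded
#' in the run manifest changes iff any parameter changes.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Single integer seed governing all randomness.
#' @param n_variants Library members to simulate.
#' @param scheme A [codon_scheme()].
#' @param rule A [stability_rule()]; defaults to the planted Ile/Leu rule.
#' @param tft A [tft_params()].
#' @param sort A [sort_config()].
#' @param reads A [read_sim_config()].
#' @param layout An [amplicon_layout()], or `NULL` to derive one from `reads`
#'   with [default_layout()].
#' @param pseudocount_input Pseudocount for the input-relative enrichment
#'   panel.
#' @param top_k Candidates to report.
#' @param abundance,abundance_param Library abundance model (see
#'   [sample_library()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, n_variants = 2e5,
                            scheme = codon_scheme("NNN"),
                            rule = planted_ile_leu_rule(),
                            tft = tft_params(),
                            sort = sort_config(),
                            reads = read_sim_config(),
                            layout = NULL,
                            pseudocount_input = 0.5,
                            top_k = 20L,
                            abundance = "lognormal",
                            abundance_param = 1) {
  if (!is.character(outdir) || length(outdir) != 1L || !nzchar(outdir)) {
    abort("`outdir` must be a single non-empty path.",
          class = "degronscan_config_error")
  }
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_variants, "n_variants", lower = 1)
  stopifnot(inherits(scheme, "codon_scheme"),
            inherits(rule, "stability_rule"),
            inherits(tft, "tft_params"),
            inherits(sort, "sort_config"),
            inherits(reads, "read_sim_config"))
  if (is.null(layout)) layout <- default_layout(reads)
  stopifnot(inherits(layout, "amplicon_layout"))
  assert_scalar_number(pseudocount_input, "pseudocount_input", lower = 0)
  assert_scalar_number(top_k, "top_k", lower = 1)
  cfg <- structure(list(
    outdir = outdir, seed = as.integer(seed),
    n_variants = as.integer(n_variants),
    scheme = scheme, rule = rule, tft = tft, sort = sort, reads = reads,
    layout = layout, pseudocount_input = pseudocount_input,
    top_k = as.integer(top_k),
    abundance = abundance, abundance_param = abundance_param),
    class = "pipeline_config")
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<pipeline_config: %d variants (%s), %d cells, bin %.3g, ",
    "%d reads/sample, err %.4g, seed %d>\n  outdir: %s\n  hash: %s\n"),
    x$n_variants, x$scheme$name, x$sort$n_cells,
    x$sort$unstable_bin_fraction, x$reads$reads_per_sample,
    x$reads$substitution_error_rate, x$seed, x$outdir, config_hash(x)))
  invisible(x)
}

# stable hash of the scientific parameters (paths excluded)
config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  x <- lapply(x, function(el) if (is.list(el)) unclass(el) else el)
  rlang::hash(x)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the constructor arguments, one block per stage:
#' top-level `outdir`, `seed`, `n_variants`, `abundance`, `abundance_param`,
#' `pseudocount_input`, `top_k`, plus optional mappings `scheme`
#' (`name`/`num_codon_positions`), `rule` (`base_rate`, `stop_rate`,
#' `position_effects` rows), `tft`, `sort`, `reads`, `layout` whose keys are
#' the corresponding constructor's arguments.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, fields) {
    if (is.null(fields)) return(ctor())
    if (!is.null(fields$position_effects)) {
      fields$position_effects <- bind_rows(lapply(fields$position_effects, as_tibble))
    }
    do.call(ctor, fields)
  }
  args <- list(
    outdir = y$outdir %||% ".",
    scheme = build(codon_scheme, y$scheme),
    rule = if (is.null(y$rule)) planted_ile_leu_rule() else
      build(stability_rule, y$rule),
    tft = build(tft_params, y$tft),
    sort = build(sort_config, y$sort),
    reads = build(read_sim_config, y$reads),
    layout = if (is.null(y$layout)) NULL else build(amplicon_layout, y$layout))
  for (nm in c("seed", "n_variants", "pseudocount_input", "top_k",
               "abundance", "abundance_param")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(pipeline_config, args)
}

log_stage <- function(outdir, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  path <- file.path(outdir, "pipeline_log.jsonl")
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = path, append = TRUE, sep = "")
  invisible(path)
}

#' Run the simulation stage
#'
#' Simulates the library, the sorted cells and both sequencing samples
#' (input pool and unstable bin), writing FASTQ files, per-read ground truth,
#' the variant-level ground truth table, and a manifest JSON recording paths,
#' per-stage seeds and the configuration hash.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list; also written to
#'   `outdir/manifest.json`).
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- fan_out_seeds(config$seed, 4L,
                         c("library", "cells", "reads_input", "reads_unstable"))
  lib <- sample_library(config$n_variants, config$scheme, config$rule,
                            abundance = config$abundance,
                            abundance_param = config$abundance_param,
                            seed = seeds[["library"]])
  sort_cfg <- config$sort
  sort_cfg$seed <- seeds[["cells"]]
  cells <- simulate_cells(lib, config$tft, sort_cfg)
  bins <- sort_unstable_bin(cells, sort_cfg)

  paths <- list(
    input_fastq = file.path(config$outdir, "input.fastq"),
    unstable_fastq = file.path(config$outdir, "unstable.fastq"),
    input_truth = file.path(config$outdir, "input_truth.tsv"),
    unstable_truth = file.path(config$outdir, "unstable_truth.tsv"),
    ground_truth = file.path(config$outdir, "ground_truth.tsv"))

  lib_cols <- lib[, c("variant_id", "dna_insert")]
  for (sample in c("input", "unstable")) {
    rcfg <- config$reads
    rcfg$seed <- seeds[[paste0("reads_", sample)]]
    members <- dplyr::left_join(
      bins[[sample]][, "variant_id", drop = FALSE], lib_cols,
      by = "variant_id")
    emit_amplicon_reads(members, rcfg,
                        fastq_path = paths[[paste0(sample, "_fastq")]],
                        truth_path = paths[[paste0(sample, "_truth")]],
                        read_prefix = paste0(sample, "_"))
  }
  readr::write_tsv(lib, paths$ground_truth)

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    n_variants = config$n_variants,
    n_cells = config$sort$n_cells,
    n_gated = nrow(bins$input),
    n_unstable_bin = nrow(bins$unstable),
    paths = paths)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage(config$outdir, "simulate", seed = config$seed,
            n_gated = nrow(bins$input), n_unstable = nrow(bins$unstable))
  invisible(manifest)
}

#' Run the extraction stage
#'
#' Extracts pentapeptide counts from each FASTQ, writing a counts TSV, a
#' stop-peptide TSV, and one JSON-lines report entry per sample.
#'
#' @param config A [pipeline_config()].
#' @param fastq_paths Named character vector/list of FASTQ paths (names become
#'   sample labels); defaults to the simulate stage's outputs in `outdir`.
#' @return Named list (per sample) of `extract_and_classify()` results, with
#'   a `counts_path` added; invisibly.
#' @export
run_extract <- function(config, fastq_paths = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(fastq_paths)) {
    fastq_paths <- c(input = file.path(config$outdir, "input.fastq"),
                     unstable = file.path(config$outdir, "unstable.fastq"))
  }
  missing <- !vapply(fastq_paths, file.exists, logical(1))
  if (any(missing)) {
    abort(sprintf("FASTQ input(s) not found: %s",
                  paste(unlist(fastq_paths[missing]), collapse = ", ")),
          class = "degronscan_io_error")
  }
  results <- list()
  for (sample in names(fastq_paths)) {
    res <- extract_and_classify(fastq_paths[[sample]], config$layout,
                                sample_label = sample)
    counts_path <- file.path(config$outdir, paste0(sample, "_counts.tsv"))
    stop_path <- file.path(config$outdir, paste0(sample, "_stop_counts.tsv"))
    write_counts(res$counts, counts_path)
    write_counts(res$stop_counts, stop_path)
    log_stage(config$outdir, "extract", sample = sample,
              report = as.list(res$report))
    res$counts_path <- counts_path
    results[[sample]] <- res
  }
  invisible(results)
}

#' Run the enrichment stage
#'
#' Computes position frequencies for both samples and both enrichment panels
#' — unstable bin vs the degenerate-codon null (raw frequencies) and vs the
#' input library (pseudocount-smoothed) — plus the ranked candidate list.
#' Writes frequency TSVs, one heatmap TSV + PNG per panel, and the candidate
#' table.
#'
#' @param config A [pipeline_config()].
#' @param counts_paths Named paths to `input` and `unstable` counts TSVs;
#'   defaults to the extract stage's outputs in `outdir`.
#' @return List with `freqs`, `enr_null`, `enr_input`, `candidates`;
#'   invisibly.
#' @export
run_enrich <- function(config, counts_paths = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(counts_paths)) {
    counts_paths <- c(input = file.path(config$outdir, "input_counts.tsv"),
                      unstable = file.path(config$outdir, "unstable_counts.tsv"))
  }
  if (!all(c("input", "unstable") %in% names(counts_paths))) {
    abort("`counts_paths` must name both an 'input' and an 'unstable' sample.",
          class = "degronscan_config_error")
  }
  counts <- lapply(counts_paths, read_counts)
  freqs <- lapply(counts, position_frequencies)
  null <- position_null_distribution(config$scheme)
  enr_null <- enrichment_vs_null(freqs$unstable, null, pseudocount = 0)
  enr_input <- enrichment_vs_input(freqs$unstable, freqs$input,
                                   pseudocount = config$pseudocount_input)
  candidates <- rank_candidates(counts$unstable, enr_input, config$top_k)

  for (sample in names(freqs)) {
    readr::write_tsv(as_tibble(freqs[[sample]]),
                     file.path(config$outdir,
                               paste0(sample, "_frequencies.tsv")))
  }
  export_heatmap(enr_null,
                 file.path(config$outdir, "enrichment_vs_null.tsv"),
                 file.path(config$outdir, "enrichment_vs_null.png"))
  export_heatmap(enr_input,
                 file.path(config$outdir, "enrichment_vs_input.tsv"),
                 file.path(config$outdir, "enrichment_vs_input.png"))
  readr::write_tsv(candidates, file.path(config$outdir, "candidates.tsv"))
  log_stage(config$outdir, "enrich",
            n_candidates = nrow(candidates),
            top_candidate = if (nrow(candidates)) candidates$peptide[1] else NA)
  invisible(list(freqs = freqs, enr_null = enr_null, enr_input = enr_input,
                 candidates = candidates))
}

#' Run the kinetics stage
#'
#' Fits per-construct (and replicate) half-lives from a tidy chase TSV with
#' columns `construct`, `replicate`, `time_min`, `intensity`.
#'
#' @param config A [pipeline_config()].
#' @param chase_path Path to the chase TSV.
#' @return The half-life tibble, invisibly (also written to
#'   `outdir/halflives.tsv`).
#' @export
run_kinetics <- function(config, chase_path) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(chase_path)) {
    abort(sprintf("Chase table not found: %s", chase_path),
          class = "degronscan_io_error")
  }
  chase <- readr::read_tsv(chase_path, show_col_types = FALSE)
  needed <- c("construct", "replicate", "time_min", "intensity")
  if (!all(needed %in% names(chase))) {
    abort(sprintf("Chase TSV needs columns: %s.", paste(needed, collapse = ", ")),
          class = "degronscan_parse_error")
  }
  fits <- fit_decay_halflives(chase, .data$construct, .data$replicate)
  readr::write_tsv(fits, file.path(config$outdir, "halflives.tsv"))
  log_stage(config$outdir, "kinetics", n_series = nrow(fits))
  invisible(fits)
}

#' Assemble a Markdown report from a pipeline output directory
#'
#' Gathers whatever stage outputs are present — extraction accounting,
#' enrichment heatmaps and candidates, half-lives, and (when ground truth is
#' available) planted-signal recovery diagnostics — into a single
#' `report.md`. Missing stages are listed as absent; regeneration is
#' idempotent.
#'
#' @param outdir Pipeline output directory.
#' @return Path to `report.md`, invisibly.
#' @export
run_report <- function(outdir) {
  md <- c("# degronscan pipeline report", "")
  missing_sections <- character(0)

  log_path <- file.path(outdir, "pipeline_log.jsonl")
  extract_reports <- list()
  if (file.exists(log_path)) {
    for (line in readr::read_lines(log_path)) {
      entry <- jsonlite::fromJSON(line)
      if (identical(entry$stage, "extract")) {
        extract_reports[[entry$sample]] <- entry$report
      }
    }
  }
  md <- c(md, "## Extraction accounting", "")
  if (length(extract_reports) > 0) {
    tab <- bind_rows(lapply(extract_reports, as_tibble))
    md <- c(md, knit_md_table(tab), "")
  } else {
    md <- c(md, "_absent_", "")
    missing_sections <- c(missing_sections, "extraction")
  }

  md <- c(md, "## Enrichment", "")
  any_heat <- FALSE
  for (panel in c("enrichment_vs_null", "enrichment_vs_input")) {
    if (file.exists(file.path(outdir, paste0(panel, ".tsv")))) {
      any_heat <- TRUE
      md <- c(md, sprintf("- `%s.tsv`", panel))
      if (file.exists(file.path(outdir, paste0(panel, ".png")))) {
        md <- c(md, sprintf("  ![%s](%s.png)", panel, panel))
      }
    }
  }
  if (!any_heat) {
    md <- c(md, "_absent_")
    missing_sections <- c(missing_sections, "enrichment")
  }
  md <- c(md, "")

  md <- c(md, "## Candidates", "")
  cand_path <- file.path(outdir, "candidates.tsv")
  if (file.exists(cand_path)) {
    cand <- readr::read_tsv(cand_path, show_col_types = FALSE)
    md <- c(md,
            "Ranking is a heuristic additive log-fold score, not a measured stability.",
            "", knit_md_table(head(cand, 10)), "")
  } else {
    md <- c(md, "_absent_", "")
    missing_sections <- c(missing_sections, "candidates")
  }

  md <- c(md, "## Kinetics", "")
  hl_path <- file.path(outdir, "halflives.tsv")
  if (file.exists(hl_path)) {
    hl <- readr::read_tsv(hl_path, show_col_types = FALSE)
    md <- c(md, knit_md_table(hl), "")
  } else {
    md <- c(md, "_absent_", "")
    missing_sections <- c(missing_sections, "kinetics")
  }

  gt_path <- file.path(outdir, "ground_truth.tsv")
  enr_path <- file.path(outdir, "enrichment_vs_input.tsv")
  md <- c(md, "## Ground-truth recovery", "")
  if (file.exists(gt_path) && file.exists(enr_path)) {
    gt <- readr::read_tsv(gt_path, show_col_types = FALSE)
    enr <- read_enrichment_tsv(enr_path)
    planted <- gt$k_deg > min(gt$k_deg)
    sense <- !grepl("*", gt$peptide, fixed = TRUE)
    planted_aas <- sort(unique(substr(gt$peptide[planted & sense], 1, 1)))
    p1 <- enr[enr$position == 1, ]
    top2 <- p1$amino_acid[order(-p1$fold)][1:2]
    md <- c(md,
            sprintf("- Destabilized position-1 residues in ground truth: %s",
                    paste(planted_aas, collapse = ", ")),
            sprintf("- Top two position-1 folds vs input: %s",
                    paste(sprintf("%s (%.2f)", top2,
                                  p1$fold[match(top2, p1$amino_acid)]),
                          collapse = ", ")),
            "")
  } else {
    md <- c(md, "_absent (no ground truth in this directory)_", "")
    missing_sections <- c(missing_sections, "ground-truth recovery")
  }

  if (length(missing_sections) > 0) {
    md <- c(md, "## Missing stages", "",
            paste0("- ", missing_sections), "")
  }
  path <- file.path(outdir, "report.md")
  readr::write_lines(md, path)
  invisible(path)
}

# minimal Markdown table renderer for the report
knit_md_table <- function(df) {
  df <- as_tibble(df)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(signif(col, 5), trim = TRUE) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Run the full pipeline: simulate, extract, enrich, report
#'
#' @param config A [pipeline_config()].
#' @param chase_path Optional chase TSV for the kinetics stage.
#' @return List with the stage results, invisibly.
#' @export
run_pipeline <- function(config, chase_path = NULL) {
  manifest <- run_simulate(config)
  extracted <- run_extract(config)
  enriched <- run_enrich(config)
  kinetics <- if (!is.null(chase_path)) run_kinetics(config, chase_path)
  report <- run_report(config$outdir)
  invisible(list(manifest = manifest, extracted = extracted,
                 enriched = enriched, kinetics = kinetics, report = report))
}
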