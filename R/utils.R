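# internal helpers shared across modules

# Fan one user-facing seed out into independent per-stage seeds. Seeds stay
# below 2^31 - 1 (R integers). Deterministic in `seed`; does not disturb the
# caller's RNG state.
fan_out_seeds <- function(seed, n, stage_names = NULL) {
  stopifnot(length(seed) == 1, is.finite(seed))
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(stage_names)) names(seeds) <- stage_names
  seeds
}

# Run `expr` under `seed` if non-NULL, otherwise with the ambient RNG.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "degronscan_config_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x),
      class = "degronscan_config_error")
  }
  invisible(x)
}

assert_dna_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L ||
      grepl("[^ACGT]", x)) {
    abort(sprintf("`%s` must be a non-empty string over {A,C,G,T}.", name),
          class = "degronscan_config_error")
  }
  invisible(x)
}

# 20 amino acids in the fixed display order used for all matrices/heatmaps
aa_alphabet <- function(include_stop = FALSE) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (include_stop) c(aas, "*") else aas
}
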