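#' Planted stability rule for simulated libraries
#'
#' A stability rule is a pure function of peptide sequence that assigns each
#' library member a first-order degradation rate. It is the simulator's
#' ground truth: a neutral base rate, multiplicative per-(position, amino
#' acid) effects, optional whole-peptide motif effects, and a dedicated rate
#' class for stop-containing (truncated) peptides. The default base rate
#' corresponds to a stable reporter (half-life 180 min); stop-containing
#' peptides default to the unstable class (8x the base rate) and are flagged
#' in all downstream reports.
#'
#' @param base_rate Degradation rate (1/min) of peptides with no effect.
#' @param position_effects Data frame with columns `position`, `amino_acid`,
#'   `factor` (multiplicative, > 0), or `NULL` for a neutral rule.
#' @param motif_effects Data frame with columns `pattern` (regular expression
#'   matched against the full peptide) and `factor`, or `NULL`.
#' @param stop_rate Rate assigned to any peptide containing `"*"`.
#' @return An object of class `stability_rule`.
#' @seealso [planted_ile_leu_rule()] for the default degron-screen scenario.
#' @export
stability_rule <- function(base_rate = log(2) / 180,
                           position_effects = NULL,
                           motif_effects = NULL,
                           stop_rate = 8 * base_rate) {
  assert_scalar_number(base_rate, "base_rate", lower = 0, strict_lower = TRUE)
  assert_scalar_number(stop_rate, "stop_rate", lower = 0, strict_lower = TRUE)
  if (!is.null(position_effects)) {
    position_effects <- as_tibble(position_effects)
    stopifnot(all(c("position", "amino_acid", "factor") %in%
                    names(position_effects)))
    if (any(position_effects$factor <= 0)) {
      abort("All position-effect factors must be > 0.",
            class = "degronscan_config_error")
    }
  }
  if (!is.null(motif_effects)) {
    motif_effects <- as_tibble(motif_effects)
    stopifnot(all(c("pattern", "factor") %in% names(motif_effects)))
    if (any(motif_effects$factor <= 0)) {
      abort("All motif-effect factors must be > 0.",
            class = "degronscan_config_error")
    }
  }
  structure(list(base_rate = base_rate,
                 position_effects = position_effects,
                 motif_effects = motif_effects,
                 stop_rate = stop_rate),
            class = "stability_rule")
}

#' Default planted rule: Ile/Leu at position 1 destabilize
#'
#' Plants the signature the screen is designed to recover: peptides beginning
#' with isoleucine or leucine degrade `factor` times faster than the neutral
#' base rate.
#'
#' @param base_rate Neutral degradation rate (1/min).
#' @param factor Multiplicative destabilization for I/L at position 1.
#' @return A [stability_rule()].
#' @export
planted_ile_leu_rule <- function(base_rate = log(2) / 180, factor = 8) {
  stability_rule(
    base_rate = base_rate,
    position_effects = tibble(position = c(1L, 1L),
                              amino_acid = c("I", "L"),
                              factor = c(factor, factor)),
    stop_rate = factor * base_rate)
}

#' Degradation rate of peptides under a stability rule
#'
#' @param rule A [stability_rule()].
#' @param peptides Character vector of peptides (may contain `"*"`).
#' @return Numeric vector of degradation rates (1/min).
#' @export
degradation_rate <- function(rule, peptides) {
  stopifnot(inherits(rule, "stability_rule"))
  k <- rep(rule$base_rate, length(peptides))
  if (!is.null(rule$position_effects)) {
    pe <- rule$position_effects
    for (r in seq_len(nrow(pe))) {
      hit <- substr(peptides, pe$position[r], pe$position[r]) == pe$amino_acid[r]
      k[hit] <- k[hit] * pe$factor[r]
    }
  }
  if (!is.null(rule$motif_effects)) {
    me <- rule$motif_effects
    for (r in seq_len(nrow(me))) {
      hit <- grepl(me$pattern[r], peptides)
      k[hit] <- k[hit] * me$factor[r]
    }
  }
  # truncations are their own rate class, overriding sequence effects
  k[grepl("*", peptides, fixed = TRUE)] <- rule$stop_rate
  k
}

#' @export
print.stability_rule <- function(x, ...) {
  cat(sprintf("<stability_rule: base %.4g/min, stop class %.4g/min, %d position effect(s)>\n",
              x$base_rate, x$stop_rate,
              if (is.null(x$position_effects)) 0L else nrow(x$position_effects)))
  invisible(x)
}
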