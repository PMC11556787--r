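#' Fit a first-order decay half-life to a chase time course
#'
#' After translation shutoff (cycloheximide or emetine chase), a protein
#' degraded with first-order kinetics decays as
#' \eqn{I(t) = I_0 e^{-kt}}, so log intensity is linear in time. The fit is
#' ordinary least squares of `log(intensity)` on `time`; `k` is minus the
#' slope and the half-life is `ln(2) / k`. A non-positive fitted `k` is
#' reported as stable with infinite half-life. The fit is scale-invariant:
#' multiplying all intensities by a constant leaves `k` unchanged.
#'
#' @param data Data frame holding one chase series.
#' @param time,intensity Columns (tidy-eval) holding times (minutes,
#'   non-negative, distinct) and loading-control-normalized intensities
#'   (strictly positive). At least 3 points are required.
#' @param construct_label Optional label carried into tidiers.
#' @return An object of class `decay_fit` with fields `k_deg` (1/min),
#'   `half_life` (min), `stable`, `r_squared`, `k_se`, `n_points`, and the
#'   underlying `lm` fit. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' chase <- data.frame(time_min = c(0, 30, 60, 90),
#'                     intensity = c(100, 50, 25, 12.5))
#' fit <- fit_decay_halflife(chase)
#' fit$half_life  # 30
#' @export
fit_decay_halflife <- function(data, time = time_min, intensity = intensity,
                               construct_label = NA_character_) {
  stopifnot(is.data.frame(data))
  t <- rlang::eval_tidy(rlang::enquo(time), data)
  i <- rlang::eval_tidy(rlang::enquo(intensity), data)
  if (length(t) < 3L) {
    abort("A decay fit needs at least 3 time points.",
          class = "degronscan_insufficient_data")
  }
  if (anyNA(t) || anyNA(i) || any(t < 0) || anyDuplicated(t)) {
    abort("Times must be non-negative and distinct.",
          class = "degronscan_domain_error")
  }
  if (any(i <= 0)) {
    abort("Intensities must be strictly positive (log-linear fit).",
          class = "degronscan_domain_error")
  }
  fit <- lm(log(i) ~ t)
  # noiseless series trip summary.lm's "essentially perfect fit" warning;
  # exact exponentials are legitimate input here
  sm <- suppressWarnings(summary(fit))
  k <- -unname(coef(fit)[2])
  # absorb least-squares rounding noise on perfectly flat series: a rate that
  # would change log-intensity by < 1e-9 over the observed window is zero
  if (abs(k) * max(t) < 1e-9) k <- 0
  k_se <- unname(sm$coefficients[2, 2])
  stable <- k <= 0
  structure(list(
    construct_label = construct_label,
    k_deg = k,
    half_life = if (stable) Inf else log(2) / k,
    stable = stable,
    r_squared = sm$r.squared,
    k_se = k_se,
    n_points = length(t),
    model = fit,
    data = tibble(time = t, intensity = i)),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit%s: k = %.4g /min, half-life = %s min, R^2 = %.3f, n = %d%s>\n",
              if (is.na(x$construct_label)) "" else paste0(" ", x$construct_label),
              x$k_deg,
              if (is.finite(x$half_life)) sprintf("%.3g", x$half_life) else "Inf",
              x$r_squared, x$n_points,
              if (x$stable) ", stable" else ""))
  invisible(x)
}

#' Fit half-lives for many constructs/replicates at once
#'
#' Groups a tidy chase table and fits [fit_decay_halflife()] per group,
#' returning one [glance()] row per series.
#'
#' @param data Tidy data frame of chase measurements.
#' @param ... Grouping columns (tidy-select), e.g. `construct, replicate`.
#' @param time,intensity Measurement columns (tidy-eval).
#' @return A tibble with the grouping columns plus `k_deg`, `k_se`,
#'   `half_life`, `stable`, `r_squared`, `n_points`.
#' @export
fit_decay_halflives <- function(data, ..., time = time_min,
                                intensity = intensity) {
  stopifnot(is.data.frame(data))
  tq <- rlang::enquo(time)
  iq <- rlang::enquo(intensity)
  grouped <- dplyr::group_by(as_tibble(data), ...)
  out <- dplyr::group_modify(grouped, function(df, key) {
    fit <- fit_decay_halflife(df, time = !!tq, intensity = !!iq)
    glance(fit)[, c("k_deg", "k_se", "half_life", "stable",
                    "r_squared", "n_points")]
  })
  ungroup(out)
}

#' @describeIn fit_decay_halflife One row per model coefficient
#'   (`log_intensity_0`, `k_deg`) with estimate, standard error, statistic,
#'   p-value.
#' @param x A `decay_fit`.
#' @param ... Ignored.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble(term = c("log_intensity_0", "k_deg"),
         estimate = c(cf[1, 1], -cf[2, 1]),
         std.error = cf[, 2],
         statistic = cf[, 3],
         p.value = cf[, 4])
}

#' @describeIn fit_decay_halflife One-row model summary with `k_deg`, `k_se`,
#'   `half_life`, `stable`, `r_squared`, `n_points`, `construct_label`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(construct_label = x$construct_label,
         k_deg = x$k_deg, k_se = x$k_se, half_life = x$half_life,
         stable = x$stable, r_squared = x$r_squared, n_points = x$n_points)
}

#' @describeIn fit_decay_halflife Chase data and fitted exponential on a log
#'   intensity scale.
#' @param object A `decay_fit`.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- object$data
  line <- tibble(time = seq(min(df$time), max(df$time), length.out = 100))
  line$intensity <- exp(predict(object$model,
                                newdata = data.frame(t = line$time)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(data = line, color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time after shutoff (min)",
                  y = "Normalized intensity (log scale)",
                  subtitle = if (is.finite(object$half_life)) {
                    sprintf("half-life %.3g min", object$half_life)
                  } else "stable (k <= 0)") +
    ggplot2::theme_minimal(base_size = 11)
}

#' Per-construct summary of mCherry/GFP ratio distributions
#'
#' Summarises per-cell log(mCherry/GFP) values by construct (and optional
#' treatment) as the geometric mean ratio — the exponentiated mean of the
#' log-ratios, the natural center for log-normally distributed flow ratios —
#' with the standard deviation on the log scale. An arithmetic variant is
#' available for comparison with mean-of-ratios reporting.
#'
#' @param data Tidy data frame of per-cell observations.
#' @param ... Grouping columns (tidy-select), e.g. `construct_label`.
#' @param log_ratio Column of per-cell log ratios (tidy-eval).
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return A tibble with the grouping columns plus `mean_ratio`, `sd`
#'   (log-scale SD for geometric, ratio-scale SD for arithmetic), `n`.
#' @export
mean_ratio_summary <- function(data, ..., log_ratio = log_ratio,
                               method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) {
    abort("No ratio observations supplied.",
          class = "degronscan_insufficient_data")
  }
  lrq <- rlang::enquo(log_ratio)
  lr_all <- rlang::eval_tidy(lrq, data)
  if (anyNA(lr_all) || any(!is.finite(lr_all))) {
    abort("Log-ratios must be finite.", class = "degronscan_domain_error")
  }
  grouped <- dplyr::group_by(as_tibble(data), ...)
  out <- dplyr::summarise(
    grouped,
    mean_ratio = if (method == "geometric") exp(mean(!!lrq)) else mean(exp(!!lrq)),
    sd = if (method == "geometric") {
      if (n() > 1) sd(!!lrq) else 0
    } else {
      if (n() > 1) sd(exp(!!lrq)) else 0
    },
    n = n(),
    .groups = "drop")
  out
}
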