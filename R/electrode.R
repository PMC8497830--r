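#' Fraction of narrow-spiking units along an electrode track
#'
#' Bins the signed distance to the anatomical boundary and reports the
#' narrow-spiking fraction per bin; empty bins are omitted.
#'
#' @param data Data frame with `distance_um` (signed; positive = inside
#'   the target structure) and logical `is_narrow`.
#' @param bin_width_um Bin width in um (> 0).
#' @return Data frame `distance_um` (bin center), `fraction`, `n`.
#' @export
narrow_fraction_profile <- function(data, bin_width_um = 20) {
  check_positive(bin_width_um, "bin_width_um")
  if (nrow(data) == 0) stop_domain("empty spike-track data")
  bin <- floor(data$distance_um / bin_width_um)
  agg <- stats::aggregate(data$is_narrow, list(bin = bin),
                          function(v) c(mean(v), length(v)))
  data.frame(distance_um = (agg$bin + 0.5) * bin_width_um,
             fraction = agg$x[, 1], n = agg$x[, 2])
}

#' Logistic fit of the narrow-spiking transition
#'
#' Bernoulli maximum-likelihood fit of
#' `P(narrow | d) = 1 / (1 + exp(-(d - d0)/s))` on the raw unit labels
#' (no binning). `d0` is the distance at half probability -- the
#' electrophysiological estimate of the boundary location -- and `s > 0`
#' is the transition width. The confidence interval on `d0` comes from
#' the profile likelihood (deviance within the chi-square quantile).
#'
#' @param data Data frame with `distance_um` and logical `is_narrow`,
#'   containing both classes.
#' @param conf_level Confidence level of the profile-likelihood interval.
#' @return A list of class `sigmoid_fit`: `d0_um, slope_um, loglik,
#'   ci_d0` (possibly `NA` when the profile bound lies outside the
#'   searched range, e.g. for separated data).
#' @export
fit_sigmoid <- function(data, conf_level = 0.95) {
  stopifnot(all(c("distance_um", "is_narrow") %in% names(data)))
  y <- as.logical(data$is_narrow)
  d <- data$distance_um
  if (length(unique(y)) < 2) {
    stop_domain("single-class data: the boundary is not identifiable")
  }
  fit <- suppressWarnings(
    stats::glm(y ~ d, family = stats::binomial()))
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] == 0) stop_domain("degenerate logistic fit")
  d0 <- -b[1] / b[2]
  slope <- 1 / b[2]
  if (slope <= 0) {
    stop_domain("narrow-spiking probability decreases with distance; ",
                "check the sign convention (positive = inside the target)")
  }
  # profile likelihood on d0: refit the scale with d0 fixed
  dev_at <- function(d0_fix) {
    f <- suppressWarnings(
      stats::glm(y ~ 0 + I(d - d0_fix), family = stats::binomial()))
    stats::deviance(f)
  }
  dev_min <- stats::deviance(fit)
  crit <- dev_min + stats::qchisq(conf_level, 1)
  span <- diff(range(d)) + 6 * abs(slope)
  bound <- function(side) {
    lim <- d0 + side * span
    f <- function(v) dev_at(v) - crit
    if (f(lim) < 0) return(side * Inf)
    tryCatch(stats::uniroot(f, sort(c(d0 + side * 1e-6, lim)))$root,
             error = function(e) NA_real_)
  }
  structure(list(d0_um = unname(d0), slope_um = unname(slope),
                 loglik = as.numeric(stats::logLik(fit)),
                 ci_d0 = c(lower = bound(-1), upper = bound(1)),
                 conf_level = conf_level,
                 n = length(y)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> d0 = %.2f um (%.0f%% CI %.2f..%.2f), slope = %.2f um, n = %d\n",
    x$d0_um, 100 * x$conf_level, x$ci_d0[1], x$ci_d0[2], x$slope_um, x$n))
  invisible(x)
}

#' Fit the boundary transition per track and pooled
#'
#' @param data Data frame with `distance_um`, `is_narrow`, and a `track`
#'   column.
#' @param conf_level Passed to [fit_sigmoid()].
#' @return A list with `pooled` (one `sigmoid_fit`) and `per_track` (a
#'   named list of fits; tracks whose fit fails are reported as `NULL`).
#' @export
fit_sigmoid_by_track <- function(data, conf_level = 0.95) {
  stopifnot("track" %in% names(data))
  per <- lapply(split(data, data$track), function(g) {
    tryCatch(fit_sigmoid(g, conf_level), error = function(e) NULL)
  })
  list(pooled = fit_sigmoid(data, conf_level), per_track = per)
}
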