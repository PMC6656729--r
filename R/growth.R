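#' Fit a logistic growth curve to a rosette-area series
#'
#' Least-squares fit of the 3-parameter logistic
#' `A(t) = K / (1 + exp(-r (t - t0)))` by Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). Starting values: `K` from the maximum area,
#' `t0` from the time of half-maximum, `r` from the early log-linear slope
#' (exponential phase of the logistic). A fit is flagged unconverged when
#' the optimizer fails or when the fitted asymptote exceeds ten times the
#' largest observed area (no plateau in the data, e.g. a still-linear
#' series).
#'
#' @param day numeric time points (d); at least 5, spanning the inflection.
#' @param area rosette areas (mm^2), same length as `day`.
#' @return list of class `growth_fit` with `K` (mm^2), `r` (d^-1), `t0`
#'   (d), `rss`, `converged`.
#' @export
fit_logistic_growth <- function(day, area) {
  stopifnot(length(day) == length(area), length(day) >= 5,
            all(is.finite(day)), all(is.finite(area)))
  K0 <- max(area)
  t00 <- day[which.min(abs(area - K0 / 2))]
  early <- area > 0 & area < K0 / 2
  r0 <- if (sum(early) >= 2) {
    sl <- stats::coef(stats::lm(log(area[early]) ~ day[early]))[2]
    max(sl, 0.01)
  } else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      area ~ K / (1 + exp(-r * (day - t0))),
      start = list(K = K0, r = r0, t0 = t00),
      lower = c(K = 1e-8, r = 1e-8, t0 = min(day) - diff(range(day))),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("logistic fit did not converge; start values reported")
    return(structure(list(K = K0, r = r0, t0 = t00, rss = NA_real_,
                          converged = FALSE), class = "growth_fit"))
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  # a logistic that cannot beat a straight line carries no sigmoid signal
  # (typical of series still in the linear phase, without a plateau)
  rss_line <- sum(stats::resid(stats::lm(area ~ day))^2)
  conv <- isTRUE(fit$convInfo$isConv) && cf[["K"]] <= 10 * max(area) &&
    rss < rss_line
  if (!conv) warning("logistic fit flagged unconverged (no plateau?)")
  structure(list(K = cf[["K"]], r = cf[["r"]], t0 = cf[["t0"]],
                 rss = rss, converged = conv),
            class = "growth_fit")
}

#' @exportS3Method base::print
print.growth_fit <- function(x, ...) {
  cat("growth_fit: K =", format(x$K, digits = 5), "mm^2, r =",
      format(x$r, digits = 4), "d^-1, t0 =", format(x$t0, digits = 4),
      "d; converged:", x$converged, "\n")
  invisible(x)
}

#' Relative growth rate at the inflection point
#'
#' For the logistic, the absolute slope at the inflection is `r K / 4` and
#' the area there is `K / 2`, so the relative growth rate
#' `(dA/dt) / A = r / 2` (mm^2 mm^-2 d^-1) — dimensionless per day, hence
#' invariant to any rescaling of the areas.
#'
#' @param fit converged [fit_logistic_growth()] result.
#' @return RGR in mm^2 mm^-2 d^-1.
#' @export
rgr_at_inflection <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!isTRUE(fit$converged)) {
    stop("RGR requires a converged growth fit")
  }
  fit$r / 2
}

#' Fit growth curves for every plant in a series table
#'
#' @param series data.frame with columns `plant`, `day`, `area` (as
#'   produced by [simulate_growth_series()]).
#' @return data.frame with one row per plant: `plant`, `K`, `r`, `t0`,
#'   `rgr`, `converged`.
#' @export
fit_growth_table <- function(series) {
  stopifnot(all(c("plant", "day", "area") %in% names(series)))
  out <- lapply(split(series, series$plant), function(d) {
    f <- suppressWarnings(fit_logistic_growth(d$day, d$area))
    data.frame(plant = d$plant[1], K = f$K, r = f$r, t0 = f$t0,
               rgr = if (f$converged) rgr_at_inflection(f) else NA_real_,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
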