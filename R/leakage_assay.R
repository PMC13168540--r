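#' Four-parameter logistic curve
#'
#' `y = c + (d - c) / (1 + (x/e)^b)`. With `b > 0` the response falls from
#' `d` (at x = 0) to `c`; with `b < 0` it rises from `c` to `d`, the usual
#' shape for dose-dependent dye release. At `x = e` the response is the
#' midpoint `(c + d) / 2` regardless of the slope; `e` is the EC50.
#'
#' @param x concentration(s), >= 0.
#' @param b hill slope.
#' @param c,d asymptotes (percent release).
#' @param e EC50 (same unit as `x`), > 0.
#' @return numeric response(s).
#' @export
fourpl <- function(x, b, c, d, e) {
  r <- (x / e)^b
  ifelse(is.nan(r), (c + d) / 2, c + (d - c) / (1 + r))
}

#' Dilution-corrected calcein release
#'
#' `I% = (I1 - f * I0) / (I2 - f * I0) * 100`, where `I0`, `I1`, `I2` are
#' fluorescence before saponin, after saponin, and after Triton X-100, and
#' `f` is the assay dilution factor (default 0.89) recalculating the initial
#' intensity before dilution. Noisy data may fall outside [0, 100]; values
#' are not clipped but flagged in the `"flagged"` attribute.
#'
#' @param I0,I1,I2 fluorescence readings (AU); alternatively pass a
#'   data.frame with columns `I0`, `I1`, `I2` as the first argument.
#' @param dilution_factor dimensionless dilution correction in (0, 1].
#' @return numeric percent release with logical attribute `"flagged"`.
#' @export
percent_release <- function(I0, I1 = NULL, I2 = NULL,
                            dilution_factor = 0.89) {
  if (is.data.frame(I0)) {
    df <- I0
    stopifnot(all(c("I0", "I1", "I2") %in% names(df)))
    I1 <- df$I1; I2 <- df$I2; I0 <- df$I0
  }
  if (dilution_factor <= 0 || dilution_factor > 1)
    stop("'dilution_factor' must lie in (0, 1]", call. = FALSE)
  if (any(I0 < 0 | I1 < 0 | I2 < 0))
    stop("fluorescence intensities must be >= 0", call. = FALSE)
  den <- I2 - dilution_factor * I0
  if (any(den <= 0))
    stop("invalid measurement: I2 - f*I0 must be > 0", call. = FALSE)
  rel <- (I1 - dilution_factor * I0) / den * 100
  structure(rel, flagged = rel < 0 | rel > 100)
}

# Accepts a data.frame with concentration(_uM) and release columns.
get_dose_response <- function(curve) {
  cn <- if ("concentration" %in% names(curve)) "concentration"
        else if ("concentration_uM" %in% names(curve)) "concentration_uM"
        else stop("curve needs a 'concentration' or 'concentration_uM' column",
                  call. = FALSE)
  if (!"release" %in% names(curve)) {
    if (all(c("I0", "I1", "I2") %in% names(curve)))
      curve$release <- as.numeric(percent_release(curve))
    else stop("curve needs a 'release' column (or I0/I1/I2 triplets)",
              call. = FALSE)
  }
  list(x = curve[[cn]], y = curve$release)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of [fourpl()] by the Levenberg-Marquardt algorithm
#' (via \pkg{minpack.lm}), with self-starting initial values: the asymptotes
#' from the mean responses at the lowest and highest concentration, the EC50
#' from the concentration whose mean response is nearest the half-range, and
#' slope 1. After fitting, parameters are canonicalized so that `c <= d`
#' (swapping asymptotes and negating the slope leaves the curve unchanged).
#' Standard errors come from the estimated covariance at the optimum.
#' Non-convergence is reported through the `converged` flag, not an error.
#'
#' @param curve data.frame with columns `concentration` (or
#'   `concentration_uM`) and `release` (or raw `I0`/`I1`/`I2` columns);
#'   one row per replicate measurement; at least 5 distinct concentrations.
#' @param init optional named list/vector overriding starting values
#'   (`b`, `c`, `d`, `e`).
#' @return object of class `"fourpl_fit"`: coefficients `b`, `c`, `d`, `e`,
#'   `se` (named), `rss`, `residual_sd`, `n`, `converged`, `censored`
#'   (FALSE), `ci` (NULL until [ec50_profile_ci()]), `message`.
#' @export
fit_4pl <- function(curve, init = NULL) {
  dr <- get_dose_response(curve)
  x <- dr$x; y <- dr$y
  if (length(unique(x)) < 5L)
    stop("need at least 5 distinct concentrations", call. = FALSE)
  means <- tapply(y, x, mean)
  xs <- as.numeric(names(means))
  y_lo <- means[[which.min(xs)]]        # response toward x -> 0
  y_hi <- means[[which.max(xs)]]        # response toward x -> Inf
  half <- (y_lo + y_hi) / 2
  pos <- xs > 0
  e0 <- xs[pos][which.min(abs(means[pos] - half))]
  if (!length(e0) || !is.finite(e0) || e0 <= 0) e0 <- stats::median(xs[pos])
  # slope sign follows the data direction; a sign-inconsistent start makes
  # the Jacobian singular at the initial estimates
  start <- list(b = if (y_lo >= y_hi) 1 else -1,
                c = unname(min(y_lo, y_hi)), d = unname(max(y_lo, y_hi)),
                e = unname(e0))
  if (!is.null(init)) start[names(init)] <- as.list(init)

  failed <- function(msg) structure(list(
    b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_,
    se = c(b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_),
    rss = NA_real_, residual_sd = NA_real_, n = length(y),
    converged = FALSE, censored = FALSE, censor_bound = NA_real_,
    censor_label = NA_character_, ci = NULL, message = msg,
    x = x, y = y), class = "fourpl_fit")

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fourpl(x, b, c, d, e), start = start,
                      lower = c(-Inf, -Inf, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-8, ptol = 1e-8)),
    error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  if (cf[["c"]] > cf[["d"]]) {   # canonicalize: c is the lower asymptote
    cf[c("c", "d")] <- cf[c("d", "c")]
    se[c("c", "d")] <- se[c("d", "c")]
    cf[["b"]] <- -cf[["b"]]
  }
  rss <- sum(stats::resid(fit)^2)
  structure(list(
    b = unname(cf[["b"]]), c = unname(cf[["c"]]), d = unname(cf[["d"]]),
    e = unname(cf[["e"]]),
    se = se[c("b", "c", "d", "e")], rss = rss,
    residual_sd = sqrt(rss / max(1L, length(y) - 4L)), n = length(y),
    converged = TRUE, censored = FALSE, censor_bound = NA_real_,
    censor_label = NA_character_, ci = NULL, message = "converged",
    x = x, y = y), class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("fourpl_fit: did not converge (", x$message, ")\n", sep = "")
  } else {
    cat(sprintf(
      "fourpl_fit: EC50 = %.4g (SE %.3g), slope %.3g, asymptotes [%.3g, %.3g]\n",
      x$e, x$se[["e"]], x$b, x$c, x$d))
    if (!is.null(x$ci))
      cat(sprintf("  95%% profile CI: [%.4g, %s]\n", x$ci[1],
                  if (is.finite(x$ci[2])) sprintf("%.4g", x$ci[2]) else "open"))
  }
  if (isTRUE(x$censored))
    cat("  censored: EC50 ", x$censor_label, "\n", sep = "")
  invisible(x)
}

# Profile residual sum of squares at fixed EC50: the asymptotes are linear
# given (b, e), so only the slope needs a 1D optimization.
profile_rss_fixed_e <- function(x, y, e, b_center) {
  rss_given_b <- function(b) {
    u <- 1 / (1 + (x / e)^b)
    u[is.nan(u)] <- 0.5
    X <- cbind(1, u)
    qr_ <- qr(X)
    if (qr_$rank < 2L) return(sum((y - mean(y))^2))
    sum(qr.resid(qr_, y)^2)
  }
  opt <- stats::optim(b_center, rss_given_b, method = "Brent",
                      lower = b_center - 15, upper = b_center + 15)
  opt$value
}

#' Profile-likelihood confidence interval for the EC50
#'
#' Profiles the residual sum of squares over a fixed EC50, re-optimizing the
#' remaining parameters, and inverts the F test
#' `RSS(e) <= RSS_hat * (1 + qF(level; 1, n - 4) / (n - 4))`; the crossing
#' points are located by bisection to a relative tolerance of 1e-4. When the
#' upper crossing lies beyond 10x the largest tested concentration, an open
#' interval (`Inf`) is reported.
#'
#' @param fit a converged [fit_4pl()] result.
#' @param curve the dose-response data used for the fit (optional; the fit
#'   stores its data).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)` with attribute `"level"`; also stored
#'   in the returned value of [fit_4pl()] if reassigned by the caller.
#' @export
ec50_profile_ci <- function(fit, curve = NULL, level = 0.95) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) stop("cannot profile a non-converged fit",
                           call. = FALSE)
  if (!is.null(curve)) { dr <- get_dose_response(curve); x <- dr$x; y <- dr$y }
  else { x <- fit$x; y <- fit$y }
  n <- length(y)
  thresh <- fit$rss * (1 + stats::qf(level, 1, n - 4L) / (n - 4L))
  inside <- function(e) profile_rss_fixed_e(x, y, e, fit$b) <= thresh
  e_hat <- fit$e
  e_open <- 10 * max(x)

  # bisection keeping [ein inside, eout outside], to 1e-4 relative tolerance
  bisect <- function(ein, eout) {
    for (it in 1:200) {
      mid <- sqrt(ein * eout)
      if (inside(mid)) ein <- mid else eout <- mid
      if (abs(eout - ein) / max(ein, eout, 1e-300) < 1e-4) break
    }
    (ein + eout) / 2
  }
  # upper bound: geometric expansion from e_hat (inside by construction)
  lo_in <- e_hat; hi <- e_hat * (1 + 1e-4)
  while (hi <= e_open && inside(hi)) { lo_in <- hi; hi <- hi * 1.25 }
  up <- if (hi > e_open) {
    if (inside(e_open)) Inf else bisect(lo_in, e_open)
  } else bisect(lo_in, hi)
  # lower bound: geometric contraction from e_hat
  hi_in <- e_hat; lo <- e_hat / (1 + 1e-4)
  floor_e <- e_hat * 1e-9
  while (lo >= floor_e && inside(lo)) { hi_in <- lo; lo <- lo / 1.25 }
  low <- if (lo < floor_e && inside(lo)) 0 else bisect(hi_in, lo)
  structure(c(lower = low, upper = up), level = level)
}

#' Censor an EC50 beyond the tested concentration range
#'
#' Flags a fit as censored (`EC50 > c_max`) when (a) the fit failed to
#' converge, (b) the fitted EC50 exceeds `c_max`, or (c) no plateau was
#' reached: the maximum observed mean response is below half the fitted
#' upper asymptote while the asymptote's standard error exceeds half its
#' value. Otherwise the fit is returned unchanged.
#'
#' @param fit a [fit_4pl()] result (converged or not).
#' @param curve the dose-response data (optional; the fit stores its data).
#' @param c_max largest tested concentration (uM).
#' @return the fit, possibly with `censored = TRUE` and a textual bound.
#' @export
censor_ec50 <- function(fit, curve = NULL, c_max = 100) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!is.null(curve)) { dr <- get_dose_response(curve); x <- dr$x; y <- dr$y }
  else { x <- fit$x; y <- fit$y }
  max_mean <- max(tapply(y, x, mean))
  no_plateau <- fit$converged && is.finite(fit$se[["d"]]) &&
    max_mean < 0.5 * fit$d && fit$se[["d"]] > fit$d / 2
  if (!fit$converged || (fit$converged && fit$e > c_max) || no_plateau) {
    fit$censored <- TRUE
    fit$censor_bound <- c_max
    fit$censor_label <- sprintf("> %g uM", c_max)
  }
  fit
}
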