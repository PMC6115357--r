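#' Evaluate the Naka-Rushton displacement response function
#'
#' R(d) = Rmax * d^n / (d^n + d50^n) + b: a saturating hyperbolic-ratio
#' function, equal to the baseline `b` at d = 0, to `Rmax/2 + b` at
#' d = d50, and approaching `Rmax + b` for large displacements.
#'
#' @param d Displacement(s) in arcmin, >= 0.
#' @param p An [nr_params()] object (or list with rmax, d50, n, b).
#' @return Response in microvolts, same length as `d`.
#' @export
nr_eval <- function(d, p) {
  if (any(d < 0)) stop("domain error: displacement must be >= 0")
  dn <- d^p$n
  p$rmax * dn / (dn + p$d50^p$n) + p$b
}

#' Fit a Naka-Rushton function to a displacement response
#'
#' Bounded weighted least squares with a deterministic multi-start grid
#' (d50 starts at the displacement grid quartiles, exponent starts at
#' 0.5, 1, 2, 4), optimized by L-BFGS-B. Bounds: Rmax in [0, 10 max(amp)],
#' d50 in [0.1 d_min, 10 d_max], n in (0, 6], b in [0, max(amp)]
#' (amplitudes are magnitudes, so the baseline cannot be negative). The
#' reported fit is the best over all starts. Flat data yield a degenerate
#' fit with Rmax near 0 and b near the mean, flagged as such.
#'
#' @param displacements Displacement grid, arcmin.
#' @param amplitudes Response amplitudes, microvolts (>= 0).
#' @param weights Optional positive weights (e.g. 1/SEM); default
#'   unweighted.
#' @return An `nr_fit`: `params` ([nr_params()]), `rss`, `converged`,
#'   `degenerate`, `start_id`, `n_points`.
#' @export
fit_nr <- function(displacements, amplitudes, weights = NULL) {
  stopifnot(length(displacements) == length(amplitudes))
  ok <- is.finite(displacements) & is.finite(amplitudes)
  d <- displacements[ok]; y <- amplitudes[ok]
  if (length(d) < 4) stop("need at least 4 points to fit 4 parameters")
  if (any(y < 0)) stop("amplitudes must be >= 0")
  w <- if (is.null(weights)) rep(1, length(d)) else weights[ok]
  stopifnot(all(w > 0))

  ymax <- max(y)
  if (ymax == 0) {
    return(structure(list(params = nr_params(0, stats::median(d), 1, 0),
                          rss = 0, converged = TRUE, degenerate = TRUE,
                          start_id = 0L, n_points = length(d)),
                     class = "nr_fit"))
  }
  lower <- c(rmax = 0, d50 = 0.1 * min(d), n = 1e-3, b = 0)
  upper <- c(rmax = 10 * ymax, d50 = 10 * max(d), n = 6, b = ymax)
  obj <- function(th) {
    r <- th[1] * d^th[3] / (d^th[3] + th[2]^th[3]) + th[4]
    sum(w * (y - r)^2)
  }
  d50_starts <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  n_starts <- c(0.5, 1, 2, 4)
  starts <- expand.grid(d50 = d50_starts, n = n_starts)
  best <- NULL; best_id <- 0L
  for (i in seq_len(nrow(starts))) {
    th0 <- c(ymax - min(y), starts$d50[i], starts$n[i], min(y))
    th0 <- pmin(pmax(th0, lower + 1e-9), upper - 1e-9)
    fit <- try(stats::optim(th0, obj, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit; best_id <- i
    }
  }
  if (is.null(best)) stop("all starts failed to converge")
  th <- best$par
  degenerate <- th[1] < 1e-3 * ymax || stats::sd(y) < 1e-9 * ymax
  structure(list(params = nr_params(th[1], th[2], max(th[3], 1e-3), th[4]),
                 rss = best$value,
                 converged = best$convergence == 0,
                 degenerate = degenerate,
                 start_id = best_id, n_points = length(d)),
            class = "nr_fit")
}

#' @export
print.nr_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<nr_fit> Rmax=%.3g uV, d50=%.3g arcmin, n=%.3g, b=%.3g uV (RSS %.3g%s)\n",
              p$rmax, p$d50, p$n, p$b, x$rss,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Anti-phase suppression index
#'
#' Ratio of anti-phase to in-phase half-saturation displacement,
#' d50_anti / d50_in. A value above 1 indicates a rightward shift of the
#' anti-phase response function along the displacement axis, i.e.
#' suppression of the response to interocularly opposed motion.
#'
#' @param fit_inphase,fit_antiphase `nr_fit` objects (or `nr_params`).
#' @return Dimensionless ratio.
#' @export
suppression_index <- function(fit_inphase, fit_antiphase) {
  get_par <- function(f) {
    if (inherits(f, "nr_fit")) {
      if (isTRUE(f$degenerate) || !isTRUE(f$converged))
        stop("suppression index undefined: degenerate or unconverged fit")
      f$params
    } else f
  }
  p_in <- get_par(fit_inphase)
  p_anti <- get_par(fit_antiphase)
  p_anti$d50 / p_in$d50
}
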