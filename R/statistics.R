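#' Vector average of per-participant complex coefficients
#'
#' Averages real and imaginary parts across participants and takes the
#' amplitude of the result. Because response phase is consistent across
#' participants, vector averaging suppresses non-phase-locked noise that
#' would survive averaging of individual amplitudes. The SEM is computed
#' from the projected amplitudes (see [projected_amplitude()]), whose mean
#' equals the vector-average amplitude exactly.
#'
#' @param x Complex vector, one trial-mean coefficient per participant
#'   (each participant's re/im already averaged over their valid epochs).
#' @return A list: `mean` (complex), `amplitude`, `sem`, `n`,
#'   `projections` (per-participant projected amplitudes).
#' @export
vector_average <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0)
    return(list(mean = NA_complex_, amplitude = NA_real_, sem = NA_real_,
                n = 0L, projections = numeric(0), empty = TRUE))
  m <- mean(x)
  proj <- projected_amplitude(x, m)
  list(mean = m, amplitude = Mod(m),
       sem = if (n > 1) stats::sd(proj) / sqrt(n) else NA_real_,
       n = n, projections = proj)
}

#' Displacement average across sweep bins
#'
#' Averages real and imaginary parts across the displacement bins within
#' each participant first, then vector-averages across participants. The
#' two-stage order matters when validity is unbalanced: it weights each
#' participant equally regardless of how many epochs survived cleaning.
#'
#' @param x Participants x bins complex matrix (NA for missing bins).
#' @return As [vector_average()], plus `per_participant` (complex vector
#'   of within-participant bin means).
#' @export
displacement_average <- function(x) {
  stopifnot(is.matrix(x))
  per_part <- apply(x, 1, function(v) mean(v[!is.na(v)]))
  out <- vector_average(per_part)
  out$per_participant <- per_part
  out
}

#' Projected amplitude of participant vectors onto the group mean
#'
#' The signed scalar projection of each participant's complex coefficient
#' onto the unit vector in the direction of the group vector average:
#' p_i = Re(x_i * Conj(ybar)) / |ybar|. The group mean includes the
#' participant being projected; with that convention the mean of the
#' projections equals the amplitude of the vector average exactly, while
#' preserving cross-participant phase consistency in the error estimate.
#'
#' @param x Complex vector of participant coefficients.
#' @param group_mean Complex group vector average (defaults to `mean(x)`).
#' @return Numeric vector of signed projected amplitudes, microvolts.
#' @export
projected_amplitude <- function(x, group_mean = mean(x, na.rm = TRUE)) {
  if (!is.finite(Mod(group_mean)) || Mod(group_mean) == 0) {
    warning("group mean has zero amplitude: projection undefined")
    return(rep(NA_real_, length(x)))
  }
  u <- group_mean / Mod(group_mean)
  Re(x * Conj(u))
}

#' Paired t comparison of projected amplitudes
#'
#' Two-tailed paired t test on per-participant differences, with Cohen's d
#' for paired samples (mean difference over SD of differences). Identical
#' inputs give t = 0, p = 1 by convention.
#'
#' @param a,b Numeric vectors of projected amplitudes, same participants
#'   in the same order.
#' @param labels Length-2 character vector naming the conditions.
#' @return One-row data.frame: `t`, `df`, `p`, `d`, `mean_diff`, `n`.
#' @export
paired_t_comparison <- function(a, b, labels = c("A", "B")) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("paired comparison needs at least 3 complete pairs")
  diffs <- a - b
  sdd <- stats::sd(diffs)
  if (sdd == 0) {
    tt <- 0; p <- 1; d <- if (mean(diffs) == 0) 0 else Inf
  } else {
    res <- stats::t.test(diffs)
    tt <- unname(res$statistic); p <- res$p.value
    d <- mean(diffs) / sdd
  }
  data.frame(pair = paste(labels, collapse = " vs "), t = tt, df = n - 1,
             p = p, d = d, mean_diff = mean(diffs), n = n)
}

#' Bin-wise and displacement-average condition comparison
#'
#' For each displacement bin, and for the displacement average, projects
#' each condition's participant coefficients onto that condition's group
#' mean and runs the paired t test on the projected amplitudes.
#'
#' @param a,b Participants x bins complex matrices for the two conditions
#'   (same participant order).
#' @param labels Condition names.
#' @param bonferroni Apply Bonferroni correction across the bins
#'   (off by default; per-bin p values are conventionally reported
#'   uncorrected alongside the displacement average).
#' @return Data.frame with one row per bin plus an `"average"` row.
#' @export
condition_comparison <- function(a, b, labels = c("A", "B"),
                                 bonferroni = FALSE) {
  stopifnot(dim(a) == dim(b))
  nb <- ncol(a)
  rows <- lapply(seq_len(nb), function(k) {
    pa <- projected_amplitude(a[, k])
    pb <- projected_amplitude(b[, k])
    cbind(bin = as.character(k), paired_t_comparison(pa, pb, labels))
  })
  da <- displacement_average(a)
  db <- displacement_average(b)
  rows[[nb + 1]] <- cbind(bin = "average",
                          paired_t_comparison(da$projections,
                                              db$projections, labels))
  out <- do.call(rbind, rows)
  if (bonferroni) {
    is_bin <- out$bin != "average"
    out$p[is_bin] <- pmin(1, out$p[is_bin] * nb)
  }
  out
}

#' Noise floor from projected sideband estimates
#'
#' Incoherent (amplitude-domain) average of the two-sideband mean
#' amplitude across trials, participants and conditions, per displacement
#' bin. Sidebands must have been projected through the same component
#' weights as the signal.
#'
#' @param sidebands List (over trials/participants/conditions) of
#'   harmonics x 2 x bins complex arrays as produced by
#'   [project_through()] (`$noise`), or a single such array.
#' @param harmonic Row to use (position in the harmonic dimension), or
#'   NULL to average all.
#' @return Numeric vector, one noise amplitude per bin (microvolts).
#' @export
noise_floor <- function(sidebands, harmonic = NULL) {
  if (!is.list(sidebands)) sidebands <- list(sidebands)
  per <- lapply(sidebands, function(a) {
    amp <- Mod(a)
    if (!is.null(harmonic)) amp <- amp[harmonic, , , drop = FALSE]
    apply(amp, length(dim(amp)), mean)
  })
  Reduce(`+`, per) / length(per)
}
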