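#' Harmonic frequency set
#'
#' Target frequencies are the first `n_harmonics` multiples of the
#' stimulation frequency; each harmonic carries two noise sidebands at
#' +/- `sideband_offset` Hz. With 1-s analysis bins all target and
#' sideband frequencies fall on the 1 Hz bin resolution, so they are
#' mutually orthogonal over a bin.
#'
#' @param f_stim Stimulation frequency in Hz.
#' @param n_harmonics Number of harmonics.
#' @param sideband_offset Sideband distance in Hz.
#' @return A `harmonic_set`: `harmonics`, `freqs`, `sidebands` (matrix
#'   n_harmonics x 2), `all_freqs` (sorted unique target + sideband
#'   frequencies).
#' @export
harmonic_set <- function(f_stim = 2, n_harmonics = 4, sideband_offset = 1) {
  h <- seq_len(n_harmonics)
  freqs <- h * f_stim
  sb <- cbind(lower = freqs - sideband_offset, upper = freqs + sideband_offset)
  if (any(sb <= 0)) stop("sideband below DC: decrease sideband_offset")
  structure(list(f_stim = f_stim, harmonics = h, freqs = freqs,
                 sidebands = sb,
                 all_freqs = sort(unique(c(freqs, as.numeric(sb))))),
            class = "harmonic_set")
}

#' Windowed Fourier coefficients of one analysis bin
#'
#' Least-squares projection of each channel onto cos/sin pairs at the
#' requested frequencies; with a whole number of cycles per bin this
#' equals the scaled DFT bin. The convention is
#' c = (2/N) * sum x(t) exp(-i 2 pi f t), so a cosine of amplitude A and
#' phase phi yields c = A exp(i phi): `Re` is the cosine (real) part,
#' `Im` the sine (imaginary) part, `Mod` the amplitude in microvolts.
#'
#' @param x Numeric vector (samples) or channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param freqs Frequencies to evaluate, Hz.
#' @return Complex matrix channels x frequencies (a vector input is
#'   treated as one channel).
#' @export
dft_coefficients <- function(x, fs, freqs) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  t <- (seq_len(n) - 1) / fs
  cycles <- freqs * n / fs
  if (any(abs(cycles - round(cycles)) > 1e-8))
    warning("non-integer cycles per bin: spectral leakage expected")
  basis <- exp(-2i * pi * outer(t, freqs))
  out <- (2 / n) * (x %*% basis)
  colnames(out) <- as.character(freqs)
  out
}

#' Recursive least-squares harmonic coefficients per bin
#'
#' Joint multi-frequency exponentially weighted recursive least squares:
#' the signal is regressed on cos/sin pairs at every target and sideband
#' frequency simultaneously, with forgetting factor
#' lambda = 1 - 1/memory_samples (memory equal to the 1-s bin length by
#' default) and inverse-covariance initialisation P = delta * I. The
#' coefficient state is read out at each bin's final sample. On a
#' stationary sinusoid the estimate converges to the true (re, im) with
#' time constant `memory_samples`; the first bin is flagged as burn-in
#' because the filter starts cold.
#'
#' The regressor Gram matrix is shared across channels, so one P
#' recursion serves the whole montage.
#'
#' @param x Channels x samples matrix (or vector) spanning the full trial.
#' @param fs Sampling rate, Hz.
#' @param freqs Frequencies to track (must be distinct and below fs/2).
#' @param bin_ends Sample indices at which coefficients are reported
#'   (default: every `memory_samples`).
#' @param memory_samples Filter memory in samples (default `fs`, i.e. 1 s).
#' @param delta P-matrix initialisation scale.
#' @return Complex array channels x frequencies x bins, with attribute
#'   `burn_in` marking the first bin.
#' @export
rls_coefficients <- function(x, fs, freqs, bin_ends = NULL,
                             memory_samples = fs, delta = 1e4) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (anyDuplicated(freqs))
    stop("configuration error: duplicate frequencies give a singular regressor covariance")
  if (any(freqs >= fs / 2)) stop("frequencies must be below fs/2")
  n <- ncol(x); n_ch <- nrow(x); nf <- length(freqs)
  if (is.null(bin_ends)) bin_ends <- seq(memory_samples, n, by = memory_samples)
  p <- 2L * nf
  lambda <- 1 - 1 / memory_samples
  t_all <- (seq_len(n) - 1) / fs
  # regressors: [cos f1, sin f1, cos f2, sin f2, ...]
  ang <- 2 * pi * outer(t_all, freqs)
  X <- matrix(0, n, p)
  X[, seq(1, p, by = 2)] <- cos(ang)
  X[, seq(2, p, by = 2)] <- sin(ang)
  P <- diag(delta, p)
  W <- matrix(0, p, n_ch)
  out <- array(NA_complex_, dim = c(n_ch, nf, length(bin_ends)),
               dimnames = list(rownames(x), as.character(freqs), NULL))
  bin_i <- 1L
  y <- t(x)
  for (s in seq_len(n)) {
    xt <- X[s, ]
    Px <- P %*% xt
    k <- Px / (lambda + sum(xt * Px))
    P <- (P - tcrossprod(k, Px)) / lambda
    err <- y[s, ] - drop(crossprod(W, xt))
    W <- W + tcrossprod(k, err)
    if (bin_i <= length(bin_ends) && s == bin_ends[bin_i]) {
      out[, , bin_i] <- t(W[seq(1, p, by = 2), , drop = FALSE]) -
        1i * t(W[seq(2, p, by = 2), , drop = FALSE])
      bin_i <- bin_i + 1L
    }
  }
  attr(out, "burn_in") <- 1L
  out
}

#' Sideband noise estimate for one harmonic
#'
#' Coefficients at f - offset and f + offset Hz computed with the same
#' estimator and samples as the signal coefficient; the scalar noise level
#' is the incoherent mean of the two sideband amplitudes.
#'
#' @param x Samples vector or channels x samples matrix for one bin.
#' @param fs Sampling rate, Hz.
#' @param harmonic_freq Target frequency in Hz (e.g. 4 for 2F at 2 Hz).
#' @param offset Sideband offset, Hz.
#' @return List with `coefficients` (complex channels x 2 matrix at the
#'   lower/upper sidebands) and `level` (per-channel scalar mean sideband
#'   amplitude, microvolts).
#' @export
sideband_noise <- function(x, fs, harmonic_freq, offset = 1) {
  if (harmonic_freq - offset < offset)
    stop("lower sideband below resolvable frequency")
  co <- dft_coefficients(x, fs, c(harmonic_freq - offset,
                                  harmonic_freq + offset))
  list(coefficients = co, level = rowMeans(Mod(co)))
}

#' Extract harmonic coefficient tables from epoched data
#'
#' Estimates complex SSVEP coefficients at each harmonic and its two
#' sidebands, per channel and per 1-s displacement bin, using either the
#' recursive least-squares adaptive filter (`"rls"`, the default) or
#' per-bin DFT projection (`"dft"`). Both estimators agree on stationary
#' input; RLS tracks the sweep adaptively with memory equal to the bin
#' length. Coefficients for invalid channel-epochs are masked.
#'
#' @param epoched An `epoched_data` object (or a `synthetic_recording`,
#'   which is segmented first).
#' @param hset A [harmonic_set()].
#' @param estimator `"rls"` or `"dft"`.
#' @return A `coef_table`: `signal` (complex channels x harmonics x bins),
#'   `noise` (complex channels x harmonics x 2 x bins sideband
#'   coefficients), `valid` (channels x bins), `hset`, `estimator`,
#'   `labels`, and `burn_in_bin` (1 for RLS, NA for DFT).
#' @export
extract_coefficients <- function(epoched, hset = harmonic_set(),
                                 estimator = c("rls", "dft")) {
  estimator <- match.arg(estimator)
  if (inherits(epoched, "synthetic_recording"))
    epoched <- segment_epochs(epoched)
  stopifnot(inherits(epoched, "epoched_data"))
  d <- dim(epoched$data)
  n_ep <- d[1]; n_ch <- d[2]; len <- d[3]
  fs <- epoched$fs
  nh <- length(hset$harmonics)
  freqs <- hset$all_freqs

  co <- if (estimator == "dft") {
    out <- array(NA_complex_, dim = c(n_ch, length(freqs), n_ep),
                 dimnames = list(NULL, as.character(freqs), NULL))
    for (e in seq_len(n_ep))
      out[, , e] <- dft_coefficients(epoched$data[e, , , drop = TRUE],
                                     fs, freqs)
    out
  } else {
    stream <- matrix(0, n_ch, n_ep * len)
    for (e in seq_len(n_ep))
      stream[, ((e - 1) * len + 1):(e * len)] <- epoched$data[e, , , drop = TRUE]
    rls_coefficients(stream, fs, freqs, bin_ends = seq_len(n_ep) * len,
                     memory_samples = len)
  }

  sig <- array(NA_complex_, dim = c(n_ch, nh, n_ep),
               dimnames = list(NULL, as.character(hset$harmonics), NULL))
  noi <- array(NA_complex_, dim = c(n_ch, nh, 2, n_ep),
               dimnames = list(NULL, as.character(hset$harmonics),
                               c("lower", "upper"), NULL))
  fidx <- function(f) match(as.character(f), as.character(freqs))
  for (j in seq_len(nh)) {
    sig[, j, ] <- co[, fidx(hset$freqs[j]), ]
    noi[, j, 1, ] <- co[, fidx(hset$sidebands[j, 1]), ]
    noi[, j, 2, ] <- co[, fidx(hset$sidebands[j, 2]), ]
  }
  structure(list(signal = sig, noise = noi, valid = epoched$valid,
                 hset = hset, estimator = estimator,
                 labels = epoched$labels,
                 burn_in_bin = if (estimator == "rls") 1L else NA_integer_),
            class = "coef_table")
}

#' @export
print.coef_table <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<coef_table> %d ch x %d harmonics x %d bins (%s estimator)\n",
              d[1], d[2], d[3], x$estimator))
  invisible(x)
}

#' Coefficient table as a long-format data frame
#'
#' One row per channel x harmonic x bin with real/imaginary parts,
#' amplitude, validity, and any recording labels. Suitable for CSV export.
#'
#' @param x A `coef_table`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.coef_table <- function(x, ...) {
  d <- dim(x$signal)
  grid <- expand.grid(channel = seq_len(d[1]),
                      harmonic = x$hset$harmonics,
                      bin = seq_len(d[3]))
  co <- as.vector(x$signal)
  lab <- x$labels
  data.frame(participant = if (!is.null(lab)) lab$participant else NA,
             trial = if (!is.null(lab)) lab$trial else NA,
             condition = if (!is.null(lab)) format(lab$condition) else NA,
             grid,
             re = Re(co), im = Im(co), amplitude = Mod(co),
             valid = as.vector(x$valid[grid$channel +
                                         (grid$bin - 1) * d[1]]))
}
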