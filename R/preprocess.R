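#' Bandpass filter a recording
#'
#' Zero-phase 4th-order Butterworth band-pass (forward-backward via
#' `signal::filtfilt`), run `passes` times in cascade. The default band
#' (0.3-50 Hz) and double application minimise power outside the band
#' while preserving SSVEP phase, which downstream complex-domain
#' statistics rely on.
#'
#' @param x Channels x time matrix, numeric vector, or
#'   `synthetic_recording`.
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate (taken from the recording if `x` is one).
#' @param passes Number of cascade applications of the full filter.
#' @param order Butterworth order per pass.
#' @return Same shape/class as the input.
#' @export
bandpass_filter <- function(x, low = 0.3, high = 50, fs = NULL, passes = 2,
                            order = 4) {
  if (inherits(x, "synthetic_recording")) {
    x$samples <- bandpass_filter(x$samples, low, high, x$fs, passes, order)
    return(x)
  }
  if (is.null(fs)) stop("fs is required for matrix/vector input")
  if (fs <= 2 * high)
    stop("configuration error: fs must exceed twice the upper band edge")
  bf <- signal::butter(order, c(low, high) * 2 / fs, type = "pass")
  filt1 <- function(v) {
    # demeaning first keeps the slow 0.3 Hz corner from ringing on the
    # channel offset (the high-pass removes DC asymptotically anyway)
    v <- v - mean(v)
    for (i in seq_len(passes)) v <- signal::filtfilt(bf, v)
    v
  }
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

#' Resample to the analysis rate
#'
#' Polyphase rational resampling (`signal::resample`) to `fs_out`
#' (default 420 Hz, seven samples per 60 Hz video frame). 500 -> 420 uses
#' the exact 21/25 ratio. Rates other than 420 or 500 Hz are accepted
#' with a warning.
#'
#' @param x Channels x time matrix, vector, or `synthetic_recording`.
#' @param fs_in Input sampling rate (from the recording if applicable).
#' @param fs_out Target rate.
#' @return Resampled input; identity when `fs_in == fs_out`.
#' @export
resample_to_420 <- function(x, fs_in = NULL, fs_out = 420) {
  if (inherits(x, "synthetic_recording")) {
    ratio <- fs_out / x$fs
    x$samples <- resample_to_420(x$samples, x$fs, fs_out)
    x$bin_bounds <- cbind(
      start = as.integer(round((x$bin_bounds[, "start"] - 1) * ratio)) + 1L,
      end = as.integer(round((x$bin_bounds[, "end"] - 1) * ratio)) + 1L)
    x$fs <- fs_out
    return(x)
  }
  if (is.null(fs_in)) stop("fs_in is required for matrix/vector input")
  if (fs_in == fs_out) return(x)
  if (!fs_in %in% c(420, 500))
    warning("resampling from a non-standard rate: ", fs_in, " Hz")
  g <- gcd(round(fs_out), round(fs_in))
  p <- round(fs_out) / g
  q <- round(fs_in) / g
  res1 <- function(v) signal::resample(v, p, q)
  if (is.matrix(x)) t(apply(x, 1, res1)) else res1(x)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Detect bad sensors by amplitude criterion
#'
#' A sensor is flagged if strictly more than `frac` of its samples exceed
#' `amp_thresh` microvolts in absolute value. The adult threshold is
#' 30 microvolts; infant data use a more liberal threshold in 30-100.
#'
#' @param x Channels x time matrix or `synthetic_recording`.
#' @param amp_thresh Amplitude threshold in microvolts.
#' @param frac Fraction of samples that must be exceeded (strictly).
#' @return Integer vector of flagged channel indices.
#' @export
detect_bad_sensors <- function(x, amp_thresh = 30, frac = 0.15) {
  if (inherits(x, "synthetic_recording")) x <- x$samples
  unname(which(rowMeans(abs(x) > amp_thresh) > frac))
}

#' Interpolate bad sensors from nearest neighbors
#'
#' Each bad channel is replaced by the arithmetic mean of its six nearest
#' good channels, distance measured in 3-D montage coordinates; other bad
#' channels are never used as donors. Ties are broken by channel index.
#'
#' @param x Channels x time matrix or `synthetic_recording`.
#' @param bad Integer indices of bad channels.
#' @param montage A `montage_spec` matching the channel dimension.
#' @param k Number of donor neighbors (default 6).
#' @return Input with bad channels replaced.
#' @export
interpolate_sensors <- function(x, bad, montage, k = 6) {
  if (inherits(x, "synthetic_recording")) {
    x$samples <- interpolate_sensors(x$samples, bad, montage, k)
    return(x)
  }
  if (length(bad) == 0) return(x)
  n_ch <- nrow(x)
  stopifnot(length(montage$labels) == n_ch)
  good <- setdiff(seq_len(n_ch), bad)
  d <- as.matrix(stats::dist(montage$positions))
  for (ch in bad) {
    if (length(good) < k)
      stop("interpolation error: fewer than ", k,
           " good neighbors for sensor ", montage$labels[ch])
    donors <- good[order(d[ch, good], good)][seq_len(k)]
    x[ch, ] <- colMeans(x[donors, , drop = FALSE])
  }
  x
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across all sensors, so the
#' channel mean is zero at each time point. Idempotent.
#'
#' @param x Channels x time matrix or `synthetic_recording`.
#' @return Re-referenced input.
#' @export
rereference_common_average <- function(x) {
  if (inherits(x, "synthetic_recording")) {
    x$samples <- rereference_common_average(x$samples)
    return(x)
  }
  sweep(x, 2, colMeans(x))
}

#' Segment a trial into fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' `epoch_ms` milliseconds aligned to the start; with the default 1000 ms
#' at 2 Hz stimulation each epoch holds exactly two stimulus cycles and
#' maps to one displacement bin.
#'
#' @param x Channels x time matrix or `synthetic_recording`.
#' @param epoch_ms Epoch length in ms.
#' @param fs Sampling rate (from the recording if applicable).
#' @return An `epoched_data` object: `data` (epochs x channels x samples
#'   array), `fs`, `epoch_map` (epoch -> bin), `valid` (channels x epochs
#'   logical mask, all `TRUE`).
#' @export
segment_epochs <- function(x, epoch_ms = 1000, fs = NULL) {
  labels <- NULL
  if (inherits(x, "synthetic_recording")) {
    fs <- x$fs
    labels <- x$labels
    x <- x$samples
  }
  if (is.null(fs)) stop("fs is required for matrix input")
  len <- round(fs * epoch_ms / 1000)
  n <- ncol(x)
  if (n %% len != 0)
    stop("segmentation error: trial length ", n,
         " is not a multiple of the epoch length ", len)
  n_ep <- n %/% len
  dat <- array(0, dim = c(n_ep, nrow(x), len))
  for (e in seq_len(n_ep))
    dat[e, , ] <- x[, ((e - 1) * len + 1):(e * len)]
  structure(list(data = dat, fs = fs,
                 epoch_map = data.frame(epoch = seq_len(n_ep),
                                        bin = seq_len(n_ep)),
                 valid = matrix(TRUE, nrow(x), n_ep),
                 labels = labels),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_data> %d epochs x %d ch x %d samples @ %g Hz (%d%% valid)\n",
              d[1], d[2], d[3], x$fs, round(100 * mean(x$valid))))
  invisible(x)
}

#' Reject noisy channel-epochs and blink-contaminated epochs
#'
#' A channel-epoch is rejected if strictly more than `frac` of its samples
#' exceed `noise_thresh` microvolts, or if any sample exceeds
#' `peak_thresh`. If strictly more than `max_peak_sensors` sensors violate
#' the peak threshold within an epoch, that epoch is rejected for all
#' channels (the typical blink/eye-movement signature).
#'
#' @param epoched An `epoched_data` object.
#' @param noise_thresh,frac Sample-noise criterion (default 30 uV, 10%).
#' @param peak_thresh Peak/blink threshold (default 60 uV).
#' @param max_peak_sensors Sensor count above which the whole epoch goes.
#' @return The `epoched_data` with its `valid` mask updated and a
#'   `cleaning_report` element recording thresholds, per-channel rejected
#'   epochs, and fully rejected epochs.
#' @export
reject_epochs <- function(epoched, noise_thresh = 30, frac = 0.10,
                          peak_thresh = 60, max_peak_sensors = 7) {
  stopifnot(inherits(epoched, "epoched_data"))
  d <- dim(epoched$data)
  n_ep <- d[1]; n_ch <- d[2]
  valid <- epoched$valid
  peak_viol <- matrix(FALSE, n_ch, n_ep)
  for (e in seq_len(n_ep)) {
    seg <- abs(epoched$data[e, , , drop = TRUE])
    noisy <- rowMeans(seg > noise_thresh) > frac
    peaky <- apply(seg > peak_thresh, 1, any)
    peak_viol[, e] <- peaky
    valid[, e] <- valid[, e] & !noisy & !peaky
  }
  full_reject <- which(colSums(peak_viol) > max_peak_sensors)
  valid[, full_reject] <- FALSE
  epoched$valid <- valid
  epoched$cleaning_report <- modify_report(
    epoched$cleaning_report,
    rejected_epochs_by_channel = apply(!valid, 1, which),
    fully_rejected_epochs = full_reject,
    thresholds = list(noise_thresh = noise_thresh, frac = frac,
                      peak_thresh = peak_thresh,
                      max_peak_sensors = max_peak_sensors))
  epoched
}

modify_report <- function(report, ...) {
  if (is.null(report)) report <- structure(list(), class = "cleaning_report")
  utils::modifyList(report, list(...))
}

#' Serialize a cleaning report as JSON
#'
#' Writes the thresholds and every exclusion/interpolation/rejection
#' decision of a preprocessing run to a JSON file.
#'
#' @param report The `cleaning_report` attached to an `epoched_data`
#'   object by [preprocess_trial()] or [reject_epochs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Full preprocessing chain for one trial
#'
#' Runs the fixed cleaning order: bandpass filter (applied twice) ->
#' resample to 420 Hz -> bad-sensor detection and interpolation ->
#' common-average re-reference -> segmentation into 1-s epochs ->
#' channel-epoch and whole-epoch rejection. Every decision lands in the
#' attached `cleaning_report`.
#'
#' @param rec A `synthetic_recording` (or compatible list).
#' @param montage A `montage_spec`.
#' @param amp_thresh Bad-sensor amplitude threshold (microvolts).
#' @param filter Logical; skip the bandpass/resample stage when the data
#'   are already band-limited synthetic signals at 420 Hz.
#' @param ... Passed to [reject_epochs()].
#' @return An `epoched_data` object with `cleaning_report`.
#' @export
preprocess_trial <- function(rec, montage, amp_thresh = 30, filter = TRUE,
                             ...) {
  if (filter) {
    rec <- bandpass_filter(rec)
    if (rec$fs != 420) rec <- resample_to_420(rec)
  }
  bad <- detect_bad_sensors(rec, amp_thresh = amp_thresh)
  rec <- interpolate_sensors(rec, bad, montage)
  rec <- rereference_common_average(rec)
  ep <- segment_epochs(rec)
  ep$cleaning_report <- modify_report(
    NULL, excluded_sensors = bad, interpolated_sensors = bad,
    amp_thresh = amp_thresh)
  reject_epochs(ep, ...)
}
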