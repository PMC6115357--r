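# Minimal single-record EDF I/O. EDF stores a fixed-size ASCII header
# followed by int16 little-endian samples; physical scaling is linear
# between the digital and physical ranges declared per signal. Only the
# subset needed for sweep trials is implemented: one data record holding
# the whole trial, identical sampling rate across channels.

pad <- function(x, width) formatC(as.character(x), width = -width)

#' Write a recording to EDF
#'
#' European Data Format: 16-bit samples scaled to a declared physical
#' range (default +/-500 microvolts, which sets the quantization step to
#' 1000/65534 ~ 0.0153 uV). One data record holds the entire trial;
#' channel labels come from the recording or default to E1..En.
#'
#' @param rec A `synthetic_recording` or list with `samples` (channels x
#'   time) and `fs`.
#' @param path Output file path.
#' @param phys_range Physical range in microvolts (symmetric).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 500) {
  x <- rec$samples
  fs <- rec$fs
  n_sig <- nrow(x); n <- ncol(x)
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("E", seq_len(n_sig))
  if (any(abs(x) > phys_range))
    warning("samples exceed the physical range and will clip")
  dig <- round(pmin(pmax(x, -phys_range), phys_range) *
                 32767 / phys_range)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + n_sig), 8), pad("", 44), pad(1, 8),
    pad(format(n / fs, digits = 8), 8), pad(n_sig, 4))
  field <- function(vals, width)
    paste(vapply(vals, pad, "", width = width), collapse = "")
  hdr <- paste0(hdr,
    field(labels, 16), field(rep("", n_sig), 80),
    field(rep("uV", n_sig), 8),
    field(rep(-phys_range, n_sig), 8), field(rep(phys_range, n_sig), 8),
    field(rep(-32767L, n_sig), 8), field(rep(32767L, n_sig), 8),
    field(rep("", n_sig), 80), field(rep(n, n_sig), 8),
    field(rep("", n_sig), 32))
  writeChar(hdr, con, eos = NULL)
  for (s in seq_len(n_sig))
    writeBin(as.integer(dig[s, ]), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return List with `samples` (channels x time, microvolts), `fs`,
#'   `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))
  rdn <- function(width) vapply(seq_len(n_sig), function(i) rd(width), "")
  labels <- rdn(16); rdn(80); rdn(8)
  pmin_ <- as.numeric(rdn(8)); pmax_ <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  out <- matrix(0, n_sig, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2,
                     endian = "little")
      phys <- pmin_[s] + (dig - dmin[s]) *
        (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- phys
    }
  }
  rownames(out) <- labels
  list(samples = out, fs = spr[1] * n_rec / (dur * n_rec), labels = labels)
}

cond_to_list <- function(cond) unclass(cond)

list_to_cond <- function(x) do.call(condition_spec, x)

truth_to_list <- function(truth) {
  list(condition = cond_to_list(truth$condition),
       harmonics = lapply(truth$harmonics, function(h)
         list(params = unclass(h$params), phase = h$phase,
              topography = h$topography)))
}

#' Binary array container with JSON sidecar
#'
#' Stores samples as raw little-endian doubles (`<prefix>.f64`) with a
#' JSON sidecar (`<prefix>.json`) carrying dimensions, sampling rate, bin
#' boundaries, condition, seed and planted ground-truth parameters.
#' The roundtrip is bit-identical.
#'
#' @param rec A `synthetic_recording`.
#' @param prefix Path prefix (without extension).
#' @return `read_container` returns a `synthetic_recording`.
#' @export
write_container <- function(rec, prefix) {
  con <- file(paste0(prefix, ".f64"), "wb")
  writeBin(as.vector(rec$samples), con, size = 8, endian = "little")
  close(con)
  meta <- list(n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
               channel_labels = rownames(rec$samples),
               fs = rec$fs, bin_bounds = rec$bin_bounds,
               labels = list(participant = rec$labels$participant,
                             trial = rec$labels$trial,
                             condition = cond_to_list(rec$labels$condition)),
               seed = rec$seed,
               ground_truth = truth_to_list(rec$ground_truth))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_container
#' @export
read_container <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(prefix, ".f64"), "rb")
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  samples <- matrix(x, meta$n_channels, meta$n_samples)
  rownames(samples) <- meta$channel_labels
  cond <- list_to_cond(as.list(meta$labels$condition))
  truth <- structure(
    list(condition = list_to_cond(as.list(meta$ground_truth$condition)),
         harmonics = lapply(meta$ground_truth$harmonics, function(h)
           list(params = structure(as.list(h$params), class = "nr_params"),
                phase = h$phase, topography = h$topography))),
    class = "ground_truth_response")
  bb <- as.matrix(meta$bin_bounds)
  storage.mode(bb) <- "integer"
  colnames(bb) <- c("start", "end")
  structure(list(samples = samples, fs = meta$fs, bin_bounds = bb,
                 labels = list(participant = meta$labels$participant,
                               trial = meta$labels$trial, condition = cond),
                 ground_truth = truth, artifact_ledger = list(),
                 seed = meta$seed),
            class = "synthetic_recording")
}
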