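#' Sweep protocol
#'
#' Describes the temporal and displacement structure of one sweep trial: a
#' periodic stimulus at `f_stim` Hz whose displacement amplitude is stepped
#' through `n_bins` log-spaced values, one value per `bin_duration`-second
#' bin, sampled at `fs` Hz. Defaults follow the adult protocol: 2 Hz
#' stimulation, ten 1-s bins sweeping 0.5-16 arcmin, 420 Hz sampling, and
#' analysis of the first four harmonics.
#'
#' @param f_stim Stimulation frequency in Hz.
#' @param n_bins Number of displacement bins per trial.
#' @param d_min,d_max Smallest and largest displacement in arcmin.
#' @param bin_duration Duration of one bin in seconds. Must contain a whole
#'   number of stimulus cycles.
#' @param fs Sampling rate in Hz. `fs * bin_duration` must be an integer.
#' @param n_harmonics Number of stimulus harmonics analysed.
#' @param n_test_bands,display_deg Number of moving test bands and display
#'   width in degrees; their ratio is the stimulus band spatial frequency.
#' @return An object of class `sweep_protocol`.
#' @seealso [infant_protocol()], [make_sweep_grid()]
#' @export
sweep_protocol <- function(f_stim = 2, n_bins = 10, d_min = 0.5, d_max = 16,
                           bin_duration = 1, fs = 420, n_harmonics = 4,
                           n_test_bands = 20, display_deg = 40) {
  if (d_min <= 0 || d_max < d_min)
    stop("invalid protocol: displacements must satisfy 0 < d_min <= d_max")
  if (n_bins < 2)
    stop("invalid protocol: n_bins must be >= 2")
  cycles <- bin_duration * f_stim
  if (abs(cycles - round(cycles)) > 1e-9)
    stop("invalid protocol: bin_duration * f_stim must be a whole number of cycles")
  nsamp <- fs * bin_duration
  if (abs(nsamp - round(nsamp)) > 1e-9)
    stop("invalid protocol: fs * bin_duration must be an integer sample count")
  structure(list(f_stim = f_stim, n_bins = n_bins, d_min = d_min,
                 d_max = d_max, bin_duration = bin_duration, fs = fs,
                 n_harmonics = n_harmonics, n_test_bands = n_test_bands,
                 display_deg = display_deg),
            class = "sweep_protocol")
}

#' @rdname sweep_protocol
#' @export
infant_protocol <- function(...) {
  args <- utils::modifyList(list(d_min = 2, d_max = 32), list(...))
  do.call(sweep_protocol, args)
}

#' Log-spaced displacement grid for a sweep protocol
#'
#' Returns the geometric sequence of `n_bins` displacements from `d_min` to
#' `d_max` inclusive (equal log steps), one per 1-s bin.
#'
#' @param protocol A [sweep_protocol()].
#' @return Numeric vector of displacements in arcmin, length `n_bins`.
#' @export
make_sweep_grid <- function(protocol) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  exp(seq(log(protocol$d_min), log(protocol$d_max),
          length.out = protocol$n_bins))
}

#' Stimulus band spatial frequency
#'
#' Alternating test and reference bands tile the display, so one full cycle
#' (test + reference band pair) spans `display_deg / n_test_bands` degrees;
#' the spatial frequency is the reciprocal.
#'
#' @param protocol A [sweep_protocol()].
#' @return Spatial frequency in cycles per degree.
#' @export
band_spatial_frequency <- function(protocol) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  protocol$n_test_bands / protocol$display_deg
}

#' Experimental condition specification
#'
#' One cell of the dichoptic-motion design: interocular temporal phase of
#' the test-band motion (0 deg in-phase vs 180 deg anti-phase), interocular
#' correlation of the test dots (+1 full-cue, 0 IOVD-uncorrelated, -1
#' IOVD-anticorrelated), the state of the flanking reference bands (static
#' correlated dots, temporally/interocularly uncorrelated dots, or none),
#' display orientation, the monocular motion trajectory (one-sided
#' disparity excursion vs straddling zero disparity), and the population
#' preset.
#'
#' @param interocular_phase `"in_phase"` or `"anti_phase"`.
#' @param test_correlation +1, 0, or -1.
#' @param reference_type `"full"`, `"noise"`, or `"none"`.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param trajectory `"one_sided"` or `"straddle_zero"`.
#' @param population `"adult"` or `"infant"`.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(interocular_phase = c("in_phase", "anti_phase"),
                           test_correlation = 1,
                           reference_type = c("full", "noise", "none"),
                           orientation = c("horizontal", "vertical"),
                           trajectory = c("one_sided", "straddle_zero"),
                           population = c("adult", "infant")) {
  interocular_phase <- match.arg(interocular_phase)
  reference_type <- match.arg(reference_type)
  orientation <- match.arg(orientation)
  trajectory <- match.arg(trajectory)
  population <- match.arg(population)
  if (!test_correlation %in% c(1, 0, -1))
    stop("test_correlation must be +1, 0 or -1")
  structure(list(interocular_phase = interocular_phase,
                 test_correlation = test_correlation,
                 reference_type = reference_type,
                 orientation = orientation,
                 trajectory = trajectory,
                 population = population),
            class = "condition_spec")
}

#' @export
format.condition_spec <- function(x, ...) {
  paste(x$interocular_phase,
        sprintf("corr%+d", x$test_correlation),
        x$reference_type, x$orientation, x$trajectory, sep = "/")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("<condition_spec>", format(x), "\n")
  invisible(x)
}

#' Harmonics expected to carry a response for a condition
#'
#' Symmetric stimulus alternation (e.g. leftward/rightward motion) drives
#' only even harmonics of the stimulation frequency; an asymmetric
#' alternation of global perceptual organisation (segmented vs uniform
#' plane) adds odd harmonics, chiefly 1F. The asymmetry requires anti-phase
#' motion with fully correlated test dots, a static correlated reference,
#' and a one-sided disparity trajectory; removing any of these restores
#' symmetry and eliminates 1F.
#'
#' @param cond A [condition_spec()].
#' @return Integer vector of harmonic numbers with a nonzero planted
#'   response (always contains 2 and 4).
#' @export
expected_harmonic_signature <- function(cond) {
  stopifnot(inherits(cond, "condition_spec"))
  harmonics <- c(2L, 4L)
  if (cond$interocular_phase == "anti_phase" &&
      cond$test_correlation == 1 &&
      cond$reference_type == "full" &&
      cond$trajectory == "one_sided") {
    harmonics <- c(1L, harmonics)
  }
  harmonics
}

#' Naka-Rushton parameter set
#'
#' Parameters of the saturating hyperbolic-ratio displacement response
#' function R(d) = Rmax * d^n / (d^n + d50^n) + b.
#'
#' @param rmax Maximal response above baseline, in microvolts (>= 0).
#' @param d50 Displacement at half-maximal response, arcmin (> 0).
#' @param n Exponent of the power function (> 0).
#' @param b Baseline response in microvolts.
#' @return An object of class `nr_params`.
#' @export
nr_params <- function(rmax, d50, n, b = 0) {
  if (rmax < 0) stop("rmax must be >= 0")
  if (d50 <= 0 || !is.finite(d50)) stop("d50 must be finite and > 0")
  if (n <= 0) stop("n must be > 0")
  structure(list(rmax = rmax, d50 = d50, n = n, b = b), class = "nr_params")
}
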