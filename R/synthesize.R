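#' Ground-truth harmonic response for a condition
#'
#' Assembles the planted per-harmonic response structure for one condition:
#' a Naka-Rushton displacement response function, a fixed response phase,
#' and a fixed scalp topography for each of the first `n_harmonics`
#' harmonics. Harmonics outside [expected_harmonic_signature()] get
#' rmax = 0 exactly (the symmetry rule: symmetric stimulus alternation
#' drives only even harmonics).
#'
#' Condition effects are planted as parameter modifiers:
#' \describe{
#'   \item{anti-phase suppression}{`d50` of the active even (motion)
#'     harmonics is multiplied by `suppression_d50_factor` (default 2)
#'     for adult anti-phase conditions, a rightward shift of the response
#'     function; the odd-harmonic segmentation response keeps its own
#'     parameters.}
#'   \item{reference removal}{`rmax` is multiplied by
#'     `reference_rmax_factor` (default 0.5) when the reference bands are
#'     noise or absent.}
#'   \item{infant preset}{reference removal has no effect and the
#'     anti-phase response is larger than in-phase instead of shifted
#'     (`infant_antiphase_rmax_factor`, default 1.5), matching the infant
#'     regime where referenced anti-phase responses are not suppressed.}
#' }
#'
#' @param cond A [condition_spec()].
#' @param montage A `montage_spec` providing channel geometry for the
#'   topographies.
#' @param base_params Named list of `nr_params` for harmonics `"1"`, `"2"`,
#'   `"4"` before condition modifiers.
#' @param phases Response phase in radians per harmonic (length 4).
#' @param suppression_d50_factor,reference_rmax_factor,infant_antiphase_rmax_factor
#'   Condition modifiers, see Details.
#' @param topo_centers List of unit 3-vectors, one topography centre per
#'   harmonic.
#' @return An object of class `ground_truth_response`: per-harmonic list of
#'   `params` (`nr_params`), `phase`, `topography` (unit-norm channel
#'   weights).
#' @export
ground_truth_response <- function(cond, montage,
    base_params = list(`1` = nr_params(1.5, 4, 2),
                       `2` = nr_params(3, 2, 2),
                       `4` = nr_params(1.5, 3, 2)),
    phases = c(pi / 4, pi / 3, pi / 2, 2 * pi / 3),
    suppression_d50_factor = 2,
    reference_rmax_factor = 0.5,
    infant_antiphase_rmax_factor = 1.5,
    topo_centers = list(c(0, -0.55, 0.84), c(0, -0.6, 0.8),
                        c(0.2, -0.6, 0.78), c(0, -0.45, 0.89))) {
  stopifnot(inherits(cond, "condition_spec"), inherits(montage, "montage_spec"))
  active <- expected_harmonic_signature(cond)
  infant <- cond$population == "infant"
  per_harmonic <- lapply(1:4, function(h) {
    p <- base_params[[as.character(h)]]
    if (is.null(p) || !(h %in% active)) {
      p <- nr_params(0, 1, 1, 0)
    } else {
      rmax <- p$rmax
      d50 <- p$d50
      if (cond$interocular_phase == "anti_phase") {
        if (infant) {
          rmax <- rmax * infant_antiphase_rmax_factor
        } else if (h %% 2 == 0) {
          # suppression shifts the motion response (even harmonics); the
          # odd-harmonic segmentation response has its own parameters
          d50 <- d50 * suppression_d50_factor
        }
      }
      if (!infant && cond$reference_type != "full")
        rmax <- rmax * reference_rmax_factor
      p <- nr_params(rmax, d50, p$n, p$b)
    }
    list(params = p, phase = phases[h],
         topography = smooth_topography(montage, topo_centers[[h]]))
  })
  names(per_harmonic) <- as.character(1:4)
  structure(list(harmonics = per_harmonic, condition = cond),
            class = "ground_truth_response")
}

# 1/f^alpha coloured noise, unit RMS, via spectral shaping
colored_noise <- function(n, alpha = 1) {
  nf <- floor(n / 2)
  freqs <- seq_len(nf)
  mag <- freqs^(-alpha / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = c(0, mag, rep(0, n - nf - 1)),
                  argument = c(0, phase, rep(0, n - nf - 1)))
  x <- Re(stats::fft(spec, inverse = TRUE))
  x / sqrt(mean(x^2))
}

#' Noise specification for synthetic recordings
#'
#' Background activity is modelled as `n_sources` independent 1/f^alpha
#' processes mixed into the channels through random smooth topographies
#' (spatially correlated component, RMS `pink_rms` per channel on average)
#' plus independent white sensor noise (`white_rms` per channel).
#'
#' @param pink_rms Per-channel RMS of the spatially correlated 1/f
#'   component, in microvolts.
#' @param white_rms Per-channel RMS of white sensor noise, in microvolts.
#' @param alpha Spectral exponent of the coloured component.
#' @param n_sources Number of independent coloured sources.
#' @return A list with class `noise_spec`.
#' @export
noise_spec <- function(pink_rms = 8, white_rms = 3, alpha = 1,
                       n_sources = 8) {
  structure(list(pink_rms = pink_rms, white_rms = white_rms, alpha = alpha,
                 n_sources = n_sources), class = "noise_spec")
}

#' Synthesize one sweep trial
#'
#' Builds a channels x time recording in which, within displacement bin k,
#' channel c carries
#' sum_h A_h(d_k) * w_c(h) * cos(2 pi h f_stim t + phi_h)
#' plus background noise, where A_h evaluates the planted Naka-Rushton
#' function at the bin's displacement d_k and w(h) is the harmonic's
#' topography. Phase is locked to the trial clock, so repeated trials of a
#' condition share component phase exactly.
#'
#' @param cond A [condition_spec()].
#' @param protocol A [sweep_protocol()].
#' @param truth A [ground_truth_response()] consistent with `cond`.
#' @param montage A `montage_spec`; topography lengths must match.
#' @param noise A [noise_spec()], or `NULL` for noiseless output.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @param participant,trial Labels stored with the recording.
#' @return An object of class `synthetic_recording` with elements `samples`
#'   (channels x time, microvolts), `fs`, `bin_bounds` (half-open sample
#'   index ranges per bin), `labels`, `ground_truth`, `artifact_ledger`,
#'   `seed`.
#' @export
synthesize_trial <- function(cond, protocol, truth, montage,
                             noise = noise_spec(), seed = 1,
                             participant = "P01", trial = 1L) {
  stopifnot(inherits(protocol, "sweep_protocol"),
            inherits(truth, "ground_truth_response"))
  n_ch <- length(montage$labels)
  for (h in names(truth$harmonics))
    if (length(truth$harmonics[[h]]$topography) != n_ch)
      stop("montage mismatch: topography length != n_channels for harmonic ", h)
  nsamp_bin <- round(protocol$fs * protocol$bin_duration)
  n <- protocol$n_bins * nsamp_bin
  t <- (seq_len(n) - 1) / protocol$fs
  grid <- make_sweep_grid(protocol)
  bin_of <- rep(seq_len(protocol$n_bins), each = nsamp_bin)

  samples <- matrix(0, n_ch, n,
                    dimnames = list(montage$labels, NULL))
  for (h in 1:4) {
    gt <- truth$harmonics[[as.character(h)]]
    if (gt$params$rmax == 0 && gt$params$b == 0) next
    amp_bin <- nr_eval(grid, gt$params)
    carrier <- amp_bin[bin_of] *
      cos(2 * pi * h * protocol$f_stim * t + gt$phase)
    samples <- samples + outer(gt$topography, carrier)
  }

  if (!is.null(noise)) {
    set.seed(seed %% .Machine$integer.max)
    if (noise$pink_rms > 0 && noise$n_sources > 0) {
      mix <- vapply(seq_len(noise$n_sources), function(s) {
        ctr <- stats::rnorm(3)
        smooth_topography(montage, ctr, width = stats::runif(1, 0.5, 1.2))
      }, numeric(n_ch))
      src <- vapply(seq_len(noise$n_sources),
                    function(s) colored_noise(n, noise$alpha),
                    numeric(n))
      pink <- mix %*% t(src)
      # scale so the average per-channel RMS is pink_rms
      pink <- pink * (noise$pink_rms / sqrt(mean(pink^2)))
      samples <- samples + pink
    }
    if (noise$white_rms > 0)
      samples <- samples + matrix(stats::rnorm(n_ch * n, 0, noise$white_rms),
                                  n_ch, n)
  }

  starts <- as.integer((seq_len(protocol$n_bins) - 1) * nsamp_bin + 1)
  structure(list(samples = samples, fs = protocol$fs,
                 bin_bounds = cbind(start = starts,
                                    end = starts + as.integer(nsamp_bin)),
                 labels = list(participant = participant, trial = trial,
                               condition = cond),
                 protocol = protocol,
                 ground_truth = truth,
                 artifact_ledger = list(),
                 seed = seed),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %d ch x %d samples @ %g Hz, %s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              format(x$labels$condition)))
  invisible(x)
}

#' Inject artifacts into a recording
#'
#' Adds blink-like slow deflections, single-sample spikes, and sustained
#' bad-channel contamination, recording the exact samples and channels
#' modified in an artifact ledger so that downstream rejection can be
#' verified against ground truth.
#'
#' @param rec A `synthetic_recording`.
#' @param artifacts List with any of:
#'   \describe{
#'     \item{blinks}{list of `list(start, duration, channels, amplitude)`:
#'       a half-sine deflection of `amplitude` microvolts over
#'       `duration` samples starting at sample `start` on `channels`.}
#'     \item{spikes}{list of `list(sample, channels, amplitude)`.}
#'     \item{bad_channels}{list of `list(channel, amplitude, frac)`: a
#'       fraction `frac` of evenly spaced samples on `channel` are set to
#'       `amplitude` (alternating sign).}
#'   }
#' @return The recording with artifacts added and `artifact_ledger` filled.
#' @export
inject_artifacts <- function(rec, artifacts = list()) {
  stopifnot(inherits(rec, "synthetic_recording"))
  n <- ncol(rec$samples)
  n_ch <- nrow(rec$samples)
  ledger <- list(blinks = list(), spikes = list(), bad_channels = list())

  for (bl in artifacts$blinks) {
    idx <- bl$start + seq_len(bl$duration) - 1L
    if (bl$start < 1 || max(idx) > n) stop("blink outside recording bounds")
    if (any(bl$channels < 1 | bl$channels > n_ch)) stop("blink channel out of range")
    wave <- bl$amplitude * sin(pi * seq_len(bl$duration) / bl$duration)
    for (ch in bl$channels)
      rec$samples[ch, idx] <- rec$samples[ch, idx] + wave
    ledger$blinks[[length(ledger$blinks) + 1L]] <-
      list(channels = bl$channels, samples = idx, amplitude = bl$amplitude)
  }
  for (sp in artifacts$spikes) {
    if (sp$sample < 1 || sp$sample > n) stop("spike outside recording bounds")
    if (any(sp$channels < 1 | sp$channels > n_ch)) stop("spike channel out of range")
    rec$samples[sp$channels, sp$sample] <-
      rec$samples[sp$channels, sp$sample] + sp$amplitude
    ledger$spikes[[length(ledger$spikes) + 1L]] <-
      list(channels = sp$channels, samples = sp$sample,
           amplitude = sp$amplitude)
  }
  for (bc in artifacts$bad_channels) {
    if (bc$channel < 1 || bc$channel > n_ch) stop("bad channel out of range")
    k <- round(bc$frac * n)
    idx <- unique(round(seq(1, n, length.out = k)))
    rec$samples[bc$channel, idx] <- bc$amplitude * (-1)^(seq_along(idx))
    ledger$bad_channels[[length(ledger$bad_channels) + 1L]] <-
      list(channel = as.integer(bc$channel), samples = idx,
           amplitude = bc$amplitude)
  }
  rec$artifact_ledger <- ledger
  rec
}

# deterministic sub-seed derivation, counter-based, < 2^31
derive_subseed <- function(master, counter) {
  ((master %% 1000003) * 48271 + counter * 16807) %% 2147483647
}

#' Generate a cohort of synthetic sweep recordings
#'
#' Produces `n_trials` recordings per participant per condition with
#' participant-level variation: a multiplicative amplitude scale (log-normal
#' with spread `amp_sd`) and a small topography perturbation
#' (`topo_jitter`). Sub-seeds are derived deterministically from the master
#' seed with a counter scheme, so the cohort is reproducible and any single
#' recording can be regenerated independently.
#'
#' @param n_participants Number of participants (>= 2).
#' @param conditions List of [condition_spec()]s.
#' @param protocol A [sweep_protocol()].
#' @param montage A `montage_spec` (default 128-channel synthetic net).
#' @param noise A [noise_spec()] or `NULL`.
#' @param n_trials Trials per participant per condition (default 15).
#' @param amp_sd Log-scale SD of per-participant amplitude scaling.
#' @param topo_jitter SD of topography perturbation before renormalisation.
#' @param seed Master seed.
#' @param truth_args Extra arguments forwarded to
#'   [ground_truth_response()].
#' @return List of `synthetic_recording` objects; each records its
#'   participant label, trial number, condition and participant-scaled
#'   ground truth.
#' @export
generate_cohort <- function(n_participants, conditions, protocol,
                            montage = make_montage(128),
                            noise = noise_spec(), n_trials = 15,
                            amp_sd = 0.1, topo_jitter = 0.05, seed = 1,
                            truth_args = list()) {
  if (n_participants < 2)
    warning("cohorts with a single participant support no group statistics")
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  recs <- list()
  counter <- 0L
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    set.seed(derive_subseed(seed, counter <- counter + 1L))
    scale_p <- exp(stats::rnorm(1, 0, amp_sd))
    jitter_p <- stats::rnorm(3, 0, topo_jitter)
    for (cond in conditions) {
      truth <- do.call(ground_truth_response,
                       c(list(cond = cond, montage = montage), truth_args))
      for (h in names(truth$harmonics)) {
        gt <- truth$harmonics[[h]]
        if (gt$params$rmax > 0) {
          gt$params$rmax <- gt$params$rmax * scale_p
          if (topo_jitter > 0) {
            w <- gt$topography +
              smooth_topography(montage, c(0, -0.6, 0.8) + jitter_p) *
                sqrt(sum(jitter_p^2))
            gt$topography <- w / sqrt(sum(w^2))
          }
        }
        truth$harmonics[[h]] <- gt
      }
      for (tr in seq_len(n_trials)) {
        recs[[length(recs) + 1L]] <- synthesize_trial(
          cond, protocol, truth, montage, noise,
          seed = derive_subseed(seed, counter <- counter + 1L),
          participant = pid, trial = tr)
      }
    }
  }
  recs
}

#' Simulate a cohort at the coefficient level
#'
#' A scaled-down generative model that skips the time-domain stage: for
#' each participant, condition and displacement bin it draws the
#' trial-mean complex coefficient of one harmonic directly,
#' amplitude from the planted Naka-Rushton function times a per-participant
#' log-normal scale, phase fixed per condition, plus complex Gaussian noise
#' with per-trial-mean SD `coef_noise_sd / sqrt(n_trials)`. This is the
#' generator used for statistical power and type-I calibration at many
#' repetitions, where full time-domain synthesis would add nothing but the
#' extraction stage already validated elsewhere.
#'
#' @param n_participants Cohort size.
#' @param protocol A [sweep_protocol()] (supplies the displacement grid).
#' @param truths Named list of `nr_params`, one per condition, e.g.
#'   `list(in_phase = ..., anti_phase = ...)`.
#' @param phases Named numeric vector of response phases per condition.
#' @param coef_noise_sd Per-trial complex-component noise SD, microvolts.
#' @param n_trials Trials averaged per participant.
#' @param amp_sd Log-scale SD of participant amplitude scaling.
#' @param seed Seed.
#' @return A list per condition of `n_participants x n_bins` complex
#'   matrices of participant trial-mean coefficients.
#' @export
simulate_coefficient_cohort <- function(n_participants, protocol, truths,
                                        phases = NULL,
                                        coef_noise_sd = 1, n_trials = 15,
                                        amp_sd = 0.1, seed = 1) {
  set.seed(seed %% .Machine$integer.max)
  grid <- make_sweep_grid(protocol)
  nb <- length(grid)
  if (is.null(phases))
    phases <- stats::setNames(rep(pi / 3, length(truths)), names(truths))
  sem_sd <- coef_noise_sd / sqrt(n_trials)
  scales <- exp(stats::rnorm(n_participants, 0, amp_sd))
  out <- lapply(names(truths), function(cn) {
    amp <- nr_eval(grid, truths[[cn]])
    m <- matrix(0+0i, n_participants, nb)
    for (p in seq_len(n_participants)) {
      mu <- scales[p] * amp * exp(1i * phases[[cn]])
      m[p, ] <- mu + complex(real = stats::rnorm(nb, 0, sem_sd),
                             imaginary = stats::rnorm(nb, 0, sem_sd))
    }
    m
  })
  names(out) <- names(truths)
  out
}
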