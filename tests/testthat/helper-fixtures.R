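# Shared fixtures: small montages and truth objects built in code.

adult_protocol <- function() sweep_protocol()

tiny_montage <- function(n = 16) make_montage(n)

# ground truth with a single active harmonic and a custom topography
single_harmonic_truth <- function(cond, montage, harmonic = 2, rmax = 1,
                                  d50 = 2, n = 2, b = 0, phase = 0,
                                  topography = NULL) {
  truth <- ground_truth_response(
    cond, montage,
    base_params = stats::setNames(list(nr_params(rmax, d50, n, b)),
                                  as.character(harmonic)),
    suppression_d50_factor = 1, reference_rmax_factor = 1)
  for (h in names(truth$harmonics)) {
    if (h == as.character(harmonic)) {
      truth$harmonics[[h]]$phase <- phase
      if (!is.null(topography)) truth$harmonics[[h]]$topography <- topography
    } else {
      truth$harmonics[[h]]$params <- nr_params(0, 1, 1, 0)
    }
  }
  truth
}

flat_topography <- function(montage) {
  n <- length(montage$labels)
  rep(1 / sqrt(n), n)
}

# rca_input built directly from per-trial matrices (rows = re block then
# im block over epochs)
manual_rca_input <- function(trials, condition = "c", participant = NULL,
                             n_epochs = nrow(trials[[1]]) / 2) {
  if (is.null(participant)) participant <- seq_along(trials)
  structure(list(trials = trials,
                 epochs = rep(list(seq_len(n_epochs)), length(trials)),
                 keys = data.frame(participant = participant,
                                   condition = condition, session = 1),
                 harmonic = 2),
            class = "rca_input")
}
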