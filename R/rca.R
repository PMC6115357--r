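#' Assemble RCA input from coefficient tables
#'
#' Stacks the real and imaginary coefficient vectors of every valid 1-s
#' epoch (sensors as variables) for one harmonic, keeping one matrix per
#' trial so that cross-trial covariance can be formed. An epoch enters
#' only if it is valid on all channels (complete-case: reliable components
#' need matched rows across trials).
#'
#' @param coef_tables List of `coef_table` objects, one per trial.
#' @param harmonic Which harmonic's coefficients to use.
#' @param session Optional numeric vector, one session index per table
#'   (for [pool_participants()]).
#' @return An `rca_input`: `trials` (list of (2 x epochs) x channels real
#'   matrices), `epochs` (list of epoch indices used), `keys` (data.frame
#'   with participant, condition, session).
#' @export
rca_input <- function(coef_tables, harmonic = 2, session = NULL) {
  if (inherits(coef_tables, "coef_table")) coef_tables <- list(coef_tables)
  if (is.null(session)) session <- rep(1, length(coef_tables))
  trials <- list(); epochs <- list(); keys <- NULL
  for (i in seq_along(coef_tables)) {
    ct <- coef_tables[[i]]
    hj <- match(harmonic, ct$hset$harmonics)
    if (is.na(hj)) stop("harmonic ", harmonic, " not present in coef_table")
    ok <- which(colSums(!ct$valid) == 0)
    co <- ct$signal[, hj, ok, drop = FALSE]  # channels x 1 x epochs
    x <- rbind(t(Re(co[, 1, , drop = TRUE])), t(Im(co[, 1, , drop = TRUE])))
    if (length(ok) == 1)
      x <- rbind(Re(co[, 1, 1]), Im(co[, 1, 1]))
    trials[[i]] <- x
    epochs[[i]] <- ok
    lab <- ct$labels
    keys <- rbind(keys, data.frame(
      participant = if (!is.null(lab)) lab$participant else NA,
      condition = if (!is.null(lab)) format(lab$condition) else "c1",
      session = session[i]))
  }
  structure(list(trials = trials, epochs = epochs, keys = keys,
                 harmonic = harmonic),
            class = "rca_input")
}

#' Pool RCA inputs across experiments, one session per participant
#'
#' Concatenates several `rca_input` objects. Participants appearing in
#' more than one input (e.g. repeated across experiments) contribute only
#' the trials from their first session, determined by the `session` key.
#'
#' @param inputs List of `rca_input` objects.
#' @return A single pooled `rca_input` with provenance in
#'   `attr(, "pooled_from")`.
#' @export
pool_participants <- function(inputs) {
  all_keys <- do.call(rbind, lapply(seq_along(inputs), function(i)
    cbind(inputs[[i]]$keys, .src = i)))
  first_session <- tapply(all_keys$session, all_keys$participant, min)
  if (anyNA(first_session))
    stop("duplicate participant with unresolvable session ordering")
  trials <- list(); epochs <- list(); keys <- NULL
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    keep <- which(inp$keys$session ==
                    first_session[as.character(inp$keys$participant)])
    trials <- c(trials, inp$trials[keep])
    epochs <- c(epochs, inp$epochs[keep])
    keys <- rbind(keys, inp$keys[keep, , drop = FALSE])
  }
  out <- structure(list(trials = trials, epochs = epochs, keys = keys,
                        harmonic = inputs[[1]]$harmonic),
                   class = "rca_input")
  attr(out, "pooled_from") <- length(inputs)
  out
}

#' Fit reliable components
#'
#' Reliable Components Analysis: finds sensor weightings w maximizing
#' trial-to-trial consistency, the ratio of across-trial covariance
#' (phase-locked, reproducible activity) to pooled within-trial
#' covariance. Because SSVEP response phase is constant across repeated
#' trials of a condition, reproducible activity concentrates in a few
#' reliable components.
#'
#' The across-trial covariance averages X_i' X_j over all ordered pairs of
#' distinct trials within the same condition cell (rows matched by
#' displacement bin, restricted to epochs valid in every trial of the
#' cell), symmetrized; the pooled covariance averages X_i' X_i. Second
#' moments are used without mean removal: the across-trial mean is the
#' phase-locked response itself and must stay in the across-trial
#' covariance. The generalized eigenproblem
#' R_xy w = rho R_pool w is solved in the top-`rank` principal subspace of
#' R_pool (standard stabilization for high-density montages), giving
#' eigenvalues rho in [-1, 1] interpreted as trial-to-trial correlation of
#' the component.
#'
#' @param input An `rca_input`.
#' @param K Number of components returned.
#' @param rank Dimension of the principal subspace used for
#'   regularization. The default takes `min(60, n_channels)` capped at
#'   the numerically supported rank of the pooled covariance
#'   (common-average referencing alone removes one dimension).
#' @return An `rca_model`: `W` (sensors x K weights, each column
#'   sign-normalized so its largest-magnitude entry is positive), `A`
#'   (forward topographies), `rho` (descending), `R_pool`, `R_xy`,
#'   `rank`, `n_trials`.
#' @export
fit_rca <- function(input, K = 3, rank = NULL) {
  stopifnot(inherits(input, "rca_input"))
  trials <- input$trials
  n_tr <- length(trials)
  if (n_tr < 2) stop("need >= 2 trials for cross-trial covariance")
  n_ch <- ncol(trials[[1]])
  auto_rank <- is.null(rank)
  if (auto_rank) rank <- min(60L, n_ch)
  if (rank > n_ch) stop("rank cannot exceed the channel count")

  groups <- split(seq_len(n_tr), input$keys$condition)
  Rxy <- matrix(0, n_ch, n_ch)
  Rpool <- matrix(0, n_ch, n_ch)
  n_xy <- 0; n_pool <- 0
  for (g in groups) {
    # match rows by (epoch, re/im) across whichever trials of the cell
    # have that epoch valid; sum-of-rows trick gives all ordered pairs
    all_ep <- sort(unique(unlist(input$epochs[g])))
    for (e in all_ep) {
      for (part in 1:2) {
        rows <- lapply(g, function(i) {
          pos <- match(e, input$epochs[[i]])
          if (is.na(pos)) return(NULL)
          half <- nrow(trials[[i]]) / 2
          trials[[i]][(part - 1) * half + pos, ]
        })
        rows <- rows[!vapply(rows, is.null, TRUE)]
        m <- length(rows)
        if (m == 0) next
        X <- do.call(rbind, rows)
        Cii <- crossprod(X)
        S <- colSums(X)
        Rpool <- Rpool + Cii
        n_pool <- n_pool + m
        if (m >= 2) {
          Rxy <- Rxy + (tcrossprod(S) - Cii)
          n_xy <- n_xy + m * (m - 1)
        }
      }
    }
  }
  if (n_xy == 0) stop("no condition cell has >= 2 trials sharing a valid epoch")
  Rxy <- (Rxy + t(Rxy)) / (2 * n_xy)
  Rpool <- Rpool / n_pool

  ep <- eigen(Rpool, symmetric = TRUE)
  if (auto_rank) {
    # common-average referencing (and finite trial counts) leave R_pool
    # short of full rank; keep only numerically supported dimensions
    rank <- min(rank, sum(ep$values > ep$values[1] * 1e-10))
  }
  keep <- seq_len(rank)
  ev <- ep$values[keep]
  if (ev[length(ev)] <= ev[1] * 1e-12)
    stop("R_pool is rank-deficient in the requested subspace; ",
         "reduce `rank` or supply more trials")
  Uw <- ep$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(ev), rank)
  M <- crossprod(Uw, Rxy) %*% Uw
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  K <- min(K, rank)
  W <- Uw %*% eg$vectors[, seq_len(K), drop = FALSE]
  rho <- eg$values[seq_len(K)]
  # forward topographies: A = R_pool W (W' R_pool W)^-1
  A <- Rpool %*% W %*% solve(crossprod(W, Rpool %*% W))
  for (k in seq_len(K)) {
    s <- sign(W[which.max(abs(W[, k])), k])
    W[, k] <- W[, k] * s
    A[, k] <- A[, k] * s
  }
  structure(list(W = W, A = A, rho = rho, R_pool = Rpool, R_xy = Rxy,
                 rank = rank, K = K, n_trials = n_tr,
                 harmonic = input$harmonic),
            class = "rca_model")
}

#' @export
print.rca_model <- function(x, ...) {
  cat(sprintf("<rca_model> %d components over %d sensors (rank %d, %d trials)\n",
              x$K, nrow(x$W), x$rank, x$n_trials))
  cat("  rho:", format(round(x$rho, 3)), "\n")
  invisible(x)
}

#' Reliability and variance explained per component
#'
#' Definitional summaries: `reliability_explained_k` is rho_k divided by
#' the sum of all non-negative generalized eigenvalues in the regularized
#' subspace; `variance_explained_k` is the variance of the rank-1
#' reconstruction of the data from component k (forward topography times
#' component projection) divided by the total input variance (trace of
#' the pooled covariance).
#'
#' @param model An `rca_model`.
#' @return Data frame with one row per retained component.
#' @export
explained_summaries <- function(model) {
  stopifnot(inherits(model, "rca_model"))
  ep <- eigen(model$R_pool, symmetric = TRUE)
  keep <- seq_len(model$rank)
  Uw <- ep$vectors[, keep] %*% diag(1 / sqrt(ep$values[keep]), model$rank)
  M <- crossprod(Uw, model$R_xy) %*% Uw
  all_rho <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  pos_sum <- sum(pmax(all_rho, 0))
  rel <- pmax(model$rho, 0) / pos_sum
  # variance of the rank-1 reconstruction A_k y_k over total variance;
  # y_k = X w_k has variance w' R_pool w
  varex <- vapply(seq_len(model$K), function(k) {
    w <- model$W[, k]
    vk <- drop(crossprod(w, model$R_pool %*% w))
    sum(model$A[, k]^2) * vk / sum(diag(model$R_pool))
  }, 0)
  data.frame(component = seq_len(model$K), rho = model$rho,
             reliability_explained = rel, variance_explained = varex)
}

#' Export component topographies as CSV
#'
#' Channel-by-component table of weights and forward-model topographies,
#' for scalp plotting in external tools.
#'
#' @param model An `rca_model`.
#' @param path Output CSV path.
#' @param montage Optional `montage_spec` supplying channel labels and
#'   positions.
#' @return `path`, invisibly.
#' @export
write_rca_topography_csv <- function(model, path, montage = NULL) {
  df <- data.frame(channel = seq_len(nrow(model$W)))
  if (!is.null(montage)) {
    df$label <- montage$labels
    df <- cbind(df, montage$positions)
  }
  colnames(model$W) <- paste0("w", seq_len(ncol(model$W)))
  colnames(model$A) <- paste0("a", seq_len(ncol(model$A)))
  utils::write.csv(cbind(df, model$W, model$A), path, row.names = FALSE)
  invisible(path)
}

#' Project coefficients through reliable component weights
#'
#' Projects real and imaginary parts separately through one weight column,
#' reducing channels x harmonics x bins coefficient arrays to component
#' space. Sideband noise coefficients are projected with the same weights
#' so signal and noise remain comparable. A component bin is valid only if
#' every contributing channel was valid.
#'
#' @param coefs A `coef_table` (or complex matrix/array with channels as
#'   the first dimension).
#' @param model An `rca_model`.
#' @param component Which component's weights to use (default RC1).
#' @return For `coef_table` input, a `component_coefs` object with
#'   `signal` (harmonics x bins complex), `noise` (harmonics x 2 x bins),
#'   `valid` (bins), `labels`; otherwise the projected array.
#' @export
project_through <- function(coefs, model, component = 1) {
  stopifnot(inherits(model, "rca_model"))
  w <- model$W[, component]
  if (!inherits(coefs, "coef_table")) {
    d <- dim(coefs)
    if (is.null(d)) d <- c(length(coefs), 1)
    if (d[1] != length(w)) stop("channel dimension does not match weights")
    m <- matrix(coefs, nrow = d[1])
    out <- drop(t(m) %*% w)
    if (length(d) > 2) out <- array(out, dim = d[-1])
    return(out)
  }
  d <- dim(coefs$signal)
  if (d[1] != length(w)) stop("channel dimension does not match weights")
  sig <- apply(coefs$signal, c(2, 3), function(v) sum(v * w))
  noi <- apply(coefs$noise, c(2, 3, 4), function(v) sum(v * w))
  structure(list(signal = sig, noise = noi,
                 valid = colSums(!coefs$valid) == 0,
                 hset = coefs$hset, labels = coefs$labels,
                 component = component),
            class = "component_coefs")
}
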