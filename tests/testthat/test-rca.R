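test_that("a planted reliable component is recovered from sensor noise", {
  set.seed(5)
  n_ch <- 128
  mont <- make_montage(n_ch)
  topo <- smooth_topography(mont)
  s <- rnorm(20, 0, 2)  # stimulus-locked series, identical across trials
  trials <- lapply(seq_len(15 * 20), function(i)
    outer(s, topo) + matrix(rnorm(20 * n_ch, 0, 0.35), 20, n_ch))
  inp <- manual_rca_input(trials,
                          participant = rep(1:15, each = 20))
  # the planted component carries >= 10% of total variance
  sig_var <- mean(outer(s, topo)^2)
  expect_gt(sig_var / (sig_var + 0.35^2), 0.10)

  m <- fit_rca(inp, K = 3)
  expect_gt(abs(cor(m$W[, 1], topo)), 0.95)
  expect_true(all(diff(m$rho) <= 0))
})

test_that("noiseless identical trials give perfect reliability", {
  mont <- make_montage(24)
  topo <- smooth_topography(mont)
  s <- rnorm(20, 0, 1)
  trials <- rep(list(outer(s, topo)), 5)
  m <- fit_rca(manual_rca_input(trials), K = 2, rank = 1)
  expect_equal(m$rho[1], 1, tolerance = 1e-10)
  # with near-identical trials and a larger subspace the trailing
  # eigenvalues vanish
  set.seed(2)
  m2 <- fit_rca(manual_rca_input(
    lapply(1:5, function(i) outer(s, topo) +
             matrix(rnorm(20 * 24, 0, 1e-3), 20, 24))), K = 3, rank = 5)
  expect_equal(m2$rho[1], 1, tolerance = 1e-3)
  expect_lt(abs(m2$rho[2]), 0.2)
})

test_that("channel permutation permutes the weight rows identically", {
  set.seed(8)
  n_ch <- 20
  s <- rnorm(12)
  topo <- exp(-(1:n_ch - 7)^2 / 20)
  trials <- lapply(1:6, function(i)
    outer(s, topo) + matrix(rnorm(12 * n_ch, 0, 0.3), 12, n_ch))
  perm <- sample(n_ch)
  m1 <- fit_rca(manual_rca_input(trials), K = 2, rank = 10)
  m2 <- fit_rca(manual_rca_input(lapply(trials, function(x) x[, perm])),
                K = 2, rank = 10)
  # same component up to sign; compare via absolute correlation
  expect_gt(abs(cor(m1$W[perm, 1], m2$W[, 1])), 1 - 1e-8)
})

test_that("the generalized eigenvalue residual vanishes in the subspace", {
  set.seed(3)
  n_ch <- 16
  s <- rnorm(10)
  topo <- cos(seq(0, pi, length.out = n_ch))
  trials <- lapply(1:8, function(i)
    outer(s, topo) + matrix(rnorm(10 * n_ch, 0, 0.5), 10, n_ch))
  m <- fit_rca(manual_rca_input(trials, n_epochs = 5), K = 3, rank = n_ch)
  resid <- m$R_xy %*% m$W - m$R_pool %*% m$W %*% diag(m$rho)
  expect_lt(norm(resid, "F") / norm(m$R_xy %*% m$W, "F"), 1e-8)
})

test_that("rank-deficient pooled covariance is caught with a hint", {
  trials <- rep(list(outer(rnorm(10), rnorm(30))), 3)  # rank 1
  expect_error(fit_rca(manual_rca_input(trials, n_epochs = 5), K = 2,
                       rank = 30),
               "rank-deficient")
  expect_error(fit_rca(manual_rca_input(trials, n_epochs = 5), rank = 31),
               "rank cannot exceed")
})

test_that("projection through weights behaves as a spatial filter", {
  mont <- tiny_montage(12)
  prot <- adult_protocol()
  cond <- condition_spec("in_phase")
  truth <- single_harmonic_truth(cond, mont, rmax = 2, d50 = 2, phase = 0.5)
  rec <- synthesize_trial(cond, prot, truth, mont, noise = NULL, seed = 4)
  ct <- extract_coefficients(segment_epochs(rec), estimator = "dft")

  # unit selector weight returns that channel's coefficients
  sel <- structure(list(W = matrix(c(1, rep(0, 11)), ncol = 1),
                        K = 1), class = "rca_model")
  pr <- project_through(ct, sel)
  expect_equal(pr$signal[2, ], ct$signal[1, 2, ])

  # topography-matched weights return a series proportional to the
  # planted amplitude series
  w <- truth$harmonics[["2"]]$topography
  mdl <- structure(list(W = matrix(w, ncol = 1), K = 1),
                   class = "rca_model")
  pr2 <- project_through(ct, mdl)
  planted <- nr_eval(make_sweep_grid(prot), truth$harmonics[["2"]]$params)
  expect_gt(cor(Mod(pr2$signal[2, ]), planted), 0.999)

  # sidebands are projected with the same weights
  expect_equal(dim(pr2$noise), c(4, 2, 10))
  expect_error(project_through(ct$signal[1:5, , ], mdl),
               "channel dimension")
})

test_that("explained summaries behave on constructed data", {
  # rank-1 noiseless: component 1 explains everything
  s <- rnorm(16)
  topo <- exp(-(1:10 - 5)^2 / 8)
  m <- fit_rca(manual_rca_input(rep(list(outer(s, topo)), 4), n_epochs = 8),
               K = 1, rank = 1)
  es <- explained_summaries(m)
  expect_equal(es$reliability_explained[1], 1, tolerance = 1e-9)
  expect_equal(es$variance_explained[1], 1, tolerance = 1e-9)

  # two orthogonal planted components with ~3:1 variance ratio; a trace
  # of independent noise breaks the eigenvalue degeneracy so the
  # stronger component is ordered first
  set.seed(21)
  t1 <- c(rep(1, 5), rep(0, 5)) / sqrt(5)
  t2 <- c(rep(0, 5), rep(1, 5)) / sqrt(5)
  s1 <- rnorm(16, 0, sqrt(3)); s2 <- rnorm(16, 0, 1)
  trials <- lapply(1:8, function(i)
    outer(s1, t1) + outer(s2, t2) + matrix(rnorm(160, 0, 0.02), 16, 10))
  m2 <- fit_rca(manual_rca_input(trials, n_epochs = 8), K = 2)
  es2 <- explained_summaries(m2)
  # second-moment ratio of the planted series (uncentered, as fitted)
  expect_equal(es2$variance_explained[1] / es2$variance_explained[2],
               mean(s1^2) / mean(s2^2), tolerance = 0.05)
  expect_lte(sum(es2$reliability_explained), 1 + 1e-9)
})

test_that("pooling keeps one session per participant", {
  mk <- function(participants, session, val) {
    trials <- lapply(seq_along(participants), function(i)
      matrix(val, 4, 6))
    structure(list(trials = trials, epochs = rep(list(1:2), length(trials)),
                   keys = data.frame(participant = participants,
                                     condition = "c", session = session),
                   harmonic = 2), class = "rca_input")
  }
  a <- mk(c("P1", "P2"), 1, 1)
  b <- mk(c("P2", "P3"), 2, 2)
  pooled <- pool_participants(list(a, b))
  # P2's second session is dropped
  expect_equal(nrow(pooled$keys), 3)
  expect_setequal(pooled$keys$participant, c("P1", "P2", "P3"))
  expect_equal(pooled$trials[[which(pooled$keys$participant == "P2")]][1, 1], 1)
  # distinct-participant count oracle
  expect_equal(nrow(pooled$keys),
               length(union(a$keys$participant, b$keys$participant)))

  # disjoint inputs concatenate
  c2 <- mk(c("P4", "P5"), 1, 3)
  expect_equal(nrow(pool_participants(list(a, c2))$keys), 4)

  # unresolvable duplicate identity errors
  bad <- mk(c("P1", "P1"), NA, 1)
  expect_error(pool_participants(list(a, bad)), "unresolvable")
})

test_that("recovery degrades monotonically with sensor noise", {
  set.seed(12)
  n_ch <- 32
  mont <- make_montage(n_ch)
  topo <- smooth_topography(mont)
  s <- rnorm(20, 0, 2)
  sigmas <- c(0.1, 0.5, 1.5, 4)
  mean_cor <- vapply(sigmas, function(sg) {
    mean(replicate(8, {
      trials <- lapply(1:10, function(i)
        outer(s, topo) + matrix(rnorm(20 * n_ch, 0, sg), 20, n_ch))
      m <- fit_rca(manual_rca_input(trials), K = 1, rank = 20)
      abs(cor(m$W[, 1], topo))
    }))
  }, 0)
  # isotonic trend: correlation non-increasing in noise (small slack for
  # sampling error)
  expect_true(all(diff(mean_cor) < 0.05))
  expect_gt(mean_cor[1], mean_cor[length(mean_cor)])
})
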