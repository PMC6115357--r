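test_that("vector averaging follows the complex mean", {
  va <- vector_average(c(1 + 0i, 0 + 1i))
  expect_equal(va$mean, 0.5 + 0.5i)
  expect_equal(va$amplitude, sqrt(0.5))

  # identical vectors: amplitude equals the common magnitude
  v <- 2 - 1.5i
  expect_equal(vector_average(rep(v, 6))$amplitude, Mod(v))

  # random phases: group amplitude bounded by mean individual amplitude
  set.seed(31)
  for (i in 1:20) {
    x <- complex(modulus = runif(10, 0.5, 2), argument = runif(10, -pi, pi))
    expect_lte(vector_average(x)$amplitude, mean(Mod(x)) + 1e-12)
  }

  empty <- vector_average(complex(0))
  expect_true(empty$empty)
})

test_that("displacement averaging is within-participant first", {
  # identical bins: participant average is the common value
  x <- matrix(rep(1 + 2i, 8), 2, 4)
  da <- displacement_average(x)
  expect_equal(unname(da$per_participant), rep(1 + 2i, 2))

  # opposite phases cancel (the zero group mean makes the projection
  # undefined, which is warned about)
  x2 <- matrix(rep(c(1 + 1i, -1 - 1i), 3), 1, 6)
  expect_equal(
    Mod(suppressWarnings(displacement_average(rbind(x2, x2)))$mean), 0)

  # unbalanced validity: result equals the two-stage oracle, not the
  # pooled-epoch mean
  x3 <- rbind(c(1 + 0i, 3 + 0i, NA), c(10 + 0i, NA, NA))
  da3 <- displacement_average(x3)
  two_stage <- mean(c(mean(c(1, 3)), 10))
  pooled <- mean(c(1, 3, 10))
  expect_equal(Re(da3$mean), two_stage)
  expect_false(isTRUE(all.equal(Re(da3$mean), pooled)))
})

test_that("the projection-mean identity is exact", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:25, 1)
    x <- complex(real = rnorm(n), imaginary = rnorm(n))
    p <- projected_amplitude(x)
    expect_lt(abs(mean(p) - Mod(mean(x))), 1e-12)
  }
  # all participants share a vector: every projection equals its magnitude
  v <- 1.2 - 0.8i
  expect_equal(projected_amplitude(rep(v, 5)), rep(Mod(v), 5))
  # orthogonal participant projects to zero
  expect_equal(projected_amplitude(1i, group_mean = 1 + 0i), 0)
  expect_warning(projected_amplitude(c(1 + 0i, -1 + 0i)), "zero amplitude")
})

test_that("paired t comparison matches the closed form", {
  # constructed differences 1..5 against zero
  a <- c(1, 2, 3, 4, 5); b <- rep(0, 5)
  res <- paired_t_comparison(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(res$t, t_oracle)
  expect_equal(res$p, p_oracle)
  expect_equal(res$df, 4)
  expect_equal(res$d, mean(d) / sd(d))

  # identical conditions: t = 0, p = 1
  res0 <- paired_t_comparison(a, a)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  expect_error(paired_t_comparison(1:2, 2:3), "at least 3")
})

test_that("a global phase rotation leaves amplitudes and tests unchanged", {
  set.seed(44)
  n <- 12; nb <- 10
  a <- matrix(complex(real = rnorm(n * nb, 1), imaginary = rnorm(n * nb)),
              n, nb)
  b <- a + matrix(complex(real = rnorm(n * nb, 0.3),
                          imaginary = rnorm(n * nb, 0.1)), n, nb)
  theta <- 1.234
  rot <- exp(1i * theta)
  va1 <- vector_average(a[, 1]); va2 <- vector_average(a[, 1] * rot)
  expect_equal(Arg(va2$mean), Arg(va1$mean * rot))
  expect_lt(abs(va2$amplitude - va1$amplitude), 1e-9)
  expect_lt(max(abs(va2$projections - va1$projections)), 1e-9)
  c1 <- condition_comparison(a, b)
  c2 <- condition_comparison(a * rot, b * rot)
  expect_lt(max(abs(c1$t - c2$t)), 1e-9)
  expect_lt(max(abs(c1$p - c2$p)), 1e-9)
})

test_that("condition comparison covers bins and the displacement average", {
  set.seed(9)
  n <- 10; nb <- 4
  a <- matrix(complex(real = rnorm(n * nb, 2, 0.2),
                      imaginary = rnorm(n * nb, 0, 0.2)), n, nb)
  b <- matrix(complex(real = rnorm(n * nb, 1, 0.2),
                      imaginary = rnorm(n * nb, 0, 0.2)), n, nb)
  cmp <- condition_comparison(a, b, labels = c("in", "anti"))
  expect_equal(nrow(cmp), nb + 1)
  expect_true("average" %in% cmp$bin)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_true(all(cmp$df == n - 1))
  # planted difference is detected
  expect_lt(cmp$p[cmp$bin == "average"], 0.01)
  # bonferroni inflates per-bin p values only
  cmpb <- condition_comparison(a, b, bonferroni = TRUE)
  expect_equal(cmpb$p[cmpb$bin == "average"], cmp$p[cmp$bin == "average"])
  expect_true(all(cmpb$p[cmpb$bin != "average"] >=
                    cmp$p[cmp$bin != "average"]))
})

test_that("null simulations reject at the nominal rate", {
  set.seed(100)
  prot <- adult_protocol()
  truths <- list(a = nr_params(2, 2, 2), b = nr_params(2, 2, 2))
  rej <- replicate(300, {
    sim <- simulate_coefficient_cohort(12, prot, truths,
                                       coef_noise_sd = 1.5, n_trials = 5,
                                       seed = sample.int(2^30, 1))
    da <- displacement_average(sim$a)
    db <- displacement_average(sim$b)
    paired_t_comparison(da$projections, db$projections)$p < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.10)
})

test_that("noise floor scales with noise and ignores coherent signal", {
  # zero-noise synthetic data: floor at numerical zero
  prot <- adult_protocol()
  mont <- tiny_montage(8)
  cond <- condition_spec("in_phase")
  truth <- single_harmonic_truth(cond, mont, rmax = 2, phase = 0.3)
  rec <- synthesize_trial(cond, prot, truth, mont, noise = NULL, seed = 1)
  ct <- extract_coefficients(segment_epochs(rec), estimator = "dft")
  w <- truth$harmonics[["2"]]$topography
  mdl <- structure(list(W = matrix(w, ncol = 1), K = 1),
                   class = "rca_model")
  pr <- project_through(ct, mdl)
  nf <- noise_floor(pr$noise, harmonic = 2)
  expect_lt(max(nf), 1e-9)
  # and the planted 2F signal is far above it
  expect_gt(min(Mod(pr$signal[2, 5:10])), 1e-3)

  # doubling white noise doubles the floor (within Monte-Carlo error)
  floor_at <- function(sigma, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      x <- matrix(rnorm(8 * 4200, 0, sigma), 8, 4200)
      ctn <- extract_coefficients(segment_epochs(x, fs = 420),
                                  estimator = "dft")
      mean(noise_floor(project_through(ctn, mdl)$noise, harmonic = 2))
    }, 0))
  }
  f1 <- floor_at(1, 1:12)
  f2 <- floor_at(2, 13:24)
  expect_gt(f2 / f1, 1.7)
  expect_lt(f2 / f1, 2.3)
})
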