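test_that("all-zero recordings yield all-zero blocks with zero residual", {
  ts <- parcellated_ts(matrix(0, 6, 50), dt = 0.72)
  part <- partition_spec(1:4, 5:6)
  fit <- fit_causal_signature(ts, part, lambda = 0.1)
  expect_equal(fit$Q, matrix(0, 4, 4))
  expect_equal(fit$A, matrix(0, 4, 4))
  expect_equal(fit$B1, matrix(0, 4, 2))
  expect_equal(fit$residual_norm, 0)
})

test_that("noise-free data is fit to numerical zero residual and the
           state-evolution form is recovered", {
  for (seed in 1:3) {
    truth <- random_signature(m = 5, n = 2, seed = seed)
    set.seed(seed + 100)
    U <- matrix(rnorm(2 * 401), 2, 401)
    ts <- simulate(truth, U = U, x0 = rnorm(5), noise_sd = 0)
    fit <- fit_causal_signature(ts, truth$partition, lambda = 1e-8)
    expect_lt(fit$residual_norm, 1e-9)
    sf <- state_evolution(fit); st <- state_evolution(truth)
    expect_lt(causalprint:::rel_frob(sf$A_hat, st$A_hat), 1e-6)
    expect_lt(causalprint:::rel_frob(sf$B1_hat, st$B1_hat), 1e-6)
    expect_lt(causalprint:::rel_frob(sf$B2_hat, st$B2_hat), 1e-6)
  }
})

test_that("the scalar-state model (no fast block exists) is recovered exactly", {
  # m = 1 has no off-diagonal Q, so all remaining blocks are identifiable
  truth <- causal_signature(Q = matrix(0), A = matrix(0.6),
                            B1 = matrix(0.8), B2 = matrix(-0.4))
  set.seed(9)
  U <- matrix(rnorm(301), 1, 301)
  ts <- simulate(truth, U = U, x0 = 1, noise_sd = 0)
  fit <- fit_causal_signature(ts, truth$partition, lambda = 1e-10)
  expect_equal(fit$A[1, 1], 0.6, tolerance = 1e-8)
  expect_equal(fit$B1[1, 1], 0.8, tolerance = 1e-8)
  expect_equal(fit$B2[1, 1], -0.4, tolerance = 1e-8)
})

test_that("identified signatures have a bit-exact zero Q diagonal", {
  spec <- cohort_spec(n_subjects = 1, n_tasks = 1, runs_per_pair = 1,
                      m = 8, n = 2, T = 120, seed = 4)
  run <- generate_cohort(spec)$runs[[1]]
  for (mode in c("ridge", "stated")) {
    fit <- fit_causal_signature(run$ts, run$truth$partition, lambda = 0.5,
                                mode = mode)
    expect_identical(diag(fit$Q), rep(0, 8))
  }
})

test_that("full-scale 100-parcel problems produce a 90 x 200 signature", {
  set.seed(2)
  ts <- parcellated_ts(matrix(rnorm(100 * 211), 100, 211), dt = 0.72)
  part <- partition_spec(1:90, 91:100)
  fit <- fit_causal_signature(ts, part, lambda = 1, keep_data = FALSE)
  expect_identical(dim(coef(fit)), c(90L, 200L))
})

test_that("a too-short recording warns about underdetermination", {
  ts <- parcellated_ts(matrix(rnorm(6 * 10), 6, 10), dt = 0.72)
  part <- partition_spec(1:4, 5:6)
  expect_warning(fit_causal_signature(ts, part, lambda = 0.1), "underdetermined")
})

test_that("one-step residual equals the stored norm and beats the zero model", {
  spec <- cohort_spec(n_subjects = 1, n_tasks = 1, runs_per_pair = 1,
                      m = 6, n = 2, T = 150, seed = 5)
  run <- generate_cohort(spec)$runs[[1]]
  part <- run$truth$partition
  fit <- fit_causal_signature(run$ts, part, lambda = 1e-8)
  expect_equal(one_step_residual(fit, run$ts), fit$residual_norm,
               tolerance = 1e-10)
  X <- unclass(run$ts)[part$state_idx, , drop = FALSE]
  zero_model <- causalprint:::frob(X[, -1, drop = FALSE])
  expect_lte(fit$residual_norm, zero_model)
  # objective never exceeds the zero-solution objective, both modes
  for (mode in c("ridge", "stated")) {
    f2 <- fit_causal_signature(run$ts, part, lambda = 0.3, mode = mode)
    zero_obj <- if (mode == "ridge") zero_model^2 else zero_model
    expect_lte(f2$objective, zero_obj)
  }
})

test_that("residual grows with the noise level on a fixed system", {
  truth <- random_signature(m = 5, n = 2, seed = 11)
  set.seed(12)
  U <- matrix(rnorm(2 * 151), 2, 151)
  x0 <- rnorm(5)
  grid <- seq(0, 0.5, length.out = 20)
  res <- vapply(seq_along(grid), function(i) {
    ts <- simulate(truth, U = U, x0 = x0, noise_sd = grid[i], seed = 100 + i)
    fit_causal_signature(ts, truth$partition, lambda = 1e-6,
                         keep_data = FALSE)$residual_norm
  }, numeric(1))
  expect_gt(cor(grid, res, method = "spearman"), 0)
})

test_that("ridge and stated objectives coincide with OLS at vanishing lambda", {
  spec <- cohort_spec(n_subjects = 1, n_tasks = 1, runs_per_pair = 1,
                      m = 5, n = 2, T = 200, noise_sd = 0.1, seed = 6)
  run <- generate_cohort(spec)$runs[[1]]
  fr <- fit_causal_signature(run$ts, run$truth$partition, lambda = 1e-8)
  fs <- fit_causal_signature(run$ts, run$truth$partition, lambda = 1e-8,
                             mode = "stated")
  expect_lt(causalprint:::rel_frob(coef(fs), coef(fr)), 1e-5)
})

test_that("the stated-mode solution is no worse than the ridge solution
           under the unsquared objective", {
  spec <- cohort_spec(n_subjects = 1, n_tasks = 1, runs_per_pair = 1,
                      m = 5, n = 2, T = 200, noise_sd = 0.1, seed = 13)
  run <- generate_cohort(spec)$runs[[1]]
  lam <- 0.8
  stated_obj <- function(fit) {
    fit$residual_norm + lam * (causalprint:::frob(fit$Q) +
      causalprint:::frob(fit$A) + causalprint:::frob(fit$B1) +
      causalprint:::frob(fit$B2))
  }
  fr <- fit_causal_signature(run$ts, run$truth$partition, lambda = lam)
  fs <- fit_causal_signature(run$ts, run$truth$partition, lambda = lam,
                             mode = "stated")
  expect_lte(stated_obj(fs), stated_obj(fr) + 1e-8)
})
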