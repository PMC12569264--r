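test_that("with no fast block the state-evolution form is the model itself", {
  set.seed(200)
  A <- matrix(rnorm(16, sd = 0.2), 4, 4)
  B1 <- matrix(rnorm(8), 4, 2); B2 <- matrix(rnorm(8), 4, 2)
  sig <- causal_signature(Q = matrix(0, 4, 4), A = A, B1 = B1, B2 = B2)
  se <- state_evolution(sig)
  expect_equal(se$A_hat, A)
  expect_equal(se$B1_hat, B1)
  expect_equal(se$B2_hat, B2)
})

test_that("implicit and explicit trajectories coincide", {
  for (seed in 201:220) {
    sig <- random_signature(m = 4, n = 2, seed = seed)
    se <- state_evolution(sig)
    set.seed(seed + 1000)
    U <- matrix(rnorm(2 * 51), 2, 51)
    x0 <- rnorm(4)
    imp <- unclass(simulate(sig, U = U, x0 = x0, noise_sd = 0))[1:4, ]
    exp_ <- unroll_explicit(se, U, x0)
    expect_lt(max(abs(imp - exp_)), 1e-8)
  }
})

test_that("without input couplings nothing is reachable from rest", {
  sig <- random_signature(m = 4, n = 2, seed = 230)
  sig$B1[] <- 0; sig$B2[] <- 0
  v <- reachability_values(state_evolution(sig), T_M = 5)
  expect_equal(unname(v), rep(0, 4))
})

test_that("energy values match the attainment oracle and dominate sampling", {
  sig <- random_signature(m = 4, n = 2, seed = 231)
  se <- state_evolution(sig)
  T_M <- 6; n <- 2
  v <- reachability_values(se, T_M, "energy")
  # rebuild the input-to-terminal-state map column-block by column-block
  W <- matrix(0, 4, n * T_M)
  for (k in 0:(T_M - 1)) {
    Mk <- mat_pow(se$A_hat, T_M - 1 - k) %*% se$B2_hat
    if (k >= 1) Mk <- Mk + mat_pow(se$A_hat, T_M - k) %*% se$B1_hat
    W[, k * n + 1:n] <- Mk
  }
  set.seed(232)
  sampled <- replicate(500, {
    u <- rnorm(n * T_M); u <- u / sqrt(sum(u^2))
    as.vector(W %*% u)
  })
  for (i in 1:4) {
    expect_lte(max(sampled[i, ]), v[i] + 1e-12)
    ustar <- W[i, ] / sqrt(sum(W[i, ]^2))           # analytic maximizer
    Ustar <- cbind(matrix(ustar, n, T_M), 0)        # u(T_M) = 0
    traj <- unroll_explicit(se, Ustar, rep(0, 4))
    expect_equal(traj[i, T_M + 1], unname(v[i]), tolerance = 1e-8)
  }
})

test_that("reachability is exactly monotone in the horizon when inputs
           couple only through the lagged gain", {
  for (seed in 240:244) {
    sig <- random_signature(m = 5, n = 2, seed = seed)
    sig$B1[] <- 0                      # lagged-only input coupling
    se <- state_evolution(sig)
    v1 <- reachability_values(se, 1)
    v5 <- reachability_values(se, 5)
    v9 <- reachability_values(se, 9)
    expect_true(all(v1 <= v5 + 1e-12))
    expect_true(all(v5 <= v9 + 1e-12))
  }
})

test_that("horizon growth can shed at most the concurrent boundary term", {
  # with x(0) = 0 the first input has no concurrent path, so extending the
  # horizon is worth values(T) minus the norm of the Ahat^T B1hat row
  for (seed in 240:244) {
    sig <- random_signature(m = 5, n = 2, seed = seed)
    se <- state_evolution(sig)
    for (Tm in c(1, 3, 5)) {
      v_lo <- reachability_values(se, Tm)
      v_hi <- reachability_values(se, Tm + 1)
      bnd <- sqrt(rowSums((mat_pow(se$A_hat, Tm) %*% se$B1_hat)^2))
      expect_true(all(v_hi >= v_lo - bnd - 1e-12))
    }
  }
})

test_that("box-model values dominate energy-model values", {
  for (seed in 240:244) {
    sig <- random_signature(m = 5, n = 2, seed = seed)
    se <- state_evolution(sig)
    v5 <- reachability_values(se, 5)
    expect_true(all(reachability_values(se, 5, "box") >= v5 - 1e-12))
  }
})

test_that("energy values are invariant to orthogonal input recombination", {
  sig <- random_signature(m = 4, n = 3, seed = 250)
  se <- state_evolution(sig)
  set.seed(251)
  O <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  sig2 <- causal_signature(sig$Q, sig$A, sig$B1 %*% O, sig$B2 %*% O)
  v1 <- reachability_values(se, 6, "energy")
  v2 <- reachability_values(state_evolution(sig2), 6, "energy")
  expect_equal(unname(v1), unname(v2), tolerance = 1e-10)
})

test_that("the landscape grid places, masks, normalizes and inverts correctly", {
  set.seed(260)
  v <- runif(90)
  l <- reachability_landscape(v, horizon = 5L, norm_model = "energy")
  expect_identical(sum(!is.na(l$grid)), 90L)
  expect_identical(sum(is.na(l$grid)), 54L)
  expect_equal(range(l$values), c(0, 1))
  expect_equal(grid_to_values(l), l$values)
  # row-major atlas order: first grid row holds regions 1..12
  expect_equal(l$grid[1, ], l$values[1:12])
  # constant input maps to a uniform grid of ones
  lc <- reachability_landscape(rep(3, 10))
  expect_equal(lc$values, rep(1, 10))
  expect_error(reachability_landscape(runif(145)), "144")
  expect_error(reachability_values(state_evolution(
    random_signature(4, 1, 1)), T_M = 0), "T_M")
})
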