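test_that("a diagonal slow block yields identity mode vectors", {
  sig <- causal_signature(Q = matrix(0, 2, 2), A = diag(c(0.9, 0.5)))
  mf <- modal_features(sig, "slow")
  expect_equal(abs(mf$T_slow), diag(2), tolerance = 1e-12)
  expect_setequal(round(Re(mf$eig_slow), 10), c(0.9, 0.5))
})

test_that("symmetric matrices give an orthogonal mode basis", {
  set.seed(21)
  M <- matrix(rnorm(36), 6, 6); M <- (M + t(M)) / 2
  sig <- causal_signature(Q = matrix(0, 6, 6), A = M)
  mf <- modal_features(sig, "slow")
  expect_lt(max(abs(crossprod(mf$T_slow) - diag(6))), 1e-8)
})

test_that("eigendecomposition reconstructs random diagonalizable matrices", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    A <- matrix(rnorm(36, sd = 0.4), 6, 6)
    sig <- causal_signature(Q = matrix(0, 6, 6), A = A)
    mf <- modal_features(sig, "slow")
    expect_lt(mf$recon_error, 1e-8)
    # canonicalization: unit columns with a positive dominant entry
    nrm <- sqrt(colSums(mf$T_slow^2))
    expect_equal(nrm, rep(1, 6), tolerance = 1e-12)
    dom <- vapply(seq_len(6), function(j) {
      col <- mf$T_slow[, j]; col[which.max(abs(col))]
    }, numeric(1))
    expect_true(all(dom > 0))
  }
})

test_that("complex eigenpairs become real (Re, Im) feature pairs", {
  th <- 0.7
  R2 <- 0.9 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sig <- causal_signature(Q = matrix(0, 2, 2), A = R2)
  mf <- modal_features(sig, "slow")
  expect_true(is.numeric(mf$features))
  expect_identical(dim(mf$features), c(2L, 2L))
  expect_equal(sort(Mod(mf$eig_slow)), c(0.9, 0.9), tolerance = 1e-10)
})

test_that("near-defective matrices fall back to Schur vectors with a warning", {
  J <- rbind(c(0.5, 1), c(0, 0.5))    # Jordan block, not diagonalizable
  sig <- causal_signature(Q = matrix(0, 2, 2), A = J)
  expect_warning(mf <- modal_features(sig, "slow"), "Schur")
  expect_lt(max(abs(crossprod(mf$T_slow) - diag(2))), 1e-8)
})

test_that("the full feature set stacks slow and fast modes", {
  sig <- random_signature(m = 5, n = 2, seed = 41)
  mf <- modal_features(sig, "full")
  expect_identical(dim(mf$features), c(5L, 10L))
  expect_identical(dim(mf$T_fast), c(5L, 5L))
})

test_that("single-timescale features need the training data", {
  sig <- random_signature(m = 4, n = 1, seed = 42)   # no data attached
  expect_error(modal_features(sig, "single"), "keep_data")
  spec <- cohort_spec(n_subjects = 1, n_tasks = 1, runs_per_pair = 1,
                      m = 4, n = 1, T = 80, seed = 42)
  run <- generate_cohort(spec)$runs[[1]]
  fit <- fit_causal_signature(run$ts, run$truth$partition, lambda = 0.5)
  mf <- modal_features(fit, "single")
  expect_identical(mf$feature_mode, "single")
  expect_identical(dim(mf$features), c(4L, 4L))
})
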