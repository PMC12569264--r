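test_that("a query identical to a library entry matches it at distance zero", {
  sigs <- lapply(1:4, function(s) random_signature(m = 6, n = 2, seed = 60 + s))
  feats <- lapply(sigs, modal_features)
  lib <- reference_library(setNames(feats, sprintf("sub%02d", 1:4)), "rest")
  res <- identify_subject(feats[[3]], lib)
  expect_identical(res$label, "sub03")
  expect_lt(res$distance, 1e-12)
  expect_identical(nrow(res$ranking), 4L)
})

test_that("ties are broken by the lexicographically smallest label", {
  f <- modal_features(random_signature(m = 4, n = 1, seed = 71))
  lib <- reference_library(list(zeta = f, alpha = f), "rest")
  res <- identify_subject(f, lib)
  expect_identical(res$label, "alpha")
})

test_that("an empty or ill-formed library is rejected", {
  expect_error(reference_library(list()), "empty")
  f <- modal_features(random_signature(m = 4, n = 1, seed = 72))
  expect_error(reference_library(list(f, f)), "named")
})

test_that("duplicate runs give perfect accuracy on every fold", {
  feats <- lapply(1:5, function(s)
    modal_features(random_signature(m = 5, n = 1, seed = 80 + s)))
  features <- c(feats, feats)                       # two identical conditions
  subject <- rep(sprintf("s%02d", 1:5), 2)
  condition <- rep(c("run1", "run2"), each = 5)
  ev <- evaluate_subject_accuracy(features, subject, condition)
  expect_equal(ev$per_fold$accuracy, c(1, 1))
  expect_equal(ev$mean_accuracy, 1)
})

test_that("a subject missing from the reference fold raises an error", {
  feats <- lapply(1:4, function(s)
    modal_features(random_signature(m = 4, n = 1, seed = 90 + s)))
  subject <- c("a", "b", "a", "b")
  condition <- c("r1", "r1", "r2", "r2")
  ev <- evaluate_subject_accuracy(feats, subject, condition)
  expect_identical(nrow(ev$per_fold), 2L)
  expect_error(
    evaluate_subject_accuracy(feats[1:3], c("a", "b", "a"), c("r1", "r1", "r2")),
    "missing")
})

test_that("a low-noise cohort is identified perfectly across runs", {
  spec <- cohort_spec(n_subjects = 12, n_tasks = 1, runs_per_pair = 2,
                      noise_sd = 0.02, seed = 101)
  coh <- generate_cohort(spec)
  feats <- lapply(coh$runs, function(r)
    modal_features(fit_causal_signature(r$ts, coh$partition, lambda = 2,
                                        keep_data = FALSE)))
  subj <- vapply(coh$runs, `[[`, "", "subject")
  runv <- vapply(coh$runs, function(r) as.character(r$run), "")
  ev <- evaluate_subject_accuracy(feats, subj, runv)
  expect_equal(ev$mean_accuracy, 1)
})

test_that("without subject differences accuracy collapses to chance", {
  ns <- 8
  accs <- vapply(1:5, function(seed) {
    spec <- cohort_spec(n_subjects = ns, n_tasks = 1, runs_per_pair = 2,
                        m = 10, n = 3, T = 150, subject_spread = 0, seed = seed)
    coh <- generate_cohort(spec)
    feats <- lapply(coh$runs, function(r)
      modal_features(fit_causal_signature(r$ts, coh$partition, lambda = 2,
                                          keep_data = FALSE)))
    subj <- vapply(coh$runs, `[[`, "", "subject")
    runv <- vapply(coh$runs, function(r) as.character(r$run), "")
    evaluate_subject_accuracy(feats, subj, runv)$mean_accuracy
  }, numeric(1))
  # binomial check around chance 1/ns: 5 seeds x 2 folds x 8 queries = 80 trials
  p_chance <- 1 / ns
  se <- sqrt(p_chance * (1 - p_chance) / (5 * 2 * ns))
  expect_lt(mean(accs), p_chance + 4 * se)
})
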