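small_cfg <- function(classes = 3, ...) {
  task_classifier_config(heads1 = 2, out1 = 4, skip1 = 8, heads2 = 2,
                         out2 = 3, skip2 = 6, classes = classes, ...)
}

random_graph <- function(m, fdim, label, seed) {
  set.seed(seed)
  Q <- matrix(rnorm(m * m, sd = 0.1), m, m); diag(Q) <- 0
  n <- (fdim - 2 * m) / 2
  sig <- causal_signature(Q, matrix(rnorm(m * m, sd = 0.2), m, m),
                          matrix(rnorm(m * n), m, n),
                          matrix(rnorm(m * n), m, n))
  signature_graph(sig, label = label)
}

test_that("configuration invariants are enforced", {
  expect_error(task_classifier_config(heads1 = 4, out1 = 32, skip1 = 100),
               "skip1")
  expect_error(task_classifier_config(pool_ratio = 0), "pool_ratio")
  expect_silent(task_classifier_config())
})

test_that("forward passes emit normalized log-probabilities of length C", {
  cfg <- task_classifier_config(classes = 8, seed = 3)
  clf <- init_task_classifier(cfg, in_dim = 16)
  for (seed in 1:5) {
    g <- random_graph(m = 6, fdim = 16, label = 0L, seed = 120 + seed)
    expect_warning(pr <- predict(clf, g), "trained")
    expect_length(pr$logp, 8L)
    expect_equal(log(sum(exp(pr$logp))), 0, tolerance = 1e-6)
  }
})

test_that("top-k pooling keeps ceil(0.8 * 90) = 72 nodes on a 90-node graph", {
  cfg <- task_classifier_config(classes = 8, seed = 3)
  clf <- init_task_classifier(cfg, in_dim = 200)
  g <- random_graph(m = 90, fdim = 200, label = 0L, seed = 130)
  gt <- causalprint:::graph_tensors(g)
  fw <- causalprint:::net_forward(clf$params, cfg, gt$X, gt$src, gt$dst, gt$ew)
  expect_identical(fw$n_pooled, 72)
})

test_that("analytic gradients match central finite differences", {
  cfg <- small_cfg(attn_dropout = 0, edge_dropout = 0, seed = 7)
  set.seed(140)
  N <- 5; Fin <- 6
  X <- matrix(rnorm(N * Fin), N, Fin)
  src <- c(1, 2, 3, 4, 5, 1); dst <- c(2, 3, 4, 5, 1, 3)
  ew <- runif(6)
  par <- causalprint:::with_seed(7, causalprint:::init_gat_params(cfg, Fin))
  y <- 2L
  fw <- causalprint:::net_forward(par, cfg, X, src, dst, ew, training = FALSE,
                                  want_cache = TRUE)
  gr <- causalprint:::net_backward(par, cfg, fw$cache, y)
  loss_of <- function(p)
    -causalprint:::net_forward(p, cfg, X, src, dst, ew)$logp[y + 1]
  eps <- 1e-6
  for (nm in c("l1_Ws_1", "l1_a_2", "l1_We_1", "sk1_W", "pool_p",
               "l2_Wt_2", "sk2_b", "out_W")) {
    ref <- par[[nm]]
    pick <- seq_len(min(6L, length(ref)))
    for (i in pick) {
      p1 <- par; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] - eps
      gnum <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
      expect_equal(gr[[nm]][i], gnum, tolerance = 1e-4)
    }
  }
})

test_that("inference is deterministic: two forward passes agree exactly", {
  cfg <- small_cfg(seed = 8)
  clf <- init_task_classifier(cfg, in_dim = 16)
  g <- random_graph(m = 6, fdim = 16, label = 1L, seed = 150)
  suppressWarnings({
    p1 <- predict(clf, g)$logp
    p2 <- predict(clf, g)$logp
  })
  expect_identical(p1, p2)
})

test_that("training is a deterministic function of the seed", {
  graphs <- c(lapply(1:4, function(s) random_graph(6, 16, 0L, 160 + s)),
              lapply(1:4, function(s) random_graph(6, 16, 1L, 170 + s)))
  cfg <- small_cfg(classes = 2, epochs = 3, patience = Inf, seed = 9)
  c1 <- fit_task_classifier(cfg, graphs)
  c2 <- fit_task_classifier(cfg, graphs)
  expect_identical(c1$params, c2$params)
  expect_identical(c1$history, c2$history)
})

test_that("training loss decreases over the first epochs on a separable set", {
  spec <- cohort_spec(n_subjects = 6, n_tasks = 2, runs_per_pair = 1,
                      m = 8, n = 2, T = 120, task_spread = 1, seed = 10)
  ens <- generate_task_ensemble(spec, lambda = 1)
  drops <- vapply(1:5, function(seed) {
    cfg <- small_cfg(classes = 2, epochs = 10, patience = Inf,
                     learning_rate = 5e-3, seed = seed)
    h <- fit_task_classifier(cfg, ens$train)$history
    h$loss[1] - h$loss[10]
  }, numeric(1))
  expect_gt(median(drops), 0)
})

test_that("a single-class training set is rejected", {
  graphs <- lapply(1:4, function(s) random_graph(6, 16, 0L, 180 + s))
  cfg <- small_cfg(classes = 2, epochs = 2, seed = 1)
  expect_error(fit_task_classifier(cfg, graphs), "single class")
})

test_that("a small well-separated two-task ensemble is classified", {
  spec <- cohort_spec(n_subjects = 10, n_tasks = 2, runs_per_pair = 1,
                      m = 8, n = 2, T = 120, task_spread = 1, seed = 12)
  ens <- generate_task_ensemble(spec, lambda = 1)
  cfg <- task_classifier_config(classes = 2, epochs = 30, patience = Inf,
                                seed = 12)
  clf <- fit_task_classifier(cfg, ens$train)
  expect_gte(task_accuracy(clf, ens$test), 0.8)
})
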