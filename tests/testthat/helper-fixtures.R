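# Shared fixture builders. Everything is generated in code under fixed seeds.

# random continuous two-timescale system with zero F_f diagonal
random_cts <- function(m, n, seed, epsilon = 0.2, dt = 0.72) {
  set.seed(seed)
  F_f <- matrix(rnorm(m * m, sd = 0.3), m, m); diag(F_f) <- 0
  two_timescale_system(
    F_s = matrix(rnorm(m * m, sd = 0.5), m, m),
    G_s = matrix(rnorm(m * n), m, n),
    F_f = F_f,
    G_f = matrix(rnorm(m * n), m, n),
    epsilon = epsilon, dt = dt)
}

# random discrete signature with stable state evolution
random_signature <- function(m, n, seed, margin = 0.9, dt = 0.72) {
  set.seed(seed)
  Q <- matrix(rnorm(m * m, sd = 0.3 / sqrt(m)), m, m); diag(Q) <- 0
  A <- matrix(rnorm(m * m, sd = 1 / sqrt(m)), m, m)
  rho <- max(Mod(eigen(solve(diag(m) - Q, A))$values))
  A <- A * margin / rho
  B1 <- if (n > 0) matrix(rnorm(m * n, sd = 0.5), m, n) else matrix(0, m, 0)
  B2 <- if (n > 0) matrix(rnorm(m * n, sd = 0.5), m, n) else matrix(0, m, 0)
  causal_signature(Q, A, B1, B2, dt = dt)
}

# wrap a raw feature matrix as a modal feature set (for distance tests)
feat_from_matrix <- function(M, feature_mode = "slow") {
  structure(list(features = causalprint:::canonicalize_columns(M),
                 m = nrow(M), feature_mode = feature_mode),
            class = "modal_features")
}

# brute-force oracle for the permutation-aligned distance
brute_force_distance <- function(X, Y) {
  X <- causalprint:::canonicalize_columns(X)
  Y <- causalprint:::canonicalize_columns(Y)
  cost <- 1 - crossprod(X, Y)
  n <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], Recall(v[-i])))
    out
  }
  P <- perms(seq_len(n))
  best <- Inf
  for (r in seq_len(nrow(P)))
    best <- min(best, sum(cost[cbind(seq_len(n), P[r, ])]))
  best
}

# explicit state-evolution unrolling (independent of simulate())
unroll_explicit <- function(form, U, x0) {
  m <- form$m; Tn <- ncol(U) - 1L
  X <- matrix(0, m, Tn + 1L); X[, 1L] <- x0
  for (k in seq_len(Tn))
    X[, k + 1L] <- form$A_hat %*% X[, k] + form$B1_hat %*% U[, k + 1L] +
      form$B2_hat %*% U[, k]
  X
}

# iterative matrix power (oracle helper)
mat_pow <- function(M, k) {
  P <- diag(nrow(M))
  while (k > 0) { P <- P %*% M; k <- k - 1 }
  P
}
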