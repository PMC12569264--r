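#' @keywords internal
"_PACKAGE"

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_finite <- function(x, name = deparse(substitute(x))) {
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}

# 2-norm condition number via SVD (matrices here are small and dense).
cond2 <- function(M) {
  s <- svd(M, nu = 0, nv = 0)$d
  if (min(s) == 0) Inf else max(s) / min(s)
}

frob <- function(M) sqrt(sum(M^2))

rel_frob <- function(est, truth) {
  d <- frob(truth)
  if (d == 0) frob(est) else frob(est - truth) / d
}

spectral_radius <- function(M) {
  if (nrow(M) == 0L) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Solve (G + diag(pen)) beta = b for symmetric PSD G via eigendecomposition,
# truncating numerically null directions (relative eigenvalue < rcond).
# When the penalized system is degenerate this returns the minimum-norm
# solution restricted to the informative subspace.
solve_psd <- function(G, b, pen = 0, rcond = 1e-11) {
  if (length(pen) == 1L) pen <- rep(pen, nrow(G))
  M <- G
  diag(M) <- diag(M) + pen
  ee <- eigen(M, symmetric = TRUE)
  d <- ee$values
  dmax <- max(d, 0)
  keep <- d > dmax * rcond
  if (dmax <= 0) return(b * 0)
  Vk <- ee$vectors[, keep, drop = FALSE]
  Vk %*% (crossprod(Vk, b) / d[keep])
}
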