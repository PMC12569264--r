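#' State-evolution form of a causal signature
#'
#' Rewrites the implicit two-timescale model as an explicit recursion
#' \deqn{x(t) = \hat A x(t-1) + \hat B_1 u(t) + \hat B_2 u(t-1)}
#' with \eqn{\hat A = (I-Q)^{-1}A}, \eqn{\hat B_1 = (I-Q)^{-1}B_1},
#' \eqn{\hat B_2 = (I-Q)^{-1}B_2}, folding the fast concurrent interactions
#' into the state evolution. Computed by linear solves, not an explicit
#' inverse.
#'
#' @param sig a [causal_signature].
#' @return An object of class `state_evolution` with `A_hat`, `B1_hat`,
#'   `B2_hat` and a logical `stable` flag (spectral radius of `A_hat` < 1).
#' @export
state_evolution <- function(sig) {
  stopifnot(inherits(sig, "causal_signature"))
  M <- diag(sig$m) - sig$Q
  kap <- cond2(M)
  if (!is.finite(kap) || kap >= 1e12)
    stop(sprintf("(I - Q) is numerically singular (condition number %.3e >= 1e12)", kap))
  Mqr <- qr(M)
  A_hat <- solve(Mqr, sig$A)
  B1_hat <- if (sig$n > 0) solve(Mqr, sig$B1) else sig$B1
  B2_hat <- if (sig$n > 0) solve(Mqr, sig$B2) else sig$B2
  rho <- spectral_radius(A_hat)
  if (rho >= 1)
    warning(sprintf("state evolution is unstable (spectral radius %.4f >= 1)", rho))
  structure(list(A_hat = A_hat, B1_hat = B1_hat, B2_hat = B2_hat,
                 m = sig$m, n = sig$n, spectral_radius = rho,
                 stable = rho < 1, state_labels = sig$state_labels),
            class = "state_evolution")
}

#' @export
print.state_evolution <- function(x, ...) {
  cat(sprintf("State evolution form: m = %d, n = %d, spectral radius %.4f%s\n",
              x$m, x$n, x$spectral_radius,
              if (x$stable) "" else " (unstable)"))
  invisible(x)
}

#' Per-region maximal terminal activation under bounded input
#'
#' Starting from rest (`x(0) = 0`), unrolls the state evolution over a
#' horizon of `T_M` scans, with the input window restricted to
#' `u(0), ..., u(T_M - 1)` (so `u(T_M) = 0`):
#' \deqn{x(T_M) = \sum_{k=0}^{T_M-1} M_k u(k),\quad
#'   M_k = [k \ge 1]\,\hat A^{T_M-k}\hat B_1 + \hat A^{T_M-1-k}\hat B_2.}
#' Each region's value is the maximum of its entry of `x(T_M)` over the
#' admissible input set, optimized independently per region:
#' * `norm_model = "energy"`: inputs bounded in total energy,
#'   `||U||_F <= 1`; the maximum is the Euclidean norm of the corresponding
#'   row of `[M_0 ... M_{T_M-1}]`, attained by the unit input aligned with
#'   that row.
#' * `norm_model = "box"`: every input entry bounded, `|u| <= 1` (the
#'   linear-programming reading); the maximum is the row's l1 norm.
#'
#' Powers of `A_hat` are accumulated iteratively for numerical robustness.
#'
#' @param form a [state_evolution()].
#' @param T_M horizon in scans, >= 1.
#' @param norm_model `"energy"` or `"box"`.
#' @return Numeric m-vector of non-negative maximal activations.
#' @export
reachability_values <- function(form, T_M, norm_model = c("energy", "box")) {
  norm_model <- match.arg(norm_model)
  stopifnot(inherits(form, "state_evolution"))
  T_M <- as.integer(T_M)
  if (is.na(T_M) || T_M < 1L) stop("'T_M' must be an integer >= 1")
  m <- form$m; n <- form$n
  if (n == 0L) return(stats::setNames(numeric(m), form$state_labels))
  # build M_k columns right-to-left: powers of A_hat grow with T_M - k
  blocks <- vector("list", T_M)
  P1 <- diag(m)                       # A_hat^(T_M - 1 - k) factor for B2_hat
  P2 <- form$A_hat                    # A_hat^(T_M - k)    factor for B1_hat
  for (k in (T_M - 1L):0L) {
    Mk <- P1 %*% form$B2_hat
    if (k >= 1L) Mk <- Mk + P2 %*% form$B1_hat
    blocks[[k + 1L]] <- Mk
    if (k > 0L) { P1 <- form$A_hat %*% P1; P2 <- form$A_hat %*% P2 }
  }
  W <- do.call(cbind, blocks)         # m x (n * T_M)
  vals <- if (norm_model == "energy") sqrt(rowSums(W^2)) else rowSums(abs(W))
  stats::setNames(vals, form$state_labels)
}

#' Arrange reachability values on the cortical 12 x 12 grid
#'
#' Places the per-region values row-major in atlas (row) order on a 12 x 12
#' layout, masking unused cells, and optionally min-max normalizes them
#' (max -> 1, min -> 0; a constant vector maps to all 1).
#'
#' @param values numeric m-vector from [reachability_values()], m <= 144.
#' @param normalization `"minmax"` (default) or `"none"`.
#' @param horizon,norm_model metadata recorded in the result.
#' @return An object of class `reachability_landscape` with `values`
#'   (normalized), `raw_values`, `grid` (12 x 12 matrix, `NA` = masked),
#'   and metadata. `plot()` renders the heatmap.
#' @export
reachability_landscape <- function(values, normalization = c("minmax", "none"),
                                   horizon = NA_integer_,
                                   norm_model = NA_character_) {
  normalization <- match.arg(normalization)
  values <- as.numeric(values)
  m <- length(values)
  if (m > 144L) stop("m > 144 regions cannot be placed on a 12 x 12 layout")
  if (any(!is.finite(values)) || any(values < 0))
    stop("reachability values must be finite and >= 0")
  norm_values <- if (normalization == "minmax") {
    rng <- range(values)
    if (rng[1] == rng[2]) rep(1, m) else (values - rng[1]) / (rng[2] - rng[1])
  } else values
  # row-major placement in atlas order
  gt <- matrix(NA_real_, 12L, 12L)
  gt[seq_len(m)] <- norm_values
  grid <- t(gt)
  structure(list(values = norm_values, raw_values = values, grid = grid,
                 m = m, horizon = horizon, norm_model = norm_model,
                 normalization = normalization),
            class = "reachability_landscape")
}

#' Recover the value vector from a landscape grid
#'
#' Inverse of the row-major placement used by [reachability_landscape()].
#'
#' @param landscape a `reachability_landscape`.
#' @return Numeric m-vector equal to `landscape$values`.
#' @export
grid_to_values <- function(landscape) {
  stopifnot(inherits(landscape, "reachability_landscape"))
  v <- as.vector(t(landscape$grid))
  v[seq_len(landscape$m)]
}

#' @export
print.reachability_landscape <- function(x, ...) {
  cat(sprintf("Reachability landscape: %d regions on a 12 x 12 grid (%d masked)\n",
              x$m, 144L - x$m))
  if (!is.na(x$horizon))
    cat(sprintf("  horizon T_M = %d scans, input model '%s'\n", x$horizon, x$norm_model))
  invisible(x)
}

#' @export
plot.reachability_landscape <- function(x, ...) {
  g <- x$grid[rev(seq_len(12L)), , drop = FALSE]
  graphics::image(seq_len(12L), seq_len(12L), t(g), axes = FALSE,
                  col = grDevices::hcl.colors(64, "Viridis"),
                  xlab = "", ylab = "",
                  main = "Reachability landscape", ...)
  graphics::box()
  invisible(x)
}
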