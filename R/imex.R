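#' Continuous-time two-timescale system
#'
#' A linear system with slow and fast modes,
#' \deqn{\dot x(t) = F_s x(t) + G_s u(t) + (1/\epsilon)(F_f x(t) + G_f u(t)),}
#' where the small parameter \eqn{\epsilon \in (0,1)} separates the
#' timescales. Each sampling period of length `dt` is split into a slow
#' sub-interval of length `dt - tau` and a fast one of length `tau`, with
#' `(dt - tau)/tau = 1/epsilon`, i.e. `tau = dt * epsilon / (1 + epsilon)`.
#'
#' @param F_s,F_f m x m slow/fast drift matrices (1/s).
#' @param G_s,G_f m x n slow/fast input gain matrices (1/s); may have 0 columns.
#' @param epsilon timescale ratio in (0, 1).
#' @param dt sampling interval (s).
#' @return An object of class `two_timescale_system`.
#' @seealso [imex_discretize()]
#' @export
two_timescale_system <- function(F_s, G_s, F_f, G_f, epsilon, dt) {
  F_s <- as.matrix(F_s); F_f <- as.matrix(F_f)
  G_s <- as.matrix(G_s); G_f <- as.matrix(G_f)
  m <- nrow(F_s)
  if (!all(dim(F_s) == c(m, m), dim(F_f) == c(m, m)))
    stop("F_s and F_f must be square with matching size")
  if (nrow(G_s) != m || nrow(G_f) != m || ncol(G_s) != ncol(G_f))
    stop("G_s and G_f must be m x n")
  for (nm in c("F_s", "G_s", "F_f", "G_f"))
    stopifnot_finite(get(nm), nm)
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("'epsilon' must lie strictly inside (0, 1)")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  tau <- dt * epsilon / (1 + epsilon)
  structure(list(F_s = F_s, G_s = G_s, F_f = F_f, G_f = G_f,
                 epsilon = epsilon, dt = dt, tau = tau),
            class = "two_timescale_system")
}

#' @export
print.two_timescale_system <- function(x, ...) {
  cat(sprintf(
    "Two-timescale continuous system: m = %d, n = %d, dt = %g s, epsilon = %g (tau = %g s)\n",
    nrow(x$F_s), ncol(x$G_s), x$dt, x$epsilon, x$tau))
  invisible(x)
}

#' IMEX discretization of a two-timescale system
#'
#' Maps the continuous system to the discrete causal-signature blocks by an
#' implicit-explicit Euler split of each sampling period: explicit Euler over
#' the slow sub-interval `dt - tau`, implicit Euler over the fast one `tau`.
#' The unobserved mid-interval state cancels, leaving the closed form
#' \deqn{Q = \tau F_f,\quad A = I + (\Delta t-\tau) F_s,\quad
#'       B_1 = \tau G_f,\quad B_2 = (\Delta t-\tau) G_s.}
#'
#' `Q` then carries the fast, concurrent interactions and `A` the slow,
#' lagged transition; `B1` couples current inputs, `B2` lagged inputs.
#'
#' @param sys a [two_timescale_system()].
#' @return A [causal_signature] object. If `diag(F_f)` is not zero the
#'   resulting `Q` diagonal is zeroed with a warning (the discrete model
#'   constrains `Q_ii = 0`).
#' @examples
#' sys <- two_timescale_system(F_s = matrix(-1), G_s = matrix(0, 1, 0),
#'                             F_f = matrix(0), G_f = matrix(0, 1, 0),
#'                             epsilon = 0.2, dt = 0.72)
#' imex_discretize(sys)$A  # 1 + 0.6 * (-1) = 0.4
#' @export
imex_discretize <- function(sys) {
  stopifnot(inherits(sys, "two_timescale_system"))
  tau <- sys$tau; slow <- sys$dt - tau
  Q <- tau * sys$F_f
  A <- diag(nrow(sys$F_s)) + slow * sys$F_s
  B1 <- tau * sys$G_f
  B2 <- slow * sys$G_s
  if (nrow(Q) > 0 && any(diag(Q) != 0)) {
    warning("diag(F_f) is not zero; zeroing diag(Q) to satisfy the model constraint")
    diag(Q) <- 0
  }
  new_causal_signature(Q = Q, A = A, B1 = B1, B2 = B2, dt = sys$dt,
                       lambda = 0, mode = "imex", residual_norm = NA_real_)
}

#' Invert the IMEX mapping
#'
#' Recovers the continuous-time blocks from a discrete causal signature,
#' given the timescale ratio: `F_s = (A - I)/(dt - tau)`, `F_f = Q/tau`,
#' `G_s = B2/(dt - tau)`, `G_f = B1/tau`.
#'
#' @param sig a [causal_signature].
#' @param epsilon timescale ratio in (0, 1).
#' @return A [two_timescale_system()].
#' @export
imex_continuous <- function(sig, epsilon) {
  stopifnot(inherits(sig, "causal_signature"))
  dt <- sig$dt
  tau <- dt * epsilon / (1 + epsilon); slow <- dt - tau
  two_timescale_system(F_s = (sig$A - diag(nrow(sig$A))) / slow,
                       G_s = sig$B2 / slow,
                       F_f = sig$Q / tau,
                       G_f = sig$B1 / tau,
                       epsilon = epsilon, dt = dt)
}
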