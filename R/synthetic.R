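#' Specification of a synthetic multi-subject, multi-task cohort
#'
#' Describes a seeded cohort generated from known ground-truth two-timescale
#' systems, emulating a multi-subject, multi-task, multi-run fMRI design
#' (every subject-task pair recorded `runs_per_pair` times). Subjects differ
#' by perturbations of the slow interaction block `A`; tasks differ by
#' their input patterns and input-coupling blocks `B1`/`B2`; runs differ by
#' independent input realizations and noise. The fast block `Q` is shared
#' across subjects and, when `fast_noise_sd > 0`, additionally perturbed
#' independently per run.
#'
#' Defaults are a scaled-down analogue of a 100-parcel acquisition
#' (90 states + 10 inputs, repetition time 0.72 s, ~1200 scans): 20 states,
#' 5 inputs, 300 scans, preserving the real design's ratio of samples to
#' regression parameters (`T / (2m+2n)` of about 6). Signals are generated
#' on a unit scale (inputs are standard normal), so `noise_sd = 0.05` is
#' moderate (5%) process noise and `subject_spread = 0.2` reflects the
#' strong individual differences reported for functional connectomes.
#'
#' @param n_subjects,n_tasks,runs_per_pair cohort design counts, >= 1.
#' @param m,n,T,dt state/input dimensions, scans, sampling interval (s).
#' @param subject_spread s.d. scale of subject-specific perturbations of
#'   the slow block `A`.
#' @param task_spread s.d. scale of task-specific input patterns and
#'   `B1`/`B2` perturbations.
#' @param noise_sd s.d. of per-scan additive Gaussian noise on the states.
#' @param fast_noise_sd s.d. of extra noise carried by the fast channels:
#'   each run's fast blocks (`Q`, `B1`) are independently perturbed at this
#'   scale and an iid disturbance of the same scale is injected through the
#'   fast channel during simulation (before the concurrent `(I-Q)` solve).
#'   This makes fast features unreliable across runs while slow features
#'   stay stable.
#' @param stability_margin target spectral radius of `(I-Q)^{-1}A` for
#'   every generated system (each `A` is rescaled to hit it exactly).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L, n_tasks = 8L, runs_per_pair = 2L,
                        m = 20L, n = 5L, T = 300L, dt = 0.72,
                        subject_spread = 0.2, task_spread = 0.5,
                        noise_sd = 0.05, fast_noise_sd = 0,
                        stability_margin = 0.9, seed = 1L) {
  counts <- c(n_subjects = n_subjects, n_tasks = n_tasks,
              runs_per_pair = runs_per_pair, m = m, T = T)
  if (any(counts < 1L)) stop("all design counts must be >= 1")
  if (n < 0L) stop("'n' must be >= 0")
  if (any(c(subject_spread, task_spread, noise_sd, fast_noise_sd) < 0))
    stop("spreads and noise levels must be >= 0")
  if (stability_margin <= 0 || stability_margin >= 1)
    stop("'stability_margin' must lie in (0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_tasks = as.integer(n_tasks),
                 runs_per_pair = as.integer(runs_per_pair),
                 m = as.integer(m), n = as.integer(n), T = as.integer(T),
                 dt = dt, subject_spread = subject_spread,
                 task_spread = task_spread, noise_sd = noise_sd,
                 fast_noise_sd = fast_noise_sd,
                 stability_margin = stability_margin,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d subjects x %d tasks x %d runs, m = %d, n = %d, T = %d\n",
              x$n_subjects, x$n_tasks, x$runs_per_pair, x$m, x$n, x$T))
  cat(sprintf("  spreads: subject %.3g, task %.3g; noise %.3g (fast extra %.3g); seed %d\n",
              x$subject_spread, x$task_spread, x$noise_sd, x$fast_noise_sd, x$seed))
  invisible(x)
}

rmat <- function(r, c, sd = 1) matrix(stats::rnorm(r * c, sd = sd), r, c)

#' Generate a labeled synthetic cohort with ground truth
#'
#' Draws one base system, derives subject systems by perturbing `A` and `Q`,
#' task variants by perturbing `B1`/`B2` and the input mean pattern, and
#' simulates every subject-task-run recording with independent noise. Every
#' generated state-evolution matrix `(I-Q)^{-1}A` is rescaled to spectral
#' radius exactly `stability_margin`. Fully reproducible under the spec's
#' seed; ground-truth signatures are returned for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `runs` (each: `ts`, `subject`, `task`, `run`,
#'   `truth` the generating [causal_signature]), `partition` (states first,
#'   then inputs), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- spec$m; n <- spec$n; Tn <- spec$T
  part <- partition_spec(state_idx = seq_len(m),
                         input_idx = if (n > 0) m + seq_len(n) else integer(0))
  labs <- c(sprintf("S%03d", seq_len(m)),
            if (n > 0) sprintf("U%03d", seq_len(n)) else character(0))
  with_seed(spec$seed, {
    Q_base <- rmat(m, m, sd = 0.3 / sqrt(m)); diag(Q_base) <- 0
    A_base <- rmat(m, m, sd = 1 / sqrt(m))
    B1_base <- rmat(m, max(n, 1L), sd = 0.5)[, seq_len(n), drop = FALSE]
    B2_base <- rmat(m, max(n, 1L), sd = 0.5)[, seq_len(n), drop = FALSE]
    # subject identity lives in the slow block A; the fast block Q is
    # population-shared (run-level fast noise is added below), emulating
    # the regime where fast concurrent interactions carry no reliable
    # subject signature at the fMRI sampling rate
    subjects <- lapply(seq_len(spec$n_subjects), function(s) {
      As <- A_base + spec$subject_spread * rmat(m, m, sd = 1 / sqrt(m))
      list(Q = Q_base, A = As)
    })
    tasks <- lapply(seq_len(spec$n_tasks), function(h) {
      list(B1 = B1_base + spec$task_spread * rmat(m, max(n, 1L), 1)[, seq_len(n), drop = FALSE],
           B2 = B2_base + spec$task_spread * rmat(m, max(n, 1L), 1)[, seq_len(n), drop = FALSE],
           mu = if (n > 0) spec$task_spread * stats::rnorm(n) else numeric(0))
    })
    runs <- list(); r <- 0L
    for (s in seq_len(spec$n_subjects)) for (h in seq_len(spec$n_tasks))
      for (rep in seq_len(spec$runs_per_pair)) {
        Qr <- subjects[[s]]$Q
        B1r <- tasks[[h]]$B1
        if (spec$fast_noise_sd > 0) {
          Qr <- Qr + spec$fast_noise_sd * rmat(m, m, sd = 1 / sqrt(m))
          diag(Qr) <- 0
          B1r <- B1r + spec$fast_noise_sd *
            rmat(m, max(n, 1L), 1)[, seq_len(n), drop = FALSE]
        }
        # rescale A so the state-evolution spectral radius is the margin
        Ahat <- solve(diag(m) - Qr, subjects[[s]]$A)
        rho <- spectral_radius(Ahat)
        Ar <- subjects[[s]]$A * (spec$stability_margin / rho)
        truth <- new_causal_signature(Qr, Ar, B1r, tasks[[h]]$B2,
                                      dt = spec$dt, lambda = 0,
                                      mode = "truth", residual_norm = 0,
                                      partition = part,
                                      state_labels = labs[seq_len(m)],
                                      input_labels = labs[m + seq_len(n)])
        U <- if (n > 0) tasks[[h]]$mu + rmat(n, Tn + 1L) else matrix(0, 0, Tn + 1L)
        x0 <- stats::rnorm(m)
        ts <- simulate(truth, U = U, x0 = x0, noise_sd = spec$noise_sd,
                       fast_noise_sd = spec$fast_noise_sd)
        r <- r + 1L
        runs[[r]] <- list(ts = ts, subject = sprintf("sub%03d", s),
                          task = h - 1L, run = rep, truth = truth)
      }
    list(runs = runs, partition = part, spec = spec)
  })
}

#' Generate stratified train/test sets of signature graphs
#'
#' Runs the identification stage on every recording of a generated cohort,
#' converts the fitted signatures to [signature_graph()]s labeled by task,
#' and splits them evenly (50/50) per task, mirroring an even train/test
#' protocol. Split sizes per class differ by at most 1.
#'
#' @param spec a [cohort_spec()].
#' @param lambda regularization weight for the identification stage.
#' @param mode objective variant passed to [fit_causal_signature()].
#' @return A list with `train` and `test` (lists of `signature_graph`),
#'   and `labels` (0-based task ids present).
#' @export
generate_task_ensemble <- function(spec, lambda = 1e-6, mode = "ridge") {
  coh <- generate_cohort(spec)
  graphs <- lapply(coh$runs, function(run) {
    sig <- fit_causal_signature(run$ts, coh$partition, lambda = lambda,
                                mode = mode, keep_data = FALSE)
    signature_graph(sig, label = run$task)
  })
  task_of <- vapply(coh$runs, function(run) run$task, integer(1))
  train_ix <- integer(0)
  # deterministic stratified even split, interleaving within each class
  for (h in sort(unique(task_of))) {
    ix <- which(task_of == h)
    train_ix <- c(train_ix, ix[seq_along(ix) %% 2L == 1L])
  }
  test_ix <- setdiff(seq_along(graphs), train_ix)
  list(train = graphs[train_ix], test = graphs[test_ix],
       labels = sort(unique(task_of)))
}
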