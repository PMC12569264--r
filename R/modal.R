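# Eigendecomposition with real canonicalization of the mode vectors.
#
# For a real matrix M = T Lambda T^{-1}, complex conjugate eigenpairs are
# replaced by the real pair (Re v, Im v) of the member with positive
# imaginary eigenvalue, so the feature set stays real and cosine distances
# are well defined. Every vector is canonicalized: unit norm, entry of
# largest magnitude made positive (ties broken by lowest index).
decompose_real_modes <- function(M, kappa_max = 1e10) {
  m <- nrow(M)
  ed <- eigen(M)
  V <- ed$vectors; lam <- ed$values
  kap <- tryCatch(cond2(V), error = function(e) Inf)
  recon <- tryCatch(
    Mod(frob_c(V %*% diag(lam, m) %*% solve(V) - M)) / max(frob(M), .Machine$double.eps),
    error = function(e) Inf)
  if (!is.finite(kap) || kap >= kappa_max) {
    # near-defective: fall back to orthogonal (real Schur) vectors
    warning("eigenvector matrix is ill-conditioned (near-defective); using real Schur vectors")
    sc <- Matrix::Schur(M)
    V <- as.matrix(sc$Q)
    lam <- eigen(M, only.values = TRUE)$values
    cols <- V
  } else {
    tol <- 1e-9 * max(1, max(Mod(lam)))
    used <- rep(FALSE, m)
    cols <- matrix(0, m, m)
    jout <- 0L
    for (i in seq_len(m)) {
      if (used[i]) next
      if (abs(Im(lam[i])) <= tol) {
        used[i] <- TRUE
        jout <- jout + 1L
        cols[, jout] <- Re(V[, i])
      } else {
        # pick the member with Im > 0; locate and consume its conjugate
        cand <- which(!used & abs(Re(lam) - Re(lam[i])) <= tol + 1e-12 &
                        abs(Im(lam) + Im(lam[i])) <= tol + 1e-12)
        cand <- setdiff(cand, i)
        if (length(cand) == 0L) stop("unpaired complex eigenvalue; matrix is not real?")
        j <- cand[1L]
        used[i] <- TRUE; used[j] <- TRUE
        vi <- if (Im(lam[i]) > 0) V[, i] else V[, j]
        jout <- jout + 1L; cols[, jout] <- Re(vi)
        jout <- jout + 1L; cols[, jout] <- Im(vi)
      }
    }
  }
  list(vectors = canonicalize_columns(cols), values = lam,
       recon_error = recon, kappa = kap)
}

frob_c <- function(M) sqrt(sum(Mod(M)^2))

canonicalize_columns <- function(X) {
  for (j in seq_len(ncol(X))) {
    nrm <- sqrt(sum(X[, j]^2))
    if (nrm > 0) X[, j] <- X[, j] / nrm
    k <- which.max(abs(X[, j]))          # ties: lowest index wins
    if (X[k, j] < 0) X[, j] <- -X[, j]
  }
  X
}

#' Dynamic-mode features of a causal signature
#'
#' Diagonalizes the slow block `A = T Lambda T^{-1}` (and, for the full
#' feature set, the fast block `Q`) and returns the canonicalized mode
#' vectors used as one-shot subject features. Each state then evolves
#' independently along its mode, so the mode vectors form a basis of
#' invariant directions of the dynamics. Complex conjugate eigenpairs are
#' converted to real (Re, Im) pairs; each vector is scaled to unit norm with
#' its largest-magnitude entry positive, removing the sign/phase ambiguity
#' of eigenvectors before cosine comparison.
#'
#' @param sig a [causal_signature].
#' @param feature_mode `"slow"` (modes of `A` only; the default and the
#'   best-performing configuration), `"full"` (modes of `A` and `Q`), or
#'   `"single"` (modes of the `A` matrix of a one-timescale refit with
#'   `Q = 0`, `B1 = 0`; requires the signature to carry its training data).
#' @return An object of class `modal_features` with components `T_slow`,
#'   `T_fast` (full mode only), `eig_slow`, `eig_fast`, `features` (the
#'   m x m or m x 2m matrix entering the distance), `feature_mode`, `m`.
#'   The eigenvalues are retained for inspection but deliberately do not
#'   enter the fingerprinting distance: all modes are treated as equally
#'   informative.
#' @export
modal_features <- function(sig, feature_mode = c("slow", "full", "single")) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(inherits(sig, "causal_signature"))
  T_fast <- NULL; eig_fast <- NULL
  if (feature_mode == "single") {
    if (identical(sig$timescales, "one")) {
      dec <- decompose_real_modes(sig$A)
    } else {
      if (is.null(sig$data))
        stop("feature_mode = 'single' needs the training data; refit with keep_data = TRUE")
      refit <- fit_causal_signature(sig$data, sig$partition, lambda = sig$lambda,
                                    mode = "ridge", timescales = "one",
                                    keep_data = FALSE)
      dec <- decompose_real_modes(refit$A)
    }
    T_slow <- dec$vectors; eig_slow <- dec$values; recon <- dec$recon_error
  } else {
    dec <- decompose_real_modes(sig$A)
    T_slow <- dec$vectors; eig_slow <- dec$values; recon <- dec$recon_error
    if (feature_mode == "full") {
      decq <- decompose_real_modes(sig$Q)
      T_fast <- decq$vectors; eig_fast <- decq$values
      recon <- max(recon, decq$recon_error)
    }
  }
  feats <- if (feature_mode == "full") cbind(T_slow, T_fast) else T_slow
  structure(list(T_slow = T_slow, T_fast = T_fast,
                 eig_slow = eig_slow, eig_fast = eig_fast,
                 features = feats, feature_mode = feature_mode,
                 m = sig$m, recon_error = recon),
            class = "modal_features")
}

#' @export
print.modal_features <- function(x, ...) {
  cat(sprintf("Modal feature set: mode = %s, %d x %d feature matrix\n",
              x$feature_mode, nrow(x$features), ncol(x$features)))
  invisible(x)
}

# Hungarian algorithm (O(n^3), potentials formulation) for the square
# minimum-cost assignment problem. Returns the column assigned to each row
# and the optimal total cost.
lap_min <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 1L) return(list(assignment = 1L, cost = cost[1, 1]))
  u <- numeric(n + 1L); v <- numeric(n + 1L)      # potentials (index = id + 1)
  p <- integer(n + 1L); way <- integer(n + 1L)    # p[j+1]: row matched to col j
  for (i in seq_len(n)) {
    p[1L] <- i; j0 <- 0L
    minv <- rep(Inf, n); used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[2:(n + 1L)])
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      jbest <- free[which.min(minv[free])]
      delta <- minv[jbest]
      uc <- which(used)                           # used column ids + 1
      u[p[uc] + 1L] <- u[p[uc] + 1L] + delta
      v[uc] <- v[uc] - delta
      minv[free] <- minv[free] - delta
      j0 <- jbest
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

#' Permutation-aligned cosine distance between modal feature sets
#'
#' Compares two unordered sets of mode vectors by the minimum over all
#' pairings of summed cosine distances,
#' \deqn{Dist(X, Y) = \min_\pi \sum_i (1 - \cos(x_i, y_{\pi(i)})),}
#' solved exactly as a linear assignment problem. Because the vectors are
#' canonicalized (unit norm, dominant entry positive), the distance is
#' invariant to column permutation and sign flips, symmetric, non-negative,
#' and zero iff the two column sets coincide up to those symmetries.
#'
#' @param a,b [modal_features()] objects with equal `m` and `feature_mode`.
#' @return A non-negative scalar.
#' @export
modal_distance <- function(a, b) {
  stopifnot(inherits(a, "modal_features"), inherits(b, "modal_features"))
  if (a$m != b$m || !identical(dim(a$features), dim(b$features)))
    stop("feature sets have mismatched dimensions")
  if (!identical(a$feature_mode, b$feature_mode))
    stop("feature sets have different feature_mode")
  X <- a$features; Y <- b$features
  # columns are unit-norm, so cosine similarity is the plain inner product;
  # clamp at zero against rounding on identical sets
  max(0, lap_min(1 - crossprod(X, Y))$cost)
}

#' Labeled reference library of modal feature sets
#'
#' One entry per subject, all extracted under the same task condition.
#'
#' @param entries named list of [modal_features()] (names = subject labels).
#' @param task_label condition the entries were recorded under.
#' @return An object of class `reference_library`.
#' @export
reference_library <- function(entries, task_label = "") {
  if (length(entries) == 0L) stop("empty reference library")
  if (is.null(names(entries)) || anyDuplicated(names(entries)) ||
      any(names(entries) == ""))
    stop("entries must be uniquely named by subject label")
  m0 <- entries[[1L]]$m; fm <- entries[[1L]]$feature_mode
  ok <- vapply(entries, function(e)
    inherits(e, "modal_features") && e$m == m0 && identical(e$feature_mode, fm),
    logical(1))
  if (!all(ok)) stop("all entries must share m and feature_mode")
  structure(list(entries = entries, task_label = task_label),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("Reference library: %d subjects (task '%s', feature mode %s)\n",
              length(x$entries), x$task_label, x$entries[[1]]$feature_mode))
  invisible(x)
}

#' One-shot subject identification against a reference library
#'
#' Returns the subject whose stored feature set minimizes the
#' permutation-aligned cosine distance to the query. Ties are broken by the
#' lexicographically smallest subject label, making the result
#' deterministic.
#'
#' @param query a [modal_features()] set of unknown identity.
#' @param lib a [reference_library()].
#' @return A list with `label` (predicted subject), `distance`, and
#'   `ranking` (data frame of all subjects ordered by distance).
#' @export
identify_subject <- function(query, lib) {
  stopifnot(inherits(lib, "reference_library"))
  labs <- names(lib$entries)
  d <- vapply(lib$entries, function(e) modal_distance(query, e), numeric(1))
  ord <- order(d, labs)                         # lexicographic tie-break
  ranking <- data.frame(label = labs[ord], distance = unname(d[ord]),
                        stringsAsFactors = FALSE)
  list(label = ranking$label[1L], distance = ranking$distance[1L],
       ranking = ranking)
}

#' Cross-condition subject identification accuracy
#'
#' Evaluates one-shot identification with disjoint reference and query sets:
#' each condition (run) is taken in turn as the reference database while all
#' other conditions serve as queries, mirroring the four-fold resting-scan
#' protocol used in fMRI fingerprinting studies.
#'
#' @param features list of [modal_features()] sets.
#' @param subject character vector of subject labels, one per feature set.
#' @param condition character vector of condition/run labels, one per set.
#' @return A list with `per_fold` (data frame: reference condition, number
#'   of queries, top-1 accuracy) and `mean_accuracy`.
#' @export
evaluate_subject_accuracy <- function(features, subject, condition) {
  stopifnot(length(features) == length(subject),
            length(subject) == length(condition))
  subject <- as.character(subject); condition <- as.character(condition)
  conds <- sort(unique(condition))
  if (length(conds) < 2L) stop("need at least 2 conditions/runs per subject")
  folds <- lapply(conds, function(rc) {
    ref_ix <- which(condition == rc)
    if (anyDuplicated(subject[ref_ix]))
      stop("duplicate subject in reference condition ", rc)
    miss <- setdiff(unique(subject), subject[ref_ix])
    if (length(miss) > 0L)
      stop("subject(s) missing from reference condition ", rc, ": ",
           paste(miss, collapse = ", "))
    lib <- reference_library(stats::setNames(features[ref_ix], subject[ref_ix]),
                             task_label = rc)
    qry_ix <- which(condition != rc)
    hits <- vapply(qry_ix, function(i)
      identify_subject(features[[i]], lib)$label == subject[i], logical(1))
    data.frame(reference = rc, n_queries = length(qry_ix),
               accuracy = mean(hits), stringsAsFactors = FALSE)
  })
  per_fold <- do.call(rbind, folds)
  list(per_fold = per_fold, mean_accuracy = mean(per_fold$accuracy))
}
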