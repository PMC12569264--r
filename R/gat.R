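#' Configuration of the graph attention task classifier
#'
#' Hyperparameters of the five-layer network used for task fingerprinting:
#' a GATv2 attention block (4 heads, 32 output features each) summed with a
#' parallel linear skip path (128 channels), top-k node pooling (ratio 0.8),
#' a second GATv2 block (2 heads, 32 features) with its own skip path
#' (64 channels), global mean pooling, and a linear log-softmax head.
#'
#' @param heads1,out1,skip1 first attention block: heads, per-head output
#'   width, skip width (must satisfy `heads1 * out1 == skip1`).
#' @param pool_ratio top-k pooling keep ratio in (0, 1]; `ceil(ratio * m)`
#'   nodes survive.
#' @param heads2,out2,skip2 second attention block (`heads2 * out2 == skip2`).
#' @param attn_dropout dropout probability on attention coefficients
#'   (training only).
#' @param edge_dropout fraction of edges dropped independently each epoch
#'   (training only; surviving edge weights are not rescaled).
#' @param classes number of task classes C.
#' @param epochs,learning_rate,batch_size,patience training schedule: Adam
#'   with the given learning rate, minibatch gradient accumulation, early
#'   stopping on validation loss with the given patience (set
#'   `patience = Inf` to disable).
#' @param use_edge_attr whether attention consumes the edge weight as a
#'   scalar edge feature.
#' @param seed integer seed controlling initialization and dropout.
#' @return An object of class `task_classifier_config`.
#' @export
task_classifier_config <- function(heads1 = 4L, out1 = 32L, skip1 = 128L,
                                   pool_ratio = 0.8, heads2 = 2L, out2 = 32L,
                                   skip2 = 64L, attn_dropout = 0.30,
                                   edge_dropout = 0.10, classes = 8L,
                                   epochs = 200L, learning_rate = 1e-3,
                                   batch_size = 32L, patience = 20,
                                   use_edge_attr = TRUE, seed = 1L) {
  if (heads1 * out1 != skip1) stop("need heads1 * out1 == skip1")
  if (heads2 * out2 != skip2) stop("need heads2 * out2 == skip2")
  if (pool_ratio <= 0 || pool_ratio > 1) stop("'pool_ratio' must be in (0, 1]")
  if (attn_dropout < 0 || attn_dropout >= 1 || edge_dropout < 0 || edge_dropout >= 1)
    stop("dropout probabilities must be in [0, 1)")
  if (classes < 2L) stop("need at least 2 classes")
  structure(list(heads1 = as.integer(heads1), out1 = as.integer(out1),
                 skip1 = as.integer(skip1), pool_ratio = pool_ratio,
                 heads2 = as.integer(heads2), out2 = as.integer(out2),
                 skip2 = as.integer(skip2), attn_dropout = attn_dropout,
                 edge_dropout = edge_dropout, classes = as.integer(classes),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), patience = patience,
                 use_edge_attr = isTRUE(use_edge_attr),
                 seed = as.integer(seed)),
            class = "task_classifier_config")
}

glorot <- function(r, c) {
  s <- sqrt(6 / (r + c))
  matrix(stats::runif(r * c, -s, s), r, c)
}

# Parameter list of the network (flat, named, for the Adam loop).
init_gat_params <- function(cfg, in_dim) {
  par <- list()
  for (h in seq_len(cfg$heads1)) {
    par[[paste0("l1_Ws_", h)]] <- glorot(in_dim, cfg$out1)
    par[[paste0("l1_Wt_", h)]] <- glorot(in_dim, cfg$out1)
    par[[paste0("l1_a_", h)]] <- glorot(cfg$out1, 1)[, 1]
    par[[paste0("l1_We_", h)]] <- glorot(1, cfg$out1)[1, ]
  }
  par$l1_b <- numeric(cfg$skip1)
  par$sk1_W <- glorot(in_dim, cfg$skip1); par$sk1_b <- numeric(cfg$skip1)
  par$pool_p <- glorot(cfg$skip1, 1)[, 1]
  for (h in seq_len(cfg$heads2)) {
    par[[paste0("l2_Ws_", h)]] <- glorot(cfg$skip1, cfg$out2)
    par[[paste0("l2_Wt_", h)]] <- glorot(cfg$skip1, cfg$out2)
    par[[paste0("l2_a_", h)]] <- glorot(cfg$out2, 1)[, 1]
    par[[paste0("l2_We_", h)]] <- glorot(1, cfg$out2)[1, ]
  }
  par$l2_b <- numeric(cfg$skip2)
  par$sk2_W <- glorot(cfg$skip1, cfg$skip2); par$sk2_b <- numeric(cfg$skip2)
  par$out_W <- glorot(cfg$skip2, cfg$classes); par$out_b <- numeric(cfg$classes)
  par
}

# scatter rowsum() results back onto all N rows (missing groups -> 0)
rs_full <- function(M, group, N) {
  R <- matrix(0, N, ncol(M))
  rs <- rowsum(M, group)
  R[as.integer(rownames(rs)), ] <- rs
  R
}

leaky <- function(x, s = 0.2) ifelse(x > 0, x, s * x)
dleaky <- function(x, s = 0.2) ifelse(x > 0, 1, s)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
delu <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

# GATv2 attention block, one head. Scores follow the GATv2 form
# a' leakyReLU(W_s x_dst + W_t x_src + W_e w_edge), softmax over incoming
# edges per target node, messages are the attended source transforms.
gat_head_fwd <- function(X, src, dst, ew, Ws, Wt, a, We, training, pdrop) {
  N <- nrow(X)
  S <- X %*% Ws; Tt <- X %*% Wt
  U <- S[dst, , drop = FALSE] + Tt[src, , drop = FALSE] + outer(ew, We)
  L <- leaky(U)
  sc <- as.vector(L %*% a)
  mx <- rep(-Inf, N)
  mxg <- tapply(sc, dst, max)
  mx[as.integer(names(mxg))] <- mxg
  ex <- exp(sc - mx[dst])
  den <- rs_full(matrix(ex, ncol = 1), dst, N)[, 1]
  alpha <- ex / den[dst]
  mask <- NULL
  alpha_t <- alpha
  if (training && pdrop > 0) {
    mask <- stats::rbinom(length(alpha), 1L, 1 - pdrop)
    alpha_t <- alpha * mask / (1 - pdrop)
  }
  msg <- alpha_t * Tt[src, , drop = FALSE]
  Out <- rs_full(msg, dst, N)
  list(Out = Out, cache = list(X = X, src = src, dst = dst, ew = ew,
                               S = S, Tt = Tt, U = U, L = L, alpha = alpha,
                               alpha_t = alpha_t, mask = mask, pdrop = pdrop,
                               Ws = Ws, Wt = Wt, a = a, We = We))
}

gat_head_bwd <- function(dOut, cache) {
  with(cache, {
    N <- nrow(X); Fo <- ncol(S)
    dmsg <- dOut[dst, , drop = FALSE]
    dalpha_t <- rowSums(dmsg * Tt[src, , drop = FALSE])
    dTt_edge1 <- alpha_t * dmsg                       # to be scattered at src
    dalpha <- if (!is.null(mask)) dalpha_t * mask / (1 - pdrop) else dalpha_t
    g <- rs_full(matrix(alpha * dalpha, ncol = 1), dst, N)[, 1]
    dsc <- alpha * (dalpha - g[dst])
    dL <- outer(dsc, a)
    da <- as.vector(crossprod(L, dsc))
    dU <- dL * dleaky(U)
    dS_edge <- dU
    dTt_edge <- dU
    dWe <- as.vector(crossprod(dU, ew))
    dS <- rs_full(dS_edge, dst, N)
    dTt <- rs_full(dTt_edge1, src, N) + rs_full(dTt_edge, src, N)
    dWs <- crossprod(X, dS)
    dWt <- crossprod(X, dTt)
    dX <- dS %*% t(Ws) + dTt %*% t(Wt)
    list(dX = dX, dWs = dWs, dWt = dWt, da = da, dWe = dWe)
  })
}

gat_block_fwd <- function(X, src, dst, ew, par, prefix, H, training, pdrop) {
  heads <- vector("list", H)
  outs <- vector("list", H)
  for (h in seq_len(H)) {
    hf <- gat_head_fwd(X, src, dst, ew,
                       par[[paste0(prefix, "_Ws_", h)]],
                       par[[paste0(prefix, "_Wt_", h)]],
                       par[[paste0(prefix, "_a_", h)]],
                       par[[paste0(prefix, "_We_", h)]],
                       training, pdrop)
    heads[[h]] <- hf$cache
    outs[[h]] <- hf$Out
  }
  Z <- do.call(cbind, outs)
  Z <- sweep(Z, 2L, par[[paste0(prefix, "_b")]], "+")
  list(Z = Z, heads = heads)
}

gat_block_bwd <- function(dZ, heads, par, prefix, grad) {
  H <- length(heads); Fo <- ncol(heads[[1]]$S)
  dX <- 0
  grad[[paste0(prefix, "_b")]] <- grad[[paste0(prefix, "_b")]] %||%
    numeric(ncol(dZ))
  grad[[paste0(prefix, "_b")]] <- grad[[paste0(prefix, "_b")]] + colSums(dZ)
  for (h in seq_len(H)) {
    dOut <- dZ[, (h - 1L) * Fo + seq_len(Fo), drop = FALSE]
    bw <- gat_head_bwd(dOut, heads[[h]])
    dX <- dX + bw$dX
    for (nm in c("Ws", "Wt", "a", "We")) {
      key <- paste0(prefix, "_", nm, "_", h)
      g <- switch(nm, Ws = bw$dWs, Wt = bw$dWt, a = bw$da, We = bw$dWe)
      grad[[key]] <- if (is.null(grad[[key]])) g else grad[[key]] + g
    }
  }
  list(dX = dX, grad = grad)
}

# add self loops; their edge weight is the mean of existing weights (1 if none)
add_self_loops <- function(src, dst, ew, N) {
  fill <- if (length(ew) > 0) mean(ew) else 1
  list(src = c(src, seq_len(N)), dst = c(dst, seq_len(N)),
       ew = c(ew, rep(fill, N)))
}

# Full network forward pass on one graph. Returns log-probabilities and,
# if requested, the cache needed for backpropagation.
net_forward <- function(par, cfg, X, src, dst, ew, training = FALSE,
                        want_cache = FALSE) {
  N <- nrow(X)
  if (!cfg$use_edge_attr) ew <- rep(0, length(ew))
  sl <- add_self_loops(src, dst, ew, N)
  b1 <- gat_block_fwd(X, sl$src, sl$dst, sl$ew, par, "l1", cfg$heads1,
                      training, cfg$attn_dropout)
  Sk1 <- sweep(X %*% par$sk1_W, 2L, par$sk1_b, "+")
  H1pre <- b1$Z + Sk1
  H1 <- elu(H1pre)
  # top-k pooling on the learned score vector
  pr <- sqrt(sum(par$pool_p^2)); phat <- par$pool_p / pr
  s <- as.vector(H1 %*% phat)
  k <- ceiling(cfg$pool_ratio * N)
  idx <- sort(order(s, decreasing = TRUE)[seq_len(k)])
  th <- tanh(s[idx])
  X2 <- H1[idx, , drop = FALSE] * th
  keep_e <- which(sl$src %in% idx & sl$dst %in% idx)
  remap <- integer(N); remap[idx] <- seq_len(k)
  src2 <- remap[sl$src[keep_e]]; dst2 <- remap[sl$dst[keep_e]]
  ew2 <- sl$ew[keep_e]
  b2 <- gat_block_fwd(X2, src2, dst2, ew2, par, "l2", cfg$heads2,
                      training, cfg$attn_dropout)
  Sk2 <- sweep(X2 %*% par$sk2_W, 2L, par$sk2_b, "+")
  H2pre <- b2$Z + Sk2
  H2 <- elu(H2pre)
  z <- colMeans(H2)
  logits <- as.vector(z %*% par$out_W) + par$out_b
  lse <- max(logits) + log(sum(exp(logits - max(logits))))
  logp <- logits - lse
  out <- list(logp = logp, n_pooled = k)
  if (want_cache)
    out$cache <- list(X = X, sl = sl, b1 = b1, H1pre = H1pre, H1 = H1,
                      s = s, idx = idx, th = th, X2 = X2, phat = phat,
                      pr = pr, src2 = src2, dst2 = dst2, b2 = b2,
                      H2pre = H2pre, H2 = H2, z = z, logp = logp, N = N,
                      k = k)
  out
}

# Backward pass for the negative log-likelihood of the true class.
net_backward <- function(par, cfg, cache, y) {
  grad <- list()
  with(cache, {
    probs <- exp(logp)
    dlogits <- probs
    dlogits[y + 1L] <- dlogits[y + 1L] - 1
    grad$out_W <- outer(z, dlogits)
    grad$out_b <- dlogits
    dz <- as.vector(par$out_W %*% dlogits)
    dH2 <- matrix(dz, k, length(dz), byrow = TRUE) / k
    dH2pre <- dH2 * delu(H2pre)
    grad$sk2_W <- crossprod(X2, dH2pre)
    grad$sk2_b <- colSums(dH2pre)
    dX2 <- dH2pre %*% t(par$sk2_W)
    bb2 <- gat_block_bwd(dH2pre, b2$heads, par, "l2", grad)
    grad <- bb2$grad
    dX2 <- dX2 + bb2$dX
    # through top-k gating
    dH1 <- matrix(0, N, ncol(H1))
    dH1[idx, ] <- dX2 * th
    dsi <- rowSums(dX2 * H1[idx, , drop = FALSE]) * (1 - th^2)
    dH1[idx, ] <- dH1[idx, ] + outer(dsi, phat)
    grad$pool_p <- as.vector(
      crossprod(H1[idx, , drop = FALSE], dsi) - sum(dsi * s[idx]) * phat) / pr
    dH1pre <- dH1 * delu(H1pre)
    grad$sk1_W <- crossprod(X, dH1pre)
    grad$sk1_b <- colSums(dH1pre)
    bb1 <- gat_block_bwd(dH1pre, b1$heads, par, "l1", grad)
    grad <- bb1$grad
    grad
  })
}

#' Initialize a task classifier
#'
#' Builds the five-layer graph attention network with deterministic
#' parameter initialization under `cfg$seed`. The forward pass maps a
#' [signature_graph()] to `classes` log-probabilities.
#'
#' @param cfg a [task_classifier_config()].
#' @param in_dim node feature dimension (2m + 2n for a signature graph).
#' @return An object of class `task_classifier` (untrained).
#' @export
init_task_classifier <- function(cfg, in_dim) {
  stopifnot(inherits(cfg, "task_classifier_config"))
  in_dim <- as.integer(in_dim)
  if (in_dim < 1L) stop("'in_dim' must be >= 1")
  par <- with_seed(cfg$seed, init_gat_params(cfg, in_dim))
  structure(list(cfg = cfg, in_dim = in_dim, params = par,
                 trained = FALSE, history = NULL),
            class = "task_classifier")
}

#' @export
print.task_classifier <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("Graph attention task classifier (%strained)\n",
              if (x$trained) "" else "un"))
  cat(sprintf("  GATv2(%d -> %dx%d) + skip %d | top-k pool %.2f | GATv2(%d -> %dx%d) + skip %d | mean pool | linear %d x %d\n",
              x$in_dim, cfg$heads1, cfg$out1, cfg$skip1, cfg$pool_ratio,
              cfg$skip1, cfg$heads2, cfg$out2, cfg$skip2, cfg$skip2, cfg$classes))
  invisible(x)
}

graph_tensors <- function(g) {
  list(X = g$node_features, src = g$edge_index[1L, ], dst = g$edge_index[2L, ],
       ew = g$edge_weight)
}

#' Train the task classifier
#'
#' Minimizes the negative log-likelihood with Adam, accumulating gradients
#' over minibatches. Each epoch independently drops `edge_dropout` of every
#' graph's edges (surviving weights are not rescaled) and applies
#' `attn_dropout` to the attention coefficients; both are inactive at
#' inference. Early stopping monitors validation loss (a stratified 20%
#' carve-out of the training set if no validation set is supplied) with the
#' configured patience, restoring the best parameters. Training is a
#' deterministic function of `cfg$seed` and the data.
#'
#' @param classifier an [init_task_classifier()] object (or a
#'   [task_classifier_config()], in which case the classifier is
#'   initialized from the first graph's feature width).
#' @param graphs list of [signature_graph()]s (>= 2 classes present).
#' @param validation optional list of graphs monitored for early stopping.
#' @return The trained `task_classifier`, with a `history` data frame
#'   (epoch, training loss, training accuracy, validation loss).
#' @export
fit_task_classifier <- function(classifier, graphs, validation = NULL) {
  if (inherits(classifier, "task_classifier_config"))
    classifier <- init_task_classifier(classifier,
                                       ncol(graphs[[1L]]$node_features))
  stopifnot(inherits(classifier, "task_classifier"))
  cfg <- classifier$cfg
  ys <- vapply(graphs, function(g) g$label, integer(1))
  if (length(unique(ys)) < 2L)
    stop("training set contains a single class; need >= 2 classes")
  if (any(ys >= cfg$classes)) stop("task label out of range 0..classes-1")
  if (ncol(graphs[[1L]]$node_features) != classifier$in_dim)
    stop("graph feature width does not match classifier input width")

  with_seed(cfg$seed, {
    par <- init_gat_params(cfg, classifier$in_dim)
    if (is.null(validation) && is.finite(cfg$patience)) {
      # stratified 20% carve-out for early stopping
      val_ix <- integer(0)
      for (h in unique(ys)) {
        ix <- which(ys == h)
        val_ix <- c(val_ix, ix[seq_along(ix) %% 5L == 0L])
      }
      if (length(val_ix) > 0L) {
        validation <- graphs[val_ix]
        graphs <- graphs[-val_ix]
        ys <- ys[-val_ix]
      }
    }
    gts <- lapply(graphs, graph_tensors)
    vts <- if (!is.null(validation)) lapply(validation, graph_tensors) else NULL
    vys <- if (!is.null(validation))
      vapply(validation, function(g) g$label, integer(1)) else NULL

    mstate <- lapply(par, function(x) x * 0)
    vstate <- lapply(par, function(x) x * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
    best_par <- par; best_val <- Inf; wait <- 0
    hist <- vector("list", cfg$epochs)
    ng <- length(gts)
    for (ep in seq_len(cfg$epochs)) {
      # per-epoch edge dropout, resampled independently per graph
      dropped <- lapply(gts, function(gt) {
        if (cfg$edge_dropout > 0 && length(gt$src) > 0L) {
          keep <- stats::runif(length(gt$src)) >= cfg$edge_dropout
          list(X = gt$X, src = gt$src[keep], dst = gt$dst[keep],
               ew = gt$ew[keep])
        } else gt
      })
      ord <- sample.int(ng)
      ep_loss <- 0; ep_hits <- 0L
      bstart <- seq(1L, ng, by = cfg$batch_size)
      for (bs in bstart) {
        bix <- ord[bs:min(bs + cfg$batch_size - 1L, ng)]
        gacc <- NULL
        for (i in bix) {
          gt <- dropped[[i]]
          fw <- net_forward(par, cfg, gt$X, gt$src, gt$dst, gt$ew,
                            training = TRUE, want_cache = TRUE)
          y <- ys[i]
          ep_loss <- ep_loss - fw$logp[y + 1L]
          ep_hits <- ep_hits + as.integer(which.max(fw$logp) == y + 1L)
          gr <- net_backward(par, cfg, fw$cache, y)
          if (is.null(gacc)) gacc <- gr
          else for (nm in names(gr)) gacc[[nm]] <- gacc[[nm]] + gr[[nm]]
        }
        step <- step + 1L
        sc <- 1 / length(bix)
        for (nm in names(par)) {
          g <- gacc[[nm]] * sc
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
          mh <- mstate[[nm]] / (1 - beta1^step)
          vh <- vstate[[nm]] / (1 - beta2^step)
          par[[nm]] <- par[[nm]] - cfg$learning_rate * mh / (sqrt(vh) + eps)
        }
      }
      val_loss <- NA_real_
      if (!is.null(vts)) {
        val_loss <- 0
        for (i in seq_along(vts)) {
          gt <- vts[[i]]
          fw <- net_forward(par, cfg, gt$X, gt$src, gt$dst, gt$ew,
                            training = FALSE)
          val_loss <- val_loss - fw$logp[vys[i] + 1L]
        }
        val_loss <- val_loss / length(vts)
        if (val_loss < best_val - 1e-9) {
          best_val <- val_loss; best_par <- par; wait <- 0
        } else wait <- wait + 1
      }
      hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / ng,
                               accuracy = ep_hits / ng, val_loss = val_loss)
      if (!is.null(vts) && is.finite(cfg$patience) && wait >= cfg$patience)
        break
    }
    if (!is.null(vts) && is.finite(best_val)) par <- best_par
    classifier$params <- par
    classifier$trained <- TRUE
    classifier$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    classifier
  })
}

#' Predict the task of a signature graph
#'
#' Deterministic forward pass (dropout disabled); the predicted label is the
#' argmax of the log-probabilities, with ties broken by the lowest class
#' index.
#'
#' @param object a trained `task_classifier`.
#' @param graph a [signature_graph()] (or list of them via `graphs`).
#' @param ... unused.
#' @return A list with `label` (0-based class) and `logp`.
#' @export
predict.task_classifier <- function(object, graph, ...) {
  if (!object$trained) warning("classifier has not been trained")
  if (ncol(graph$node_features) != object$in_dim)
    stop("graph feature width does not match classifier input width")
  gt <- graph_tensors(graph)
  fw <- net_forward(object$params, object$cfg, gt$X, gt$src, gt$dst, gt$ew,
                    training = FALSE)
  list(label = which.max(fw$logp) - 1L, logp = fw$logp)
}

#' Classification accuracy of a trained classifier on a graph set
#'
#' @param classifier a trained `task_classifier`.
#' @param graphs list of labeled [signature_graph()]s.
#' @return Fraction of graphs whose predicted task matches the label.
#' @export
task_accuracy <- function(classifier, graphs) {
  hits <- vapply(graphs, function(g)
    predict(classifier, g)$label == g$label, logical(1))
  mean(hits)
}
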