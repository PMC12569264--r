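#' Convert a causal signature into a labeled graph
#'
#' Builds the graph representation consumed by the task classifier: one node
#' per state region, node `i` carrying row `i` of `R = [Q A B1 B2]` as its
#' feature vector (how region `i` is influenced by other regions and by the
#' inputs), and directed edges `j -> i` weighted by the normalized slow
#' block `A`.
#'
#' @param sig a [causal_signature].
#' @param label task id in `0..C-1`.
#' @param adjacency_norm how `|A|` is normalized into edge weights:
#'   `"row"` (default; each row divided by its absolute sum, so incoming
#'   influence per node sums to 1 and all-zero rows yield no edges),
#'   `"sym"` (symmetric degree normalization `D^-1/2 |A| D^-1/2`), or
#'   `"max"` (division by the global maximum absolute entry).
#' @return An object of class `signature_graph` with `node_features`
#'   (m x (2m+2n)), `edge_index` (2 x E integer matrix, rows = source,
#'   target), `edge_weight`, `label`, `m`.
#' @export
signature_graph <- function(sig, label,
                            adjacency_norm = c("row", "sym", "max")) {
  adjacency_norm <- match.arg(adjacency_norm)
  stopifnot(inherits(sig, "causal_signature"))
  label <- as.integer(label)
  if (is.na(label) || label < 0L) stop("'label' must be a task id >= 0")
  Xf <- coef(sig)
  stopifnot_finite(Xf, "node features")
  Aabs <- abs(sig$A)
  W <- switch(adjacency_norm,
    row = {
      rs <- rowSums(Aabs)
      out <- Aabs
      nz <- rs > 0
      out[nz, ] <- Aabs[nz, , drop = FALSE] / rs[nz]
      out
    },
    sym = {
      d <- sqrt(rowSums(Aabs))
      d[d == 0] <- 1
      Aabs / outer(d, d)
    },
    max = {
      mx <- max(Aabs)
      if (mx > 0) Aabs / mx else Aabs
    })
  nz <- which(W != 0, arr.ind = TRUE)          # (i, j): edge j -> i
  edge_index <- rbind(src = as.integer(nz[, 2L]), dst = as.integer(nz[, 1L]))
  structure(list(node_features = unname(Xf), edge_index = edge_index,
                 edge_weight = W[nz], label = label, m = sig$m,
                 adjacency_norm = adjacency_norm),
            class = "signature_graph")
}

#' @export
print.signature_graph <- function(x, ...) {
  cat(sprintf("Signature graph: %d nodes, %d directed edges, feature dim %d, task label %d\n",
              x$m, ncol(x$edge_index), ncol(x$node_features), x$label))
  invisible(x)
}
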