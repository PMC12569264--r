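#' Parcellated time series
#'
#' Container for a region-by-time activity matrix, e.g. BOLD signals after
#' cortical parcellation. Columns are scans indexed `k = 0..T`, spaced `dt`
#' seconds apart; rows are parcels with unique labels.
#'
#' @param values numeric matrix, `p` rows (parcels) by `T+1` columns (scans).
#' @param dt sampling interval in seconds (> 0); e.g. 0.72 for a scanner
#'   repetition time of 720 ms.
#' @param parcel_labels character vector of `p` unique parcel names. Defaults
#'   to `"P001"`, `"P002"`, ...
#' @return An object of class `parcellated_ts`: the value matrix with
#'   attributes `dt` and row names carrying the labels.
#' @examples
#' ts <- parcellated_ts(matrix(rnorm(40), 4, 10), dt = 0.72)
#' dim(ts)
#' @export
parcellated_ts <- function(values, dt, parcel_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  p <- nrow(values); nk <- ncol(values)
  if (p < 2L) stop("need at least 2 parcels (rows)")
  if (nk < 2L) stop("need at least 2 time points (columns, k = 0..T with T >= 1)")
  stopifnot_finite(values, "values")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)")
  if (is.null(parcel_labels)) parcel_labels <- rownames(values)
  if (is.null(parcel_labels)) parcel_labels <- sprintf("P%03d", seq_len(p))
  parcel_labels <- as.character(parcel_labels)
  if (length(parcel_labels) != p) stop("'parcel_labels' must have one entry per row")
  if (anyDuplicated(parcel_labels)) stop("parcel labels must be unique")
  rownames(values) <- parcel_labels
  colnames(values) <- NULL
  structure(values, dt = dt, class = c("parcellated_ts", "matrix", "array"))
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("Parcellated time series: %d parcels x %d scans (k = 0..%d), dt = %g s\n",
              nrow(x), ncol(x), ncol(x) - 1L, attr(x, "dt")))
  cat("Parcels:", paste(utils::head(rownames(x), 6), collapse = ", "),
      if (nrow(x) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.parcellated_ts <- function(x, parcels = seq_len(min(5L, nrow(x))), ...) {
  tt <- (seq_len(ncol(x)) - 1L) * attr(x, "dt")
  graphics::matplot(tt, t(unclass(x)[parcels, , drop = FALSE]), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "activity", ...)
  invisible(x)
}

#' Partition parcels into system states and inputs
#'
#' Splits the `p` parcels of a recording into `m` state regions (whose
#' dynamics are modelled) and `n` input regions (treated as exogenous
#' drivers), with `m + n = p` for the parcels selected.
#'
#' @param state_idx integer indices (or labels, with `labels` supplied) of
#'   state parcels, in order.
#' @param input_idx integer indices (or labels) of input parcels; may be empty.
#' @param labels optional character vector mapping labels to indices.
#' @return An object of class `partition_spec` with fields `state_idx`,
#'   `input_idx`, `m`, `n`.
#' @examples
#' part <- partition_spec(state_idx = 3:10, input_idx = 1:2)
#' @export
partition_spec <- function(state_idx, input_idx = integer(0), labels = NULL) {
  resolve <- function(ix) {
    if (is.character(ix)) {
      if (is.null(labels)) stop("label-based indices need 'labels'")
      pos <- match(ix, labels)
      if (anyNA(pos)) stop("unknown parcel label(s): ",
                           paste(ix[is.na(pos)], collapse = ", "))
      pos
    } else as.integer(ix)
  }
  state_idx <- resolve(state_idx); input_idx <- resolve(input_idx)
  if (length(state_idx) < 1L) stop("need at least one state parcel")
  if (anyDuplicated(c(state_idx, input_idx)))
    stop("state and input index sets must be disjoint and duplicate-free")
  structure(list(state_idx = state_idx, input_idx = input_idx,
                 m = length(state_idx), n = length(input_idx)),
            class = "partition_spec")
}

#' @export
print.partition_spec <- function(x, ...) {
  cat(sprintf("Partition: m = %d states, n = %d inputs\n", x$m, x$n))
  invisible(x)
}

check_partition <- function(part, ts) {
  p <- nrow(ts)
  idx <- c(part$state_idx, part$input_idx)
  if (any(idx < 1L | idx > p)) stop("partition indices outside 1..p")
  if (length(idx) != p)
    warning("partition does not cover all parcels; unselected rows are ignored")
  invisible(part)
}

#' Downsample a recording by keeping every k-th scan
#'
#' Emulates a coarser repetition time: keeping every 2nd column of a
#' dt = 0.72 s series yields a dt = 1.44 s series.
#'
#' @param ts a [parcellated_ts()].
#' @param factor integer >= 1; keep columns 1, 1+factor, 1+2*factor, ...
#' @return A `parcellated_ts` with `dt` multiplied by `factor`.
#' @export
downsample_ts <- function(ts, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be >= 1")
  keep <- seq(1L, ncol(ts), by = factor)
  if (length(keep) < 2L) stop("downsampling leaves fewer than 2 scans")
  parcellated_ts(unclass(ts)[, keep, drop = FALSE], dt = attr(ts, "dt") * factor,
                 parcel_labels = rownames(ts))
}
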