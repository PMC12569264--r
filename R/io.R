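fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Read and write parcellated time series
#'
#' The on-disk format is a delimited text file with `p` rows and `T + 2`
#' columns: the parcel label followed by the `T + 1` scan values, plus a
#' JSON sidecar (same path with extension `.json`) recording the sampling
#' interval `dt`. Values round-trip at full double precision.
#'
#' @param ts a [parcellated_ts()].
#' @param path file path (e.g. `run1.csv`; the sidecar becomes `run1.json`).
#' @param sep field separator (`","` by default; use `"\t"` for TSV).
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a `parcellated_ts`.
#' @export
write_timeseries <- function(ts, path, sep = ",") {
  stopifnot(inherits(ts, "parcellated_ts"))
  V <- unclass(ts)
  lines <- vapply(seq_len(nrow(V)), function(i)
    paste(c(rownames(V)[i], fmt_num(V[i, ])), collapse = sep), character(1))
  writeLines(lines, path)
  jsonlite::write_json(list(dt = attr(ts, "dt"), p = nrow(V),
                            n_scans = ncol(V)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar '", sc, "' (must record the sampling interval dt)")
  meta <- jsonlite::read_json(sc)
  if (is.null(meta$dt)) stop("sidecar '", sc, "' is missing 'dt'")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row in '%s': line %d has %d fields, line 1 has %d",
                 path, bad, nf[bad], nf[1L]))
  }
  labs <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(labs)) {
    dup <- labs[duplicated(labs)][1L]
    stop(sprintf("duplicate parcel label '%s' at line %d of '%s'",
                 dup, which(labs == dup)[2L], path))
  }
  V <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(nf[1L] - 1L)))
  if (anyNA(V)) {
    bad <- which(apply(is.na(V), 1L, any))[1L]
    stop(sprintf("non-numeric value at line %d of '%s'", bad, path))
  }
  parcellated_ts(V, dt = as.numeric(meta$dt), parcel_labels = labs)
}

#' Read a state/input partition from JSON
#'
#' The file holds `{"state": [labels...], "input": [labels...]}`. When
#' `labels` (the parcel labels of the recording) is supplied, the result is
#' a resolved [partition_spec()]; unknown labels raise an error naming them.
#'
#' @param path JSON file path.
#' @param labels optional character vector of parcel labels to resolve
#'   against.
#' @return A `partition_spec` (if `labels` given) or a list with `state`
#'   and `input` character vectors.
#' @export
read_partition <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$state)) stop("partition file '", path, "' has no 'state' list")
  state <- as.character(js$state)
  input <- as.character(js$input %||% character(0))
  if (is.null(labels)) return(list(state = state, input = input))
  partition_spec(state_idx = state, input_idx = input, labels = labels)
}

#' @rdname read_partition
#' @param part a list with `state`/`input` label vectors or a `partition_spec`
#'   plus `labels`.
#' @export
write_partition <- function(part, path, labels = NULL) {
  if (inherits(part, "partition_spec")) {
    if (is.null(labels)) stop("writing a partition_spec needs 'labels'")
    part <- list(state = labels[part$state_idx], input = labels[part$input_idx])
  }
  jsonlite::write_json(part, path, auto_unbox = FALSE)
  invisible(path)
}

#' Persist a causal signature as a directory of delimited files
#'
#' Writes `manifest.json` (m, n, dt, lambda, residual norm, mode, labels)
#' and `Q.csv`, `A.csv`, `B1.csv`, `B2.csv` at full precision.
#'
#' @param sig a [causal_signature].
#' @param dir directory path (created if needed).
#' @return `write_signature` returns `dir` invisibly; `read_signature`
#'   returns the `causal_signature` (without training data).
#' @export
write_signature <- function(sig, dir) {
  stopifnot(inherits(sig, "causal_signature"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(M, name) {
    lines <- apply(M, 1L, function(r) paste(fmt_num(r), collapse = ","))
    if (nrow(M) == 0L || ncol(M) == 0L) lines <- character(0)
    writeLines(as.character(lines), file.path(dir, name))
  }
  wr(sig$Q, "Q.csv"); wr(sig$A, "A.csv")
  wr(sig$B1, "B1.csv"); wr(sig$B2, "B2.csv")
  jsonlite::write_json(
    list(m = sig$m, n = sig$n, dt = sig$dt, lambda = sig$lambda,
         residual_norm = sig$residual_norm, mode = sig$mode,
         timescales = sig$timescales,
         state_labels = sig$state_labels, input_labels = sig$input_labels),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_matrix_csv <- function(path, nrow_expect, ncol_expect) {
  if (ncol_expect == 0L || nrow_expect == 0L)
    return(matrix(0, nrow_expect, ncol_expect))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  M <- t(vapply(strsplit(lines, ",", fixed = TRUE),
                function(f) as.numeric(f), numeric(ncol_expect)))
  if (nrow(M) != nrow_expect)
    stop(sprintf("'%s': expected %d rows, found %d", path, nrow_expect, nrow(M)))
  M
}

#' @rdname write_signature
#' @export
read_signature <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", dir)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  m <- as.integer(meta$m); n <- as.integer(meta$n)
  Q <- read_matrix_csv(file.path(dir, "Q.csv"), m, m)
  A <- read_matrix_csv(file.path(dir, "A.csv"), m, m)
  B1 <- read_matrix_csv(file.path(dir, "B1.csv"), m, n)
  B2 <- read_matrix_csv(file.path(dir, "B2.csv"), m, n)
  part <- partition_spec(state_idx = seq_len(m),
                         input_idx = if (n > 0) m + seq_len(n) else integer(0))
  new_causal_signature(Q, A, B1, B2, dt = meta$dt, lambda = meta$lambda,
                       mode = meta$mode %||% "ridge",
                       residual_norm = meta$residual_norm %||% NA_real_,
                       partition = part,
                       state_labels = meta$state_labels,
                       input_labels = meta$input_labels,
                       timescales = meta$timescales %||% "two")
}

#' Write a reachability landscape to delimited files
#'
#' Writes `<prefix>_values.csv` (region, raw value, normalized value) and
#' `<prefix>_grid.csv` (the 12 x 12 layout, masked cells as `NA`).
#'
#' @param landscape a [reachability_landscape()].
#' @param prefix output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_landscape <- function(landscape, prefix) {
  stopifnot(inherits(landscape, "reachability_landscape"))
  vf <- paste0(prefix, "_values.csv")
  gf <- paste0(prefix, "_grid.csv")
  utils::write.csv(
    data.frame(region = seq_len(landscape$m),
               raw = landscape$raw_values,
               normalized = landscape$values),
    vf, row.names = FALSE)
  utils::write.table(landscape$grid, gf, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(values = vf, grid = gf))
}
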