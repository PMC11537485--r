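#' Binary spike raster
#'
#' The universal data container of the package: a binary matrix of `Nv`
#' neurons (rows) by `T` time-steps (columns), with an optional sampling
#' interval `dt` and neuron identifiers.
#'
#' @param values binary (0/1) numeric matrix, neurons x time
#' @param dt sampling interval between consecutive columns (arbitrary units)
#' @param unit_ids optional character or integer vector of length `nrow(values)`
#' @return an object of class `spike_raster`
#' @examples
#' r <- spike_raster(matrix(rbinom(20, 1, 0.3), 4, 5))
#' dim(r$values)
#' @export
spike_raster <- function(values, dt = 1, unit_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("spike_raster needs at least one neuron and one time-step", call. = FALSE)
  }
  assert_binary(values, "raster values")
  if (!is.null(unit_ids) && length(unit_ids) != nrow(values)) {
    stop_dims("unit_ids", nrow(values), length(unit_ids))
  }
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  structure(
    list(values = values, dt = dt, unit_ids = unit_ids),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "spike_raster: %d neurons x %d time-steps (dt = %g), mean activity %.3f\n",
    nrow(x$values), ncol(x$values), x$dt, mean(x$values)
  ))
  invisible(x)
}

#' @export
dim.spike_raster <- function(x) dim(x$values)

as_raster <- function(x, dt = 1) {
  if (inherits(x, "spike_raster")) x else spike_raster(x, dt = dt)
}

#' Downsample a raster by decimation
#'
#' Keeps every `dtd`-th column starting from the first, without averaging or
#' interpolation — the same operation an imaging system performs when it only
#' visits a plane every `dtd` sampling intervals. The `dt` metadata is scaled
#' accordingly.
#'
#' @param raster a [spike_raster()]
#' @param dtd positive integer down-sampling rate
#' @return a [spike_raster()] with `ceiling(T / dtd)` columns
#' @export
downsample_raster <- function(raster, dtd) {
  raster <- as_raster(raster)
  dtd <- as.integer(dtd)
  if (dtd < 1L) stop("dtd must be >= 1", call. = FALSE)
  T <- ncol(raster$values)
  if (dtd >= T) stop("dtd must be smaller than the number of time-steps", call. = FALSE)
  keep <- seq(1L, T, by = dtd)
  spike_raster(raster$values[, keep, drop = FALSE],
               dt = raster$dt * dtd, unit_ids = raster$unit_ids)
}

#' Split a raster into train and test segments
#'
#' Divides the recording into `n_segments` contiguous, equal-length segments
#' (the remainder going to the last one) and labels a fixed subset as test
#' data. Segment indices are 1-based. The defaults reproduce the conventional
#' 10-segment split with segments 2, 6, and 7 held out.
#'
#' @param raster a [spike_raster()]
#' @param n_segments number of contiguous segments
#' @param test_segments 1-based indices of segments forming the test set
#' @return list with `train` and `test`, each a list of [spike_raster()]s,
#'   and `segment_columns`, the column index ranges per segment
#' @export
split_segments <- function(raster, n_segments = 10L, test_segments = c(2L, 6L, 7L)) {
  raster <- as_raster(raster)
  T <- ncol(raster$values)
  n_segments <- as.integer(n_segments)
  if (T < n_segments) stop("fewer time-steps than segments", call. = FALSE)
  test_segments <- sort(unique(as.integer(test_segments)))
  if (length(test_segments) == 0L || length(test_segments) >= n_segments ||
      any(test_segments < 1L) || any(test_segments > n_segments)) {
    stop("test_segments must be a non-empty proper subset of 1..n_segments", call. = FALSE)
  }
  len <- T %/% n_segments
  starts <- (seq_len(n_segments) - 1L) * len + 1L
  ends <- c(starts[-1L] - 1L, T)
  seg <- function(i) {
    spike_raster(raster$values[, starts[i]:ends[i], drop = FALSE],
                 dt = raster$dt, unit_ids = raster$unit_ids)
  }
  is_test <- seq_len(n_segments) %in% test_segments
  list(
    train = lapply(which(!is_test), seg),
    test = lapply(which(is_test), seg),
    segment_columns = Map(function(s, e) c(s, e), starts, ends)
  )
}

# Column-bind a list of rasters back into one (used for training on the
# concatenated train segments; the seam columns are batch boundaries upstream).
bind_rasters <- function(rasters) {
  stopifnot(length(rasters) >= 1L)
  vals <- do.call(cbind, lapply(rasters, function(r) as_raster(r)$values))
  spike_raster(vals, dt = as_raster(rasters[[1L]])$dt,
               unit_ids = as_raster(rasters[[1L]])$unit_ids)
}
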