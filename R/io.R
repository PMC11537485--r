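# Raster and checkpoint containers plus run manifests.
#
# Containers are R serialization files (.rds) holding named lists with a
# `kind` tag and a metadata block; rasters additionally round-trip through a
# legacy plain-matrix dialect (bare matrix .rds or a headerless CSV of 0/1
# values) which is accepted with dt = 1 and a warning.

#' Write / read a spike raster container
#'
#' Lossless round trip of `values`, `dt` and `unit_ids`. `read_raster`
#' validates that all values are binary and names offending entries
#' otherwise; a legacy file holding a bare matrix (RDS) or a headerless CSV
#' is accepted with a `dt = 1` default and a warning.
#'
#' @param raster a [spike_raster()]
#' @param path file path (`.rds`, or `.csv` for the legacy dialect)
#' @return `write_raster` returns `path` invisibly; `read_raster` a
#'   [spike_raster()]
#' @export
write_raster <- function(raster, path) {
  raster <- as_raster(raster)
  if (grepl("\\.csv$", path)) {
    utils::write.table(raster$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    saveRDS(list(kind = "spike_raster", values = raster$values, dt = raster$dt,
                 unit_ids = raster$unit_ids,
                 meta = container_meta(Nv = nrow(raster$values),
                                       T = ncol(raster$values))),
            path)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (grepl("\\.csv$", path)) {
    vals <- as.matrix(utils::read.csv(path, header = FALSE))
    warning("legacy plain-matrix raster: assuming dt = 1, no unit ids", call. = FALSE)
    return(spike_raster(unname(vals)))
  }
  obj <- readRDS(path)
  if (is.matrix(obj)) {
    warning("legacy plain-matrix raster: assuming dt = 1, no unit ids", call. = FALSE)
    return(spike_raster(obj))
  }
  if (!is.list(obj) || is.null(obj$values) ||
      (!is.null(obj$kind) && obj$kind != "spike_raster")) {
    stop("not a spike raster container", call. = FALSE)
  }
  spike_raster(obj$values, dt = if (is.null(obj$dt)) 1 else obj$dt,
               unit_ids = obj$unit_ids)
}

container_meta <- function(...) {
  c(list(package = "rtrbm",
         version = as.character(utils::packageVersion("rtrbm")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    list(...))
}

#' Write / read a model checkpoint
#'
#' Checkpoints hold the named parameter arrays (`W`, `bv`, `bh`, plus `U`
#' and `binit` for an RTRBM) and a metadata block (model kind, sizes). Any
#' checkpoint's `W` can serve as a transfer-learning donor via
#' `read_donor_W()`.
#'
#' @param params an [rbm_params()] or [rtrbm_params()]
#' @param path file path (`.rds`)
#' @param seed optional creation seed recorded in the metadata
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   the parameter object; `read_donor_W` the `Nh x Nv` weight matrix
#' @export
write_checkpoint <- function(params, path, seed = NULL) {
  kind <- if (inherits(params, "rtrbm_params")) "rtrbm" else "rbm"
  obj <- list(kind = kind, W = params$W, bv = params$bv, bh = params$bh,
              meta = container_meta(Nv = n_visible(params),
                                    Nh = n_hidden(params), seed = seed))
  if (kind == "rtrbm") {
    obj$U <- params$U
    obj$binit <- params$binit
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @param expect `"any"`, `"rbm"` or `"rtrbm"`: fail with a kind error when
#'   the checkpoint does not match
#' @export
read_checkpoint <- function(path, expect = c("any", "rbm", "rtrbm")) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$kind) || is.null(obj$W)) {
    stop("not a model checkpoint", call. = FALSE)
  }
  if (expect != "any" && obj$kind != expect) {
    stop(sprintf("checkpoint kind is '%s' but '%s' was expected",
                 obj$kind, expect), call. = FALSE)
  }
  if (obj$kind == "rtrbm") {
    rtrbm_params(obj$W, obj$U, obj$bv, obj$bh, obj$binit)
  } else if (obj$kind == "rbm") {
    rbm_params(obj$W, obj$bv, obj$bh)
  } else {
    stop(sprintf("unknown checkpoint kind '%s'", obj$kind), call. = FALSE)
  }
}

#' @rdname write_checkpoint
#' @export
read_donor_W <- function(path) {
  obj <- readRDS(path)
  if (is.matrix(obj)) return(obj)
  if (is.list(obj) && !is.null(obj$W)) return(as.matrix(obj$W))
  stop("no weight matrix found in donor file", call. = FALSE)
}

# One manifest per CLI run, next to the outputs: enough to re-execute the
# run bit-identically.
write_manifest <- function(dir, command, args, seed, inputs, outputs,
                           wall_time) {
  manifest <- list(
    command = command, args = as.list(args), seed = seed,
    inputs = inputs, outputs = outputs,
    package_version = as.character(utils::packageVersion("rtrbm")),
    wall_time_s = round(wall_time, 3),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  path <- file.path(dir, sprintf("manifest-%s.json", command))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
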