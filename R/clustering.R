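# Grouping assemblies by temporal-connectivity similarity and extracting
# their receptive fields.

#' Cluster assemblies by temporal connectivity
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances between
#' the incoming (row) or outgoing (column) connection vectors of the
#' temporal weight matrix; flat clusters are obtained by cutting the
#' dendrogram at a distance threshold.
#'
#' @param U_hat `Nh x Nh` (aligned) temporal weight matrix
#' @param axis `"rows"` (incoming connections) or `"cols"` (outgoing)
#' @param threshold positive distance cutoff on the linkage tree
#' @return a `cluster_assignment`: `labels` (cluster index per hidden unit,
#'   relabelled in order of first appearance), `linkage` (the `hclust`
#'   object), `merge_heights`, `threshold`, `axis`, `n_clusters`
#' @export
cluster_U <- function(U_hat, axis = c("rows", "cols"), threshold) {
  axis <- match.arg(axis)
  U_hat <- as.matrix(U_hat)
  if (nrow(U_hat) < 2L) stop("need at least 2 hidden units", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  X <- if (axis == "rows") U_hat else t(U_hat)
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  raw <- stats::cutree(hc, h = threshold)
  labels <- as.integer(factor(raw, levels = unique(raw)))
  structure(list(labels = labels, linkage = hc, merge_heights = hc$height,
                 threshold = threshold, axis = axis,
                 n_clusters = length(unique(labels))),
            class = "cluster_assignment")
}

#' Receptive fields of assembly clusters
#'
#' Proportional weight thresholding: `w_thr` is set so that exactly
#' `n_strong` neurons have a maximal absolute visible-to-hidden weight above
#' it (ties at the threshold resolved by including the lower neuron index
#' first). Each strong neuron is assigned to the cluster of its strongest
#' hidden unit.
#'
#' @param W `Nh x Nv` weight matrix
#' @param assignment a `cluster_assignment` from [cluster_U()]
#' @param n_strong number of strong neurons to select (defaults to
#'   `ceiling(0.125 Nv)` for small rasters, 5000 otherwise)
#' @return list with `neurons` (list of neuron index vectors per cluster),
#'   `w_thr`, `strong_neurons`, `cluster_of_neuron`
#' @export
receptive_fields <- function(W, assignment, n_strong = NULL) {
  W <- as.matrix(W)
  Nv <- ncol(W)
  if (is.null(n_strong)) n_strong <- if (Nv < 5000L) ceiling(0.125 * Nv) else 5000L
  n_strong <- as.integer(n_strong)
  if (n_strong > Nv) stop("n_strong exceeds the number of neurons", call. = FALSE)
  if (n_strong < 1L) stop("n_strong must be >= 1", call. = FALSE)
  m <- apply(abs(W), 2L, max)
  ord <- order(-m, seq_len(Nv))            # descending, ties -> lower index first
  strong <- sort(ord[seq_len(n_strong)])
  w_thr <- m[ord[n_strong]]
  top_hidden <- apply(abs(W[, strong, drop = FALSE]), 2L, which.max)
  cl <- assignment$labels[top_hidden]
  neurons <- split(strong, factor(cl, levels = sort(unique(assignment$labels))))
  list(neurons = neurons, w_thr = w_thr, strong_neurons = strong,
       cluster_of_neuron = stats::setNames(cl, strong))
}

#' Count strong weights per visible unit
#'
#' For each neuron, the number of hidden units whose absolute weight to it
#' exceeds `multiple_of_sd` times the standard deviation of the whole weight
#' matrix. A cleanly recovered one-assembly-per-neuron structure gives a
#' count of exactly 1 everywhere.
#'
#' @param W `Nh x Nv` weight matrix
#' @param multiple_of_sd threshold in units of `sd(W)` (default 0.5)
#' @return integer vector of length `Nv`
#' @export
strong_weight_count <- function(W, multiple_of_sd = 0.5) {
  W <- as.matrix(W)
  thr <- multiple_of_sd * stats::sd(as.numeric(W))
  colSums(abs(W) > thr)
}
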