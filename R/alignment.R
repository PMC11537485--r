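# Permutation and sign alignment of estimated assemblies against ground truth.

#' Match hidden units to ground-truth assemblies
#'
#' Scores every (hidden unit, assembly) pair by the mean absolute
#' visible-to-hidden weight over the assembly's neurons and assigns
#' assemblies to hidden units greedily in order of decreasing score, so a
#' contested hidden unit goes to the assembly with the stronger match.
#' A matched unit whose mean signed weight over the assembly is negative is
#' an inverse match and gets sign -1.
#'
#' @param W_hat estimated `Nh x Nv` weight matrix
#' @param membership assembly index (1-based) per visible unit, covering all
#'   `Nv` columns; the number of assemblies must equal `Nh`
#' @return an `alignment_map`: `permutation` (`permutation[k]` = hidden unit
#'   matched to assembly `k`), `sign` (+/-1 per assembly slot), `conflicts`
#'   (assemblies that lost their best hidden unit to a stronger match), and
#'   the score matrix
#' @export
match_assemblies <- function(W_hat, membership) {
  W_hat <- as.matrix(W_hat)
  membership <- as.integer(membership)
  if (length(membership) != ncol(W_hat)) {
    stop_dims("membership", ncol(W_hat), length(membership))
  }
  assemblies <- sort(unique(membership))
  Nh <- nrow(W_hat)
  if (length(assemblies) != Nh) {
    stop_dims("assembly count", Nh, length(assemblies))
  }
  # scores[j, k]: mean |W| from assembly k's neurons to hidden unit j
  scores <- vapply(assemblies, function(k) {
    rowMeans(abs(W_hat[, membership == k, drop = FALSE]))
  }, numeric(Nh))
  best <- apply(scores, 2L, which.max)

  permutation <- integer(Nh)
  assigned_h <- logical(Nh)
  assigned_a <- logical(Nh)
  conflicts <- integer(0)
  s <- scores
  for (step in seq_len(Nh)) {
    # highest remaining score; ties broken by lowest assembly then hidden index
    idx <- which(s == max(s), arr.ind = TRUE)
    idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE][1L, ]
    j <- unname(idx[1L]); k <- unname(idx[2L])
    permutation[k] <- j
    if (best[k] != j) conflicts <- c(conflicts, k)
    assigned_h[j] <- TRUE; assigned_a[k] <- TRUE
    s[j, ] <- -Inf
    s[, k] <- -Inf
  }
  sgn <- vapply(seq_len(Nh), function(k) {
    m <- mean(W_hat[permutation[k], membership == assemblies[k]])
    if (m < 0) -1 else 1
  }, numeric(1))
  structure(list(permutation = permutation, sign = sgn,
                 conflicts = sort(conflicts), scores = scores),
            class = "alignment_map")
}

#' Align an estimated temporal weight matrix
#'
#' Reorders the rows and columns of `U_hat` by the matched permutation and
#' flips the row and column of every inverse-matched unit. Two mutually
#' inverted units keep the signs of their mutual weights (the two flips
#' cancel).
#'
#' @param U_hat estimated `Nh x Nh` temporal weight matrix
#' @param map an `alignment_map` from [match_assemblies()]
#' @return aligned `Nh x Nh` matrix comparable entrywise to the true `U`
#' @export
align_U <- function(U_hat, map) {
  U_hat <- as.matrix(U_hat)
  p <- map$permutation
  if (nrow(U_hat) != length(p) || ncol(U_hat) != length(p)) {
    stop_dims("U_hat", length(p), nrow(U_hat))
  }
  tcrossprod(map$sign) * U_hat[p, p, drop = FALSE]
}

#' Align an estimated visible-to-hidden weight matrix
#'
#' Companion to [align_U()]: rows of `W_hat` reordered to assembly order and
#' inverse matches sign-flipped.
#'
#' @inheritParams align_U
#' @param W_hat estimated `Nh x Nv` weight matrix
#' @return aligned `Nh x Nv` matrix
#' @export
align_W <- function(W_hat, map) {
  W_hat <- as.matrix(W_hat)
  map$sign * W_hat[map$permutation, , drop = FALSE]
}

#' Cosine similarity between z-scored interaction matrices
#'
#' Flattens both matrices, standardizes each to mean 0 and unit variance
#' (population normalization), and returns the cosine of the angle between
#' them. Equals 1 for a perfect match and -1 for a sign-flipped match.
#'
#' @param U_true,U_hat_aligned equally sized numeric matrices
#' @return scalar in `[-1, 1]`
#' @export
cosine_similarity_U <- function(U_true, U_hat_aligned) {
  a <- as.numeric(U_true); b <- as.numeric(U_hat_aligned)
  if (length(a) != length(b)) stop_dims("U_hat_aligned", length(a), length(b))
  zs <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("zero-variance input to cosine_similarity_U", call. = FALSE)
    (x - mean(x)) / s
  }
  a <- zs(a); b <- zs(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
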