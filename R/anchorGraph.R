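# Anchor graphs: m representative points replace the all-pairs similarity.
# The sample-sample similarity S = Z diag(delta)^(-1) Z^T is row-stochastic
# by construction, so the graph Laplacian reduces to I - B B^T with
# B = Z diag(delta)^(-1/2); nothing n-by-n is ever needed for fitting.

#' Select anchor points from a data matrix
#'
#' @param X n-by-d numeric matrix (samples in rows).
#' @param m number of anchors, 1 <= m <= n.
#' @param strategy \code{"random"} (uniform sample of rows, without
#'   replacement; O(1) per anchor) or \code{"kmeans"} (k-means centers).
#' @param seed integer seed making the selection deterministic.
#' @return m-by-d matrix of anchor rows.
#' @export
selectAnchors <- function(X, m, strategy = c("random", "kmeans"),
                          seed = NULL) {
  strategy <- match.arg(strategy)
  X <- as.matrix(X)
  n <- nrow(X)
  if (m < 1) stop("m must be at least 1")
  if (m > n) stop("m (", m, ") cannot exceed the number of samples (", n, ")")
  withSeed(seed, {
    if (strategy == "random") {
      X[sample.int(n, m), , drop = FALSE]
    } else {
      if (m == n) return(X)
      km <- stats::kmeans(X, centers = m, nstart = 1, iter.max = 50)
      unname(km$centers)
    }
  })
}

#' Sample-to-anchor affinity with k-sparse closed form
#'
#' For each sample, squared Euclidean distances to all anchors are
#' ranked; the k nearest anchors receive weight
#' \deqn{z_{ij} = (d_{i,k+1} - d_{ij}) / (k d_{i,k+1} - \sum_{j'=1}^{k} d_{ij'})}
#' and all others 0, which is the closed-form minimizer of the
#' regularized affinity objective when the per-row regularizer is set
#' from the (k+1)-th neighbor distance. Rows are nonnegative, sum to 1,
#' and have at most k nonzeros. Distance ties are broken by anchor index.
#'
#' @param X n-by-d matrix of samples.
#' @param anchors m-by-d matrix of anchors.
#' @param kNN number of nearest anchors, 1 <= kNN <= m - 1 (the (k+1)-th
#'   distance must exist).
#' @return n-by-m affinity matrix Z. Rows whose k+1 nearest distances are
#'   all equal (zero denominator) fall back to uniform 1/k weights over
#'   the k nearest, with a warning.
#' @examples
#' X <- matrix(c(0, 0), 1, 2)
#' A <- rbind(c(1, 0), c(0, sqrt(2)), c(2, 0))  # squared dists 1, 2, 4
#' anchorAffinity(X, A, kNN = 2)                # 0.6, 0.4, 0
#' @export
anchorAffinity <- function(X, anchors, kNN) {
  if (is(X, "AnchorGraph")) return(X@Z)
  X <- as.matrix(X); anchors <- as.matrix(anchors)
  if (ncol(X) != ncol(anchors))
    stop("X and anchors must have the same number of columns")
  m <- nrow(anchors)
  if (kNN < 1) stop("kNN must be at least 1")
  if (kNN >= m)
    stop("kNN (", kNN, ") must be smaller than the number of anchors (",
         m, ") so that the (k+1)-th distance exists")
  n <- nrow(X)
  # squared Euclidean distances, n x m
  D2 <- outer(rowSums(X^2), rep(1, m)) +
        outer(rep(1, n), rowSums(anchors^2)) -
        2 * tcrossprod(X, anchors)
  D2[D2 < 0] <- 0  # roundoff guard
  Z <- matrix(0, n, m)
  degenerate <- 0L
  for (i in seq_len(n)) {
    ord <- order(D2[i, ], seq_len(m))  # stable: ties by anchor index
    near <- ord[seq_len(kNN)]
    dk1 <- D2[i, ord[kNN + 1L]]
    denom <- kNN * dk1 - sum(D2[i, near])
    if (denom <= 0) {
      degenerate <- degenerate + 1L
      Z[i, near] <- 1 / kNN
    } else {
      Z[i, near] <- (dk1 - D2[i, near]) / denom
    }
  }
  if (degenerate > 0L)
    warning(degenerate, " sample(s) had their k+1 nearest anchor distances ",
            "all equal; uniform 1/k weights used for those rows")
  Z
}

#' Anchor degrees and the normalized factor B
#'
#' Computes the anchor degree vector delta (column sums of Z) and
#' B = Z diag(delta)^(-1/2). Anchors receiving zero total affinity are
#' dropped from both matrices first (with a warning): they contribute
#' nothing to the similarity and would make the normalization singular.
#'
#' @param Z n-by-m nonnegative row-stochastic affinity.
#' @return list with \code{B} (n-by-m'), \code{delta} (length m'), and
#'   \code{kept} (indices of retained anchor columns).
#' @export
anchorFactor <- function(Z) {
  if (is(Z, "AnchorGraph"))
    return(list(B = Z@B, delta = Z@delta, kept = seq_along(Z@delta)))
  Z <- as.matrix(Z)
  delta <- colSums(Z)
  if (all(delta == 0)) stop("Z is all zero; no anchor receives any affinity")
  kept <- which(delta > 0)
  if (length(kept) < ncol(Z)) {
    warning(ncol(Z) - length(kept),
            " anchor(s) with zero affinity mass dropped")
    Z <- Z[, kept, drop = FALSE]
    delta <- delta[kept]
  }
  B <- sweep(Z, 2, sqrt(delta), "/")
  list(B = B, delta = delta, kept = kept)
}

#' Materialized sample-sample similarity (small n only)
#'
#' Returns S = Z diag(delta)^(-1) Z^T, the symmetric row-stochastic
#' similarity implied by the anchor graph. Intended for inspection and
#' testing; fitting never forms it (see [laplacianQuadratic()]).
#'
#' @param Z n-by-m affinity matrix.
#' @param maxSamples guard cap on n (default 2000).
#' @return n-by-n symmetric matrix with unit row sums.
#' @export
anchorSimilarity <- function(Z, maxSamples = 2000) {
  Z <- as.matrix(Z)
  if (nrow(Z) > maxSamples)
    stop("n = ", nrow(Z), " exceeds the materialization cap (", maxSamples,
         "); use laplacianQuadratic() for Laplacian terms instead")
  f <- anchorFactor(Z)
  tcrossprod(f$B)
}

#' Laplacian quadratic form tr(M^T (I - B B^T) M) without the n-by-n graph
#'
#' Because the anchor similarity is row-stochastic its degree matrix is
#' the identity, so the Laplacian is I - B B^T and the quadratic form
#' reduces to ||M||_F^2 - ||B^T M||_F^2, computable in O(nmc).
#'
#' @param B n-by-m factor from [anchorFactor()].
#' @param M n-by-c matrix.
#' @return nonnegative scalar (up to roundoff; I - B B^T is positive
#'   semidefinite).
#' @export
laplacianQuadratic <- function(B, M) {
  B <- as.matrix(B); M <- as.matrix(M)
  if (nrow(B) != nrow(M))
    stop("B and M must have the same number of rows (",
         nrow(B), " vs ", nrow(M), ")")
  sum(M^2) - sum(crossprod(B, M)^2)
}

#' Build the anchor graph of one modality
#'
#' Convenience wrapper running [selectAnchors()], [anchorAffinity()] and
#' [anchorFactor()] and bundling the result into an
#' [AnchorGraph-class] object.
#'
#' @inheritParams selectAnchors
#' @inheritParams anchorAffinity
#' @param m anchor count; \code{NULL} picks min(4 * ceiling(sqrt(n)), n).
#' @param kNN nearest-anchor count (default 5, clipped to m - 1).
#' @return an [AnchorGraph-class].
#' @export
buildAnchorGraph <- function(X, m = NULL, kNN = 5,
                             strategy = c("random", "kmeans"), seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(m) || is.na(m)) m <- min(4L * as.integer(ceiling(sqrt(n))), n)
  kNN <- min(as.integer(kNN), m - 1L)
  if (kNN < 1) stop("need at least 2 anchors to form a k-sparse affinity")
  A <- selectAnchors(X, m, match.arg(strategy), seed = seed)
  Z <- anchorAffinity(X, A, kNN)
  f <- anchorFactor(Z)
  new("AnchorGraph", anchors = A[f$kept, , drop = FALSE],
      Z = Z[, f$kept, drop = FALSE], delta = f$delta, B = f$B,
      kNN = as.integer(kNN))
}

#' @rdname AnchorGraph-class
#' @export
setMethod("anchors", "AnchorGraph", function(object) object@anchors)

#' @rdname AnchorGraph-class
#' @export
setMethod("anchorDegrees", "AnchorGraph", function(object) object@delta)

setMethod("show", "AnchorGraph", function(object) {
  cat("AnchorGraph:", nrow(object@Z), "samples,", ncol(object@Z),
      "anchors, k =", object@kNN, "\n")
})
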