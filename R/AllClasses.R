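#' @import methods
NULL

#' MultiModalDataset: aligned feature blocks plus one-hot labels
#'
#' Container for a multi-modal dataset: one numeric sample-by-feature
#' matrix per modality, all sharing the same row (sample) order, together
#' with a k-by-n one-hot label matrix whose columns correspond to
#' samples and whose rows correspond to classes.
#'
#' @slot blocks list of numeric matrices, one per modality, each with
#'   \code{n} rows; column counts may differ between modalities.
#' @slot labels numeric k-by-n one-hot matrix (each column sums to 1).
#' @slot classLevels character vector of class names, one per label row.
#' @slot modalityNames character vector naming the blocks.
#' @slot sampleIDs character vector of sample identifiers (row names).
#'
#' @seealso [multiModalDataset()], [simulateMultiModal()],
#'   [readMultiModal()]
#' @export
setClass("MultiModalDataset",
  representation(
    blocks = "list",
    labels = "matrix",
    classLevels = "character",
    modalityNames = "character",
    sampleIDs = "character"
  )
)

setValidity("MultiModalDataset", function(object) {
  msgs <- character()
  if (length(object@blocks) == 0L)
    msgs <- c(msgs, "at least one modality block is required")
  ns <- vapply(object@blocks, nrow, integer(1))
  if (length(unique(ns)) > 1L)
    msgs <- c(msgs, "all modality blocks must have the same number of rows")
  if (!all(vapply(object@blocks, is.numeric, logical(1))))
    msgs <- c(msgs, "all modality blocks must be numeric matrices")
  n <- if (length(ns)) ns[1] else 0L
  if (ncol(object@labels) != n)
    msgs <- c(msgs, sprintf(
      "label matrix has %d columns but blocks have %d rows",
      ncol(object@labels), n))
  if (nrow(object@labels) != length(object@classLevels))
    msgs <- c(msgs, "label matrix rows must match classLevels")
  cs <- colSums(object@labels)
  if (n > 0 && any(abs(cs - 1) > 1e-12))
    msgs <- c(msgs, "label matrix columns must each sum to 1 (one-hot)")
  if (length(object@modalityNames) != length(object@blocks))
    msgs <- c(msgs, "modalityNames must match the number of blocks")
  if (length(object@sampleIDs) != n)
    msgs <- c(msgs, "sampleIDs must have one entry per sample")
  if (length(msgs)) msgs else TRUE
})

#' AnchorGraph: a sparse bipartite sample-to-anchor affinity graph
#'
#' Holds the anchor set of one modality, the k-sparse row-stochastic
#' affinity matrix Z between samples and anchors, the anchor degree
#' vector delta (column sums of Z), and the factor B = Z diag(delta)^(-1/2).
#' The implied sample-sample similarity is S = Z diag(delta)^(-1) Z^T and
#' the graph Laplacian used by the optimizer is I - B B^T; neither is
#' ever materialized for large n.
#'
#' @slot anchors m-by-d numeric matrix of anchor points (rows).
#' @slot Z n-by-m nonnegative affinity matrix; each row sums to 1 and has
#'   at most \code{kNN} nonzero entries.
#' @slot delta length-m positive vector of anchor degrees (column sums of Z).
#' @slot B n-by-m matrix Z diag(delta)^(-1/2).
#' @slot kNN integer, number of nearest anchors retained per sample.
#'
#' @seealso [buildAnchorGraph()], [anchorAffinity()], [laplacianQuadratic()]
#' @export
setClass("AnchorGraph",
  representation(
    anchors = "matrix",
    Z = "matrix",
    delta = "numeric",
    B = "matrix",
    kNN = "integer"
  )
)

setValidity("AnchorGraph", function(object) {
  msgs <- character()
  m <- ncol(object@Z)
  if (nrow(object@anchors) < m)
    msgs <- c(msgs, "fewer anchor rows than affinity columns")
  if (any(object@Z < 0))
    msgs <- c(msgs, "affinity entries must be nonnegative")
  if (any(abs(rowSums(object@Z) - 1) > 1e-12))
    msgs <- c(msgs, "affinity rows must sum to 1")
  nz <- apply(object@Z > 0, 1, sum)
  if (any(nz > object@kNN))
    msgs <- c(msgs, "affinity rows must have at most kNN nonzero entries")
  if (length(object@delta) != m || any(object@delta <= 0))
    msgs <- c(msgs, "delta must be a positive vector with one entry per anchor column")
  if (!all(dim(object@B) == dim(object@Z)))
    msgs <- c(msgs, "B must have the same shape as Z")
  if (length(msgs)) msgs else TRUE
})

#' AGFSParams: hyperparameters for the anchor-graph feature selection fit
#'
#' @slot alpha positive real; weight of the l2,1 row-sparsity penalty.
#' @slot beta nonnegative real; weight of the anchor-graph Laplacian
#'   smoothness penalty.
#' @slot epsilon small positive real smoothing the l2,1 norm so the
#'   reweighted closed-form update is defined at zero rows.
#' @slot mAnchors integer or NA; anchors per modality (NA = automatic,
#'   min(4 * ceiling(sqrt(n)), n)).
#' @slot kNN integer; nearest anchors per sample in the affinity.
#' @slot anchorStrategy "random" (sampled data rows) or "kmeans"
#'   (k-means centers).
#' @slot mu0,rho,muMax augmented-Lagrangian penalty start, growth factor
#'   and cap for the simplex subproblem.
#' @slot almTol inner feasibility tolerance of the simplex solver.
#' @slot maxInnerIters cap on inner ALM iterations.
#' @slot maxOuterIters cap on outer alternating sweeps.
#' @slot outerTol relative objective-change stopping tolerance.
#' @slot coupling "additive" (one concatenated residual; objective is
#'   provably non-increasing) or "independent" (per-modality residuals).
#' @slot scale logical; z-score each feature column before graph
#'   construction and fitting.
#' @slot updateTheta logical; if FALSE the feature weight vector stays
#'   frozen at its uniform initialization.
#' @slot seed integer or NA; seeds anchor selection (the optimizer itself
#'   is deterministic).
#'
#' @seealso [agfsParams()], [agfsFit()]
#' @export
setClass("AGFSParams",
  representation(
    alpha = "numeric",
    beta = "numeric",
    epsilon = "numeric",
    mAnchors = "integer",
    kNN = "integer",
    anchorStrategy = "character",
    mu0 = "numeric",
    rho = "numeric",
    muMax = "numeric",
    almTol = "numeric",
    maxInnerIters = "integer",
    maxOuterIters = "integer",
    outerTol = "numeric",
    coupling = "character",
    scale = "logical",
    updateTheta = "logical",
    seed = "integer"
  )
)

setValidity("AGFSParams", function(object) {
  msgs <- character()
  if (!(length(object@alpha) == 1 && object@alpha > 0))
    msgs <- c(msgs, "alpha must be a single positive number")
  if (!(length(object@beta) == 1 && object@beta >= 0))
    msgs <- c(msgs, "beta must be a single nonnegative number")
  if (!(object@epsilon > 0)) msgs <- c(msgs, "epsilon must be positive")
  if (!(object@rho > 1)) msgs <- c(msgs, "rho must exceed 1")
  if (!(object@mu0 > 0)) msgs <- c(msgs, "mu0 must be positive")
  if (!(object@muMax >= object@mu0)) msgs <- c(msgs, "muMax must be at least mu0")
  if (!(object@almTol > 0)) msgs <- c(msgs, "almTol must be positive")
  if (!(object@outerTol > 0)) msgs <- c(msgs, "outerTol must be positive")
  if (!(object@kNN >= 1)) msgs <- c(msgs, "kNN must be at least 1")
  if (!object@anchorStrategy %in% c("random", "kmeans"))
    msgs <- c(msgs, "anchorStrategy must be 'random' or 'kmeans'")
  if (!object@coupling %in% c("additive", "independent"))
    msgs <- c(msgs, "coupling must be 'additive' or 'independent'")
  if (length(msgs)) msgs else TRUE
})

#' AGFSModel: the fitted state of the anchor-graph feature selector
#'
#' @slot W list of d_v-by-k per-modality weight matrices.
#' @slot b length-k bias vector shared across modalities.
#' @slot theta length-d nonnegative simplex vector of per-feature weights,
#'   concatenated over modalities.
#' @slot N list of per-modality positive reweighting vectors (diagonals of
#'   the iteratively reweighted l2,1 matrices).
#' @slot objectiveHistory numeric vector, objective value after each sweep.
#' @slot dims integer vector of per-modality feature counts.
#' @slot modalityNames character vector.
#' @slot featureNames character vector of length sum(dims).
#' @slot classLevels character vector of class names.
#' @slot params the AGFSParams used.
#' @slot scaling list with per-modality centers and scales applied before
#'   fitting (empty when scale = FALSE).
#' @slot converged logical; TRUE when the relative objective-change rule
#'   fired before the sweep cap.
#' @slot nSweeps integer, sweeps actually run.
#'
#' @seealso [agfsFit()], [featureScores()], [rankFeatures()]
#' @export
setClass("AGFSModel",
  representation(
    W = "list",
    b = "numeric",
    theta = "numeric",
    N = "list",
    objectiveHistory = "numeric",
    dims = "integer",
    modalityNames = "character",
    featureNames = "character",
    classLevels = "character",
    params = "AGFSParams",
    scaling = "list",
    converged = "logical",
    nSweeps = "integer"
  )
)

setValidity("AGFSModel", function(object) {
  msgs <- character()
  if (length(object@W) != length(object@dims))
    msgs <- c(msgs, "one weight matrix per modality required")
  d <- sum(object@dims)
  if (length(object@theta) != d)
    msgs <- c(msgs, "theta must have one entry per feature")
  if (length(object@theta) && abs(sum(object@theta) - 1) > 1e-6)
    msgs <- c(msgs, "theta must sum to 1")
  if (length(object@theta) && min(object@theta) < -1e-8)
    msgs <- c(msgs, "theta must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' FeatureRanking: scores, ordering and selected subset of features
#'
#' @slot scores length-d nonnegative per-feature scores.
#' @slot order integer permutation sorting scores in decreasing order
#'   (ties broken by smaller index).
#' @slot selected integer indices of the top-scoring features.
#' @slot modality integer modality id per feature.
#' @slot featureNames character names per feature.
#' @slot modalityImportance per-modality nonnegative weights summing to 1.
#' @slot mode scoring mode used ("theta_weighted" or "row_norm").
#'
#' @seealso [rankFeatures()], [featureScores()]
#' @export
setClass("FeatureRanking",
  representation(
    scores = "numeric",
    order = "integer",
    selected = "integer",
    modality = "integer",
    featureNames = "character",
    modalityImportance = "numeric",
    mode = "character"
  )
)

setValidity("FeatureRanking", function(object) {
  msgs <- character()
  if (any(object@scores < 0))
    msgs <- c(msgs, "scores must be nonnegative")
  if (length(object@order) != length(object@scores))
    msgs <- c(msgs, "order must be a permutation of the feature indices")
  if (length(object@modalityImportance) &&
      abs(sum(object@modalityImportance) - 1) > 1e-9)
    msgs <- c(msgs, "modalityImportance must sum to 1")
  if (length(msgs)) msgs else TRUE
})
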