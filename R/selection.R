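# From fitted state to a ranked feature list.

#' @rdname featureScores
#' @export
setMethod("featureScores", "AGFSModel", function(object,
    mode = c("theta_weighted", "row_norm")) {
  mode <- match.arg(mode)
  if (!length(object@objectiveHistory))
    stop("model has not been fitted")
  rn <- unlist(lapply(object@W, function(w) sqrt(rowSums(w^2))),
               use.names = FALSE)
  s <- if (mode == "theta_weighted") object@theta * rn else rn
  names(s) <- object@featureNames
  s
})

#' Indices of the top-scoring features
#'
#' @param scores numeric score vector.
#' @param nSelect number of features to keep, 1 <= nSelect <= length(scores).
#' @return integer indices of the nSelect largest scores, ties broken by
#'   smaller index.
#' @export
selectTopK <- function(scores, nSelect) {
  d <- length(scores)
  if (nSelect < 1 || nSelect > d)
    stop("nSelect must be between 1 and ", d)
  order(-scores, seq_len(d))[seq_len(nSelect)]
}

#' @describeIn modalityImportance within-modality sums of the fitted
#'   simplex feature weights.
#' @export
setMethod("modalityImportance", "AGFSModel", function(object, ...) {
  mi <- vapply(.splitTheta(object@theta, object@dims), sum, numeric(1))
  names(mi) <- object@modalityNames
  mi
})

#' Per-modality importance from a simplex feature-weight vector
#'
#' The importance of modality v is the sum of the simplex weights over
#' its feature segment; since theta sums to 1 the importances do too.
#'
#' @param object numeric simplex vector theta (or a fitted
#'   [AGFSModel-class], for which the stored theta and dims are used).
#' @param dims per-modality feature counts partitioning theta.
#' @param ... unused.
#' @return numeric vector of per-modality weights summing to 1.
#' @export
setMethod("modalityImportance", "numeric", function(object, dims, ...) {
  if (sum(dims) != length(object))
    stop("dims must partition theta: sum(dims) = ", sum(dims),
         " but length(theta) = ", length(object))
  if (abs(sum(object) - 1) > 1e-6)
    stop("theta must sum to 1")
  mi <- vapply(.splitTheta(object, dims), sum, numeric(1))
  names(mi) <- names(dims)
  mi
})

#' Rank features of a fitted model and select a subset
#'
#' @param model a fitted [AGFSModel-class].
#' @param nSelect number of features to select (default 10).
#' @param mode scoring mode, see [featureScores()].
#' @return a [FeatureRanking-class].
#' @examples
#' sim <- simulateMultiModal(nSamples = 60, modalityDims = c(12, 6),
#'                           nInformative = c(3, 2),
#'                           modalityStrength = c(0.6, 0.4), seed = 3)
#' fit <- agfsFit(sim$dataset, agfsParams(alpha = 0.1, beta = 0.1,
#'                                        seed = 3, maxOuterIters = 30))
#' rankFeatures(fit, nSelect = 5)
#' @export
rankFeatures <- function(model, nSelect = 10,
                         mode = c("theta_weighted", "row_norm")) {
  mode <- match.arg(mode)
  s <- featureScores(model, mode)
  ord <- order(-s, seq_along(s))
  new("FeatureRanking",
      scores = unname(s), order = as.integer(ord),
      selected = as.integer(selectTopK(unname(s), nSelect)),
      modality = rep(seq_along(model@dims), model@dims),
      featureNames = model@featureNames,
      modalityImportance = unname(modalityImportance(model)),
      mode = mode)
}

#' @rdname FeatureRanking-class
#' @export
setMethod("selectedFeatures", "FeatureRanking", function(object)
  object@selected)

#' Tabulate a feature ranking
#'
#' @param x a [FeatureRanking-class].
#' @param ... unused.
#' @return data.frame with one row per feature in rank order: rank,
#'   global index, modality, within-modality index, name and score.
#' @export
setMethod("as.data.frame", "FeatureRanking", function(x, ...) {
  ord <- x@order
  within <- sequence(tabulate(x@modality))
  data.frame(rank = seq_along(ord), index = ord,
             modality = x@modality[ord], withinIndex = within[ord],
             feature = x@featureNames[ord], score = x@scores[ord])
})

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking (", object@mode, "): ", length(object@scores),
      " features, ", length(object@selected), " selected\n", sep = "")
  cat("  modality importance:",
      paste(sprintf("%.3f", object@modalityImportance), collapse = ", "),
      "\n")
  print(utils::head(as.data.frame(object), 5))
})
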