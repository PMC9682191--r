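#' Hyperparameters for the anchor-graph feature selection fit
#'
#' Validated constructor for [AGFSParams-class]. \code{alpha} trades off
#' the l2,1 row-sparsity penalty (larger = fewer active features),
#' \code{beta} the anchor-graph smoothness penalty (larger = predictions
#' vary less across strongly connected samples). Both are typically tuned
#' over [alphaBetaGrid()]. The remaining settings control the augmented
#' Lagrangian simplex solver and the outer alternating loop; their
#' defaults rarely need changing.
#'
#' @param alpha positive sparsity weight (default 1e-4; note the
#'   simplex constraint on theta puts a 1/d scale inside the residual,
#'   so useful alpha values are much smaller than in an unweighted
#'   l2,1 regression).
#' @param beta nonnegative graph-smoothness weight (default 0: enable
#'   and tune it when sample-similarity structure in your feature
#'   panels is expected to be informative).
#' @param epsilon l2,1 smoothing constant (default 1e-8).
#' @param mAnchors anchors per modality; NA = min(4*ceiling(sqrt(n)), n).
#' @param kNN nearest anchors per sample (default 5).
#' @param anchorStrategy "random" (default) or "kmeans".
#' @param mu0 initial ALM penalty, in units of the normalized
#'   subproblem (default 1).
#' @param rho ALM penalty growth factor > 1 (default 1.1; inactive at
#'   the default cap).
#' @param muMax ALM penalty cap (default 1 = mu0, i.e. a fixed penalty:
#'   growing the penalty past the problem's curvature stalls the
#'   multiplier iteration, see [solveThetaALM()]).
#' @param almTol ALM feasibility tolerance (default 1e-8).
#' @param maxInnerIters ALM iteration cap (default 5000).
#' @param maxOuterIters outer sweep cap (default 100).
#' @param outerTol relative objective-change stopping rule
#'   |obj(t+1)-obj(t)|/obj(t) <= outerTol (default 1e-5).
#' @param coupling "additive" (default; single concatenated residual,
#'   monotone descent guaranteed) or "independent" (each modality fits
#'   the labels on its own; mirrors the per-modality update equations
#'   verbatim).
#' @param scale z-score features before graph construction and fitting
#'   (default TRUE; modalities of very different native scales share one
#'   alpha, so this is almost always wanted).
#' @param updateTheta if FALSE, freeze the feature weight vector at
#'   uniform 1/d (default TRUE).
#' @param seed integer seed for anchor selection; NA leaves the RNG
#'   state alone.
#' @return an [AGFSParams-class] object.
#' @examples
#' agfsParams(alpha = 0.1, beta = 1, seed = 1)
#' @export
agfsParams <- function(alpha = 1e-4, beta = 0, epsilon = 1e-8,
                       mAnchors = NA, kNN = 5,
                       anchorStrategy = c("random", "kmeans"),
                       mu0 = 1, rho = 1.1, muMax = 1,
                       almTol = 1e-8, maxInnerIters = 5000,
                       maxOuterIters = 100, outerTol = 1e-5,
                       coupling = c("additive", "independent"),
                       scale = TRUE, updateTheta = TRUE, seed = NA) {
  new("AGFSParams",
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      epsilon = as.numeric(epsilon),
      mAnchors = as.integer(mAnchors), kNN = as.integer(kNN),
      anchorStrategy = match.arg(anchorStrategy),
      mu0 = as.numeric(mu0), rho = as.numeric(rho),
      muMax = as.numeric(muMax), almTol = as.numeric(almTol),
      maxInnerIters = as.integer(maxInnerIters),
      maxOuterIters = as.integer(maxOuterIters),
      outerTol = as.numeric(outerTol),
      coupling = match.arg(coupling),
      scale = isTRUE(scale), updateTheta = isTRUE(updateTheta),
      seed = as.integer(seed))
}

setMethod("show", "AGFSParams", function(object) {
  cat("AGFSParams: alpha =", object@alpha, ", beta =", object@beta,
      ", coupling =", object@coupling, "\n",
      " anchors m =", ifelse(is.na(object@mAnchors), "auto",
                             object@mAnchors),
      ", kNN =", object@kNN, ", strategy =", object@anchorStrategy, "\n",
      " outerTol =", object@outerTol, ", maxOuterIters =",
      object@maxOuterIters, "\n")
})

#' The standard log-spaced tuning grid for alpha and beta
#'
#' Seven values spanning six decades, \{1e-3, 1e-2, 1e-1, 1, 10, 1e2,
#' 1e3\}, the customary range for both regularization weights.
#'
#' @return numeric vector of length 7.
#' @export
alphaBetaGrid <- function() 10^seq(-3, 3)
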