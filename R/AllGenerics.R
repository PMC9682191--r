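#' @rdname MultiModalDataset-class
#' @param object,x a \code{MultiModalDataset}
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname MultiModalDataset-class
#' @export
setGeneric("modalityDims", function(object) standardGeneric("modalityDims"))

#' @rdname MultiModalDataset-class
#' @export
setGeneric("modalityNames", function(object) standardGeneric("modalityNames"))

#' @rdname MultiModalDataset-class
#' @export
setGeneric("blocks", function(object) standardGeneric("blocks"))

#' @rdname MultiModalDataset-class
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @rdname MultiModalDataset-class
#' @export
setGeneric("classLevels", function(object) standardGeneric("classLevels"))

#' @rdname MultiModalDataset-class
#' @export
setGeneric("labelFactor", function(object) standardGeneric("labelFactor"))

#' @rdname MultiModalDataset-class
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname AnchorGraph-class
#' @param object an \code{AnchorGraph}
#' @export
setGeneric("anchors", function(object) standardGeneric("anchors"))

#' @rdname AnchorGraph-class
#' @export
setGeneric("anchorDegrees", function(object) standardGeneric("anchorDegrees"))

#' @rdname AGFSModel-class
#' @param object an \code{AGFSModel}
#' @export
setGeneric("weightMatrices", function(object) standardGeneric("weightMatrices"))

#' @rdname AGFSModel-class
#' @export
setGeneric("bias", function(object) standardGeneric("bias"))

#' @rdname AGFSModel-class
#' @export
setGeneric("thetaWeights", function(object) standardGeneric("thetaWeights"))

#' @rdname AGFSModel-class
#' @export
setGeneric("objectiveHistory", function(object) standardGeneric("objectiveHistory"))

#' Per-feature selection scores of a fitted model
#'
#' @param object a fitted \code{AGFSModel}
#' @param mode \code{"theta_weighted"} (default): the l2 norm of each
#'   weight row multiplied by the feature's simplex weight;
#'   \code{"row_norm"}: the plain row norm.
#' @return numeric vector of nonnegative scores, one per feature
#'   (concatenated across modalities).
#' @export
setGeneric("featureScores",
  function(object, mode = c("theta_weighted", "row_norm"))
    standardGeneric("featureScores"))

#' @rdname FeatureRanking-class
#' @param object a \code{FeatureRanking}
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("modalityImportance", function(object, ...) standardGeneric("modalityImportance"))
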