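#' Construct a MultiModalDataset
#'
#' Bundles per-modality feature matrices (samples in rows, identical row
#' order across modalities) with class labels into a validated container.
#'
#' @param blocks list of numeric matrices or data frames, one per
#'   modality, all with the same number of rows.
#' @param y class labels: a factor or vector of length n, or an already
#'   one-hot k-by-n matrix (rows = classes).
#' @param modalityNames optional character names for the blocks; defaults
#'   to names(blocks) or "modality1", ...
#' @param classLevels optional class ordering when \code{y} is a vector;
#'   defaults to the factor levels.
#' @param sampleIDs optional sample identifiers; defaults to row names of
#'   the first block or "S1", ...
#' @return a [MultiModalDataset-class] object.
#' @examples
#' sim <- simulateMultiModal(nSamples = 20, modalityDims = c(5, 3),
#'                           nInformative = c(2, 1),
#'                           modalityStrength = c(0.6, 0.4), seed = 1)
#' sim$dataset
#' @export
multiModalDataset <- function(blocks, y, modalityNames = NULL,
                              classLevels = NULL, sampleIDs = NULL) {
  if (!is.list(blocks)) blocks <- list(blocks)
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  n <- nrow(blocks[[1]])
  if (is.null(modalityNames)) {
    modalityNames <- names(blocks)
    if (is.null(modalityNames) || any(!nzchar(modalityNames)))
      modalityNames <- paste0("modality", seq_along(blocks))
  }
  names(blocks) <- modalityNames
  if (is.matrix(y)) {
    Y <- y
    if (is.null(classLevels)) {
      classLevels <- rownames(Y)
      if (is.null(classLevels)) classLevels <- paste0("class", seq_len(nrow(Y)))
    }
  } else {
    f <- if (is.null(classLevels)) factor(y) else factor(y, levels = classLevels)
    if (anyNA(f))
      stop("labels contain classes not listed in classLevels: ",
           paste(setdiff(unique(as.character(y)), levels(f)), collapse = ", "))
    classLevels <- levels(f)
    Y <- oneHot(f)
  }
  if (is.null(sampleIDs)) {
    sampleIDs <- rownames(blocks[[1]])
    if (is.null(sampleIDs)) sampleIDs <- paste0("S", seq_len(n))
  }
  new("MultiModalDataset", blocks = blocks, labels = Y,
      classLevels = as.character(classLevels),
      modalityNames = as.character(modalityNames),
      sampleIDs = as.character(sampleIDs))
}

#' One-hot encode a factor into a k-by-n {0,1} matrix
#'
#' Each column corresponds to a sample and contains a single 1 in the row
#' of its class; two classes give a 2-by-n matrix, not a signed vector.
#'
#' @param f a factor
#' @return k-by-n numeric matrix with row names = levels(f)
#' @export
oneHot <- function(f) {
  f <- as.factor(f)
  k <- nlevels(f)
  Y <- matrix(0, k, length(f), dimnames = list(levels(f), NULL))
  Y[cbind(as.integer(f), seq_along(f))] <- 1
  Y
}

#' @rdname MultiModalDataset-class
#' @export
setMethod("nSamples", "MultiModalDataset", function(object)
  nrow(object@blocks[[1]]))

#' @rdname MultiModalDataset-class
#' @export
setMethod("modalityDims", "MultiModalDataset", function(object)
  vapply(object@blocks, ncol, integer(1)))

#' @rdname MultiModalDataset-class
#' @export
setMethod("modalityNames", "MultiModalDataset", function(object)
  object@modalityNames)

#' @rdname MultiModalDataset-class
#' @export
setMethod("blocks", "MultiModalDataset", function(object) object@blocks)

#' @rdname MultiModalDataset-class
#' @export
setMethod("labelMatrix", "MultiModalDataset", function(object) object@labels)

#' @rdname MultiModalDataset-class
#' @export
setMethod("classLevels", "MultiModalDataset", function(object)
  object@classLevels)

#' @rdname MultiModalDataset-class
#' @export
setMethod("labelFactor", "MultiModalDataset", function(object) {
  idx <- apply(object@labels, 2, which.max)
  factor(object@classLevels[idx], levels = object@classLevels)
})

#' @rdname MultiModalDataset-class
#' @export
setMethod("sampleIDs", "MultiModalDataset", function(object) object@sampleIDs)

#' @rdname MultiModalDataset-class
#' @param i integer or logical index of samples to keep
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "MultiModalDataset", function(x, i, j, ..., drop = FALSE) {
  new("MultiModalDataset",
      blocks = lapply(x@blocks, function(b) b[i, , drop = FALSE]),
      labels = x@labels[, i, drop = FALSE],
      classLevels = x@classLevels,
      modalityNames = x@modalityNames,
      sampleIDs = x@sampleIDs[i])
})

setMethod("show", "MultiModalDataset", function(object) {
  cat("MultiModalDataset with", nSamples(object), "samples,",
      length(object@blocks), "modalities\n")
  d <- modalityDims(object)
  for (v in seq_along(d))
    cat("  ", object@modalityNames[v], ": ", d[v], " features\n", sep = "")
  tab <- table(labelFactor(object))
  cat("  classes:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})
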