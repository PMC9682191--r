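# File interchange: CSV feature tables with a sample-ID column, a labels
# CSV, JSON model artifacts with an embedded schema version, and a YAML
# run configuration.

MODEL_SCHEMA <- "anchorFS-model-1"

#' Write a MultiModalDataset as CSV files
#'
#' Writes one \code{modality_<name>.csv} per block (first column
#' \code{sampleID}, then named feature columns), a \code{labels.csv}
#' with columns sampleID and label, and, when \code{truth} is given, a
#' \code{ground_truth.json} describing the simulated informative
#' support.
#'
#' @param data a [MultiModalDataset-class].
#' @param dir output directory (created if missing).
#' @param truth optional ground-truth list from [simulateMultiModal()].
#' @return invisibly, the paths written.
#' @export
writeMultiModal <- function(data, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sampleIDs(data)
  paths <- character(0)
  for (v in seq_along(blocks(data))) {
    nm <- modalityNames(data)[v]
    df <- data.frame(sampleID = ids, blocks(data)[[v]],
                     check.names = FALSE)
    p <- file.path(dir, paste0("modality_", nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(sampleID = ids,
                              label = as.character(labelFactor(data))),
                   lp, row.names = FALSE)
  paths <- c(paths, lp)
  if (!is.null(truth)) {
    gp <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
      list(informativeSets = truth$informativeSets,
           classAssignments = as.character(truth$classAssignments),
           modalityStrength = truth$modalityStrength,
           shift = truth$shift),
      gp, auto_unbox = FALSE, digits = NA)
    paths <- c(paths, gp)
  }
  invisible(paths)
}

#' Read a MultiModalDataset from CSV files
#'
#' Accepts either a directory containing \code{modality_*.csv} and
#' \code{labels.csv} (as written by [writeMultiModal()]) or explicit
#' file lists. Each modality table needs a header row, a sample-ID first
#' column and numeric cells; blocks are aligned on the intersection of
#' sample IDs (dropped IDs are reported in a warning) in the order of
#' the label file.
#'
#' @param dir directory to scan (ignored when \code{modalityFiles} is
#'   given).
#' @param modalityFiles optional named character vector of CSV paths.
#' @param labelFile optional path to the labels CSV.
#' @param classLevels optional expected class order; labels outside it
#'   are an error.
#' @return a [MultiModalDataset-class].
#' @export
readMultiModal <- function(dir = NULL, modalityFiles = NULL,
                           labelFile = NULL, classLevels = NULL) {
  if (is.null(modalityFiles)) {
    if (is.null(dir)) stop("give either dir or modalityFiles")
    modalityFiles <- list.files(dir, pattern = "^modality_.*\\.csv$",
                                full.names = TRUE)
    if (!length(modalityFiles))
      stop("no modality_*.csv files found in ", dir)
    names(modalityFiles) <- sub("^modality_(.*)\\.csv$", "\\1",
                                basename(modalityFiles))
    if (is.null(labelFile)) labelFile <- file.path(dir, "labels.csv")
  }
  if (is.null(names(modalityFiles)))
    names(modalityFiles) <- paste0("modality", seq_along(modalityFiles))
  if (is.null(labelFile) || !file.exists(labelFile))
    stop("label file not found: ", labelFile)
  lab <- utils::read.csv(labelFile, check.names = FALSE,
                         colClasses = "character")
  if (ncol(lab) < 2) stop("labels.csv needs sampleID and label columns")
  tabs <- lapply(seq_along(modalityFiles), function(v) {
    p <- modalityFiles[v]
    if (!file.exists(p)) stop("modality file not found: ", p)
    df <- utils::read.csv(p, check.names = FALSE)
    if (ncol(df) < 2) stop(p, ": needs a sample-ID column plus features")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[, -1, drop = FALSE], is.numeric, logical(1)))
      stop(p, ": non-numeric cells in column(s) ",
           paste(colnames(df)[-1][bad], collapse = ", "))
    }
    rownames(m) <- ids
    m
  })
  common <- Reduce(intersect, c(list(as.character(lab[[1]])),
                                lapply(tabs, rownames)))
  if (!length(common)) stop("no sample IDs shared by all files")
  allIDs <- unique(c(as.character(lab[[1]]), unlist(lapply(tabs, rownames))))
  dropped <- setdiff(allIDs, common)
  if (length(dropped))
    warning(length(dropped), " sample ID(s) missing from some file(s) ",
            "were dropped: ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  ord <- as.character(lab[[1]])[as.character(lab[[1]]) %in% common]
  y <- lab[[2]][match(ord, as.character(lab[[1]]))]
  if (!is.null(classLevels) && length(setdiff(unique(y), classLevels)))
    stop("label file contains unexpected class(es): ",
         paste(setdiff(unique(y), classLevels), collapse = ", "))
  blocksAligned <- lapply(tabs, function(m) {
    out <- m[ord, , drop = FALSE]
    storage.mode(out) <- "double"
    out
  })
  names(blocksAligned) <- names(modalityFiles)
  multiModalDataset(blocksAligned, y, classLevels = classLevels,
                    sampleIDs = ord)
}

#' Serialize a fitted model to JSON
#'
#' Full-precision JSON with an embedded schema version;
#' [readModel()] recovers W, b, theta and the objective history exactly.
#'
#' @param model a fitted [AGFSModel-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeModel <- function(model, path) {
  p <- model@params
  obj <- list(
    schema = MODEL_SCHEMA,
    W = lapply(model@W, unname),
    b = unname(model@b),
    theta = model@theta,
    N = model@N,
    objectiveHistory = model@objectiveHistory,
    dims = model@dims,
    modalityNames = model@modalityNames,
    featureNames = model@featureNames,
    classLevels = model@classLevels,
    scaling = model@scaling,
    converged = model@converged,
    nSweeps = model@nSweeps,
    params = list(alpha = p@alpha, beta = p@beta, epsilon = p@epsilon,
                  mAnchors = p@mAnchors, kNN = p@kNN,
                  anchorStrategy = p@anchorStrategy, mu0 = p@mu0,
                  rho = p@rho, muMax = p@muMax, almTol = p@almTol,
                  maxInnerIters = p@maxInnerIters,
                  maxOuterIters = p@maxOuterIters, outerTol = p@outerTol,
                  coupling = p@coupling, scale = p@scale,
                  updateTheta = p@updateTheta, seed = p@seed))
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' Read a model written by [writeModel()]
#'
#' @param path JSON file.
#' @return an [AGFSModel-class].
#' @export
readModel <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file ", path, ": ",
                         conditionMessage(e)))
  if (is.null(obj$schema) || !identical(obj$schema, MODEL_SCHEMA))
    stop("model schema mismatch: expected '", MODEL_SCHEMA, "', found '",
         if (is.null(obj$schema)) "<none>" else obj$schema, "'")
  pp <- obj$params
  params <- agfsParams(alpha = pp$alpha, beta = pp$beta,
                       epsilon = pp$epsilon,
                       mAnchors = if (is.null(pp$mAnchors)) NA else pp$mAnchors,
                       kNN = pp$kNN, anchorStrategy = pp$anchorStrategy,
                       mu0 = pp$mu0, rho = pp$rho, muMax = pp$muMax,
                       almTol = pp$almTol, maxInnerIters = pp$maxInnerIters,
                       maxOuterIters = pp$maxOuterIters,
                       outerTol = pp$outerTol, coupling = pp$coupling,
                       scale = pp$scale, updateTheta = pp$updateTheta,
                       seed = if (is.null(pp$seed)) NA else pp$seed)
  W <- if (is.list(obj$W)) lapply(obj$W, function(w) {
    m <- as.matrix(w)
    storage.mode(m) <- "double"
    m
  }) else list(as.matrix(obj$W))
  scaling <- obj$scaling
  if (length(scaling)) scaling <- lapply(scaling, as.list)
  new("AGFSModel", W = W, b = obj$b, theta = obj$theta,
      N = lapply(obj$N, as.numeric),
      objectiveHistory = obj$objectiveHistory,
      dims = as.integer(obj$dims), modalityNames = obj$modalityNames,
      featureNames = obj$featureNames, classLevels = obj$classLevels,
      params = params, scaling = scaling,
      converged = obj$converged, nSweeps = as.integer(obj$nSweeps))
}

.configDefaults <- function() list(
  modalities = NULL, labels = NULL, outDir = ".",
  alpha = 1e-4, beta = 0, epsilon = 1e-8, mAnchors = NA, kNN = 5,
  anchorStrategy = "random", mu0 = 1, rho = 1.1, muMax = 1,
  almTol = 1e-8, maxInnerIters = 5000, maxOuterIters = 100,
  outerTol = 1e-5, coupling = "additive", scale = TRUE,
  updateTheta = TRUE, seed = 1,
  nFolds = 10, nSelect = c(5, 10, 20, 40),
  alphaGrid = alphaBetaGrid(), betaGrid = alphaBetaGrid(),
  nSamples = 200, modalityDims = c(93, 93, 3), nClasses = 2,
  nInformative = c(10, 10, 1), effectSize = 1.5, noiseSD = 1,
  modalityStrength = c(0.4, 0.4, 0.2))

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file, rejects unknown keys, applies documented defaults
#' (see \code{anchorFS:::.configDefaults()} for the full key set) and
#' validates the hyperparameters by constructing an [AGFSParams-class].
#' Referenced data paths must exist at load time.
#'
#' @param path YAML file; NULL yields pure defaults.
#' @return list with elements \code{config} (the merged key/value list)
#'   and \code{params} (the validated [AGFSParams-class]).
#' @export
loadConfig <- function(path = NULL) {
  defaults <- .configDefaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  for (key in c("modalities", "labels")) {
    for (p in unlist(cfg[[key]]))
      if (!is.null(p) && !file.exists(p))
        stop("config key '", key, "' references a missing file: ", p)
  }
  params <- agfsParams(alpha = cfg$alpha, beta = cfg$beta,
                       epsilon = cfg$epsilon, mAnchors = cfg$mAnchors,
                       kNN = cfg$kNN, anchorStrategy = cfg$anchorStrategy,
                       mu0 = cfg$mu0, rho = cfg$rho, muMax = cfg$muMax,
                       almTol = cfg$almTol,
                       maxInnerIters = cfg$maxInnerIters,
                       maxOuterIters = cfg$maxOuterIters,
                       outerTol = cfg$outerTol, coupling = cfg$coupling,
                       scale = cfg$scale, updateTheta = cfg$updateTheta,
                       seed = cfg$seed)
  list(config = cfg, params = params)
}
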