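# Cross-validation harness: stratified folds, per-fold fit -> select ->
# linear SVM, and acc/sen/spe/auc metrics. Scaling, anchor graphs,
# fitting and feature selection all see training rows only.

#' Stratified k-fold partition
#'
#' Shuffles each class under the seed and deals its members round-robin
#' across folds, so per-class counts across folds differ by at most 1.
#'
#' @param labels factor (or vector coercible to one) of length n.
#' @param nFolds number of folds (default 10).
#' @param seed integer seed.
#' @return list of \code{nFolds} elements, each a list with integer
#'   vectors \code{train} and \code{test}; the test sets partition 1..n.
#' @export
stratifiedKFold <- function(labels, nFolds = 10, seed = NULL) {
  f <- as.factor(labels)
  n <- length(f)
  tab <- table(f)
  if (any(tab < nFolds))
    stop("every class needs at least nFolds members; class ",
         names(tab)[which.min(tab)], " has ", min(tab))
  withSeed(seed, {
    fold <- integer(n)
    for (lv in levels(f)) {
      idx <- sample(which(f == lv))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    lapply(seq_len(nFolds), function(j)
      list(train = which(fold != j), test = which(fold == j)))
  })
}

#' Binary classification metrics: accuracy, sensitivity, specificity, AUC
#'
#' Sensitivity is TP/(TP+FN) and specificity TN/(TN+FP) with respect to
#' the stated positive class; AUC uses the Mann-Whitney rank
#' formulation, ties counting one half. When the truth contains a single
#' class, the undefined metrics are returned as NA rather than 0.
#'
#' @param yTrue,yPred vectors of true and predicted class labels.
#' @param yScore real-valued scores, larger meaning more positive
#'   (needed for AUC; may be NULL).
#' @param positive the positive class label (default: first level of
#'   \code{yTrue} as a factor).
#' @return named numeric vector c(acc, sen, spe, auc).
#' @examples
#' binaryMetrics(c(1,1,1,1,0,0,0,0,0,0), c(1,1,1,0,0,0,0,0,1,1),
#'               positive = 1)  # sen 0.75, spe 2/3, acc 0.7
#' @export
binaryMetrics <- function(yTrue, yPred, yScore = NULL, positive = NULL) {
  yTrue <- as.factor(yTrue)
  if (is.null(positive)) positive <- levels(yTrue)[1]
  tp <- sum(yTrue == positive & yPred == positive)
  fn <- sum(yTrue == positive & yPred != positive)
  tn <- sum(yTrue != positive & yPred != positive)
  fp <- sum(yTrue != positive & yPred == positive)
  acc <- (tp + tn) / length(yTrue)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- NA_real_
  if (!is.null(yScore) && tp + fn > 0 && tn + fp > 0) {
    r <- rank(yScore)                         # midranks handle ties as 1/2
    nPos <- tp + fn
    nNeg <- tn + fp
    auc <- (sum(r[yTrue == positive]) - nPos * (nPos + 1) / 2) /
      (nPos * nNeg)
  }
  c(acc = acc, sen = sen, spe = spe, auc = auc)
}

# trainer contract: function(x, y) -> list(predict = function(x) labels,
# score = function(x) real scores increasing toward the positive class)
.svmTrainer <- function(positive) {
  function(x, y) {
    y <- droplevels(as.factor(y))
    fit <- e1071::svm(x, y, kernel = "linear", scale = FALSE)
    list(
      predict = function(newx) stats::predict(fit, newx),
      score = function(newx) {
        p <- stats::predict(fit, newx, decision.values = TRUE)
        dv <- attr(p, "decision.values")
        lab <- colnames(dv)[1]            # "A/B": positive dv favors A
        s <- dv[, 1]
        first <- strsplit(lab, "/")[[1]][1]
        if (identical(first, as.character(positive))) s else -s
      })
  }
}

#' Cross-validated evaluation of the feature selector
#'
#' For each stratified fold: z-scoring statistics, anchor graphs, the
#' selector fit and the feature ranking are computed on the training
#' rows only; the top \code{nSelect} features (global indices across the
#' concatenated modalities) are passed to a linear maximum-margin
#' classifier (support vector machine), which is evaluated on the
#' held-out fold.
#'
#' @param data a [MultiModalDataset-class] with two classes.
#' @param params an [AGFSParams-class].
#' @param nSelect number of features given to the classifier (default 10).
#' @param nFolds folds (default 10).
#' @param seed integer seed for the fold split.
#' @param positive positive class for sen/spe/auc (default: first class
#'   level).
#' @param trainer optional classifier factory replacing the SVM; a
#'   function(x, y) returning list(predict = ., score = .).
#' @return list with \code{perFold} (data.frame of acc/sen/spe/auc per
#'   fold), \code{mean} and \code{sd} (named vectors), \code{selected}
#'   (list of per-fold selected index vectors), and the call settings.
#' @export
crossValidate <- function(data, params = agfsParams(), nSelect = 10,
                          nFolds = 10, seed = NULL, positive = NULL,
                          trainer = NULL) {
  y <- labelFactor(data)
  if (nlevels(y) != 2)
    stop("the evaluation harness is defined for two classes")
  if (is.null(positive)) positive <- levels(y)[1]
  if (is.null(trainer)) trainer <- .svmTrainer(positive)
  folds <- stratifiedKFold(y, nFolds, seed)
  perFold <- matrix(NA_real_, nFolds, 4,
                    dimnames = list(NULL, c("acc", "sen", "spe", "auc")))
  selected <- vector("list", nFolds)
  for (j in seq_len(nFolds)) {
    tr <- folds[[j]]$train
    te <- folds[[j]]$test
    fit <- agfsFit(data[tr], params)
    rk <- rankFeatures(fit, nSelect = nSelect)
    sel <- rk@selected
    selected[[j]] <- sel
    trBlocks <- .applyScaling(blocks(data[tr]), fit@scaling)
    teBlocks <- .applyScaling(blocks(data[te]), fit@scaling)
    xTr <- do.call(cbind, trBlocks)[, sel, drop = FALSE]
    xTe <- do.call(cbind, teBlocks)[, sel, drop = FALSE]
    clf <- trainer(xTr, y[tr])
    pred <- clf$predict(xTe)
    sco <- clf$score(xTe)
    perFold[j, ] <- binaryMetrics(y[te], pred, sco, positive)
  }
  perFold <- as.data.frame(perFold)
  list(perFold = perFold,
       mean = colMeans(perFold, na.rm = TRUE),
       sd = apply(perFold, 2, stats::sd, na.rm = TRUE),
       selected = selected,
       settings = list(nSelect = nSelect, nFolds = nFolds, seed = seed,
                       positive = positive, alpha = params@alpha,
                       beta = params@beta, coupling = params@coupling))
}

#' Sensitivity sweep over the alpha/beta grid
#'
#' Runs [crossValidate()] for every (alpha, beta) cell and tabulates the
#' mean and standard deviation of the four metrics — the numeric
#' analogue of a parameter-sensitivity surface. Cells are independent,
#' so results do not depend on grid ordering. The full table is
#' reported; no test-best cell is silently picked.
#'
#' @param data a [MultiModalDataset-class].
#' @param alphaGrid,betaGrid numeric vectors (default [alphaBetaGrid()]).
#' @param nSelect features passed to the classifier per cell.
#' @param nFolds,seed,params as in [crossValidate()]; \code{params}
#'   supplies all non-grid settings.
#' @return data.frame with one row per (alpha, beta): the grid values,
#'   then mean and sd of acc/sen/spe/auc.
#' @export
gridSearch <- function(data, alphaGrid = alphaBetaGrid(),
                       betaGrid = alphaBetaGrid(), nSelect = 10,
                       nFolds = 10, seed = NULL, params = agfsParams()) {
  if (!length(alphaGrid) || !length(betaGrid)) stop("empty grid")
  cells <- expand.grid(alpha = alphaGrid, beta = betaGrid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- params
    p@alpha <- cells$alpha[i]
    p@beta <- cells$beta[i]
    cv <- crossValidate(data, p, nSelect = nSelect, nFolds = nFolds,
                        seed = seed)
    data.frame(alpha = cells$alpha[i], beta = cells$beta[i],
               nSelect = nSelect,
               accMean = cv$mean["acc"], accSD = cv$sd["acc"],
               senMean = cv$mean["sen"], senSD = cv$sd["sen"],
               speMean = cv$mean["spe"], speSD = cv$sd["spe"],
               aucMean = cv$mean["auc"], aucSD = cv$sd["auc"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}
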