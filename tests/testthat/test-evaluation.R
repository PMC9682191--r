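test_that("stratified folds partition the samples with balanced classes", {
  y <- factor(rep(c("a", "b"), each = 10))
  folds <- stratifiedKFold(y, 10, seed = 1)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:20)
  for (f in folds) {
    expect_equal(sum(y[f$test] == "a"), 1)
    expect_equal(sum(y[f$test] == "b"), 1)
    expect_equal(sort(c(f$train, f$test)), 1:20)
  }
  expect_identical(stratifiedKFold(y, 10, seed = 1),
                   stratifiedKFold(y, 10, seed = 1))
  expect_error(stratifiedKFold(factor(c("a", "a", "b")), 2),
               "at least nFolds")
})

test_that("per-class fold counts never differ by more than one", {
  set.seed(2)
  y <- factor(sample(c("x", "y", "z"), 47, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)))
  folds <- stratifiedKFold(y, 4, seed = 3)
  for (lv in levels(y)) {
    cnt <- vapply(folds, function(f) sum(y[f$test] == lv), integer(1))
    expect_lte(max(cnt) - min(cnt), 1)
  }
})

test_that("binary metrics reproduce hand-computed contingency values", {
  # TP=3 FN=1 TN=4 FP=2 with positive = 1
  yt <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  yp <- c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1)
  m <- binaryMetrics(yt, yp, positive = 1)
  expect_equal(unname(m["sen"]), 0.75)
  expect_equal(unname(m["spe"]), 2 / 3)
  expect_equal(unname(m["acc"]), 0.7)
  # perfect prediction and separation
  sc <- c(5, 4, 3, 2, 1, 0, -1, -2, -3, -4)
  yp2 <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  m2 <- binaryMetrics(yt, yp2, sc, positive = 1)
  expect_equal(unname(m2), c(1, 1, 1, 1))
})

test_that("AUC uses midranks so ties count one half", {
  yt <- c(1, 1, 0, 0)
  sc <- c(2, 1, 1, 0)   # one tie across classes: AUC = (1 + 1 + 1 + 0.5)/4
  m <- binaryMetrics(yt, c(1, 1, 0, 0), sc, positive = 1)
  expect_equal(unname(m["auc"]), 3.5 / 4)
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(4)
  yt <- rep(c(1, 0), each = 500)
  sc <- rnorm(1000)
  m <- binaryMetrics(yt, ifelse(sc > 0, 1, 0), sc, positive = 1)
  # SE of the Mann-Whitney AUC under the null is about sqrt(1/12 (1/n1+1/n0))
  se <- sqrt((1 / 12) * (1 / 500 + 1 / 500))
  expect_lt(abs(m["auc"] - 0.5), 3 * se)
})

test_that("single-class truth yields NA metrics, not zero", {
  m <- binaryMetrics(c(1, 1, 1), c(1, 0, 1), c(3, 1, 2), positive = 1)
  expect_true(is.na(m["spe"]))
  expect_true(is.na(m["auc"]))
  expect_equal(unname(m["sen"]), 2 / 3)
})

test_that("cross-validation runs end to end on the worked example", {
  ex <- workedExample()
  cv <- crossValidate(ex$dataset, agfsParams(alpha = 1e-3, beta = 0),
                      nSelect = 3, nFolds = 2, seed = 5)
  expect_equal(nrow(cv$perFold), 2)
  expect_true(all(cv$perFold$acc >= 0 & cv$perFold$acc <= 1))
  expect_length(cv$selected, 2)
})

test_that("fold models never see held-out rows", {
  sim <- simulateMultiModal(nSamples = 40, modalityDims = c(8, 4),
                            nInformative = c(3, 1), effectSize = 2,
                            modalityStrength = c(0.7, 0.3), seed = 6)
  p <- agfsParams(seed = 6)
  cv <- crossValidate(sim$dataset, p, nSelect = 4, nFolds = 4, seed = 7)
  # corrupt the held-out rows of fold 1 and refit: the training-side
  # state (selected features) must be unchanged
  folds <- stratifiedKFold(labelFactor(sim$dataset), 4, seed = 7)
  b2 <- blocks(sim$dataset)
  for (v in seq_along(b2)) b2[[v]][folds[[1]]$test, ] <- 1e6
  ds2 <- multiModalDataset(b2, labelFactor(sim$dataset))
  fit2 <- agfsFit(ds2[folds[[1]]$train], p)
  expect_equal(rankFeatures(fit2, 4)@selected, cv$selected[[1]])
})

test_that("a degenerate 1x1 grid equals a single cross-validation", {
  sim <- simulateMultiModal(nSamples = 30, modalityDims = c(6, 3),
                            nInformative = c(2, 1), effectSize = 2,
                            modalityStrength = c(0.7, 0.3), seed = 8)
  p <- agfsParams(alpha = 1e-3, beta = 0, seed = 8)
  tab <- gridSearch(sim$dataset, alphaGrid = 1e-3, betaGrid = 0,
                    nSelect = 3, nFolds = 3, seed = 9, params = p)
  cv <- crossValidate(sim$dataset, p, nSelect = 3, nFolds = 3, seed = 9)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$accMean, unname(cv$mean["acc"]))
  expect_equal(tab$aucSD, unname(cv$sd["auc"]))
})

test_that("grid results are valid metrics for every cell", {
  sim <- simulateMultiModal(nSamples = 30, modalityDims = c(6, 3),
                            nInformative = c(2, 1), effectSize = 2,
                            modalityStrength = c(0.7, 0.3), seed = 10)
  tab <- gridSearch(sim$dataset, alphaGrid = c(1e-4, 1e-2),
                    betaGrid = c(0, 1e-3), nSelect = 3, nFolds = 3,
                    seed = 11, params = agfsParams(seed = 10))
  expect_equal(nrow(tab), 4)
  mcols <- c("accMean", "senMean", "speMean", "aucMean")
  expect_true(all(tab[, mcols] >= 0 & tab[, mcols] <= 1))
})
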