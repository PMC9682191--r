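# small random fixture shared by the optimizer tests
smallState <- function(seed = 1, n = 12, dims = c(5, 3), k = 2) {
  set.seed(seed)
  blocks <- lapply(dims, function(dv) matrix(rnorm(n * dv), n, dv))
  Y <- oneHot(factor(rep_len(paste0("c", 1:k), n)))
  W <- lapply(dims, function(dv) matrix(rnorm(dv * k, sd = 0.5), dv, k))
  theta <- abs(rnorm(sum(dims))); theta <- theta / sum(theta)
  b <- rnorm(k)
  graphs <- lapply(blocks, function(X)
    buildAnchorGraph(X, m = 6, kNN = 2, seed = seed))
  list(blocks = blocks, Y = Y, W = W, theta = theta, b = b,
       graphs = graphs, dims = dims, n = n, k = k)
}

test_that("objective matches a naive term-by-term recomputation", {
  st <- smallState(3)
  p <- agfsParams(alpha = 0.7, beta = 0.3, epsilon = 1e-6)
  val <- agfsObjective(st$W, st$b, st$theta, st$blocks, st$Y, st$graphs, p)
  # naive: explicit matrices, explicit loops
  offs <- c(0, cumsum(st$dims)[-length(st$dims)])
  fitSum <- matrix(0, st$k, st$n)
  pen <- 0; graphTerm <- 0
  for (v in seq_along(st$blocks)) {
    thv <- st$theta[offs[v] + seq_len(st$dims[v])]
    Fv <- t(st$W[[v]]) %*% diag(thv) %*% t(st$blocks[[v]])
    fitSum <- fitSum + Fv
    for (i in seq_len(st$dims[v]))
      pen <- pen + sqrt(sum(st$W[[v]][i, ]^2) + 1e-6)
    L <- diag(st$n) - st$graphs[[v]]@B %*% t(st$graphs[[v]]@B)
    XW <- st$blocks[[v]] %*% st$W[[v]]
    graphTerm <- graphTerm + sum(diag(t(XW) %*% L %*% XW))
  }
  R <- fitSum + st$b %*% t(rep(1, st$n)) - st$Y
  expect_equal(val, sum(R^2) + 0.7 * pen + 0.3 * graphTerm,
               tolerance = 1e-10)
})

test_that("objective reduces to ||Y||^2 at the zero model and ignores beta there", {
  st <- smallState(4)
  W0 <- lapply(st$dims, function(dv) matrix(0, dv, st$k))
  p0 <- agfsParams(alpha = 1, beta = 0, epsilon = 1e-300)
  expect_equal(agfsObjective(W0, numeric(st$k), st$theta, st$blocks, st$Y,
                             NULL, p0),
               sum(st$Y^2), tolerance = 1e-9)
  p1 <- agfsParams(alpha = 1, beta = 1, epsilon = 1e-300)
  expect_equal(agfsObjective(W0, numeric(st$k), st$theta, st$blocks, st$Y,
                             st$graphs, p1),
               sum(st$Y^2), tolerance = 1e-9)
})

test_that("bias update zeroes the numeric gradient in both couplings", {
  st <- smallState(5)
  for (coupling in c("additive", "independent")) {
    b <- updateBias(st$W, st$theta, st$blocks, st$Y, coupling)
    p <- agfsParams(alpha = 1e-4, beta = 0, coupling = coupling)
    loss <- function(bv)
      agfsObjective(st$W, bv, st$theta, st$blocks, st$Y, NULL, p)
    g <- vapply(seq_along(b), function(j) {
      h <- 1e-6
      e <- numeric(length(b)); e[j] <- h
      (loss(b + e) - loss(b - e)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g)), 1e-7)
  }
})

test_that("bias update reduces to label row means at W = 0 and is exact at n = 1", {
  st <- smallState(6)
  W0 <- lapply(st$dims, function(dv) matrix(0, dv, st$k))
  expect_equal(updateBias(W0, st$theta, st$blocks, st$Y), rowMeans(st$Y))
  # single sample: b = y_1 - W' Theta x_1
  b1 <- lapply(st$blocks, function(X) X[1, , drop = FALSE])
  bb <- updateBias(st$W, st$theta, b1, st$Y[, 1, drop = FALSE])
  offs <- c(0, cumsum(st$dims)[-length(st$dims)])
  pred <- Reduce(`+`, lapply(seq_along(b1), function(v) {
    thv <- st$theta[offs[v] + seq_len(st$dims[v])]
    drop(crossprod(st$W[[v]], thv * drop(b1[[v]])))
  }))
  expect_equal(bb, drop(st$Y[, 1]) - pred, tolerance = 1e-12)
})

test_that("weight update satisfies its stationarity system", {
  st <- smallState(7)
  p <- agfsParams(alpha = 0.05, beta = 0.2, epsilon = 1e-8)
  for (v in seq_along(st$blocks)) {
    Wnew <- st$W
    Nv <- rowReweight(st$W[[v]], p@epsilon)
    Wnew[[v]] <- updateWeights(st$W, st$b, st$theta, st$blocks, st$Y,
                               st$graphs, p, v, Nv = Nv)
    # rebuild the linear system and check the residual
    offs <- c(0, cumsum(st$dims)[-length(st$dims)])
    thv <- st$theta[offs[v] + seq_len(st$dims[v])]
    Xv <- st$blocks[[v]]
    Xt <- sweep(Xv, 2, thv, "*")
    L <- diag(st$n) - st$graphs[[v]]@B %*% t(st$graphs[[v]]@B)
    A <- crossprod(Xt) + diag(p@alpha * Nv, st$dims[v]) +
      p@beta * t(Xv) %*% L %*% Xv
    others <- setdiff(seq_along(st$blocks), v)
    Yt <- st$Y - Reduce(`+`, lapply(others, function(u) {
      thu <- st$theta[offs[u] + seq_len(st$dims[u])]
      t(st$blocks[[u]] %*% (st$W[[u]] * thu))
    }))
    rhs <- crossprod(Xt, t(Yt - st$b))
    expect_lt(norm(A %*% Wnew[[v]] - rhs, "F") / norm(rhs, "F"), 1e-8)
  }
})

test_that("weight update matches least squares when the penalties vanish", {
  set.seed(8)
  n <- 40; dv <- 4; k <- 2
  X <- matrix(rnorm(n * dv), n, dv)
  Y <- oneHot(factor(rep_len(c("a", "b"), n)))
  theta <- rep(1 / dv, dv)
  b <- rnorm(k)
  p <- agfsParams(alpha = 1e-10, beta = 0)
  W <- updateWeights(list(matrix(0, dv, k)), b, theta, list(X), Y,
                     NULL, p, 1)
  Xt <- X / dv
  Wols <- solve(crossprod(Xt), crossprod(Xt, t(Y - b)))
  expect_equal(W, Wols, tolerance = 1e-6)
})

test_that("larger alpha shrinks the one-step weight update", {
  set.seed(9)
  st <- smallState(9)
  W0 <- lapply(st$dims, function(dv) matrix(0, dv, st$k))
  norms <- vapply(c(1, 1e6), function(a) {
    p <- agfsParams(alpha = a, beta = 0)
    Wv <- updateWeights(W0, st$b, st$theta, st$blocks, st$Y, NULL, p, 1)
    norm(Wv, "F")
  }, numeric(1))
  expect_lt(norms[2], norms[1])
})

test_that("row reweighting follows 1/(2 sqrt(||w||^2 + eps))", {
  expect_equal(rowReweight(matrix(0, 1, 3), 1e-8), 5000)
  expect_equal(rowReweight(matrix(c(1, 0, 0), 1, 3), 1e-300), 0.5)
  W <- matrix(rnorm(12), 4, 3)
  expect_true(all(rowReweight(3 * W, 1e-8) < rowReweight(W, 1e-8)))
  expect_true(all(is.finite(rowReweight(matrix(0, 5, 2), 1e-8))))
})

test_that("hadamard trace identity tr(ABAC) = a'(B' o C)a holds", {
  expect_equal(hadamardTrace(rep(1, 4),
                             matrix(1:16, 4), matrix(16:1, 4)),
               sum(diag(matrix(1:16, 4) %*% matrix(16:1, 4))))
  expect_equal(hadamardTrace(numeric(3), diag(3), diag(3)), 0)
  set.seed(10)
  for (i in 1:100) {
    a <- rnorm(5); B <- matrix(rnorm(25), 5); C <- matrix(rnorm(25), 5)
    dense <- sum(diag(diag(a) %*% B %*% diag(a) %*% C))
    expect_equal(hadamardTrace(a, B, C), dense, tolerance = 1e-10)
  }
  expect_error(hadamardTrace(rnorm(3), diag(4), diag(4)), "d-by-d")
})

test_that("theta subproblem reproduces the centered trace objective", {
  st <- smallState(11)
  sub <- thetaSubproblem(st$W, st$blocks, st$Y)
  expect_equal(sub$Q, t(sub$Q))
  # dense oracle with the explicit centering matrix
  X <- do.call(cbind, st$blocks)
  H <- diag(st$n) - matrix(1 / st$n, st$n, st$n)
  Wstack <- do.call(rbind, st$W)
  Th <- diag(st$theta)
  lhs <- sum(diag(Th %*% t(X) %*% H %*% X %*% Th %*% Wstack %*% t(Wstack))) -
         sum(diag(2 * Th %*% t(X) %*% H %*% t(st$Y) %*% t(Wstack)))
  rhs <- drop(st$theta %*% sub$Q %*% st$theta) - sum(st$theta * sub$s)
  expect_equal(rhs, lhs, tolerance = 1e-9)
})

test_that("theta subproblem vanishes for zero weights and constant columns", {
  st <- smallState(12)
  W0 <- lapply(st$dims, function(dv) matrix(0, dv, st$k))
  sub <- thetaSubproblem(W0, st$blocks, st$Y)
  expect_equal(sub$Q, matrix(0, sum(st$dims), sum(st$dims)))
  expect_equal(sub$s, rep(0, sum(st$dims)))
  constBlocks <- lapply(st$dims, function(dv)
    matrix(rep(rnorm(dv), each = st$n), st$n, dv))
  sub2 <- thetaSubproblem(st$W, constBlocks, st$Y)
  expect_equal(max(abs(sub2$Q)), 0, tolerance = 1e-20)
})

test_that("the simplex solver reproduces hand-solvable programs", {
  expect_equal(solveThetaALM(diag(2), c(0, 0)), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_equal(solveThetaALM(diag(2), c(2, 0)), c(1, 0),
               tolerance = 1e-6)
  th <- solveThetaALM(matrix(0, 4, 4), rep(0, 4))
  expect_equal(sum(th), 1, tolerance = 1e-9)
  expect_true(all(th >= -1e-8))
  expect_error(solveThetaALM(matrix(c(1, 2, 0, 1), 2), c(0, 0)),
               "symmetric")
})

test_that("the simplex solver matches brute-force and projected-gradient oracles", {
  set.seed(13)
  for (i in 1:3) {
    A <- matrix(rnorm(9), 3); Q <- crossprod(A) / 3; s <- rnorm(3)
    th <- solveThetaALM(Q, s)
    expect_lt(simplexQPObjective(th, Q, s) - gridSimplex3(Q, s), 1e-4)
  }
  for (i in 1:3) {
    d <- 20
    A <- matrix(rnorm(d * d), d); Q <- crossprod(A) / d; s <- rnorm(d)
    th <- solveThetaALM(Q, s)
    ref <- pgdSimplex(Q, s)
    expect_lt(abs(simplexQPObjective(th, Q, s) -
                  simplexQPObjective(ref, Q, s)), 1e-6)
    expect_equal(sum(th), 1, tolerance = 1e-6)
    expect_gte(min(th), -1e-8)
  }
})

test_that("fitting degenerate single-class labels converges immediately", {
  set.seed(14)
  blocks <- list(matrix(rnorm(60), 20, 3))
  Y <- rbind(rep(1, 20), rep(0, 20))
  rownames(Y) <- c("only", "never")
  ds <- multiModalDataset(blocks, Y)
  fit <- agfsFit(ds, agfsParams(alpha = 1e-2, beta = 0))
  expect_true(fit@converged)
  expect_lte(fit@nSweeps, 3)
  expect_lt(max(abs(do.call(rbind, weightMatrices(fit)))), 1e-2)
  expect_equal(unname(bias(fit)), c(1, 0), tolerance = 1e-2)
})

test_that("fit produces a monotone objective and a feasible theta", {
  sim <- simulateMultiModal(nSamples = 60, modalityDims = c(10, 6),
                            nInformative = c(3, 2),
                            modalityStrength = c(0.6, 0.4), seed = 15)
  fit <- agfsFit(sim$dataset, agfsParams(beta = 1e-4, seed = 15))
  h <- objectiveHistory(fit)
  expect_true(all(diff(h) <= h[-length(h)] * 1e-6))
  expect_equal(sum(thetaWeights(fit)), 1, tolerance = 1e-6)
  expect_gte(min(thetaWeights(fit)), -1e-8)
})

test_that("a tightly converged fit is a block fixed point", {
  sim <- simulateMultiModal(nSamples = 60, modalityDims = c(10, 6),
                            nInformative = c(3, 2),
                            modalityStrength = c(0.6, 0.4), seed = 16)
  p <- agfsParams(seed = 16, outerTol = 1e-10, maxOuterIters = 400)
  fit <- agfsFit(sim$dataset, p)
  Xs <- anchorFS:::.applyScaling(blocks(sim$dataset), fit@scaling)
  Y <- labelMatrix(sim$dataset)
  W <- weightMatrices(fit); theta <- thetaWeights(fit); b <- bias(fit)
  # the bias normal equation holds at the final state
  bNew <- updateBias(W, theta, Xs, Y)
  expect_lt(max(abs(b - bNew)), 1e-6 * (1 + max(abs(b))))
  # one extra full sweep cannot improve the objective materially
  prev <- tail(objectiveHistory(fit), 1)
  b <- bNew
  for (v in seq_along(Xs))
    W[[v]] <- updateWeights(W, b, theta, Xs, Y, NULL, p, v)
  sub <- thetaSubproblem(W, Xs, Y)
  theta <- solveThetaALM(sub$Q, sub$s, p, theta0 = theta)
  b <- updateBias(W, theta, Xs, Y)
  cur <- agfsObjective(W, b, theta, Xs, Y, NULL, p)
  expect_lte(cur, prev * (1 + 1e-12))
  expect_gte(cur, prev * (1 - 1e-6))
})

test_that("independent coupling runs and honors the printed per-modality form", {
  sim <- simulateMultiModal(nSamples = 40, modalityDims = c(8, 4),
                            nInformative = c(2, 1),
                            modalityStrength = c(0.6, 0.4), seed = 17)
  fit <- agfsFit(sim$dataset,
                 agfsParams(coupling = "independent", seed = 17,
                            maxOuterIters = 40))
  expect_equal(sum(thetaWeights(fit)), 1, tolerance = 1e-6)
  expect_gte(min(thetaWeights(fit)), -1e-8)
  # independent objective counts each modality's residual separately
  st <- smallState(18)
  pi <- agfsParams(alpha = 1, beta = 0, coupling = "independent",
                   epsilon = 1e-300)
  pa <- agfsParams(alpha = 1, beta = 0, coupling = "additive",
                   epsilon = 1e-300)
  oi <- agfsObjective(st$W, st$b, st$theta, st$blocks, st$Y, NULL, pi)
  offs <- c(0, cumsum(st$dims)[-length(st$dims)])
  manual <- sum(vapply(seq_along(st$blocks), function(v) {
    thv <- st$theta[offs[v] + seq_len(st$dims[v])]
    Fv <- t(st$blocks[[v]] %*% (st$W[[v]] * thv))
    sum((Fv + st$b - st$Y)^2)
  }, numeric(1))) + sum(vapply(st$W, function(w)
    sum(sqrt(rowSums(w^2) + 1e-300)), numeric(1)))
  expect_equal(oi, manual, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(oi,
    agfsObjective(st$W, st$b, st$theta, st$blocks, st$Y, NULL, pa))))
})

test_that("grid-extreme hyperparameters terminate with feasible theta", {
  sim <- simulateMultiModal(nSamples = 40, modalityDims = c(8, 4),
                            nInformative = c(2, 1),
                            modalityStrength = c(0.6, 0.4), seed = 19)
  for (ab in list(c(1e-3, 1e-3), c(1e-3, 1e3), c(1e3, 1e-3), c(1e3, 1e3))) {
    fit <- agfsFit(sim$dataset,
                   agfsParams(alpha = ab[1], beta = ab[2], seed = 19,
                              maxOuterIters = 60))
    expect_equal(sum(thetaWeights(fit)), 1, tolerance = 1e-6)
    expect_gte(min(thetaWeights(fit)), -1e-8)
  }
})

test_that("with beta 0 and frozen theta the fit solves smoothed l2,1 least squares", {
  sim <- simulateMultiModal(nSamples = 50, modalityDims = c(8, 4),
                            nInformative = c(2, 1),
                            modalityStrength = c(0.6, 0.4), seed = 20)
  p <- agfsParams(alpha = 1e-3, beta = 0, updateTheta = FALSE,
                  outerTol = 1e-9, maxOuterIters = 500)
  fit <- agfsFit(sim$dataset, p)
  Xs <- anchorFS:::.applyScaling(blocks(sim$dataset), fit@scaling)
  X <- do.call(cbind, Xs)
  d <- ncol(X)
  ref <- irlsSmoothedL21(X, labelMatrix(sim$dataset), rep(1 / d, d),
                         alpha = 1e-3)
  got <- tail(objectiveHistory(fit), 1)
  expect_lt(abs(got - ref$objective) / ref$objective, 1e-6)
})
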