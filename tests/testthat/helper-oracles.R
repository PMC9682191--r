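# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Euclidean projection onto the probability simplex (sort-based)
projSimplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  pmax(v + (1 - css[rho]) / rho, 0)
}

# projected-gradient solver for min t'Qt - t's on the simplex
pgdSimplex <- function(Q, s, iters = 20000) {
  d <- length(s)
  x <- rep(1 / d, d)
  L <- 2 * max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values) + 1
  for (i in seq_len(iters))
    x <- projSimplex(x - drop(2 * (Q %*% x) - s) / L)
  x
}

simplexQPObjective <- function(t, Q, s) drop(t %*% Q %*% t) - sum(t * s)

# brute-force grid over the 3-simplex at the given resolution
gridSimplex3 <- function(Q, s, res = 1e-3) {
  g <- seq(0, 1, by = res)
  best <- Inf
  for (a in g) {
    b <- seq(0, 1 - a, by = res)
    c3 <- 1 - a - b
    vals <- Q[1, 1] * a^2 + Q[2, 2] * b^2 + Q[3, 3] * c3^2 +
      2 * Q[1, 2] * a * b + 2 * Q[1, 3] * a * c3 + 2 * Q[2, 3] * b * c3 -
      (s[1] * a + s[2] * b + s[3] * c3)
    best <- min(best, min(vals))
  }
  best
}

# dense-matrix Laplacian quadratic form oracle
denseLaplacianQuad <- function(B, M) {
  L <- diag(nrow(B)) - B %*% t(B)
  sum(diag(t(M) %*% L %*% M))
}

# independent iteratively-reweighted solver for the smoothed l2,1
# least-squares problem min ||W' D X' + b 1' - Y||^2 + a * S_i
# sqrt(w_i'w_i + eps), D a fixed diagonal; solves on the concatenated
# design with its own centering-based bias handling
irlsSmoothedL21 <- function(X, Y, dscale, alpha, eps = 1e-8,
                            maxIter = 2000, tol = 1e-12) {
  Xt <- sweep(X, 2, dscale, "*")
  n <- nrow(Xt)
  Xc <- scale(Xt, center = TRUE, scale = FALSE)
  Yc <- Y - rowMeans(Y)
  d <- ncol(Xt)
  W <- matrix(0, d, nrow(Y))
  obj <- function(W) {
    b <- rowMeans(Y) - drop(crossprod(W, colMeans(Xt)))
    sum((t(Xt %*% W) + b - Y)^2) +
      alpha * sum(sqrt(rowSums(W^2) + eps))
  }
  prev <- obj(W)
  for (i in seq_len(maxIter)) {
    Nv <- 1 / (2 * sqrt(rowSums(W^2) + eps))
    W <- solve(crossprod(Xc) + diag(alpha * Nv, d), crossprod(Xc, t(Yc)))
    cur <- obj(W)
    if (abs(prev - cur) <= tol * max(1, abs(prev))) break
    prev <- cur
  }
  list(W = W, objective = cur)
}

# indices of the planted informative features in the concatenated space
globalSupport <- function(truth, dims) {
  offs <- c(0, cumsum(dims)[-length(dims)])
  unlist(lapply(seq_along(dims), function(v) offs[v] + truth$informativeSets[[v]]))
}

# small random row-stochastic k-sparse affinity via the package-free route
randomAffinityInstance <- function(seed) {
  set.seed(seed)
  n <- sample(5:20, 1)
  d <- sample(2:6, 1)
  m <- sample(3:min(n, 8), 1)
  k <- sample(seq_len(m - 1), 1)
  X <- matrix(rnorm(n * d), n, d)
  A <- X[sample.int(n, m), , drop = FALSE] +
    matrix(rnorm(m * d, sd = 0.1), m, d)
  list(X = X, A = A, k = k, n = n, m = m)
}
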