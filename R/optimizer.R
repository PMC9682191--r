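# Alternating minimization of the joint objective
#
#   sum_v ||W_v' Theta_v X_v' + b 1' - Y||_F^2  (or one concatenated
#   residual in additive coupling) + alpha sum_v ||W_v||_{2,1}
#   + beta sum_v tr(W_v' X_v' (I - B B')_v X_v W_v)
#   s.t. theta >= 0, sum(theta) = 1
#
# with closed-form bias, iteratively reweighted closed-form W_v, and an
# augmented-Lagrangian solver for the simplex-constrained theta step.
# The l2,1 norm is smoothed as sum_i sqrt(w_i'w_i + epsilon) throughout,
# which is what the reweighted update actually minimizes, so monotone
# descent of the recorded objective is exact, not approximate.

.splitTheta <- function(theta, dims) {
  ends <- cumsum(dims)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(dims), function(v) theta[starts[v]:ends[v]])
}

.modalityFit <- function(Xv, Wv, thetav) {
  # k x n contribution W_v' Theta_v X_v'
  t(Xv %*% (Wv * thetav))
}

#' Smoothed l2,1 norm of a matrix
#'
#' \eqn{\sum_i \sqrt{w_i^T w_i + \epsilon}} over rows; reduces to the sum
#' of row l2 norms as epsilon goes to 0.
#'
#' @param W numeric matrix.
#' @param epsilon nonnegative smoothing constant.
#' @return scalar.
#' @export
smoothedL21 <- function(W, epsilon = 0) {
  sum(sqrt(rowSums(as.matrix(W)^2) + epsilon))
}

#' Diagonal of the iteratively reweighted l2,1 matrix
#'
#' Entry i is \eqn{1 / (2\sqrt{w_i^T w_i + \epsilon})}: the weight under
#' which the quadratic surrogate \eqn{tr(W^T N W)} majorizes the smoothed
#' l2,1 norm at the current W. Always finite and positive because
#' epsilon guards zero rows.
#'
#' @param Wv d_v-by-k weight matrix of one modality.
#' @param epsilon positive smoothing constant.
#' @return length-d_v positive vector.
#' @export
rowReweight <- function(Wv, epsilon) {
  stopifnot(epsilon > 0)
  1 / (2 * sqrt(rowSums(as.matrix(Wv)^2) + epsilon))
}

#' Joint objective value
#'
#' Evaluates the full objective at an arbitrary state. In
#' \code{coupling = "additive"} the data-fit term is the single
#' concatenated residual \eqn{||W^T \Theta X^T + b 1^T - Y||_F^2}; in
#' \code{"independent"} it is the sum of per-modality residuals each
#' fitting Y on its own. The sparsity term uses the smoothed l2,1 norm
#' for consistency with the updates; the graph term needs \code{graphs}
#' only when \code{beta > 0}.
#'
#' @param W list of d_v-by-k weight matrices.
#' @param b length-k bias vector.
#' @param theta length-d simplex vector (concatenated over modalities).
#' @param blocks list of n-by-d_v data matrices.
#' @param Y k-by-n one-hot label matrix.
#' @param graphs list of [AnchorGraph-class] objects, or NULL when
#'   beta = 0.
#' @param params an [AGFSParams-class].
#' @return nonnegative scalar.
#' @export
agfsObjective <- function(W, b, theta, blocks, Y, graphs = NULL, params) {
  dims <- vapply(blocks, ncol, integer(1))
  if (length(theta) != sum(dims)) stop("theta length must equal total dim")
  if (length(W) != length(blocks)) stop("one weight matrix per modality")
  thetas <- .splitTheta(theta, dims)
  n <- nrow(blocks[[1]])
  fits <- lapply(seq_along(blocks), function(v)
    .modalityFit(blocks[[v]], W[[v]], thetas[[v]]))
  if (params@coupling == "additive") {
    R <- Reduce(`+`, fits) + b - Y   # b recycles as b 1'
    term1 <- sum(R^2)
  } else {
    term1 <- sum(vapply(fits, function(f) sum((f + b - Y)^2), numeric(1)))
  }
  term2 <- params@alpha *
    sum(vapply(W, smoothedL21, numeric(1), epsilon = params@epsilon))
  term3 <- 0
  if (params@beta > 0) {
    if (is.null(graphs)) stop("graphs required when beta > 0")
    term3 <- params@beta * sum(vapply(seq_along(blocks), function(v)
      laplacianQuadratic(graphs[[v]]@B, blocks[[v]] %*% W[[v]]),
      numeric(1)))
  }
  term1 + term2 + term3
}

#' Closed-form bias update
#'
#' Sets the gradient of the data-fit term with respect to b to zero:
#' \eqn{b = (1/n)(Y 1 - W^T \Theta X^T 1)} under additive coupling, and
#' the analogous average over modalities under independent coupling.
#'
#' @inheritParams agfsObjective
#' @return length-k vector.
#' @export
updateBias <- function(W, theta, blocks, Y, coupling = "additive") {
  n <- nrow(blocks[[1]])
  if (n == 0) stop("no samples")
  dims <- vapply(blocks, ncol, integer(1))
  thetas <- .splitTheta(theta, dims)
  fits <- lapply(seq_along(blocks), function(v)
    .modalityFit(blocks[[v]], W[[v]], thetas[[v]]))
  if (coupling == "additive") {
    rowMeans(Y - Reduce(`+`, fits))
  } else {
    rowMeans(Y) - rowMeans(Reduce(`+`, fits)) / length(blocks)
  }
}

.graphGram <- function(Xv, graph) {
  # X_v' (I - B B') X_v as a d_v x d_v matrix
  crossprod(Xv) - crossprod(crossprod(graph@B, Xv))
}

#' Reweighted closed-form update of one modality's weight matrix
#'
#' Solves the stationarity system
#' \deqn{(\Theta_v X_v^T X_v \Theta_v + \alpha N_v +
#'        \beta X_v^T (I - B B^T)_v X_v) W_v =
#'        \Theta_v X_v^T \tilde Y^T - \Theta_v X_v^T 1 b^T}
#' by a linear solve (never an explicit inverse), where the reweighting
#' diagonal N_v is recomputed from the current W_v unless supplied, and
#' \eqn{\tilde Y} is Y (independent coupling) or Y minus the other
#' modalities' fitted contributions (additive coupling).
#'
#' @inheritParams agfsObjective
#' @param v modality index to update.
#' @param Nv optional precomputed reweighting vector; default
#'   \code{rowReweight(W[[v]], params@epsilon)}.
#' @return the updated d_v-by-k matrix.
#' @export
updateWeights <- function(W, b, theta, blocks, Y, graphs = NULL, params,
                          v, Nv = NULL) {
  dims <- vapply(blocks, ncol, integer(1))
  thetas <- .splitTheta(theta, dims)
  Xv <- blocks[[v]]
  thetav <- thetas[[v]]
  if (is.null(Nv)) Nv <- rowReweight(W[[v]], params@epsilon)
  Xt <- sweep(Xv, 2, thetav, "*")      # X_v Theta_v
  A <- crossprod(Xt) + diag(params@alpha * Nv, ncol(Xv))
  if (params@beta > 0) {
    if (is.null(graphs)) stop("graphs required when beta > 0")
    A <- A + params@beta * .graphGram(Xv, graphs[[v]])
  }
  if (params@coupling == "additive" && length(blocks) > 1L) {
    others <- setdiff(seq_along(blocks), v)
    Ytilde <- Y - Reduce(`+`, lapply(others, function(u)
      .modalityFit(blocks[[u]], W[[u]], thetas[[u]])))
  } else {
    Ytilde <- Y
  }
  rhs <- crossprod(Xt, t(Ytilde - b))  # Theta_v X_v'(Ytilde' - 1 b')
  tryCatch(solve(A, rhs), error = function(e) {
    warning("weight system for modality ", v,
            " is singular; using a least-squares solution")
    qr.coef(qr(A, LAPACK = TRUE), rhs)
  })
}

#' Trace identity for a diagonal congruence
#'
#' For diagonal A = diag(a), tr(A B A C) = a' (B' o C) a where o is the
#' elementwise (Hadamard) product. Used to reduce the theta step to a
#' quadratic program and as a test oracle for [thetaSubproblem()].
#'
#' @param a length-d vector (the diagonal).
#' @param B,C d-by-d matrices.
#' @return scalar.
#' @export
hadamardTrace <- function(a, B, C) {
  d <- length(a)
  if (!all(dim(B) == c(d, d)) || !all(dim(C) == c(d, d)))
    stop("B and C must be d-by-d with d = length(a)")
  drop(crossprod(a, (t(B) * C) %*% a))
}

#' Build the simplex quadratic program for the feature weights
#'
#' With W and b profiled out (b enters through the centering operator
#' H = I - (1/n) 1 1', applied implicitly as column centering), the
#' residual term as a function of theta is theta' Q theta - theta' s
#' plus a constant, with
#' \deqn{Q = (X^T H X) \circ (W W^T), \quad s = diag(2 X^T H Y^T W^T)}
#' where X is the column-concatenation of all modalities and W the row
#' stack of all weight matrices. Q is symmetrized to absorb roundoff;
#' it is positive semidefinite (Hadamard product of PSD matrices), so
#' the program is convex.
#'
#' @inheritParams agfsObjective
#' @return list with elements \code{Q} (d-by-d) and \code{s} (length d).
#' @export
thetaSubproblem <- function(W, blocks, Y) {
  X <- do.call(cbind, blocks)
  Xc <- scale(X, center = TRUE, scale = FALSE)  # H X, never n x n
  Wstack <- do.call(rbind, W)
  if (nrow(Wstack) != ncol(X)) stop("W rows must match total feature count")
  Q <- crossprod(Xc) * tcrossprod(Wstack)
  Q <- (Q + t(Q)) / 2
  s <- 2 * rowSums(crossprod(Xc, t(Y)) * Wstack)
  list(Q = Q, s = s)
}

#' Augmented-Lagrangian solver for the simplex quadratic program
#'
#' Minimizes theta' Q theta - theta' s subject to theta >= 0,
#' sum(theta) = 1 by splitting theta = u with u >= 0 and alternating
#' \itemize{
#'   \item theta = E^{-1} g with E = 2Q + mu I + mu 1 1' and
#'     g = mu u + mu 1 - lambda2 1 - lambda1 + s,
#'   \item u = pos(theta + lambda1 / mu) (negative entries zeroed),
#' }
#' followed by multiplier updates lambda1 += mu (theta - u),
#' lambda2 += mu (sum(theta) - 1) and mu <- min(rho mu, muMax). One
#' symmetric eigendecomposition of 2Q makes each inner solve O(d^2) via
#' a rank-one update for the mu 1 1' term.
#'
#' Two numerical safeguards make the scheme reliable. First, Q and s are
#' jointly rescaled by c = max(1, max|Q|, max|s|) before iterating (the
#' minimizer is invariant), so the penalty mu = 1 sits at the scale of
#' the problem's curvature; by default the penalty is \emph{not} grown
#' (muMax = mu0), because once mu exceeds the curvature the multiplier
#' iteration's per-step progress shrinks like 1/mu and the solver
#' stalls at a feasible but suboptimal point. Second, iteration stops
#' only when primal feasibility
#' max(||theta - u||_inf, |sum(theta) - 1|) <= almTol \emph{and} the
#' simplex KKT error of the feasible iterate u (gradient constant on
#' the support, no smaller off it) is at most
#' 10 almTol (1 + ||2Qu - s||_inf): the stationarity residual of the
#' theta solve equals mu (theta - u) + mu (sum(theta) - 1) 1, so
#' feasibility alone can hold at points far from the minimizer. On
#' degenerate programs whose objective is flat in most coordinates the
#' KKT test can stall; in that case the best feasible iterate seen is
#' returned once its Frank-Wolfe gap (an upper bound on the attainable
#' objective improvement, relative) is below sqrt(almTol). The returned
#' vector is exactly renormalized to sum to 1 (an adjustment of
#' magnitude at most almTol).
#'
#' @param Q d-by-d symmetric positive semidefinite matrix.
#' @param s length-d vector.
#' @param params an [AGFSParams-class] (fields mu0, rho, muMax, almTol,
#'   maxInnerIters).
#' @param theta0 feasible starting point (default uniform).
#' @return length-d nonnegative vector summing to 1.
#' @export
solveThetaALM <- function(Q, s, params = agfsParams(), theta0 = NULL) {
  d <- length(s)
  if (!all(dim(Q) == c(d, d))) stop("Q must be d-by-d with d = length(s)")
  if (max(abs(Q - t(Q))) > 1e-8 * max(1, max(abs(Q))))
    stop("Q must be symmetric")
  if (is.null(theta0)) theta0 <- rep(1 / d, d)
  c0 <- max(1, max(abs(Q)), max(abs(s)))   # scale normalization
  Qn <- Q / c0
  sn <- s / c0
  eg <- eigen(2 * Qn, symmetric = TRUE)
  U <- eg$vectors
  lam <- pmax(eg$values, 0)            # PSD up to roundoff
  ones <- rep(1, d)
  uOnes <- crossprod(U, ones)          # U' 1, fixed
  theta <- theta0
  u <- theta0
  l1 <- numeric(d)
  l2 <- 0
  mu <- params@mu0
  bestTheta <- theta0
  bestF <- drop(crossprod(theta0, Qn %*% theta0)) - sum(theta0 * sn)
  minGap <- Inf
  gapTol <- sqrt(params@almTol)
  bestKkt <- Inf
  lastImprove <- 0L
  for (it in seq_len(params@maxInnerIters)) {
    g <- mu * u + mu * ones - l2 * ones - l1 + sn
    w <- crossprod(U, g)
    Ag <- U %*% (w / (lam + mu))                   # (2Q + mu I)^{-1} g
    A1 <- U %*% (uOnes / (lam + mu))               # (2Q + mu I)^{-1} 1
    denom <- 1 + mu * sum(uOnes^2 / (lam + mu))
    theta <- drop(Ag - mu * A1 * sum(uOnes * w / (lam + mu)) / denom)
    u <- pmax(theta + l1 / mu, 0)
    infeas <- max(max(abs(theta - u)), abs(sum(theta) - 1))
    if (infeas <= params@almTol) {
      su <- sum(u)
      if (su <= 0) return(rep(1 / d, d))
      uf <- u / su
      # KKT error at the feasible iterate, min-form complementarity:
      # gradient equal to its support average where u carries mass,
      # nowhere below it
      grad <- drop(2 * (Qn %*% uf) - sn)
      nu <- sum(uf * grad)
      kkt <- max(abs(pmin(uf, grad - nu)))
      if (kkt <= 10 * params@almTol * (1 + max(abs(grad))))
        return(uf)
      if (kkt < 0.9 * bestKkt) {
        bestKkt <- kkt
        lastImprove <- it
      }
      # degenerate landscapes (many near-zero weight rows make Q flat in
      # most directions) stall the multiplier iteration short of the
      # tight test; keep the best feasible iterate seen (theta0
      # included) together with the smallest Frank-Wolfe gap, which
      # upper-bounds how far from optimal that iterate can be
      fu <- drop(crossprod(uf, Qn %*% uf)) - sum(uf * sn)
      fwGap <- (nu - min(grad)) / (1 + abs(fu))
      minGap <- min(minGap, fwGap)
      if (fu < bestF) {
        bestF <- fu
        bestTheta <- uf
      }
      if (it - lastImprove >= 500L && minGap <= gapTol)
        return(bestTheta)
    }
    l1 <- l1 + mu * (theta - u)
    l2 <- l2 + mu * (sum(theta) - 1)
    mu <- min(params@rho * mu, params@muMax)
  }
  if (minGap <= gapTol) return(bestTheta)
  stop("simplex solver did not converge within ", params@maxInnerIters,
       " iterations (final infeasibility ",
       format(max(max(abs(theta - u)), abs(sum(theta) - 1))),
       ", best optimality gap ", format(minGap), ")")
}

.scaleBlocks <- function(blocks) {
  centers <- lapply(blocks, colMeans)
  scales <- lapply(blocks, function(b) {
    s <- apply(b, 2, stats::sd)
    s[!is.finite(s) | s == 0] <- 1
    s
  })
  scaled <- lapply(seq_along(blocks), function(v)
    sweep(sweep(blocks[[v]], 2, centers[[v]]), 2, scales[[v]], "/"))
  names(scaled) <- names(blocks)
  list(blocks = scaled, centers = centers, scales = scales)
}

.applyScaling <- function(blocks, scaling) {
  if (!length(scaling)) return(blocks)
  out <- lapply(seq_along(blocks), function(v)
    sweep(sweep(blocks[[v]], 2, scaling$centers[[v]]), 2,
          scaling$scales[[v]], "/"))
  names(out) <- names(blocks)
  out
}

#' Fit the anchor-graph multi-modal feature selector
#'
#' Builds one anchor graph per modality (on that modality's own,
#' optionally z-scored, feature space), initializes theta uniform at
#' 1/d, W = 0 and b = 0, and alternates: bias update, per-modality
#' reweighted weight solves, the augmented-Lagrangian simplex step for
#' theta, and a final bias refresh, recording the objective after every
#' sweep. Stops when the relative objective change drops below
#' \code{outerTol} or after \code{maxOuterIters} sweeps. Under additive
#' coupling every block update minimizes the same joint objective, so
#' the recorded history is non-increasing; a violation beyond relative
#' 1e-6 raises an error.
#'
#' @param data a [MultiModalDataset-class].
#' @param params an [AGFSParams-class].
#' @return a fitted [AGFSModel-class].
#' @examples
#' sim <- simulateMultiModal(nSamples = 60, modalityDims = c(12, 6),
#'                           nInformative = c(3, 2),
#'                           modalityStrength = c(0.6, 0.4), seed = 3)
#' fit <- agfsFit(sim$dataset, agfsParams(alpha = 0.1, beta = 0.1,
#'                                        seed = 3, maxOuterIters = 30))
#' fit
#' @export
agfsFit <- function(data, params = agfsParams()) {
  stopifnot(is(data, "MultiModalDataset"), is(params, "AGFSParams"))
  rawBlocks <- blocks(data)
  scaling <- list()
  if (params@scale) {
    sc <- .scaleBlocks(rawBlocks)
    Xs <- sc$blocks
    scaling <- sc[c("centers", "scales")]
  } else {
    Xs <- rawBlocks
  }
  Y <- labelMatrix(data)
  dims <- vapply(Xs, ncol, integer(1))
  V <- length(Xs)
  d <- sum(dims)
  k <- nrow(Y)
  n <- nSamples(data)

  graphs <- NULL
  if (params@beta > 0) {
    graphs <- lapply(seq_len(V), function(v) {
      sd <- if (is.na(params@seed)) NULL else params@seed + v - 1L
      buildAnchorGraph(Xs[[v]], m = params@mAnchors, kNN = params@kNN,
                       strategy = params@anchorStrategy, seed = sd)
    })
  }

  theta <- rep(1 / d, d)
  W <- lapply(dims, function(dv) matrix(0, dv, k))
  b <- numeric(k)
  N <- lapply(dims, function(dv) rep(NA_real_, dv))

  # fixed pieces of the theta quadratic program
  Xcat <- do.call(cbind, Xs)
  Xc <- scale(Xcat, center = TRUE, scale = FALSE)
  XtHX <- crossprod(Xc)
  Cmat <- crossprod(Xc, t(Y))

  history <- numeric(0)
  converged <- FALSE
  sweeps <- 0L
  for (t in seq_len(params@maxOuterIters)) {
    sweeps <- t
    b <- updateBias(W, theta, Xs, Y, params@coupling)
    for (v in seq_len(V)) {
      N[[v]] <- rowReweight(W[[v]], params@epsilon)
      W[[v]] <- updateWeights(W, b, theta, Xs, Y, graphs, params, v,
                              Nv = N[[v]])
    }
    if (params@updateTheta) {
      Wstack <- do.call(rbind, W)
      Q <- XtHX * tcrossprod(Wstack)
      Q <- (Q + t(Q)) / 2
      s <- 2 * rowSums(Cmat * Wstack)
      theta <- solveThetaALM(Q, s, params, theta0 = theta)
    }
    b <- updateBias(W, theta, Xs, Y, params@coupling)
    obj <- agfsObjective(W, b, theta, Xs, Y, graphs, params)
    if (length(history)) {
      prev <- history[length(history)]
      if (params@coupling == "additive" && obj > prev * (1 + 1e-6))
        stop("objective increased from ", format(prev), " to ",
             format(obj), " in additive coupling; this violates the ",
             "descent contract and indicates a numerical failure")
      if (prev > 0 && abs(obj - prev) / prev <= params@outerTol) {
        history <- c(history, obj)
        converged <- TRUE
        break
      }
    }
    history <- c(history, obj)
  }

  featNames <- unlist(lapply(Xs, colnames), use.names = FALSE)
  if (is.null(featNames) || length(featNames) != d)
    featNames <- paste0("f", seq_len(d))
  new("AGFSModel", W = W, b = b, theta = theta, N = N,
      objectiveHistory = history, dims = as.integer(dims),
      modalityNames = modalityNames(data), featureNames = featNames,
      classLevels = classLevels(data), params = params,
      scaling = scaling, converged = converged, nSweeps = sweeps)
}

#' @rdname AGFSModel-class
#' @export
setMethod("weightMatrices", "AGFSModel", function(object) object@W)

#' @rdname AGFSModel-class
#' @export
setMethod("bias", "AGFSModel", function(object) object@b)

#' @rdname AGFSModel-class
#' @export
setMethod("thetaWeights", "AGFSModel", function(object) object@theta)

#' @rdname AGFSModel-class
#' @export
setMethod("objectiveHistory", "AGFSModel", function(object)
  object@objectiveHistory)

setMethod("show", "AGFSModel", function(object) {
  cat("AGFSModel:", length(object@dims), "modalities, d =",
      sum(object@dims), "features,", length(object@classLevels),
      "classes\n")
  cat("  ", object@nSweeps, " sweeps, ",
      if (object@converged) "converged" else "sweep cap reached",
      "; final objective ",
      format(tail(object@objectiveHistory, 1)), "\n", sep = "")
  mi <- vapply(.splitTheta(object@theta, object@dims), sum, numeric(1))
  cat("  modality importance:",
      paste(sprintf("%s %.3f", object@modalityNames, mi), collapse = ", "),
      "\n")
})
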