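# Masked graph-regularized nonnegative Tucker decomposition by block
# multiplicative updates.
#
# Objective (minimized over core G and factors Ay, Ax, Ag, all >= 0):
#   F(G, A) = 1/2 ||M . (T - That)||_F^2
#           + lambda/2 vec(That)' (Lg (+) Ly (+) Lx) vec(That)
# with That = G x1 Ay x2 Ax x3 Ag and (+) the Kronecker sum. Each block is
# updated elementwise by the ratio of the negative to the positive part of
# its partial gradient, which preserves nonnegativity; the split takes the
# M.That vs M.T parts of the data term and the D vs W parts of each
# Laplacian, so both parts are elementwise nonnegative.

.splitLaplacian <- function(L) {
  D <- Matrix::Diagonal(x = Matrix::diag(L))
  list(D = D, W = D - L)
}

# Gram of the core against itself with small per-mode matrices applied to
# the other modes: unfold(core x_{o} mats[[o]], mode) %*% t(unfold(core, mode))
.coreGram <- function(core, mode, mats) {
  mats[mode] <- list(NULL)  # the updated mode itself is never contracted
  unfoldTensor(.ttmChain(core, mats), mode) %*% t(unfoldTensor(core, mode))
}

# Data-term gradient factor: unfold(S contracted with the other two factors
# transposed, mode) %*% t(unfold(core, mode)), for a full-size tensor S.
.gradFactorData <- function(S, A, core, mode) {
  mats <- list(NULL, NULL, NULL)
  for (m in setdiff(1:3, mode)) mats[[m]] <- t(A[[m]])
  unfoldTensor(.ttmChain(S, mats), mode) %*% t(unfoldTensor(core, mode))
}

# Positive/negative gradient parts for one block.
#   mode 1:3 -> the factor of that mode; mode 4 -> the core.
# A is list(Ay, Ax, Ag); split is list per mode of list(D, W); MT = M * T.
# Returns list(pos, neg), both elementwise >= 0, with
# d objective / d block = pos - neg.
.gradParts <- function(mode, core, A, MT, M, split, lambda) {
  That <- tuckerReconstruct(core, A[[1]], A[[2]], A[[3]])
  MThat <- if (is.null(M)) That else M * That
  if (mode == 4L) {
    tA <- lapply(A, t)
    pos <- .ttmChain(MThat, tA)
    neg <- .ttmChain(MT, tA)
  } else {
    pos <- .gradFactorData(MThat, A, core, mode)
    neg <- .gradFactorData(MT, A, core, mode)
  }
  if (lambda > 0) {
    P <- lapply(A, crossprod)                      # r x r, A'A
    Qp <- Qn <- vector("list", 3L)
    for (m in 1:3) {
      Qp[[m]] <- as.matrix(crossprod(A[[m]], split[[m]]$D %*% A[[m]]))
      Qn[[m]] <- as.matrix(crossprod(A[[m]], split[[m]]$W %*% A[[m]]))
    }
    if (mode == 4L) {
      rp <- rn <- array(0, dim(core))
      for (m in 1:3) {
        mats <- P; mats[[m]] <- Qp[[m]]
        rp <- rp + .ttmChain(core, mats)
        mats[[m]] <- Qn[[m]]
        rn <- rn + .ttmChain(core, mats)
      }
      pos <- pos + lambda * rp
      neg <- neg + lambda * rn
    } else {
      others <- setdiff(1:3, mode)
      Sown <- .coreGram(core, mode, P)
      Am <- A[[mode]]
      rp <- as.matrix(split[[mode]]$D %*% Am) %*% Sown
      rn <- as.matrix(split[[mode]]$W %*% Am) %*% Sown
      for (o in others) {
        mats <- P; mats[[o]] <- Qp[[o]]
        rp <- rp + Am %*% .coreGram(core, mode, mats)
        mats[[o]] <- Qn[[o]]
        rn <- rn + Am %*% .coreGram(core, mode, mats)
      }
      pos <- pos + lambda * rp
      neg <- neg + lambda * rn
    }
  }
  if (any(!is.finite(pos)) || any(!is.finite(neg)))
    stop("non-finite gradient encountered; check input scaling")
  list(pos = pos, neg = neg)
}

#' Objective of the masked graph-regularized Tucker problem
#'
#' Returns the masked squared-error data term
#' \code{F1 = 1/2 ||M . (T - That)||_F^2}, the Cartesian-product graph
#' penalty \code{F2 = 1/2 vec(That)' (Lg (+) Ly (+) Lx) vec(That)} (see
#' \code{\link{productQuadraticForm}}) and \code{total = F1 + lambda * F2}.
#'
#' @param tensor a \linkS4class{SpatialTensor} or 3-way array (the data T).
#' @param mask binary array of the same shape, or NULL for "all observed"
#'   (a mask attached to \code{tensor} is used if present).
#' @param model a \linkS4class{TuckerModel}.
#' @param graphs a \linkS4class{GraphSet}; may be NULL when
#'   \code{lambda = 0}.
#' @param lambda nonnegative graph-regularization weight.
#' @return named numeric vector \code{c(F1, F2, total)}.
#' @export
tuckerObjective <- function(tensor, mask = NULL, model, graphs = NULL,
                            lambda = 0) {
  x <- .resolveTensorMask(tensor, mask)
  That <- tuckerReconstruct(model)
  if (!identical(dim(That), dim(x$T)))
    stop("model shape does not match the tensor")
  R <- x$T - That
  if (!is.null(x$M)) R <- x$M * R
  F1 <- 0.5 * sum(R * R)
  F2 <- if (is.null(graphs)) 0 else 0.5 * productQuadraticForm(That, graphs)
  c(F1 = F1, F2 = F2, total = F1 + lambda * F2)
}

.resolveTensorMask <- function(tensor, mask) {
  if (is(tensor, "SpatialTensor")) {
    T <- tensor@values
    if (is.null(mask)) mask <- tensorMask(tensor)
  } else T <- tensor
  if (!is.null(mask)) {
    if (is(mask, "SpatialTensor")) mask <- mask@values
    if (!identical(dim(mask), dim(T))) stop("mask dim must match tensor dim")
  }
  list(T = T, M = mask)
}

#' Rescale a Tucker model so factor columns sum to one
#'
#' Each factor column is divided by its sum and the scale is absorbed into
#' the core along the matching mode, so the reconstruction is numerically
#' unchanged while core entries become comparable magnitudes of multiway
#' interactions. Columns that are identically zero are left untouched
#' (scale 1) with a warning: a dead component is a legitimate outcome of a
#' multiplicative fit.
#'
#' @param model a nonnegative \linkS4class{TuckerModel}.
#' @param warnZero warn when a zero column is encountered.
#' @return a \linkS4class{TuckerModel} with unit-sum factor columns.
#' @export
normalizeModel <- function(model, warnZero = TRUE) {
  A <- list(model@Ay, model@Ax, model@Ag)
  core <- model@core
  for (m in 1:3) {
    s <- colSums(A[[m]])
    zero <- s == 0
    if (any(zero) && warnZero)
      warning(sprintf("mode-%d factor has %d all-zero column(s); left as is",
                      m, sum(zero)))
    s[zero] <- 1
    A[[m]] <- sweep(A[[m]], 2L, s, "/")
    core <- nmodeProduct(core, diag(s, nrow = length(s)), m)
  }
  TuckerModel(core, A[[1]], A[[2]], A[[3]])
}

#' Fit a graph-regularized nonnegative Tucker decomposition
#'
#' Decomposes a masked, nonnegative (y, x, gene) tensor into a core and
#' three factor matrices by block multiplicative updates: per iteration the
#' y-factor, x-factor, gene-factor and core are updated in that order, each
#' by the elementwise ratio of the negative to the positive part of its
#' partial gradient, followed by a column-sum normalization absorbed into
#' the core. Entries of the mask that are 0 carry no weight in the data
#' term, which is what lets the fitted model impute them. The graph penalty
#' couples neighbouring grid rows/columns through two chain graphs and
#' co-interacting genes through the gene network, weighted by
#' \code{lambda}; with \code{lambda = 0} the fit is a plain masked
#' nonnegative Tucker decomposition.
#'
#' All blocks are initialized i.i.d. uniform(0, 1) from \code{seed}, so a
#' run is bitwise reproducible. Iteration stops when the relative change of
#' the objective, \code{|f_k - f_(k-1)| / max(f_(k-1), 1)}, drops below
#' \code{tol}, or after \code{maxIter} iterations.
#'
#' @param tensor a \linkS4class{SpatialTensor} or nonnegative 3-way array.
#' @param mask binary array (1 = observed/training entry); defaults to the
#'   mask attached to \code{tensor}, else to all-ones.
#' @param graphs a \linkS4class{GraphSet}, a gene-network adjacency matrix
#'   (chain graphs are then built to match the grid), or NULL for an
#'   edgeless gene graph.
#' @param rank integer vector (ry, rx, rg), each >= 1 and <= the matching
#'   tensor dimension.
#' @param lambda nonnegative graph-regularization weight; 0.1 is a robust
#'   default for imputation, larger values (about 1) give smoother spatial
#'   components.
#' @param maxIter iteration cap (default 5000).
#' @param tol relative-objective convergence tolerance (default 1e-4).
#' @param seed integer seed for the random initialization.
#' @param eps denominator guard added inside the multiplicative ratio.
#' @param verbose print the objective every 100 iterations.
#' @return a \linkS4class{TuckerFit}; see \code{\link{fittedModel}},
#'   \code{\link{objectiveTrace}}, \code{\link{imputeExpression}}.
#' @examples
#' sim <- simulateSpatialData(shape = c(12, 12, 20), rank = c(2, 2, 3),
#'                            seed = 1)
#' fit <- fitSpatialTucker(sim$tensor, graphs = sim$network,
#'                         rank = c(2, 2, 3), lambda = 0.1,
#'                         maxIter = 50, seed = 1)
#' fit
#' @export
fitSpatialTucker <- function(tensor, mask = NULL, graphs = NULL, rank,
                             lambda = 0.1, maxIter = 5000, tol = 1e-4,
                             seed = 1, eps = 1e-12, verbose = FALSE) {
  x <- .resolveTensorMask(tensor, mask)
  T <- x$T
  d <- dim(T)
  rank <- as.integer(rank)
  if (length(rank) != 3L || any(rank < 1L))
    stop("rank must be three positive integers")
  if (any(rank > d))
    stop(sprintf("rank (%s) exceeds tensor dimensions (%s)",
                 paste(rank, collapse = ","), paste(d, collapse = ",")))
  if (lambda < 0) stop("lambda must be nonnegative")
  M <- x$M
  if (!is.null(M) && all(M == 1)) M <- NULL
  MT <- if (is.null(M)) T else M * T

  if (is.null(graphs)) graphs <- makeGraphSet(d[1], d[2], d[3])
  else if (!is(graphs, "GraphSet")) graphs <- makeGraphSet(d[1], d[2], graphs)
  Ls <- list(graphs@Ly, graphs@Lx, graphs@Lg)
  for (m in 1:3)
    if (nrow(Ls[[m]]) != d[m])
      stop(sprintf("graph Laplacian of mode %d does not match the tensor", m))
  split <- lapply(Ls, .splitLaplacian)

  # seeded init, restoring the caller's RNG state afterwards
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(as.integer(seed))
  A <- list(matrix(runif(d[1] * rank[1]), d[1], rank[1]),
            matrix(runif(d[2] * rank[2]), d[2], rank[2]),
            matrix(runif(d[3] * rank[3]), d[3], rank[3]))
  core <- array(runif(prod(rank)), rank)
  # least-squares rescale of the initial core onto the observed data: puts
  # the first iterate at the right overall magnitude, avoiding the long
  # flat stretch multiplicative updates show from an unscaled random start
  That0 <- tuckerReconstruct(core, A[[1]], A[[2]], A[[3]])
  if (!is.null(M)) That0 <- M * That0
  denom <- sum(That0 * That0)
  if (denom > 0) core <- core * max(sum(MT * That0) / denom, eps)

  trace <- matrix(NA_real_, maxIter, 3L,
                  dimnames = list(NULL, c("F1", "F2", "total")))
  prev <- NA_real_
  converged <- FALSE
  warnedZero <- FALSE
  nIter <- 0L
  for (it in seq_len(maxIter)) {
    for (m in 1:3) {
      g <- .gradParts(m, core, A, MT, M, split, lambda)
      A[[m]] <- A[[m]] * g$neg / (g$pos + eps)
    }
    g <- .gradParts(4L, core, A, MT, M, split, lambda)
    core <- core * g$neg / (g$pos + eps)

    # normalization: absorb factor column sums into the core
    for (m in 1:3) {
      s <- colSums(A[[m]])
      zero <- s == 0
      if (any(zero) && !warnedZero) {
        warning("a factor column became identically zero during the fit")
        warnedZero <- TRUE
      }
      s[zero] <- 1
      A[[m]] <- sweep(A[[m]], 2L, s, "/")
      core <- nmodeProduct(core, diag(s, nrow = length(s)), m)
    }

    That <- tuckerReconstruct(core, A[[1]], A[[2]], A[[3]])
    R <- if (is.null(M)) T - That else MT - M * That
    F1 <- 0.5 * sum(R * R)
    F2 <- 0.5 * productQuadraticForm(That, graphs)
    tot <- F1 + lambda * F2
    if (!is.finite(tot)) stop("objective became non-finite at iteration ", it)
    trace[it, ] <- c(F1, F2, tot)
    nIter <- it
    if (verbose && it %% 100L == 0L)
      message(sprintf("iter %5d  F1 %.6g  F2 %.6g  total %.6g",
                      it, F1, F2, tot))
    if (!is.na(prev) && abs(tot - prev) / max(prev, 1) < tol) {
      converged <- TRUE
      break
    }
    prev <- tot
  }

  new("TuckerFit",
      model = TuckerModel(core, A[[1]], A[[2]], A[[3]]),
      trace = trace[seq_len(nIter), , drop = FALSE],
      nIter = nIter, converged = converged,
      lambda = as.numeric(lambda), seed = as.integer(seed))
}

#' Impute the full expression tensor from a fitted model
#'
#' Returns the dense Tucker reconstruction \code{That}; held-out or missing
#' entries are read off at their positions by the caller.
#'
#' @param fit a \linkS4class{TuckerFit} or \linkS4class{TuckerModel}.
#' @return a nonnegative 3-way array of the full tensor shape.
#' @export
imputeExpression <- function(fit) {
  model <- if (is(fit, "TuckerFit")) fit@model else fit
  tuckerReconstruct(model)
}
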