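# Brute-force reference implementations used as independent oracles.
# These deliberately use naive loops / explicit dense algebra, never the
# package's own code paths.

randomTensor <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(prod(d)), d)
}

randomModel <- function(shape, rank, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  TuckerModel(array(runif(prod(rank)), rank),
              matrix(runif(shape[1] * rank[1]), shape[1], rank[1]),
              matrix(runif(shape[2] * rank[2]), shape[2], rank[2]),
              matrix(runif(shape[3] * rank[3]), shape[3], rank[3]))
}

# n-mode product by explicit index summation
nmodeOracle <- function(t, m, mode) {
  d <- dim(t); nd <- d; nd[mode] <- nrow(m)
  out <- array(0, nd)
  for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) for (k in seq_len(nd[3])) {
    s <- 0
    for (q in seq_len(d[mode])) {
      idx <- c(i, j, k); idx[mode] <- q
      s <- s + t[idx[1], idx[2], idx[3]] * m[c(i, j, k)[mode], q]
    }
    out[i, j, k] <- s
  }
  out
}

# Tucker reconstruction from the quadruple-sum definition
reconstructOracle <- function(core, Ay, Ax, Ag) {
  d <- c(nrow(Ay), nrow(Ax), nrow(Ag)); r <- dim(core)
  out <- array(0, d)
  for (a in seq_len(r[1])) for (b in seq_len(r[2])) for (c in seq_len(r[3]))
    out <- out + core[a, b, c] *
      outer(outer(Ay[, a], Ax[, b]), Ag[, c])
  out
}

# dense Kronecker-sum Laplacian matching R's column-major vec over (y, x, g)
denseProductLaplacian <- function(Ly, Lx, Lg) {
  Ly <- as.matrix(Ly); Lx <- as.matrix(Lx); Lg <- as.matrix(Lg)
  ny <- nrow(Ly); nx <- nrow(Lx); ng <- nrow(Lg)
  kronecker(diag(ng), kronecker(diag(nx), Ly)) +
    kronecker(diag(ng), kronecker(Lx, diag(ny))) +
    kronecker(Lg, kronecker(diag(nx), diag(ny)))
}

# objective from first principles: explicit reconstruction + dense Lc
objectiveOracle <- function(T, M, core, Ay, Ax, Ag, gs, lambda) {
  That <- reconstructOracle(core, Ay, Ax, Ag)
  R <- (T - That); if (!is.null(M)) R <- M * R
  Lc <- denseProductLaplacian(gs@Ly, gs@Lx, gs@Lg)
  v <- as.numeric(That)
  0.5 * sum(R^2) + lambda * 0.5 * drop(t(v) %*% Lc %*% v)
}

# central finite differences of objectiveOracle w.r.t. one block
finiteDiffGrad <- function(T, M, core, A, gs, lambda, mode, h = 1e-6) {
  f <- function(core, A) objectiveOracle(T, M, core, A[[1]], A[[2]], A[[3]],
                                         gs, lambda)
  x <- if (mode == 4) core else A[[mode]]
  g <- array(0, dim(as.array(x)))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    if (mode == 4) g[i] <- (f(xp, A) - f(xm, A)) / (2 * h)
    else {
      Ap <- A; Ap[[mode]] <- xp
      Am <- A; Am[[mode]] <- xm
      g[i] <- (f(core, Ap) - f(core, Am)) / (2 * h)
    }
  }
  g
}

# AUC by exhaustive pairwise comparison, ties counting one half
aucOracle <- function(score, labels) {
  pos <- score[as.logical(labels)]; neg <- score[!as.logical(labels)]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# retained-mass fraction by sort-and-sum
massFractionOracle <- function(core, percent) {
  v <- sort(as.numeric(core), decreasing = TRUE)
  k <- ceiling(percent / 100 * length(v))
  sum(v[seq_len(k)]) / sum(v)
}

# a tiny random gene adjacency (symmetric, zero diagonal)
randomGeneAdjacency <- function(ng, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, ng, ng)
  W[upper.tri(W)] <- as.numeric(runif(ng * (ng - 1) / 2) < p)
  W <- W + t(W)
  methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                          "generalMatrix"), "CsparseMatrix")
}
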