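# Spot-wise cross-validation and the evaluation metrics: imputation error
# (MAE / MAPE / per-spot R^2), region concordance (AUC, normalized
# Euclidean distance), and clustering-based segmentation (k-means + ARI).

.withSeed <- function(seed, expr) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Partition spots into cross-validation folds
#'
#' Randomly splits the eligible spots — in-tissue (when a map is given) and
#' not all-zero across genes — into k near-equal disjoint folds. Holding
#' out one fold masks 1/k of the spots; k = 5 gives the usual 20\% spot
#' holdout. All-zero spots are never put in a fold: there is nothing to
#' score there.
#'
#' @param tensor a \linkS4class{SpatialTensor} or 3-way array.
#' @param k number of folds (>= 2).
#' @param seed RNG seed; the same seed reproduces the same folds.
#' @param inTissue optional ny x nx logical map of eligible spots.
#' @return a list of k integer vectors of linear spot indices into the
#'   ny x nx grid (column-major).
#' @export
makeSpotFolds <- function(tensor, k = 5, seed = 1, inTissue = NULL) {
  v <- if (is(tensor, "SpatialTensor")) tensor@values else tensor
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  spotTotals <- apply(v, c(1L, 2L), sum)
  eligible <- which(spotTotals > 0)
  if (!is.null(inTissue)) eligible <- intersect(eligible, which(inTissue))
  n <- length(eligible)
  if (n < k) stop("fewer eligible spots than folds")
  perm <- .withSeed(seed, sample(eligible))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  folds <- split(perm, rep(seq_len(k), times = sizes))
  names(folds) <- paste0("fold", seq_len(k))
  folds
}

#' Remove held-out spots from a training mask
#'
#' Returns a copy of the mask with every gene entry at the test spots set
#' to 0, so those spots carry no weight in the fit.
#'
#' @param mask binary 3-way array.
#' @param testSpots integer linear indices into the ny x nx grid.
#' @return a binary array like \code{mask}.
#' @export
holdoutMask <- function(mask, testSpots) {
  d <- dim(mask)
  nspot <- d[1L] * d[2L]
  testSpots <- as.integer(testSpots)
  if (length(testSpots) == 0L) return(mask)
  if (any(testSpots < 1L | testSpots > nspot)) stop("spot index out of range")
  m <- mask
  dim(m) <- c(nspot, d[3L])
  m[testSpots, ] <- 0
  dim(m) <- d
  m
}

#' Imputation accuracy at held-out spots
#'
#' Compares imputed against true expression at held-out spots. MAE is the
#' mean absolute error over the evaluation entries; MAPE the mean of
#' |truth - pred| / truth over entries with positive truth; R^2 is computed
#' per spot across its evaluation genes as 1 - SSres/SStot and then
#' averaged over spots (spots whose truth has zero variance are skipped).
#' By default evaluation entries are those observed (nonzero) in the truth
#' at the held-out spots — scoring against dropout zeros would penalize a
#' correct imputation.
#'
#' @param truth,predicted 3-way arrays of identical shape.
#' @param testSpots integer linear spot indices (ny x nx grid).
#' @param entries \code{"nonzero"} (default) or \code{"all"}; MAPE is
#'   always restricted to positive-truth entries.
#' @return named numeric vector \code{c(MAE, MAPE, R2)}.
#' @export
imputationMetrics <- function(truth, predicted, testSpots,
                              entries = c("nonzero", "all")) {
  entries <- match.arg(entries)
  d <- dim(truth)
  if (!identical(d, dim(predicted))) stop("shape mismatch")
  nspot <- d[1L] * d[2L]
  tr <- truth; pr <- predicted
  dim(tr) <- c(nspot, d[3L]); dim(pr) <- c(nspot, d[3L])
  tr <- tr[testSpots, , drop = FALSE]
  pr <- pr[testSpots, , drop = FALSE]
  sel <- if (entries == "nonzero") tr > 0 else array(TRUE, dim(tr))
  if (!any(sel)) stop("no evaluation entries at the held-out spots")
  err <- abs(tr - pr)
  mae <- mean(err[sel])
  pos <- tr > 0 & sel
  if (!any(pos)) stop("MAPE undefined: no positive-truth entries")
  mape <- mean(err[pos] / tr[pos])
  r2s <- vapply(seq_len(nrow(tr)), function(s) {
    use <- sel[s, ]
    y <- tr[s, use]; yh <- pr[s, use]
    if (length(y) < 2L || stats::var(y) == 0) return(NA_real_)
    1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  c(MAE = mae, MAPE = mape, R2 = mean(r2s, na.rm = TRUE))
}

#' Area under the ROC curve of a score against binary labels
#'
#' Threshold-sweep AUC, computed as the normalized Mann-Whitney rank-sum
#' statistic; tied scores count one half. Used to score a spatial component
#' map against a binarized region annotation.
#'
#' @param score numeric vector (e.g. component values per spot).
#' @param labels logical or 0/1 vector; needs at least one positive and one
#'   negative.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(score, labels) {
  labels <- as.logical(labels)
  if (length(score) != length(labels)) stop("length mismatch")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: labels must contain both classes")
  r <- rank(score) # average ranks -> ties count 1/2
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Euclidean distance between unit-normalized maps
#'
#' Both inputs are scaled to unit L2 norm and the Euclidean distance
#' between them is returned; for nonnegative inputs the range is
#' [0, sqrt(2)], with 0 for proportional maps and sqrt(2) for maps with
#' disjoint support.
#'
#' @param a,b numeric vectors/arrays of equal length with positive norm.
#' @return nonnegative scalar.
#' @export
normalizedDistance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm input")
  sqrt(sum((a / na - b / nb)^2))
}

#' Cluster spots by their spatial-component coefficients
#'
#' Runs k-means on the rg-dimensional vector of component values at each
#' selected spot — the standard route from components to spatial domains.
#' Deterministic given the seed (a fixed number of restarts under a seeded
#' generator).
#'
#' @param comps a \linkS4class{SpatialComponents}.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed.
#' @param spots optional ny x nx logical map restricting clustering to
#'   in-tissue spots; default: all spots.
#' @param nstart k-means restarts (default 10).
#' @return integer cluster labels, one per selected spot (column-major spot
#'   order), with the linear spot indices as names.
#' @export
clusterSpots <- function(comps, k, seed = 1, spots = NULL, nstart = 10) {
  maps <- componentMaps(comps)
  d <- dim(maps)
  X <- maps; dim(X) <- c(d[1L] * d[2L], d[3L])
  idx <- if (is.null(spots)) seq_len(nrow(X)) else which(as.logical(spots))
  X <- X[idx, , drop = FALSE]
  if (nrow(X) < k) stop("fewer spots than clusters")
  km <- .withSeed(seed, stats::kmeans(X, centers = k, nstart = nstart,
                                      iter.max = 100))
  stats::setNames(km$cluster, idx)
}

#' Adjusted Rand Index between two labelings
#'
#' Rand index corrected for chance via the hypergeometric baseline,
#' computed from the contingency table: 1 for identical partitions (up to
#' relabeling), about 0 for independent ones.
#'
#' @param a,b label vectors over the same items.
#' @return numeric scalar (<= 1).
#' @export
ariScore <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumA <- sum(comb2(rowSums(tab)))
  sumB <- sum(comb2(colSums(tab)))
  expected <- sumA * sumB / comb2(n)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(1) # both partitions trivial
  (sumIJ - expected) / (maxIdx - expected)
}

#' Spot-wise cross-validated imputation
#'
#' The full evaluation protocol: split eligible spots into k folds; for
#' each fold, zero the training mask at the held-out spots, fit the
#' decomposition on the remaining spots, impute the full tensor and score
#' MAE / MAPE / R^2 at the held-out spots.
#'
#' @param tensor a \linkS4class{SpatialTensor} with a mask attached, or an
#'   array (then a nonzero-mask is built).
#' @param graphs passed to \code{\link{fitSpatialTucker}}.
#' @param rank,lambda,maxIter,tol,seed fit parameters; \code{seed} also
#'   seeds the fold split.
#' @param k number of folds (default 5).
#' @param inTissue optional eligibility map for the folds.
#' @return a data.frame with one row per fold (fold, MAE, MAPE, R2) and the
#'   fold list as attribute \code{"folds"}.
#' @export
crossValidate <- function(tensor, graphs = NULL, rank, lambda = 0.1, k = 5,
                          maxIter = 500, tol = 1e-4, seed = 1,
                          inTissue = NULL) {
  x <- .resolveTensorMask(tensor, NULL)
  T <- x$T
  M <- x$M
  if (is.null(M)) M <- array(as.numeric(T > 0), dim(T))
  folds <- makeSpotFolds(T, k = k, seed = seed, inTissue = inTissue)
  rows <- lapply(seq_along(folds), function(i) {
    mTrain <- holdoutMask(M, folds[[i]])
    fit <- fitSpatialTucker(T, mask = mTrain, graphs = graphs, rank = rank,
                            lambda = lambda, maxIter = maxIter, tol = tol,
                            seed = seed)
    met <- imputationMetrics(T, imputeExpression(fit), folds[[i]])
    data.frame(fold = i, MAE = met["MAE"], MAPE = met["MAPE"],
               R2 = met["R2"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "folds") <- folds
  out
}
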