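#' Simulate a spatial expression tensor with planted low-rank structure
#'
#' Generates everything the pipeline consumes, with the statistical
#' structure the model assumes: a nonnegative Tucker tensor whose y/x
#' factor columns are smooth bumps on the grid (discretized Gaussians at
#' staggered random centers), a sparse nonnegative gene factor in which
#' each gene has one dominant component, a core dominated by one
#' (y, x) pair per gene component so each gene component lights up one
#' spatial blob, multiplicative nonnegative noise, entry-level dropout to a
#' target density in the range seen on sparse spot-level platforms, a gene
#' network whose edges mostly connect genes sharing a dominant component
#' (plus random distractor edges), and blocky region annotations given by
#' the dominance sets of the planted spatial components.
#'
#' @param shape tensor dimensions (ny, nx, ng).
#' @param rank planted Tucker rank (ry, rx, rg); each \code{<= shape}, and
#'   \code{rg <= ry * rx} so every gene component gets its own (y, x)
#'   component pair.
#' @param smoothness bump standard deviation as a fraction of the axis
#'   length (default 0.25): neighbouring components overlap at their
#'   boundaries, as annotated tissue regions do.
#' @param noise multiplicative noise level: entries are scaled by
#'   \code{max(0, 1 + noise * N(0,1))}. The default 0.5 mimics the large
#'   relative measurement noise of low-depth spot-level counts (Poisson
#'   noise at a mean of a few UMIs is ~50-60\%).
#' @param density target fraction of observed (nonzero, kept) entries;
#'   default 0.10, at the dense end of typical spot-level data. Use 1 with
#'   \code{noise = 0} for an exactly low-rank, fully observed tensor.
#' @param edgeProb probability that two genes sharing a dominant component
#'   are connected in the network (default 0.3).
#' @param distractorFrac random distractor edges as a fraction of the true
#'   edge count (default 0.2).
#' @param seed RNG seed; identical seeds give identical outputs.
#' @return a list:
#'   \item{tensor}{\linkS4class{SpatialTensor} with the dropout mask
#'     attached (mask = 1 exactly at kept nonzero entries).}
#'   \item{network}{sparse gene-adjacency matrix.}
#'   \item{regions}{named list of binary ny x nx region maps, one per gene
#'     component.}
#'   \item{labels}{ny x nx integer map: which planted component dominates
#'     each spot.}
#'   \item{model}{the planted \linkS4class{TuckerModel}.}
#'   \item{components}{\linkS4class{SpatialComponents} of the planted
#'     model.}
#'   \item{clean}{the noiseless, fully observed low-rank array.}
#' @examples
#' sim <- simulateSpatialData(shape = c(20, 20, 40), rank = c(3, 3, 3),
#'                            seed = 7)
#' mean(tensorMask(sim$tensor))   # ~ target density
#' @export
simulateSpatialData <- function(shape = c(30, 30, 60), rank = c(4, 4, 4),
                                smoothness = 0.25, noise = 0.5,
                                density = 0.10, edgeProb = 0.3,
                                distractorFrac = 0.2, seed = 1) {
  shape <- as.integer(shape); rank <- as.integer(rank)
  if (length(shape) != 3L || length(rank) != 3L)
    stop("shape and rank must have length 3")
  if (any(rank > shape)) stop("rank cannot exceed shape")
  if (any(rank < 1L) || any(shape < 1L)) stop("shape/rank must be positive")
  if (rank[3L] > rank[1L] * rank[2L])
    stop("rg must not exceed ry * rx (one spatial pair per gene component)")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")

  .withSeed(seed, {
    # smooth spatial factors: one bump per column, centers staggered along
    # the axis so components occupy distinct territory for any seed
    bumpFactor <- function(n, r) {
      A <- matrix(0, n, r)
      seg <- n / r
      for (j in seq_len(r)) {
        center <- (j - 0.5) * seg + stats::runif(1, -0.25, 0.25) * seg
        A[, j] <- exp(-((seq_len(n) - center)^2) /
                        (2 * (smoothness * n)^2))
      }
      A
    }
    Ay <- bumpFactor(shape[1L], rank[1L])
    Ax <- bumpFactor(shape[2L], rank[2L])

    # sparse gene loadings: one dominant component per gene + faint
    # background. Genes sharing a dominant component get similar loading
    # magnitudes (co-expressed genes have similar profiles), which is the
    # assumption the gene-network penalty encodes.
    ng <- shape[3L]; rg <- rank[3L]
    dominant <- sample(rep_len(seq_len(rg), ng))
    Ag <- matrix(stats::runif(ng * rg, 0, 0.05), ng, rg)
    Ag[cbind(seq_len(ng), dominant)] <- stats::runif(ng, 0.85, 1.15)

    # core: one strong (y, x) pair per gene component (distinct pairs,
    # cycling through the grid of spatial components), sparse background
    core <- array(0, rank)
    for (k in seq_len(rg)) {
      iy <- (k - 1L) %% rank[1L] + 1L
      ix <- ((k - 1L) %/% rank[1L]) %% rank[2L] + 1L
      core[iy, ix, k] <- stats::runif(1, 2.5, 3.5)
    }
    bg <- stats::runif(length(core)) < 0.1 & core == 0
    core[bg] <- stats::runif(sum(bg), 0, 0.2)

    model <- TuckerModel(core, Ay, Ax, Ag)
    clean <- tuckerReconstruct(model)

    vals <- clean * pmax(0, 1 + noise * stats::rnorm(length(clean)))

    # dropout: keep entries with probability density / P(entry nonzero)
    nzFrac <- mean(vals > 1e-8)
    pKeep <- min(1, density / max(nzFrac, 1e-12))
    keep <- stats::runif(length(vals)) < pKeep & vals > 1e-8
    vals[!keep] <- 0
    mask <- array(as.numeric(keep), shape)

    # network: co-component edges + distractors
    pairs <- which(outer(dominant, dominant, "==") &
                     upper.tri(matrix(0, ng, ng)), arr.ind = TRUE)
    hit <- stats::runif(nrow(pairs)) < edgeProb
    ei <- pairs[hit, 1L]; ej <- pairs[hit, 2L]
    nd <- round(distractorFrac * length(ei))
    if (nd > 0) {
      di <- sample(ng, nd, replace = TRUE)
      dj <- sample(ng, nd, replace = TRUE)
      ok <- di != dj
      ei <- c(ei, pmin(di[ok], dj[ok]))
      ej <- c(ej, pmax(di[ok], dj[ok]))
    }
    gids <- paste0("g", seq_len(ng))
    network <- if (length(ei) == 0L)
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(ng, ng), dimnames = list(gids, gids))
    else geneNetworkFromEdges(data.frame(a = gids[ei], b = gids[ej]), gids)

    # planted regions: upper level sets of single planted spatial
    # components (spot belongs to region k where component k exceeds half
    # its peak); regions may overlap. Planted domain labels are the
    # k-means domains of the planted component coefficients — the same
    # segmentation procedure later applied to fitted components, run here
    # on the ground truth.
    comps <- spatialComponents(model)
    maps <- componentMaps(comps)
    regions <- lapply(seq_len(rg), function(k) {
      mk <- maps[, , k]
      matrix(as.numeric(mk >= 0.5 * max(mk)), shape[1L], shape[2L])
    })
    names(regions) <- paste0("region", seq_len(rg))
    labels <- matrix(as.integer(clusterSpots(comps, k = rg, seed = seed)),
                     shape[1L], shape[2L])

    list(tensor = SpatialTensor(vals, geneIds = gids, mask = mask),
         network = network, regions = regions, labels = labels,
         model = model, components = comps, clean = clean)
  })
}
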