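#' @import methods
#' @importFrom Matrix Diagonal sparseMatrix rowSums colSums t crossprod
NULL

.checkNonneg <- function(x, what) {
  if (any(!is.finite(x))) return(sprintf("%s contains non-finite values", what))
  if (any(x < 0)) return(sprintf("%s contains negative values", what))
  NULL
}

#' SpatialTensor: a three-way (y, x, gene) expression tensor
#'
#' Container for a nonnegative spatial gene-expression tensor laid out as
#' \code{values[y, x, gene]}, together with the gene identifiers aligned to
#' the third axis and an optional binary observation mask of the same shape
#' (1 = observed/training entry, 0 = missing or held out).
#'
#' The axis convention is fixed throughout the package: mode 1 is the
#' y-coordinate (grid row), mode 2 the x-coordinate (grid column), mode 3
#' the gene.
#'
#' @slot values nonnegative numeric 3-way array, dim \code{(ny, nx, ng)}.
#' @slot geneIds character vector of length \code{ng}.
#' @slot mask numeric 3-way array of 0/1 with the same dim as \code{values},
#'   or a 0-length array meaning "no mask attached".
#' @exportClass SpatialTensor
setClass("SpatialTensor",
  representation(values = "array", geneIds = "character", mask = "array"),
  prototype(values = array(0, c(1, 1, 1)), geneIds = "g1",
            mask = array(numeric(0), c(0, 0, 0))))

setValidity("SpatialTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-way array")
  if (any(d < 1L)) return("all tensor dimensions must be >= 1")
  msg <- .checkNonneg(object@values, "values")
  if (!is.null(msg)) return(msg)
  if (length(object@geneIds) != d[3L])
    return("geneIds length must equal the gene dimension")
  if (length(object@mask) > 0L) {
    if (!identical(dim(object@mask), d))
      return("mask dim must match values dim")
    if (!all(object@mask %in% c(0, 1)))
      return("mask must be binary (0/1)")
  }
  TRUE
})

#' Construct a SpatialTensor
#'
#' @param values nonnegative 3-way array indexed (y, x, gene).
#' @param geneIds gene identifiers for the third axis; defaults to
#'   \code{dimnames(values)[[3]]} or \code{"g1"..."gng"}.
#' @param mask optional binary array of the same shape (1 = observed).
#' @return A \linkS4class{SpatialTensor}.
#' @examples
#' st <- SpatialTensor(array(rpois(24, 2), c(2, 3, 4)))
#' dim(st)
#' @export
SpatialTensor <- function(values, geneIds = NULL, mask = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  storage.mode(values) <- "double"
  if (is.null(geneIds)) {
    geneIds <- dimnames(values)[[3L]]
    if (is.null(geneIds)) geneIds <- paste0("g", seq_len(dim(values)[3L]))
  }
  if (is.null(mask)) mask <- array(numeric(0), c(0, 0, 0))
  else storage.mode(mask) <- "double"
  new("SpatialTensor", values = values, geneIds = as.character(geneIds),
      mask = mask)
}

#' @describeIn SpatialTensor tensor dimensions (ny, nx, ng)
#' @param x a SpatialTensor
#' @export
setMethod("dim", "SpatialTensor", function(x) dim(x@values))

#' Accessors for SpatialTensor
#'
#' \code{tensorValues} returns the dense array, \code{tensorMask} the binary
#' observation mask (or NULL if none is attached) and \code{geneIds} the gene
#' identifiers of the third axis.
#'
#' @param x a \linkS4class{SpatialTensor}.
#' @return array, array/NULL, or character vector respectively.
#' @export
tensorValues <- function(x) x@values

#' @rdname tensorValues
#' @export
tensorMask <- function(x) if (length(x@mask) == 0L) NULL else x@mask

#' @rdname tensorValues
#' @export
geneIds <- function(x) x@geneIds

setMethod("show", "SpatialTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpatialTensor: %d x %d x %d (y, x, gene)\n", d[1], d[2], d[3]))
  nz <- sum(object@values != 0)
  cat(sprintf("  density: %.4f  (%d nonzero entries)\n",
              nz / prod(d), nz))
  if (length(object@mask) > 0L)
    cat(sprintf("  mask: %d observed entries (%.4f)\n",
                sum(object@mask), mean(object@mask)))
})

#' TuckerModel: core tensor plus per-mode factor matrices
#'
#' A rank-\code{(ry, rx, rg)} nonnegative Tucker model of a (y, x, gene)
#' tensor: a core array \code{G} of dim \code{(ry, rx, rg)} and factors
#' \code{Ay (ny x ry)}, \code{Ax (nx x rx)}, \code{Ag (ng x rg)}. The
#' reconstruction is \code{G x1 Ay x2 Ax x3 Ag} (see
#' \code{\link{tuckerReconstruct}}).
#'
#' @slot core nonnegative 3-way array (ry, rx, rg).
#' @slot Ay,Ax,Ag nonnegative factor matrices.
#' @exportClass TuckerModel
setClass("TuckerModel",
  representation(core = "array", Ay = "matrix", Ax = "matrix", Ag = "matrix"))

setValidity("TuckerModel", function(object) {
  r <- dim(object@core)
  if (length(r) != 3L) return("core must be a 3-way array")
  if (ncol(object@Ay) != r[1L]) return("ncol(Ay) must equal dim(core)[1]")
  if (ncol(object@Ax) != r[2L]) return("ncol(Ax) must equal dim(core)[2]")
  if (ncol(object@Ag) != r[3L]) return("ncol(Ag) must equal dim(core)[3]")
  for (nm in c("core", "Ay", "Ax", "Ag")) {
    msg <- .checkNonneg(slot(object, nm), nm)
    if (!is.null(msg)) return(msg)
  }
  TRUE
})

#' Construct a TuckerModel
#'
#' @param core nonnegative 3-way array (ry, rx, rg).
#' @param Ay,Ax,Ag nonnegative factor matrices with column counts matching
#'   the core dimensions.
#' @return A \linkS4class{TuckerModel}.
#' @export
TuckerModel <- function(core, Ay, Ax, Ag) {
  storage.mode(core) <- "double"
  new("TuckerModel", core = core, Ay = as.matrix(Ay), Ax = as.matrix(Ax),
      Ag = as.matrix(Ag))
}

#' Accessors for TuckerModel
#'
#' @param x a \linkS4class{TuckerModel}.
#' @return \code{tuckerCore} returns the core array; \code{tuckerFactor}
#'   returns the factor matrix of the requested mode (1 = y, 2 = x,
#'   3 = gene).
#' @export
tuckerCore <- function(x) x@core

#' @rdname tuckerCore
#' @param mode integer in 1:3.
#' @export
tuckerFactor <- function(x, mode) {
  switch(as.integer(mode), x@Ay, x@Ax, x@Ag,
         stop("mode must be 1, 2 or 3"))
}

#' @rdname tuckerCore
#' @export
tuckerRank <- function(x) dim(x@core)

setMethod("show", "TuckerModel", function(object) {
  r <- dim(object@core)
  cat(sprintf("TuckerModel rank (%d, %d, %d) on shape (%d, %d, %d)\n",
              r[1], r[2], r[3],
              nrow(object@Ay), nrow(object@Ax), nrow(object@Ag)))
})

#' GraphSet: per-mode graph Laplacians aligned to the tensor axes
#'
#' Holds the Laplacians of the y-chain, x-chain and gene-network graphs
#' (\code{L = D - W}, symmetric positive semidefinite, zero row sums). The
#' Cartesian-product Laplacian — the Kronecker sum of the three — is never
#' materialized; \code{\link{productQuadraticForm}} evaluates its quadratic
#' form mode-wise.
#'
#' @slot Ly,Lx,Lg sparse symmetric Laplacians (\code{Matrix} class) of
#'   dimension ny, nx, ng.
#' @exportClass GraphSet
setClass("GraphSet",
  representation(Ly = "Matrix", Lx = "Matrix", Lg = "Matrix"))

setValidity("GraphSet", function(object) {
  for (nm in c("Ly", "Lx", "Lg")) {
    L <- slot(object, nm)
    if (nrow(L) != ncol(L)) return(sprintf("%s must be square", nm))
    if (max(abs(Matrix::rowSums(L))) > 1e-8)
      return(sprintf("%s must have zero row sums", nm))
  }
  TRUE
})

#' Extract one mode's Laplacian from a GraphSet
#'
#' @param x a \linkS4class{GraphSet}.
#' @param mode integer in 1:3 (1 = y, 2 = x, 3 = gene).
#' @return a sparse symmetric Laplacian matrix.
#' @export
graphLaplacianOf <- function(x, mode) {
  switch(as.integer(mode), x@Ly, x@Lx, x@Lg,
         stop("mode must be 1, 2 or 3"))
}

setMethod("show", "GraphSet", function(object) {
  cat(sprintf("GraphSet: Ly %d x %d, Lx %d x %d, Lg %d x %d (%d gene edges)\n",
              nrow(object@Ly), ncol(object@Ly),
              nrow(object@Lx), ncol(object@Lx),
              nrow(object@Lg), ncol(object@Lg),
              (length(object@Lg@x[object@Lg@x != 0]) -
                 sum(Matrix::diag(object@Lg) != 0)) %/% 2L))
})

#' SpatialComponents: per-gene-component spatial activity maps
#'
#' A 3-way array of dim \code{(ny, nx, rg)}; slice \code{[ , , k]} is the
#' spatial activity map of gene component k, obtained by contracting the
#' core with the y- and x-factors (\code{\link{spatialComponents}}).
#'
#' @slot values nonnegative (ny, nx, rg) array.
#' @exportClass SpatialComponents
setClass("SpatialComponents", representation(values = "array"))

setValidity("SpatialComponents", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be 3-way")
  .checkNonneg(object@values, "values") %||% TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname spatialComponents
#' @param x a SpatialComponents object
#' @export
componentMaps <- function(x) x@values

#' @rdname spatialComponents
#' @export
nComponents <- function(x) dim(x@values)[3L]

setMethod("show", "SpatialComponents", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpatialComponents: %d maps of %d x %d spots\n",
              d[3], d[1], d[2]))
})

#' TuckerFit: result of a decomposition run
#'
#' @slot model the fitted (normalized) \linkS4class{TuckerModel}.
#' @slot trace numeric matrix with one row per iteration and columns
#'   \code{F1} (masked data-fit term), \code{F2} (graph penalty) and
#'   \code{total} (= F1 + lambda * F2).
#' @slot nIter number of iterations run.
#' @slot converged logical; TRUE if the relative-objective criterion was met
#'   before the iteration cap.
#' @slot lambda graph-regularization weight used.
#' @slot seed integer seed used for the random initialization.
#' @exportClass TuckerFit
setClass("TuckerFit",
  representation(model = "TuckerModel", trace = "matrix", nIter = "integer",
                 converged = "logical", lambda = "numeric", seed = "integer"))

#' @rdname fitSpatialTucker
#' @param x a TuckerFit
#' @export
fittedModel <- function(x) x@model

#' @rdname fitSpatialTucker
#' @export
objectiveTrace <- function(x) x@trace

setMethod("show", "TuckerFit", function(object) {
  r <- dim(object@model@core)
  cat(sprintf(
    "TuckerFit: rank (%d, %d, %d), lambda = %g, %d iterations (%s)\n",
    r[1], r[2], r[3], object@lambda, object@nIter,
    if (object@converged) "converged" else "iteration cap reached"))
  if (nrow(object@trace) > 0)
    cat(sprintf("  final objective: F1 = %.6g, F2 = %.6g, total = %.6g\n",
                object@trace[nrow(object@trace), "F1"],
                object@trace[nrow(object@trace), "F2"],
                object@trace[nrow(object@trace), "total"]))
})
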