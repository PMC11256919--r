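#' Spatial components of a fitted Tucker model
#'
#' Contracts the core with the y- and x-factors, leaving one nonnegative
#' (ny x nx) spatial activity map per gene component: map k aggregates, with
#' core weights, every combination of a y-component and an x-component
#' interacting with gene component k. Applying the gene factor along mode 3
#' reproduces the reconstruction exactly:
#' \code{componentMaps(sc) x3 Ag == tuckerReconstruct(model)}.
#'
#' Use a normalized model (see \code{\link{normalizeModel}}) so that core
#' magnitudes, and hence component scales, are comparable. A sparsified
#' core (\code{\link{sparsifyCore}}) can be passed to restrict the maps to
#' the strongest multiway interactions.
#'
#' @param model a \linkS4class{TuckerModel}.
#' @param core optional core override (e.g. a sparsified core); must have
#'   the model's core dimensions.
#' @return a \linkS4class{SpatialComponents} of dim (ny, nx, rg).
#' @export
spatialComponents <- function(model, core = NULL) {
  if (is.null(core)) core <- model@core
  if (!identical(dim(core), dim(model@core)))
    stop("core override must match the model's core dimensions")
  maps <- nmodeProduct(nmodeProduct(core, model@Ay, 1L), model@Ax, 2L)
  new("SpatialComponents", values = maps)
}

#' Keep only the largest entries of a core tensor
#'
#' Zeroes all but the top \code{percent}\% of core entries, ranked by value
#' (the core of a nonnegative fit is nonnegative; set
#' \code{by = "abs"} to rank by magnitude instead). The number kept is
#' \code{k = ceiling(percent/100 * length(core))}; ties at the threshold
#' are broken by keeping earlier entries in column-major order, so the
#' result is deterministic.
#'
#' @param core nonnegative 3-way array.
#' @param percent value in (0, 100].
#' @param by rank entries by \code{"value"} (default) or \code{"abs"}.
#' @return an array like \code{core} with all but k entries set to zero.
#' @export
sparsifyCore <- function(core, percent, by = c("value", "abs")) {
  by <- match.arg(by)
  if (!is.numeric(percent) || length(percent) != 1L ||
      percent <= 0 || percent > 100)
    stop("percent must be in (0, 100]")
  n <- length(core)
  k <- ceiling(percent / 100 * n)
  key <- if (by == "abs") abs(as.numeric(core)) else as.numeric(core)
  # order(-key, index) keeps earlier indices on ties
  keep <- order(key, seq_len(n), decreasing = c(TRUE, FALSE),
                method = "radix")[seq_len(k)]
  out <- array(0, dim(core))
  out[keep] <- core[keep]
  out
}

#' Fraction of total core mass retained at a sparsity level
#'
#' The sum of the entries kept by \code{\link{sparsifyCore}} divided by the
#' total core sum — how much of the total multiway-interaction weight the
#' top \code{percent}\% of entries account for.
#'
#' @inheritParams sparsifyCore
#' @return a scalar in (0, 1].
#' @export
coreMassFraction <- function(core, percent) {
  tot <- sum(core)
  if (tot <= 0) stop("core must have positive total sum")
  sum(sparsifyCore(core, percent)) / tot
}

#' Match annotated regions to spatial components
#'
#' For every (region, component) pair, computes the AUC of the component
#' map against the binary region and the Euclidean distance between the two
#' maps after normalizing each to unit length, then assigns each region the
#' component with the smallest distance. Several regions may map to the
#' same component. Regions without a positive spot are skipped with a
#' warning.
#'
#' @param comps a \linkS4class{SpatialComponents}.
#' @param regions a named list of binary (ny x nx) region maps, or a single
#'   such map.
#' @param spots optional logical (ny x nx) map restricting scoring to
#'   in-tissue spots (AUC needs negatives drawn from the tissue, not the
#'   empty frame).
#' @return a data.frame with columns \code{region}, \code{component},
#'   \code{auc}, \code{ed}, one row per scored region.
#' @export
matchRegions <- function(comps, regions, spots = NULL) {
  maps <- componentMaps(comps)
  if (is.matrix(regions)) regions <- list(region1 = regions)
  if (is.null(names(regions)))
    names(regions) <- paste0("region", seq_along(regions))
  use <- if (is.null(spots)) rep(TRUE, prod(dim(maps)[1:2]))
         else as.logical(spots)
  res <- list()
  for (rn in names(regions)) {
    reg <- as.numeric(regions[[rn]])[use]
    if (sum(reg > 0) == 0L) {
      warning(sprintf("region '%s' has no positive spot; skipped", rn))
      next
    }
    auc <- ed <- numeric(dim(maps)[3L])
    for (k in seq_len(dim(maps)[3L])) {
      cm <- as.numeric(maps[, , k])[use]
      ed[k] <- normalizedDistance(cm, reg)
      auc[k] <- if (all(reg > 0)) NA_real_ else aucScore(cm, reg > 0)
    }
    best <- which.min(ed)
    res[[rn]] <- data.frame(region = rn, component = best,
                            auc = auc[best], ed = ed[best],
                            stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(region = character(0), component = integer(0),
                      auc = numeric(0), ed = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Average several spatial components into one map
#'
#' Elementwise mean of the selected component maps — used to summarize a
#' set of components that jointly cover one anatomical structure.
#'
#' @param comps a \linkS4class{SpatialComponents}.
#' @param ids nonempty integer vector of component indices.
#' @return an (ny x nx) matrix.
#' @export
combineComponents <- function(comps, ids) {
  ids <- as.integer(ids)
  if (length(ids) == 0L) stop("ids must be nonempty")
  maps <- componentMaps(comps)
  if (any(ids < 1L | ids > dim(maps)[3L])) stop("component index out of range")
  out <- maps[, , ids[1L]]
  if (length(ids) > 1L)
    for (k in ids[-1L]) out <- out + maps[, , k]
  out / length(ids)
}
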