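# From spot-level count matrices on a Visium-style grid to the (y, x, gene)
# tensor: hex-to-square shift -> tensorize -> low-count entry threshold ->
# low-total gene filter -> crop empty border rows/columns -> log1p.

#' Read 10x-style spot-level inputs
#'
#' Loads a MatrixMarket count matrix with its features/barcodes TSVs and a
#' tissue-positions table (10x dialect: barcode, in_tissue, array_row,
#' array_col, pixel columns ignored). Counts are aligned to the positions
#' by barcode.
#'
#' @param mtx path to the MatrixMarket counts file (genes x spots).
#' @param features path to features.tsv (first column = gene id).
#' @param barcodes path to barcodes.tsv (one barcode per line).
#' @param positions path to the tissue positions CSV.
#' @return a list with \code{counts} (sparse genes x spots),
#'   \code{geneIds}, \code{barcodes} and \code{positions} (data.frame with
#'   barcode, in_tissue, array_row, array_col), the "spot table" consumed
#'   by \code{\link{buildTensor}}.
#' @export
readSpotCounts <- function(mtx, features, barcodes, positions) {
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feats <- utils::read.delim(features, header = FALSE,
                             stringsAsFactors = FALSE)
  bcs <- utils::read.delim(barcodes, header = FALSE,
                           stringsAsFactors = FALSE)[[1L]]
  pos <- utils::read.csv(positions, header = FALSE,
                         stringsAsFactors = FALSE)
  if (is.character(pos[[2L]])) # header line present
    pos <- utils::read.csv(positions, header = TRUE,
                           stringsAsFactors = FALSE)
  names(pos)[1:4] <- c("barcode", "in_tissue", "array_row", "array_col")
  if (nrow(counts) != nrow(feats))
    stop("features.tsv does not match the count matrix rows")
  if (ncol(counts) != length(bcs))
    stop("barcodes.tsv does not match the count matrix columns")
  pos <- pos[match(bcs, pos$barcode), , drop = FALSE]
  if (anyNA(pos$barcode))
    stop("some barcodes are missing from the positions table")
  list(counts = counts, geneIds = as.character(feats[[1L]]),
       barcodes = bcs, positions = pos[, 1:4])
}

#' Map Visium hexagonal array coordinates onto a square grid
#'
#' The Visium array staggers odd rows by half a spot; shifting odd rows by
#' half a spot and halving the column index gives integer square-grid
#' coordinates: \code{y = array_row}, \code{x = (array_col - (array_row
#' \%\% 2)) / 2}. On a valid slide row and column parity agree, which makes
#' the mapping injective; a parity violation is reported with the offending
#' barcode. With \code{grid = "square"} (e.g. binned Stereo-seq input) the
#' coordinates pass through unchanged.
#'
#' @param positions data.frame with columns barcode, in_tissue, array_row,
#'   array_col.
#' @param grid \code{"hex"} (Visium, default) or \code{"square"}.
#' @return the data.frame with integer columns \code{y} and \code{x} added
#'   (0-based).
#' @export
hexToSquare <- function(positions, grid = c("hex", "square")) {
  grid <- match.arg(grid)
  row <- as.integer(positions$array_row)
  col <- as.integer(positions$array_col)
  if (grid == "square") {
    positions$y <- row
    positions$x <- col
    return(positions)
  }
  bad <- (col - row %% 2L) %% 2L != 0L
  if (any(bad))
    stop(sprintf("row/column parity violated at spot '%s' (row %d, col %d)",
                 positions$barcode[which(bad)[1L]], row[which(bad)[1L]],
                 col[which(bad)[1L]]))
  positions$y <- row
  positions$x <- (col - row %% 2L) %/% 2L
  dup <- duplicated(positions[, c("y", "x")])
  if (any(dup))
    stop(sprintf("grid mapping not injective: spot '%s' collides",
                 positions$barcode[which(dup)[1L]]))
  positions
}

#' Arrange spot counts into a (y, x, gene) tensor
#'
#' Places each in-tissue spot's count vector at its square-grid coordinate
#' and crops grid rows/columns that contain no in-tissue spot, so the
#' tensor spans exactly the occupied bounding grid.
#'
#' @param spots a spot table from \code{\link{readSpotCounts}} (counts,
#'   geneIds, positions).
#' @param grid passed to \code{\link{hexToSquare}}.
#' @param inTissueOnly drop spots flagged out-of-tissue (default TRUE).
#' @return a list: \code{tensor} (a \linkS4class{SpatialTensor} of raw
#'   counts), \code{inTissue} (ny x nx logical map of occupied spots).
#' @export
buildTensor <- function(spots, grid = c("hex", "square"),
                        inTissueOnly = TRUE) {
  pos <- hexToSquare(spots$positions, grid)
  if (inTissueOnly) {
    keep <- pos$in_tissue == 1
    pos <- pos[keep, , drop = FALSE]
    counts <- spots$counts[, keep, drop = FALSE]
  } else counts <- spots$counts
  if (nrow(pos) == 0L) stop("no spots left after in-tissue filtering")
  # crop to the occupied bounding box; occupied rows/cols only
  ys <- sort(unique(pos$y)); xs <- sort(unique(pos$x))
  yi <- match(pos$y, ys); xi <- match(pos$x, xs)
  if (anyDuplicated(cbind(yi, xi)))
    stop("two spots map to the same grid cell")
  ny <- length(ys); nx <- length(xs); ng <- nrow(counts)
  vals <- array(0, c(ny, nx, ng))
  dense <- as.matrix(counts) # genes x spots
  for (s in seq_len(nrow(pos)))
    vals[yi[s], xi[s], ] <- dense[, s]
  inTissue <- matrix(FALSE, ny, nx)
  inTissue[cbind(yi, xi)] <- TRUE
  list(tensor = SpatialTensor(vals, geneIds = spots$geneIds),
       inTissue = inTissue)
}

#' Zero low-count entries and drop low-total genes
#'
#' Two cleaning rules applied in a fixed order: entries with fewer than
#' \code{entryMin} UMI counts are set to 0, then genes whose total count
#' (after the entry threshold) is below \code{geneMin} are removed and the
#' gene axis shrinks accordingly.
#'
#' @param tensor a \linkS4class{SpatialTensor} of raw counts.
#' @param entryMin entries strictly below this are zeroed (default 3).
#' @param geneMin genes with total strictly below this are dropped
#'   (default 4).
#' @return a \linkS4class{SpatialTensor}; \code{geneIds} reflects the kept
#'   genes.
#' @export
filterCounts <- function(tensor, entryMin = 3, geneMin = 4) {
  v <- tensor@values
  v[v < entryMin] <- 0
  totals <- apply(v, 3L, sum)
  keep <- totals >= geneMin
  if (!any(keep)) stop("no genes left after filtering")
  SpatialTensor(v[, , keep, drop = FALSE], geneIds = tensor@geneIds[keep])
}

#' Log-transform a count tensor
#'
#' Natural log of (1 + count), elementwise; monotone and zero-preserving.
#'
#' @param tensor a \linkS4class{SpatialTensor} (or 3-way array).
#' @return object of the same type with transformed values.
#' @export
logTransform <- function(tensor) {
  if (is(tensor, "SpatialTensor")) {
    if (any(tensor@values < 0)) stop("negative entries cannot be log-scaled")
    return(SpatialTensor(log1p(tensor@values), geneIds = tensor@geneIds,
                         mask = tensorMask(tensor)))
  }
  if (any(tensor < 0)) stop("negative entries cannot be log-scaled")
  log1p(tensor)
}

#' Build an observation mask for training
#'
#' \code{"nonzero"} (default) marks exactly the nonzero entries of the
#' tensor as observed — dropout zeros are treated as missing, which is what
#' makes imputing the complete spatial transcriptome meaningful.
#' \code{"in-tissue"} marks every gene at every occupied spot as observed,
#' treating zeros inside the tissue as true absences.
#'
#' @param tensor a \linkS4class{SpatialTensor} or 3-way array.
#' @param mode \code{"nonzero"} or \code{"in-tissue"}.
#' @param inTissue ny x nx logical map (required for \code{"in-tissue"}).
#' @return a binary array of the tensor's shape.
#' @export
buildMask <- function(tensor, mode = c("nonzero", "in-tissue"),
                      inTissue = NULL) {
  mode <- match.arg(mode)
  v <- if (is(tensor, "SpatialTensor")) tensor@values else tensor
  if (mode == "nonzero") return(array(as.numeric(v > 0), dim(v)))
  if (is.null(inTissue)) stop("mode 'in-tissue' needs the inTissue map")
  m <- array(0, dim(v))
  for (g in seq_len(dim(v)[3L])) m[, , g] <- as.numeric(inTissue)
  m
}

#' Full preprocessing pipeline
#'
#' Runs hex-to-square mapping, tensor assembly with cropping, the entry and
#' gene count filters, the log1p transform, and mask construction, in that
#' order. Rerunning the pipeline on its own output leaves it unchanged.
#'
#' @inheritParams buildTensor
#' @inheritParams filterCounts
#' @param maskMode passed to \code{\link{buildMask}}.
#' @return list: \code{tensor} (log-scale \linkS4class{SpatialTensor} with
#'   mask attached), \code{inTissue} map.
#' @export
preprocessSpots <- function(spots, grid = c("hex", "square"), entryMin = 3,
                            geneMin = 4,
                            maskMode = c("nonzero", "in-tissue")) {
  built <- buildTensor(spots, grid)
  filt <- filterCounts(built$tensor, entryMin = entryMin, geneMin = geneMin)
  logt <- logTransform(filt)
  m <- buildMask(logt, maskMode, inTissue = built$inTissue)
  list(tensor = SpatialTensor(logt@values, geneIds = logt@geneIds, mask = m),
       inTissue = built$inTissue)
}

#' Write / read a tensor as a dense-array file with a JSON sidecar
#'
#' The values go to \code{<stem>.values.tsv} (one entry per line, R
#' column-major order over (y, x, gene)); shape, axis names, gene ids and
#' the mask (as linear indices of observed entries) go to
#' \code{<stem>.json}.
#'
#' @param tensor a \linkS4class{SpatialTensor}.
#' @param stem output path stem (no extension).
#' @return \code{writeSpatialTensor}: the stem, invisibly;
#'   \code{readSpatialTensor}: a \linkS4class{SpatialTensor}.
#' @export
writeSpatialTensor <- function(tensor, stem) {
  v <- tensor@values
  utils::write.table(data.frame(value = as.numeric(v)),
                     paste0(stem, ".values.tsv"),
                     row.names = FALSE, col.names = TRUE, sep = "\t")
  m <- tensorMask(tensor)
  meta <- list(shape = dim(v), axes = c("y", "x", "gene"),
               order = "column-major", geneIds = tensor@geneIds,
               observed = if (is.null(m)) NULL else which(m == 1))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeSpatialTensor
#' @export
readSpatialTensor <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  v <- utils::read.delim(paste0(stem, ".values.tsv"))[[1L]]
  vals <- array(v, meta$shape)
  mask <- NULL
  if (!is.null(meta$observed) && length(meta$observed) > 0) {
    mask <- array(0, meta$shape)
    mask[meta$observed] <- 1
  }
  SpatialTensor(vals, geneIds = meta$geneIds, mask = mask)
}
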