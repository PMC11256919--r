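#' Chain-graph adjacency matrix
#'
#' The unweighted path graph on n nodes (node i adjacent to i-1 and i+1,
#' weight 1) used to encode adjacency of neighbouring grid rows/columns.
#'
#' @param n number of nodes (>= 1); n = 1 gives a single edgeless node.
#' @return a sparse symmetric adjacency matrix with zero diagonal.
#' @examples
#' chainAdjacency(3)
#' @export
chainAdjacency <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (n == 1L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(1L, 1L)))
  i <- seq_len(n - 1L)
  Matrix::sparseMatrix(i = c(i, i + 1L), j = c(i + 1L, i),
                       x = rep(1, 2L * (n - 1L)), dims = c(n, n))
}

#' Graph Laplacian L = D - W
#'
#' @param W symmetric nonnegative adjacency matrix (zero diagonal); sparse
#'   or dense.
#' @return sparse symmetric positive-semidefinite matrix with zero row sums.
#' @export
graphLaplacian <- function(W) {
  W <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

#' Build a gene network aligned to a tensor's gene axis
#'
#' Restricts an edge list (e.g. a BioGRID-style two-column TSV of gene
#' symbols) to the genes on the tensor's gene axis: edges with both
#' endpoints present are kept, duplicates collapse, self-loops are dropped
#' and genes absent from the network become isolated nodes. Row/column
#' order of the result follows \code{genes} exactly, so the Laplacian is
#' aligned with mode 3 of the tensor.
#'
#' @param edges data.frame whose first two columns are gene identifiers;
#'   an optional third numeric column holds edge weights.
#' @param genes character vector: the tensor's gene axis, in order.
#' @param weighted if FALSE (default) the adjacency is binarized — duplicate
#'   evidence lines collapse to weight 1; if TRUE, duplicate weights are
#'   summed.
#' @return sparse symmetric adjacency matrix over \code{genes}.
#' @export
geneNetworkFromEdges <- function(edges, genes, weighted = FALSE) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene list must be nonempty")
  a <- match(as.character(edges[[1L]]), genes)
  b <- match(as.character(edges[[2L]]), genes)
  w <- if (ncol(edges) >= 3L && is.numeric(edges[[3L]])) as.numeric(edges[[3L]])
       else rep(1, nrow(edges))
  keep <- !is.na(a) & !is.na(b) & a != b
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  n <- length(genes)
  if (length(a) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n, n),
                                dimnames = list(genes, genes)))
  # undirected: store both orientations; sparseMatrix sums duplicates
  W <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = c(w, w),
                            dims = c(n, n), dimnames = list(genes, genes))
  # a duplicate pair listed in both orientations would double-count
  if (!weighted) W@x[] <- 1
  else {
    # collapse symmetric double counting of lines already given both ways
    U <- Matrix::sparseMatrix(i = pmin(a, b), j = pmax(a, b), x = w,
                              dims = c(n, n))
    W <- U + Matrix::t(U)
    dimnames(W) <- list(genes, genes)
  }
  W
}

#' @rdname geneNetworkFromEdges
#' @param path TSV file with columns gene_a, gene_b \code{[, weight]};
#'   a header line is detected and skipped if its first field is not a gene
#'   in \code{genes}.
#' @export
readGeneNetwork <- function(path, genes, weighted = FALSE) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             colClasses = "character")
  header <- !(first[[1L]] %in% genes)
  edges <- utils::read.delim(path, header = header,
                             stringsAsFactors = FALSE)
  geneNetworkFromEdges(edges, genes, weighted = weighted)
}

#' Assemble the per-mode Laplacians for a tensor
#'
#' Builds the chain-graph Laplacians for the y and x axes and the Laplacian
#' of the supplied gene network; a missing network gives an edgeless gene
#' graph (zero Laplacian), under which the penalty couples spots but not
#' genes.
#'
#' @param ny,nx spatial grid sizes.
#' @param geneAdj sparse gene-network adjacency (ng x ng), or an integer ng
#'   for an edgeless gene graph.
#' @return a \linkS4class{GraphSet}.
#' @export
makeGraphSet <- function(ny, nx, geneAdj) {
  if (is.numeric(geneAdj) && length(geneAdj) == 1L) {
    ng <- as.integer(geneAdj)
    geneAdj <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    x = numeric(0), dims = c(ng, ng))
  }
  new("GraphSet",
      Ly = graphLaplacian(chainAdjacency(ny)),
      Lx = graphLaplacian(chainAdjacency(nx)),
      Lg = graphLaplacian(geneAdj))
}

#' Quadratic form of the Cartesian-product-graph Laplacian
#'
#' Evaluates \code{vec(t)' (Lg (+) Ly (+) Lx) vec(t)} — the Kronecker-sum
#' Laplacian of the Cartesian product of the three mode graphs — without
#' ever forming the product Laplacian: the Kronecker sum acts mode-wise, so
#' the form equals \code{sum_m <t, t x_m L_m>}. Nonnegative; zero iff t is
#' constant on every connected component of every mode graph.
#'
#' @param t numeric 3-way array.
#' @param gs a \linkS4class{GraphSet} with Laplacian dimensions matching
#'   \code{dim(t)}.
#' @return a nonnegative scalar.
#' @export
productQuadraticForm <- function(t, gs) {
  d <- dim(t)
  Ls <- list(gs@Ly, gs@Lx, gs@Lg)
  for (m in 1:3)
    if (nrow(Ls[[m]]) != d[m])
      stop(sprintf("Laplacian for mode %d has dim %d, tensor has %d",
                   m, nrow(Ls[[m]]), d[m]))
  total <- 0
  for (m in 1:3) {
    U <- unfoldTensor(t, m)
    total <- total + sum(U * as.matrix(Ls[[m]] %*% U))
  }
  # clamp tiny negative round-off
  max(total, 0)
}
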