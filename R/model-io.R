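#' Write / read a Tucker model checkpoint
#'
#' Serializes the core and the three factor matrices as plain TSV files
#' next to a JSON sidecar holding the dimensions (and, for a fit, the
#' configuration and the tail of the objective trace), so a checkpoint is
#' human-inspectable and diffable.
#'
#' @param x a \linkS4class{TuckerModel} or \linkS4class{TuckerFit}.
#' @param stem output path stem (no extension).
#' @return \code{writeTuckerModel}: the stem, invisibly;
#'   \code{readTuckerModel}: a \linkS4class{TuckerModel}.
#' @export
writeTuckerModel <- function(x, stem) {
  fit <- NULL
  if (is(x, "TuckerFit")) { fit <- x; x <- x@model }
  writeMat <- function(m, name)
    utils::write.table(m, sprintf("%s.%s.tsv", stem, name),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
  writeMat(x@Ay, "Ay"); writeMat(x@Ax, "Ax"); writeMat(x@Ag, "Ag")
  writeMat(as.numeric(x@core), "core")
  meta <- list(rank = dim(x@core),
               shape = c(nrow(x@Ay), nrow(x@Ax), nrow(x@Ag)))
  if (!is.null(fit)) {
    tr <- fit@trace
    meta$fit <- list(lambda = fit@lambda, seed = fit@seed,
                     nIter = fit@nIter, converged = fit@converged,
                     traceTail = tr[max(1, nrow(tr) - 9):nrow(tr), "total"])
  }
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeTuckerModel
#' @param stem path stem used when writing.
#' @export
readTuckerModel <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  readMat <- function(name)
    as.matrix(utils::read.delim(sprintf("%s.%s.tsv", stem, name),
                                header = FALSE))
  core <- array(readMat("core")[, 1L], meta$rank)
  m <- function(name) {
    out <- readMat(name)
    dimnames(out) <- NULL
    out
  }
  TuckerModel(core, m("Ay"), m("Ax"), m("Ag"))
}
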