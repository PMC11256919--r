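#' Mode-n matricization of a 3-way array
#'
#' Unfolds a 3-way array along one mode. Row i of the result is the vector
#' of all entries whose index along \code{mode} is i; columns cycle the
#' remaining modes in increasing order, with the lower-numbered mode varying
#' fastest. \code{foldTensor} inverts the operation given the original
#' dimensions, so \code{foldTensor(unfoldTensor(t, m), m, dim(t))} is
#' \code{t} for every mode.
#'
#' @param t numeric 3-way array.
#' @param mode integer in 1:3.
#' @return a matrix of dim \code{(dim(t)[mode], prod(dim(t)[-mode]))}.
#' @examples
#' t <- array(1:24, c(2, 3, 4))
#' dim(unfoldTensor(t, 2))          # 3 x 8
#' all(foldTensor(unfoldTensor(t, 2), 2, dim(t)) == t)
#' @export
unfoldTensor <- function(t, mode) {
  d <- dim(t)
  stopifnot(length(d) == 3L)
  mode <- as.integer(mode)
  if (!(mode %in% 1:3)) stop("mode must be 1, 2 or 3")
  rest <- setdiff(1:3, mode)
  a <- aperm(t, c(mode, rest))
  dim(a) <- c(d[mode], prod(d[rest]))
  a
}

#' @rdname unfoldTensor
#' @param m matrix produced by \code{unfoldTensor}.
#' @param dims the dim of the original array.
#' @export
foldTensor <- function(m, mode, dims) {
  mode <- as.integer(mode)
  if (!(mode %in% 1:3)) stop("mode must be 1, 2 or 3")
  rest <- setdiff(1:3, mode)
  a <- array(as.numeric(m), c(dims[mode], dims[rest]))
  aperm(a, order(c(mode, rest)))
}

#' n-mode product of a 3-way array with a matrix
#'
#' Contracts mode \code{mode} of \code{t} with the columns of \code{m}:
#' the result has the size of that mode replaced by \code{nrow(m)} and
#' equals \code{foldTensor(m \%*\% unfoldTensor(t, mode), mode, ...)}.
#' Products along distinct modes commute.
#'
#' @param t numeric 3-way array.
#' @param m matrix with \code{ncol(m) == dim(t)[mode]} (dense or sparse).
#' @param mode integer in 1:3.
#' @return a 3-way array.
#' @export
nmodeProduct <- function(t, m, mode) {
  d <- dim(t)
  mode <- as.integer(mode)
  if (!(mode %in% 1:3)) stop("mode must be 1, 2 or 3")
  if (ncol(m) != d[mode])
    stop(sprintf("ncol(m) = %d does not match mode-%d size %d",
                 ncol(m), mode, d[mode]))
  out <- as.matrix(m %*% unfoldTensor(t, mode))
  nd <- d; nd[mode] <- nrow(m)
  foldTensor(out, mode, nd)
}

#' Reconstruct the dense tensor from a Tucker model
#'
#' Computes \code{core x1 Ay x2 Ax x3 Ag}, the rank-(ry, rx, rg) Tucker
#' reconstruction; nonnegative whenever the model is.
#'
#' @param model a \linkS4class{TuckerModel}, or a core array if the factors
#'   are passed explicitly.
#' @param Ay,Ax,Ag optional explicit factors (used with a bare core array).
#' @return a 3-way array of dim (nrow(Ay), nrow(Ax), nrow(Ag)).
#' @export
tuckerReconstruct <- function(model, Ay = NULL, Ax = NULL, Ag = NULL) {
  if (is(model, "TuckerModel")) {
    core <- model@core; Ay <- model@Ay; Ax <- model@Ax; Ag <- model@Ag
  } else core <- model
  if (ncol(Ay) != dim(core)[1] || ncol(Ax) != dim(core)[2] ||
      ncol(Ag) != dim(core)[3])
    stop("factor column counts must match the core dimensions")
  t1 <- nmodeProduct(core, Ay, 1L)
  t2 <- nmodeProduct(t1, Ax, 2L)
  nmodeProduct(t2, Ag, 3L)
}

# chain of n-mode products; mats is a list indexed by mode, NULL = skip
.ttmChain <- function(t, mats) {
  for (m in 1:3) if (!is.null(mats[[m]])) t <- nmodeProduct(t, mats[[m]], m)
  t
}
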