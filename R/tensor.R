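#' Dense multilinear algebra primitives
#'
#' Mode-n unfolding (matricization), folding, Khatri-Rao products, CP
#' reconstruction and multi-mode tensor-vector contraction. These are the
#' building blocks for the coupled factorization objectives and gradients.
#' Tensors are plain numeric arrays; a matrix is treated as an order-2 tensor.
#' Modes are 1-based throughout the user-facing API.
#'
#' The unfolding convention is the one standard in the CP literature
#' (Kolda-Bader): the mode-n unfolding of an \eqn{I_1 \times \dots \times I_N}
#' tensor is the \eqn{I_n \times \prod_{m \ne n} I_m} matrix whose columns are
#' the mode-n fibers, with the remaining modes varying fastest in increasing
#' mode order. Under this convention a CP model satisfies
#' \eqn{X_{(n)} = U_n \,\mathrm{diag}(w)\, (U_N \odot \dots \odot U_{n+1}
#' \odot U_{n-1} \odot \dots \odot U_1)^T}.
#'
#' @name tensor-core
NULL

#' Frobenius norm of a numeric array
#'
#' @param x numeric vector, matrix or array.
#' @return `sqrt(sum(x^2))`.
#' @export
fnorm <- function(x) sqrt(sum(x^2))

tensor_dim <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

#' Unfold (matricize) a tensor along one mode
#'
#' @param x numeric array (order >= 1); plain matrices are order-2 tensors.
#' @param mode integer in `1:length(dim(x))`; the mode whose fibers become
#'   the columns of the result.
#' @return a `dim(x)[mode]` by `prod(dim(x)[-mode])` matrix.
#' @examples
#' x <- array(1:8, c(2, 2, 2))
#' unfold(x, 1)
#' @seealso [fold()] for the inverse.
#' @export
unfold <- function(x, mode) {
  d <- tensor_dim(x)
  n <- length(d)
  if (length(mode) != 1L || is.na(mode) || mode < 1L || mode > n)
    stop("`mode` must be a single index in 1..", n)
  mode <- as.integer(mode)
  if (n == 1L) return(matrix(as.numeric(x), nrow = d, ncol = 1L))
  if (mode == 1L) {                     # fibers already contiguous
    y <- as.numeric(x)
  } else {
    dim(x) <- d
    y <- aperm(x, c(mode, seq_len(n)[-mode]))
  }
  dim(y) <- c(d[mode], prod(d[-mode]))
  y
}

#' Fold a matricized tensor back into an array
#'
#' Inverse of [unfold()]: `fold(unfold(x, n), n, dim(x))` recovers `x`
#' exactly for every mode `n`.
#'
#' @param mat matrix with `shape[mode]` rows and `prod(shape[-mode])` columns.
#' @param mode the mode `mat` was unfolded along.
#' @param shape integer vector, the target array dimensions.
#' @return numeric array with `dim = shape`.
#' @export
fold <- function(mat, mode, shape) {
  shape <- as.integer(shape)
  n <- length(shape)
  if (length(mode) != 1L || mode < 1L || mode > n)
    stop("`mode` must be a single index in 1..", n)
  mode <- as.integer(mode)
  if (length(mat) != prod(shape))
    stop("`mat` has ", length(mat), " entries; shape requires ", prod(shape))
  if (mode == 1L) {
    x <- as.numeric(mat)
    dim(x) <- shape
    return(x)
  }
  perm <- c(mode, seq_len(n)[-mode])
  x <- as.numeric(mat)
  dim(x) <- shape[perm]
  aperm(x, order(perm))
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' @param ... matrices with a common column count `R`, or a single list of
#'   them. Column `r` of the result is the Kronecker product of the `r`-th
#'   columns of the inputs, taken in the order given (so the *last* input's
#'   row index varies fastest, matching `kronecker()` on each column).
#' @return a matrix with `prod(rows)` rows and `R` columns.
#' @export
khatri_rao <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) && !is.matrix(mats[[1]]))
    mats <- mats[[1]]
  if (length(mats) == 0L) stop("need at least one matrix")
  mats <- lapply(mats, as.matrix)
  nc <- vapply(mats, ncol, integer(1))
  if (any(nc != nc[1L]))
    stop("all matrices must have the same number of columns")
  Reduce(function(a, b) {
    # kron of columns: rows of `b` vary fastest
    a[rep(seq_len(nrow(a)), each = nrow(b)), , drop = FALSE] *
      b[rep(seq_len(nrow(b)), times = nrow(a)), , drop = FALSE]
  }, mats)
}

# Khatri-Rao of all factors except `mode`, in reversed mode order:
# for a 3-way tensor, krp_exclude(list(A,B,C), 1) == C (.) B, so that
# X_(n) %*% krp_exclude(factors, n) is the MTTKRP of the gradient formulas.
krp_exclude <- function(factors, mode) {
  keep <- rev(seq_along(factors)[-mode])
  if (length(keep) == 1L) return(as.matrix(factors[[keep]]))
  khatri_rao(factors[keep])
}

#' Reconstruct a dense tensor from a (weighted) CP model
#'
#' Computes \eqn{\sum_{r=1}^R w_r\, u^{(1)}_r \circ \dots \circ u^{(N)}_r},
#' the CP model \eqn{[\![w; U_1, \dots, U_N]\!]}. With two factor matrices
#' this is \eqn{U_1 \mathrm{diag}(w) U_2^T}.
#'
#' @param factors list of factor matrices, one per mode, all with `R` columns.
#' @param weights numeric vector of length `R`; defaults to all ones.
#' @return numeric array of dimension `sapply(factors, nrow)`.
#' @export
cp_reconstruct <- function(factors, weights = NULL) {
  factors <- lapply(factors, as.matrix)
  R <- ncol(factors[[1L]])
  if (any(vapply(factors, ncol, integer(1)) != R))
    stop("all factor matrices must have the same number of columns")
  if (is.null(weights)) weights <- rep(1, R)
  if (length(weights) != R)
    stop("`weights` must have length ", R)
  shape <- vapply(factors, nrow, integer(1))
  m <- factors[[1L]] %*% (t(krp_exclude(factors, 1L)) * weights)
  fold(m, 1L, shape)
}

#' Contract a tensor with vectors along several modes
#'
#' Multiplies `x` by a vector in each mode listed in `modes` (tensor-vector
#' products). Contracting all modes of an order-3 tensor returns the scalar
#' \eqn{\sum_{ijk} x_{ijk} a_i b_j c_k}.
#'
#' @param x numeric array.
#' @param vectors list of numeric vectors, one per contracted mode, in the
#'   order of `modes`; lengths must match the corresponding dimensions.
#' @param modes integer vector of modes to contract (default: all modes).
#' @return array over the remaining modes; a scalar if none remain.
#' @export
mode_products <- function(x, vectors, modes = seq_along(tensor_dim(x))) {
  d <- tensor_dim(x)
  if (length(vectors) != length(modes))
    stop("need one vector per contracted mode")
  if (any(modes < 1L | modes > length(d)))
    stop("mode out of range")
  for (i in seq_along(modes)) {
    if (length(vectors[[i]]) != d[modes[i]])
      stop("vector ", i, " has length ", length(vectors[[i]]),
           ", mode ", modes[i], " has dimension ", d[modes[i]])
  }
  # contract from the highest mode down so lower mode indices stay valid
  ord <- order(modes, decreasing = TRUE)
  dim(x) <- d
  for (i in ord) {
    m <- modes[i]
    v <- as.numeric(vectors[[i]])
    x <- as.numeric(crossprod(unfold(x, m), v))
    d <- d[-m]
    if (length(d) > 0L) dim(x) <- d
  }
  if (length(d) <= 1L) as.numeric(x) else x
}
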