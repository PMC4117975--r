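#' Assemble a coupled collection of tensors and matrices
#'
#' Bundles one or more dense numeric blocks (arrays of any order; matrices
#' are order-2) that are coupled through shared modes. Each block declares,
#' per block mode, the *global* mode id it lives on; blocks that list the
#' same global mode are coupled along it and must agree on its dimension.
#' In the canonical two-block setting a third-order tensor
#' \eqn{\mathcal{X}} (global modes 1,2,3) is coupled with a matrix `Y`
#' (global modes 1,4) through mode 1, which carries the shared factor
#' matrix `A`.
#'
#' @param blocks named or unnamed list of numeric arrays/matrices.
#' @param modes list of integer vectors, one per block: `modes[[b]][d]` is the
#'   global mode id of block `b`'s `d`-th mode. Global mode ids must form
#'   `1:n_modes` overall.
#' @param masks optional list (one entry per block, `NULL` allowed) of 0/1
#'   observation masks with the block's shape; 1 = observed, 0 = missing.
#'   Missing entries of the block values are treated as 0 internally.
#' @param norms optional numeric vector of per-block Frobenius norms to
#'   record (as supplied *before* any rescaling); defaults to the norms of
#'   `blocks` (over observed entries when a mask is present).
#' @return an object of class `coupled_data`: a list with elements `blocks`,
#'   `modes`, `masks`, `norms`, `mode_dims` (dimension of each global mode)
#'   and `names`.
#' @examples
#' A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(9), 3, 3)
#' C <- matrix(rnorm(6), 2, 3); V <- matrix(rnorm(15), 5, 3)
#' X <- cp_reconstruct(list(A, B, C)); Y <- tcrossprod(A, V)
#' cd <- coupled_data(list(X = X, Y = Y), modes = list(c(1, 2, 3), c(1, 4)))
#' @export
coupled_data <- function(blocks, modes, masks = NULL, norms = NULL) {
  if (!is.list(blocks) || length(blocks) == 0L)
    stop("`blocks` must be a non-empty list of numeric arrays")
  if (!is.list(modes) || length(modes) != length(blocks))
    stop("`modes` must be a list with one integer vector per block")
  nb <- length(blocks)
  blocks <- lapply(blocks, function(x) {
    if (!is.numeric(x)) stop("blocks must be numeric")
    if (is.null(dim(x))) dim(x) <- length(x)
    storage.mode(x) <- "double"
    x
  })
  modes <- lapply(modes, as.integer)
  for (b in seq_len(nb)) {
    if (length(modes[[b]]) != length(dim(blocks[[b]])))
      stop("block ", b, ": `modes` lists ", length(modes[[b]]),
           " mode ids but the block has order ", length(dim(blocks[[b]])))
    if (anyDuplicated(modes[[b]]))
      stop("block ", b, ": repeated global mode id")
  }
  all_modes <- sort(unique(unlist(modes)))
  if (!identical(all_modes, seq_along(all_modes)))
    stop("global mode ids must cover 1..n_modes without gaps")
  mode_dims <- integer(length(all_modes))
  for (b in seq_len(nb)) {
    db <- dim(blocks[[b]])
    for (d in seq_along(db)) {
      g <- modes[[b]][d]
      if (mode_dims[g] == 0L) mode_dims[g] <- db[d]
      else if (mode_dims[g] != db[d])
        stop("coupled mode ", g, " has dimension ", mode_dims[g],
             " in one block and ", db[d], " in block ", b)
    }
  }
  if (is.null(masks)) masks <- vector("list", nb)
  if (!is.list(masks) || length(masks) != nb)
    stop("`masks` must be a list with one entry (or NULL) per block")
  for (b in seq_len(nb)) {
    w <- masks[[b]]
    if (is.null(w)) next
    if (is.null(dim(w))) dim(w) <- length(w)
    if (!identical(dim(w), dim(blocks[[b]])))
      stop("mask ", b, " does not match its block's shape")
    if (!all(w %in% c(0, 1))) stop("mask ", b, " must contain only 0/1")
    storage.mode(w) <- "double"
    masks[[b]] <- w
    blocks[[b]] <- blocks[[b]] * w   # missing entries carry no information
  }
  if (is.null(norms)) {
    norms <- vapply(blocks, fnorm, numeric(1))
  } else if (length(norms) != nb) {
    stop("`norms` must have one entry per block")
  }
  nms <- names(blocks)
  if (is.null(nms)) nms <- paste0("block", seq_len(nb))
  structure(
    list(blocks = blocks, modes = modes, masks = masks,
         norms = as.numeric(norms), mode_dims = mode_dims, names = nms),
    class = "coupled_data")
}

#' @export
print.coupled_data <- function(x, ...) {
  cat("coupled_data:", length(x$blocks), "block(s),",
      length(x$mode_dims), "global modes (dims:",
      paste(x$mode_dims, collapse = " x "), ")\n")
  for (b in seq_along(x$blocks)) {
    cat(sprintf("  %s: %s  modes (%s)  |.|_F = %.4g%s\n",
                x$names[b],
                paste(dim(x$blocks[[b]]), collapse = "x"),
                paste(x$modes[[b]], collapse = ","),
                x$norms[b],
                if (is.null(x$masks[[b]])) "" else sprintf(
                  "  [%.1f%% observed]", 100 * mean(x$masks[[b]]))))
  }
  invisible(x)
}

n_blocks <- function(data) length(data$blocks)

#' Scale each block to unit Frobenius norm
#'
#' Standard preprocessing before a coupled fit: every block is divided by its
#' Frobenius norm (computed over observed entries when a mask is present) so
#' that all data-fit terms enter the objective on the same scale. The
#' original norms are recorded in the result's `norms` field, which
#' [rescale_weights()] uses to map fitted weights back to absolute units.
#' Optionally, matrix blocks are first column-scaled to unit standard
#' deviation (the usual treatment of LC-MS feature matrices).
#'
#' @param data a [coupled_data] object.
#' @param column_scaling `"none"` (default) or `"unit_std"`: divide each
#'   column of every order-2 block by its standard deviation first.
#' @return a `coupled_data` with unit-norm blocks and `norms` recording the
#'   pre-scaling Frobenius norms.
#' @export
scale_blocks <- function(data, column_scaling = c("none", "unit_std")) {
  column_scaling <- match.arg(column_scaling)
  stopifnot(inherits(data, "coupled_data"))
  blocks <- data$blocks
  if (column_scaling == "unit_std") {
    for (b in seq_along(blocks)) {
      if (length(dim(blocks[[b]])) != 2L) next
      s <- apply(blocks[[b]], 2L, stats::sd)
      if (any(s == 0)) stop("block ", b, " has a zero-variance column")
      blocks[[b]] <- sweep(blocks[[b]], 2L, s, "/")
    }
  }
  norms <- vapply(blocks, fnorm, numeric(1))
  if (any(norms == 0)) stop("cannot scale a zero block")
  for (b in seq_along(blocks)) blocks[[b]] <- blocks[[b]] / norms[b]
  out <- data
  out$blocks <- blocks
  out$norms <- norms
  out
}
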