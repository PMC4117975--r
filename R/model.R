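#' Smoothed absolute value
#'
#' Differentiable surrogate for \eqn{|x|}: \eqn{\sqrt{x^2 + \varepsilon}}
#' for a small \eqn{\varepsilon > 0}. Used to make the l1 penalty on the
#' component weights differentiable so the whole objective can be minimized
#' with gradient-based methods. Even in `x` and always \eqn{\ge |x|}.
#'
#' @param x numeric.
#' @param epsilon smoothing constant, strictly positive (default `1e-8`).
#' @return `sqrt(x^2 + epsilon)`, vectorized over `x`.
#' @export
smoothed_abs <- function(x, epsilon = 1e-8) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("`epsilon` must be a single positive number")
  sqrt(x^2 + epsilon)
}

#' Penalty and smoothing configuration for the ACMTF objective
#'
#' @param alpha nonnegative weight of the quadratic penalty enforcing
#'   unit-norm factor columns (default 1, so the constraint terms carry the
#'   same weight as the data-fit terms once blocks are Frobenius-scaled).
#' @param beta nonnegative sparsity penalty on the per-block component
#'   weights (default `1e-3`).
#' @param epsilon smoothing constant of [smoothed_abs()] (default `1e-8`).
#' @param half_factor if `TRUE` (default) the data-fit and norm-penalty
#'   terms are multiplied by 1/2, which makes the gradient expressions
#'   free of factors of two; the sparsity term is never halved. The scaling
#'   does not change the minimizers.
#' @return an object of class `penalty_config`.
#' @export
penalty_config <- function(alpha = 1, beta = 1e-3, epsilon = 1e-8,
                           half_factor = TRUE) {
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (beta < 0) stop("`beta` must be >= 0")
  if (epsilon <= 0) stop("`epsilon` must be > 0")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 half_factor = isTRUE(half_factor)),
            class = "penalty_config")
}

#' Construct a factor model for coupled data
#'
#' A factor model holds one factor matrix per global mode and, for the
#' weighted (ACMTF) formulation, one length-`R` weight vector per block.
#' The unweighted (CMTF) formulation carries `weights = NULL`; component
#' scales then live in the factor columns themselves.
#'
#' @param factors list of numeric matrices, one per global mode, all with
#'   the same number of columns `R`.
#' @param weights `NULL`, or a list of numeric length-`R` vectors, one per
#'   block.
#' @return an object of class `factor_model`.
#' @export
factor_model <- function(factors, weights = NULL) {
  factors <- lapply(factors, as.matrix)
  R <- ncol(factors[[1L]])
  if (any(vapply(factors, ncol, integer(1)) != R))
    stop("all factor matrices must have the same number of columns")
  if (!is.null(weights)) {
    weights <- lapply(weights, as.numeric)
    if (any(vapply(weights, length, integer(1)) != R))
      stop("all weight vectors must have length R = ", R)
  }
  structure(list(factors = factors, weights = weights, R = R),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: R = %d, %d mode(s)%s\n", x$R, length(x$factors),
              if (is.null(x$weights)) ", unweighted (CMTF-style)"
              else sprintf(", %d weight vector(s)", length(x$weights))))
  if (!is.null(x$weights))
    for (b in seq_along(x$weights))
      cat(sprintf("  weights[%d]: %s\n", b,
                  paste(sprintf("%.3f", x$weights[[b]]), collapse = " ")))
  invisible(x)
}

check_model_data <- function(model, data) {
  if (length(model$factors) != length(data$mode_dims))
    stop("model has ", length(model$factors), " factor matrices but data has ",
         length(data$mode_dims), " global modes")
  for (g in seq_along(model$factors))
    if (nrow(model$factors[[g]]) != data$mode_dims[g])
      stop("factor matrix ", g, " has ", nrow(model$factors[[g]]),
           " rows; global mode ", g, " has dimension ", data$mode_dims[g])
  if (!is.null(model$weights) && length(model$weights) != n_blocks(data))
    stop("model has ", length(model$weights), " weight vectors but data has ",
         n_blocks(data), " blocks")
  invisible(TRUE)
}

#' Mask a residual (or data) block
#'
#' Hadamard-multiplies a block by its 0/1 observation mask so that missing
#' entries contribute nothing to the objective or gradient. A `NULL` mask is
#' the all-observed case and returns the block unchanged.
#'
#' @param block numeric array.
#' @param mask 0/1 array of the same shape, or `NULL`.
#' @return the masked block.
#' @export
apply_mask <- function(block, mask) {
  if (is.null(mask)) return(block)
  if (is.null(dim(mask))) dim(mask) <- length(mask)
  if (is.null(dim(block))) dim(block) <- length(block)
  if (!identical(dim(block), dim(mask)))
    stop("mask shape does not match block shape")
  block * mask
}

# Fused objective/gradient evaluator for the weighted (ACMTF) and
# unweighted (CMTF) coupled factorizations.  Returns list(f=, grad=list(
# factors=, weights=)).  `want_grad = FALSE` skips gradient assembly.
# Blocks of order <= 3 go through the compiled evaluator; higher orders
# (and the consistency tests) use the R reference path below.
coupled_fg <- function(model, data, cfg, want_grad = TRUE) {
  check_model_data(model, data)
  weighted <- !is.null(model$weights)
  if (all(lengths(data$modes) <= 3L)) {
    res <- .coupled_fg_cpp(data$blocks, lapply(data$blocks, dim),
                           data$modes, data$masks, model$factors,
                           if (weighted) model$weights else list(),
                           cfg$alpha, cfg$beta, cfg$epsilon,
                           cfg$half_factor, weighted, want_grad)
    return(list(f = res$f,
                grad = if (want_grad)
                  list(factors = res$gfactors, weights = res$gweights)))
  }
  coupled_fg_ref(model, data, cfg, want_grad)
}

# Pure-R reference evaluator (any block order).
coupled_fg_ref <- function(model, data, cfg, want_grad = TRUE) {
  check_model_data(model, data)
  weighted <- !is.null(model$weights)
  s <- if (cfg$half_factor) 0.5 else 1
  factors <- model$factors
  R <- model$R
  f <- 0
  gF <- if (want_grad) lapply(factors, function(u) u * 0) else NULL
  gW <- if (want_grad && weighted) lapply(model$weights, function(w) w * 0) else NULL

  for (b in seq_len(n_blocks(data))) {
    gm <- data$modes[[b]]                 # global mode ids of this block
    Ub <- factors[gm]                     # factor matrices in block-mode order
    w <- if (weighted) model$weights[[b]] else rep(1, R)
    shape <- dim(data$blocks[[b]])
    D <- length(shape)
    mask <- data$masks[[b]]
    K1 <- krp_exclude(Ub, 1L)
    # work on the mode-1 unfolding throughout; fibers are contiguous there
    resid <- Ub[[1L]] %*% (t(K1) * w)
    bm <- data$blocks[[b]]
    dim(bm) <- dim(resid)                 # mode-1 unfolding: same layout
    resid <- resid - bm
    if (!is.null(mask)) resid <- resid * as.numeric(mask)
    f <- f + s * sum(resid^2)
    if (want_grad) {
      M1 <- resid %*% K1                  # MTTKRP with the residual, mode 1
      gF[[gm[1L]]] <- gF[[gm[1L]]] + 2 * s * (M1 * rep(w, each = shape[1L]))
      if (weighted) gW[[b]] <- gW[[b]] + 2 * s * colSums(Ub[[1L]] * M1)
      if (D == 2L) {
        M2 <- crossprod(resid, Ub[[1L]])
        gF[[gm[2L]]] <- gF[[gm[2L]]] + 2 * s * (M2 * rep(w, each = shape[2L]))
      } else if (D == 3L) {
        # contract over mode 1 once, then against single factor columns
        W <- crossprod(Ub[[1L]], resid)   # R x (J*K)
        M2 <- matrix(0, shape[2L], R); M3 <- matrix(0, shape[3L], R)
        for (r in seq_len(R)) {
          Wr <- matrix(W[r, ], shape[2L], shape[3L])
          M2[, r] <- Wr %*% Ub[[3L]][, r]
          M3[, r] <- crossprod(Wr, Ub[[2L]][, r])
        }
        gF[[gm[2L]]] <- gF[[gm[2L]]] + 2 * s * (M2 * rep(w, each = shape[2L]))
        gF[[gm[3L]]] <- gF[[gm[3L]]] + 2 * s * (M3 * rep(w, each = shape[3L]))
      } else {
        ra <- resid
        dim(ra) <- shape
        for (d in 2:D) {
          Kd <- krp_exclude(Ub, d)
          Md <- unfold(ra, d) %*% Kd
          gF[[gm[d]]] <- gF[[gm[d]]] + 2 * s * (Md * rep(w, each = shape[d]))
        }
      }
    }
  }

  if (weighted) {
    if (cfg$alpha > 0) {
      for (g in seq_along(factors)) {
        nrm <- sqrt(colSums(factors[[g]]^2))
        f <- f + s * cfg$alpha * sum((nrm - 1)^2)
        if (want_grad) {
          safe <- ifelse(nrm > 0, nrm, 1)
          uhat <- factors[[g]] * rep(ifelse(nrm > 0, 1 / safe, 0),
                                     each = nrow(factors[[g]]))
          gF[[g]] <- gF[[g]] + 2 * s * cfg$alpha * (factors[[g]] - uhat)
        }
      }
    }
    if (cfg$beta > 0) {
      for (b in seq_along(model$weights)) {
        w <- model$weights[[b]]
        sa <- smoothed_abs(w, cfg$epsilon)
        f <- f + cfg$beta * sum(sa)
        if (want_grad) gW[[b]] <- gW[[b]] + cfg$beta * w / sa
      }
    }
  }
  list(f = f, grad = if (want_grad) list(factors = gF, weights = gW))
}

#' ACMTF objective function
#'
#' The penalized, differentiable objective of the structure-revealing
#' coupled factorization: for a tensor \eqn{\mathcal{X}} (modes 1,2,3)
#' coupled with a matrix `Y` (modes 1,4),
#' \deqn{f = \tfrac12\|\mathcal{X} - [\![\lambda; A,B,C]\!]\|^2
#'   + \tfrac12\|Y - A\,\Sigma V^T\|^2
#'   + \tfrac{\alpha}{2}\sum_{\mathrm{cols}\ u} (\|u\|_2 - 1)^2
#'   + \beta \sum_r \sqrt{\lambda_r^2+\varepsilon}
#'   + \beta \sum_r \sqrt{\sigma_r^2+\varepsilon}}
#' (the 1/2 factors controlled by `cfg$half_factor`), generalized to any
#' number of blocks of any order: one data-fit term and one sparsity sum per
#' block, one norm-penalty term per factor column counted once per factor
#' matrix. Blocks with masks contribute only over observed entries.
#'
#' @param model a [factor_model] with one weight vector per block.
#' @param data a [coupled_data].
#' @param cfg a [penalty_config].
#' @return the scalar objective value.
#' @seealso [acmtf_gradient()], [cmtf_objective()]
#' @export
acmtf_objective <- function(model, data, cfg = penalty_config()) {
  if (is.null(model$weights))
    stop("ACMTF model requires one weight vector per block; see cmtf_objective() for the unweighted form")
  coupled_fg(model, data, cfg, want_grad = FALSE)$f
}

#' Analytic gradient of the ACMTF objective
#'
#' Returns the exact gradient of [acmtf_objective()] as a single stacked
#' vector in the parameter order documented in [pack_parameters()]:
#' `vec()` of each factor matrix in global mode order, then each block's
#' weight vector in block order. For the two-block third-order case this has
#' length \eqn{R(I+J+K+M+2)}.
#'
#' @inheritParams acmtf_objective
#' @return numeric vector, the stacked gradient.
#' @export
acmtf_gradient <- function(model, data, cfg = penalty_config()) {
  if (is.null(model$weights))
    stop("ACMTF model requires one weight vector per block")
  g <- coupled_fg(model, data, cfg, want_grad = TRUE)$grad
  c(unlist(lapply(g$factors, as.numeric), use.names = FALSE),
    unlist(g$weights, use.names = FALSE))
}

#' CMTF objective function
#'
#' The classical coupled matrix and tensor factorization objective
#' \deqn{f = \tfrac12\|\mathcal{X} - [\![A,B,C]\!]\|^2 +
#'   \tfrac12\|Y - A V^T\|^2} (1/2 controlled by `cfg$half_factor`),
#' generalized over blocks as in [acmtf_objective()]. The model carries no
#' weight vectors and no penalties; component scales are absorbed by the
#' factor columns.
#'
#' @param model a [factor_model] with `weights = NULL`.
#' @param data a [coupled_data].
#' @param cfg a [penalty_config]; only `half_factor` is used.
#' @return the scalar objective value.
#' @export
cmtf_objective <- function(model, data, cfg = penalty_config()) {
  model$weights <- NULL
  coupled_fg(model, data, cfg, want_grad = FALSE)$f
}

#' Analytic gradient of the CMTF objective
#'
#' @inheritParams cmtf_objective
#' @return numeric vector: stacked `vec()` of the factor-matrix partials in
#'   global mode order.
#' @export
cmtf_gradient <- function(model, data, cfg = penalty_config()) {
  model$weights <- NULL
  g <- coupled_fg(model, data, cfg, want_grad = TRUE)$grad
  unlist(lapply(g$factors, as.numeric), use.names = FALSE)
}

#' Pack a factor model into a parameter vector (and back)
#'
#' The optimizer works on a single stacked parameter vector. The stacking
#' order is part of the stable API: `vec()` of each factor matrix in global
#' mode order, followed by each block's weight vector in block order (ACMTF
#' only). For a third-order tensor coupled with one matrix the packed length
#' is \eqn{R(I+J+K+M+2)}; with two coupled matrices, \eqn{R(I+J+K+M+L+3)}.
#'
#' @param model a [factor_model].
#' @return `pack_parameters()`: numeric vector.
#' @export
pack_parameters <- function(model) {
  c(unlist(lapply(model$factors, as.numeric), use.names = FALSE),
    unlist(model$weights, use.names = FALSE))
}

#' @rdname pack_parameters
#' @param x numeric vector of packed parameters.
#' @param template a [factor_model] fixing all shapes (its values are
#'   ignored).
#' @return `unpack_parameters()`: a [factor_model] with `x`'s values.
#' @export
unpack_parameters <- function(x, template) {
  sizes <- vapply(template$factors, length, integer(1))
  nw <- if (is.null(template$weights)) 0L else
    sum(vapply(template$weights, length, integer(1)))
  if (length(x) != sum(sizes) + nw)
    stop("parameter vector has length ", length(x), "; template requires ",
         sum(sizes) + nw)
  pos <- 0L
  factors <- vector("list", length(template$factors))
  for (g in seq_along(factors)) {
    factors[[g]] <- matrix(x[pos + seq_len(sizes[g])],
                           nrow = nrow(template$factors[[g]]))
    pos <- pos + sizes[g]
  }
  weights <- NULL
  if (!is.null(template$weights)) {
    weights <- vector("list", length(template$weights))
    for (b in seq_along(weights)) {
      nb <- length(template$weights[[b]])
      weights[[b]] <- x[pos + seq_len(nb)]
      pos <- pos + nb
    }
  }
  factor_model(factors, weights)
}
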