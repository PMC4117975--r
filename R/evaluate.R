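#' Permutation-matched factor match score
#'
#' A fitted CP-type model is identifiable only up to a common column
#' permutation and per-column sign flips, so estimated factor matrices are
#' compared to the truth by the absolute cosine between columns after
#' finding the best-matching permutation. The permutation maximizes the
#' total absolute cosine over all column pairings (exhaustively for
#' `R <= 8`, by Hungarian assignment otherwise).
#'
#' @param estimated,truth numeric matrices of identical shape (`n x R`).
#' @return an object of class `match_report`: `permutation` (integer vector,
#'   `permutation[r]` is the estimated column matched to truth column `r`),
#'   `per_component_score` (absolute cosines, in `[0, 1]`), and
#'   `mean_score`.
#' @export
match_score <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!identical(dim(estimated), dim(truth)))
    stop("`estimated` and `truth` must have identical shape")
  normalize <- function(u) {
    nrm <- sqrt(colSums(u^2))
    u / rep(ifelse(nrm > 0, nrm, 1), each = nrow(u))
  }
  C <- abs(crossprod(normalize(truth), normalize(estimated)))
  perm <- best_permutation(C)
  scores <- C[cbind(seq_len(ncol(C)), perm)]
  structure(list(permutation = perm,
                 per_component_score = as.numeric(scores),
                 mean_score = mean(scores)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("match_report: permutation (truth -> estimate):",
      paste(x$permutation, collapse = " "), "\n  scores:",
      paste(sprintf("%.4f", x$per_component_score), collapse = " "), "\n")
  invisible(x)
}

# Assignment maximizing sum(C[r, perm[r]]): exhaustive for small R,
# Hungarian (shortest augmenting path, O(n^3)) otherwise.
best_permutation <- function(C, exhaustive_limit = 8L) {
  R <- ncol(C)
  if (R == 1L) return(1L)
  if (R <= exhaustive_limit) {
    perms <- all_permutations(R)
    tot <- apply(perms, 1L, function(p) sum(C[cbind(seq_len(R), p)]))
    return(perms[which.max(tot), ])
  }
  hungarian_assignment(max(C) - C)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Minimum-cost perfect assignment on a square cost matrix; returns the
# column assigned to each row. Jonker/Volgenant-style shortest augmenting
# path with potentials.
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}

#' Extract implicit component weights from an unweighted (CMTF) model
#'
#' A CMTF model stores component scales inside its factor columns. The
#' implicit weight of component `r` in block `b` is the product of the
#' 2-norms of column `r` over the block's factor matrices; the returned
#' model has all factor columns normalized to unit norm, so reconstruction
#' with the extracted weights reproduces the original model exactly.
#'
#' @param model a [factor_model] (weights ignored if present).
#' @param modes list of global-mode-id vectors, one per block, or a
#'   [coupled_data] to take them from.
#' @return a [factor_model] with unit-norm factors and one extracted weight
#'   vector per block. Zero columns get weight 0 and stay zero vectors.
#' @export
extract_cmtf_weights <- function(model, modes) {
  if (inherits(modes, "coupled_data")) modes <- modes$modes
  stopifnot(inherits(model, "factor_model"))
  norms <- lapply(model$factors, function(u) sqrt(colSums(u^2)))
  factors <- lapply(seq_along(model$factors), function(g) {
    model$factors[[g]] / rep(ifelse(norms[[g]] > 0, norms[[g]], 1),
                             each = nrow(model$factors[[g]]))
  })
  weights <- lapply(modes, function(gm) {
    Reduce(`*`, norms[gm])
  })
  factor_model(factors, weights)
}

#' Rescale fitted weights to absolute units
#'
#' Models are fitted to Frobenius-normalized blocks, so fitted weights are
#' relative to unit-norm data; multiplying each block's weights by that
#' block's original norm recovers weights on the scale of the data as
#' supplied.
#'
#' @param weights list of numeric weight vectors, one per block (or a
#'   [factor_model] carrying them).
#' @param block_norms numeric vector of per-block norms, e.g. the `norms`
#'   field recorded by [scale_blocks()].
#' @return list of rescaled weight vectors.
#' @export
rescale_weights <- function(weights, block_norms) {
  if (inherits(weights, "factor_model")) weights <- weights$weights
  if (length(weights) != length(block_norms))
    stop("need one norm per block")
  Map(function(w, nrm) w * nrm, weights, as.numeric(block_norms))
}

#' Classify components as shared or unshared from their weights
#'
#' Component `r` is "present" in block `b` when `|weight| > threshold`.
#' Components present in two or more blocks are shared; present in exactly
#' one, unshared in that block; present in none, noise.
#'
#' @param weights list of weight vectors (one per block) or a
#'   [factor_model].
#' @param threshold presence cutoff on the absolute weight (default 0.1).
#' @param block_names optional block labels.
#' @return data frame with `component`, `label`, and one logical
#'   `present_<block>` column per block.
#' @export
classify_shared <- function(weights, threshold = 0.1, block_names = NULL) {
  if (inherits(weights, "factor_model")) weights <- weights$weights
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)")
  nb <- length(weights)
  if (is.null(block_names)) block_names <- names(weights)
  if (is.null(block_names)) block_names <- paste0("block", seq_len(nb))
  R <- length(weights[[1L]])
  present <- vapply(weights, function(w) abs(w) > threshold, logical(R))
  present <- matrix(present, nrow = R,
                    dimnames = list(NULL, paste0("present_", block_names)))
  label <- character(R)
  for (r in seq_len(R)) {
    k <- sum(present[r, ])
    label[r] <- if (k >= 2L) "shared"
      else if (k == 1L) paste0("unshared-in-", block_names[which(present[r, ])])
      else "noise"
  }
  cbind(data.frame(component = seq_len(R), label = label),
        as.data.frame(present))
}

#' Cross-run consistency of recovered weights
#'
#' Uniqueness diagnostic over runs returning the same objective value:
#' every run is aligned to a reference (the ground truth if supplied,
#' otherwise the first run) by the best-matching permutation of the
#' shared-mode factor columns, and the dispersion of the aligned absolute
#' weights across runs is summarized. A structure-revealing model should
#' give near-zero dispersion; an unconstrained coupled fit typically does
#' not.
#'
#' @param results list of `coupled_fit` objects (>= 2), e.g. a same-f group
#'   from [same_f_group()]. CMTF fits have their weights extracted with
#'   [extract_cmtf_weights()] first.
#' @param data the [coupled_data] the fits were run on (needed for the
#'   block-mode map and CMTF weight extraction).
#' @param truth optional `simulation_truth` used as alignment reference.
#' @param mode global mode whose factor matrix drives the alignment
#'   (default 1, the shared mode).
#' @return list with `weights` (array run x block x component of aligned
#'   absolute weights), `weight_sd` (block x component SD across runs),
#'   `score_range` (per-component spread of match scores vs the reference),
#'   and `n_runs`.
#' @export
run_consistency <- function(results, data, truth = NULL, mode = 1L) {
  if (length(results) < 2L) stop("need at least two results")
  models <- lapply(results, function(r) {
    if (!is.null(r$model$weights)) r$model
    else extract_cmtf_weights(r$model, data)
  })
  R <- models[[1L]]$R
  nb <- n_blocks(data)
  ref <- if (!is.null(truth)) truth$factors[[mode]] else
    models[[1L]]$factors[[mode]]
  nruns <- length(models)
  w <- array(NA_real_, c(nruns, nb, R),
             dimnames = list(NULL, data$names, NULL))
  scores <- matrix(NA_real_, nruns, R)
  for (i in seq_len(nruns)) {
    mr <- match_score(models[[i]]$factors[[mode]], ref)
    scores[i, ] <- mr$per_component_score
    for (b in seq_len(nb))
      w[i, b, ] <- abs(models[[i]]$weights[[b]][mr$permutation])
  }
  list(weights = w,
       weight_sd = apply(w, c(2L, 3L), stats::sd),
       score_range = apply(scores, 2L, function(s) diff(range(s))),
       n_runs = nruns)
}

#' Principal angles between column spaces
#'
#' Angles between the subspaces spanned by the columns of `x` and `y`,
#' via the singular values of the product of their orthonormal bases. Used
#' to check that non-uniquely recovered components still span the right
#' subspace.
#'
#' @param x,y numeric matrices with the same number of rows.
#' @param degrees return degrees (default) rather than radians.
#' @return numeric vector of `min(ncol(x), ncol(y))` angles, ascending.
#' @export
principal_angles <- function(x, y, degrees = TRUE) {
  qx <- qr.Q(qr(as.matrix(x)))
  qy <- qr.Q(qr(as.matrix(y)))
  s <- svd(crossprod(qx, qy), nu = 0, nv = 0)$d
  ang <- acos(pmin(pmax(s, -1), 1))
  if (degrees) ang * 180 / pi else ang
}
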