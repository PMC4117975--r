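#' Options controlling the all-at-once fit
#'
#' @param max_iterations iteration cap for the nonlinear conjugate gradient
#'   loop (default `1e4`).
#' @param rel_f_tol stop when the relative change in objective value between
#'   accepted iterates falls below this (default `1e-10`).
#' @param grad_per_entry_tol stop when the gradient 2-norm divided by the
#'   number of gradient entries falls below this (default `1e-10`).
#' @param n_starts number of random starts for [multi_start()] (default 1).
#' @param seed base seed; start `s` uses the derived seed
#'   `(seed + 7919 * (s - 1)) mod (2^31 - 1)`.
#' @param method `"lbfgs"` (default) for limited-memory BFGS or `"ncg"` for
#'   Polak-Ribiere+ nonlinear conjugate gradients. Both are all-at-once
#'   first-order methods under the same strong-Wolfe line search and
#'   stopping rules; L-BFGS copes much better with the ill-conditioning
#'   that small `beta` values induce near zero weights and is the default
#'   for that reason.
#' @param c1,c2 sufficient-decrease and curvature constants of the strong
#'   Wolfe line search (defaults `1e-4` and `1e-2`).
#' @param max_ls maximum objective evaluations per line search (default 60).
#' @param memory L-BFGS history length (default 7).
#' @param store_trace keep the per-iteration `(f, |g|/len)` trace (default
#'   `TRUE`).
#' @return an object of class `fit_options`.
#' @export
fit_options <- function(max_iterations = 1e4, rel_f_tol = 1e-10,
                        grad_per_entry_tol = 1e-10, n_starts = 1L,
                        seed = 1L, method = c("lbfgs", "ncg"),
                        c1 = 1e-4, c2 = 1e-2, max_ls = 60L, memory = 7L,
                        store_trace = TRUE) {
  method <- match.arg(method)
  stopifnot(max_iterations >= 1, rel_f_tol >= 0, grad_per_entry_tol >= 0,
            n_starts >= 1, 0 < c1, c1 < c2, c2 < 1, memory >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 rel_f_tol = rel_f_tol,
                 grad_per_entry_tol = grad_per_entry_tol,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 method = method, c1 = c1, c2 = c2,
                 max_ls = as.integer(max_ls), memory = as.integer(memory),
                 store_trace = isTRUE(store_trace)),
            class = "fit_options")
}

derived_seed <- function(seed, s) {
  as.integer((as.numeric(seed) + 7919 * (s - 1)) %% 2147483647)
}

#' Draw a random starting model
#'
#' Factor-matrix entries are i.i.d. standard normal with columns normalized
#' to unit 2-norm (mirroring the generating distribution of the simulation
#' designs); weight vectors, when present, start at all ones.
#'
#' @param data a [coupled_data].
#' @param R number of components.
#' @param seed integer seed (the draw is fully deterministic in it).
#' @param weighted if `TRUE` (default) include per-block weight vectors
#'   (ACMTF); otherwise an unweighted CMTF-style model.
#' @return a [factor_model].
#' @export
random_model <- function(data, R, seed, weighted = TRUE) {
  set.seed(seed)
  factors <- lapply(data$mode_dims, function(n) {
    u <- matrix(stats::rnorm(n * R), n, R)
    u / rep(sqrt(colSums(u^2)), each = n)
  })
  weights <- if (weighted) replicate(n_blocks(data), rep(1, R),
                                     simplify = FALSE)
  factor_model(factors, weights)
}

# Strong-Wolfe line search (bracket + zoom with bisection safeguard).
# `phi` takes a step length and returns list(f=, dphi=, ...) caching the
# full gradient of the accepted point in its environment.
line_search_wolfe <- function(phi, f0, dphi0, a1, c1, c2, max_evals) {
  evals <- 0L
  interp <- function(lo, hi) {
    # cubic interpolation using values/derivatives at lo, safeguarded
    d1 <- lo$dphi + hi$dphi - 3 * (lo$f - hi$f) / (lo$a - hi$a)
    disc <- d1^2 - lo$dphi * hi$dphi
    a <- NA_real_
    if (is.finite(disc) && disc >= 0) {
      d2 <- sign(hi$a - lo$a) * sqrt(disc)
      a <- hi$a - (hi$a - lo$a) * (hi$dphi + d2 - d1) /
        (hi$dphi - lo$dphi + 2 * d2)
    }
    lo_a <- min(lo$a, hi$a); hi_a <- max(lo$a, hi$a)
    pad <- 0.1 * (hi_a - lo_a)
    if (!is.finite(a) || a < lo_a + pad || a > hi_a - pad)
      a <- (lo_a + hi_a) / 2
    a
  }
  zoom <- function(lo, hi) {
    for (k in seq_len(max_evals - evals)) {
      a <- interp(lo, hi)
      p <- phi(a); evals <<- evals + 1L
      p$a <- a
      if (!is.finite(p$f) || p$f > f0 + c1 * a * dphi0 || p$f >= lo$f) {
        hi <- p
      } else {
        if (abs(p$dphi) <= -c2 * dphi0) return(p)
        if (p$dphi * (hi$a - lo$a) >= 0) hi <- lo
        lo <- p
      }
      if (abs(hi$a - lo$a) < 1e-16) break
    }
    if (lo$a > 0 && lo$f < f0) { lo$weak <- TRUE; return(lo) }
    NULL
  }
  prev <- list(a = 0, f = f0, dphi = dphi0)
  a <- a1
  for (i in seq_len(max_evals)) {
    p <- phi(a); evals <- evals + 1L
    p$a <- a
    if (!is.finite(p$f) || p$f > f0 + c1 * a * dphi0 ||
        (i > 1L && p$f >= prev$f))
      return(zoom(prev, p))
    if (abs(p$dphi) <= -c2 * dphi0) return(p)
    if (p$dphi >= 0) return(zoom(p, prev))
    prev <- p
    a <- 2.5 * a
    if (evals >= max_evals) break
  }
  if (prev$a > 0 && prev$f < f0) { prev$weak <- TRUE; return(prev) }
  NULL
}

# First-order minimization on a packed parameter vector: Polak-Ribiere+
# nonlinear conjugate gradients or limited-memory BFGS (two-loop
# recursion), both under the strong-Wolfe line search above.
fo_minimize <- function(x0, fg, opts) {
  x <- x0
  ev <- fg(x)
  if (!is.finite(ev$f)) stop("objective is not finite at the starting point")
  f <- ev$f; g <- ev$g
  len <- length(g)
  lbfgs <- opts$method == "lbfgs"
  S <- list(); Y <- list(); rho <- numeric(0)   # L-BFGS history
  d <- -g
  exit <- "max_iter"
  trace <- if (opts$store_trace)
    matrix(NA_real_, opts$max_iterations + 1L, 2L,
           dimnames = list(NULL, c("f", "gnorm_per_entry")))
  if (opts$store_trace) trace[1L, ] <- c(f, sqrt(sum(g^2)) / len)
  iter <- 0L
  a_prev <- NA_real_; dphi_prev <- NA_real_
  while (iter < opts$max_iterations) {
    iter <- iter + 1L
    if (lbfgs && length(S) > 0L) {
      q <- g
      al <- numeric(length(S))
      for (i in rev(seq_along(S))) {
        al[i] <- rho[i] * sum(S[[i]] * q)
        q <- q - al[i] * Y[[i]]
      }
      k <- length(S)
      q <- q * (sum(S[[k]] * Y[[k]]) / sum(Y[[k]]^2))
      for (i in seq_along(S)) {
        be <- rho[i] * sum(Y[[i]] * q)
        q <- q + S[[i]] * (al[i] - be)
      }
      d <- -q
    }
    dphi0 <- sum(g * d)
    if (dphi0 >= 0) {            # not a descent direction: restart
      S <- list(); Y <- list(); rho <- numeric(0)
      d <- -g
      dphi0 <- -sum(g^2)
      if (dphi0 == 0) { exit <- "grad_tol"; iter <- iter - 1L; break }
    }
    last <- new.env(parent = emptyenv())
    phi <- function(a) {
      e <- fg(x + a * d)
      assign("e", e, envir = last); assign("a", a, envir = last)
      list(f = e$f, dphi = sum(e$g * d))
    }
    a1 <- if (lbfgs && length(S) > 0L) 1
          else if (is.na(a_prev)) min(1, 1 / max(sqrt(-dphi0), 1e-12))
          else max(min(1, 1.05 * a_prev * dphi_prev / dphi0), 1e-14)
    ls <- line_search_wolfe(phi, f, dphi0, a1, opts$c1, opts$c2, opts$max_ls)
    if (is.null(ls)) { exit <- "line_search_failure"; iter <- iter - 1L; break }
    e <- if (get("a", envir = last) == ls$a) get("e", envir = last)
         else fg(x + ls$a * d)
    f_new <- e$f; g_new <- e$g
    if (opts$store_trace) trace[iter + 1L, ] <- c(f_new, sqrt(sum(g_new^2)) / len)
    x <- x + ls$a * d
    if (lbfgs) {
      sv <- ls$a * d
      yv <- g_new - g
      sy <- sum(sv * yv)
      if (sy > 1e-12 * sum(yv^2)) {     # curvature condition: keep pair
        S <- c(S, list(sv)); Y <- c(Y, list(yv)); rho <- c(rho, 1 / sy)
        if (length(S) > opts$memory) {
          S <- S[-1L]; Y <- Y[-1L]; rho <- rho[-1L]
        }
      }
    } else {
      beta <- max(0, sum(g_new * (g_new - g)) / sum(g^2))
      d <- -g_new + beta * d
    }
    a_prev <- ls$a; dphi_prev <- dphi0
    rel_f <- abs(f - f_new) / max(abs(f), .Machine$double.xmin)
    gpe <- sqrt(sum(g_new^2)) / len
    f <- f_new; g <- g_new
    if (gpe <= opts$grad_per_entry_tol) { exit <- "grad_tol"; break }
    if (rel_f <= opts$rel_f_tol) { exit <- "f_tol"; break }
  }
  if (exit == "max_iter" && sqrt(sum(g^2)) / len <= opts$grad_per_entry_tol)
    exit <- "grad_tol"
  list(x = x, f = f, g = g, iterations = iter, exit = exit,
       trace = if (opts$store_trace) trace[seq_len(iter + 1L), , drop = FALSE])
}

fit_coupled <- function(data, R, cfg, opts, init, weighted, start_seed) {
  stopifnot(inherits(data, "coupled_data"), R >= 1)
  if (is.null(init)) init <- random_model(data, R, start_seed, weighted)
  if (!inherits(init, "factor_model"))
    stop("`init` must be a factor_model or NULL")
  if (weighted && is.null(init$weights))
    stop("ACMTF initialization requires weight vectors")
  if (!weighted) init$weights <- NULL
  template <- init
  if (all(lengths(data$modes) <= 3L)) {
    # compiled fused evaluator on the packed parameter vector
    mode_rows <- vapply(template$factors, nrow, integer(1))
    bdims <- lapply(data$blocks, dim)
    fg <- function(x) {
      .coupled_fg_packed(x, mode_rows, template$R, data$blocks, bdims,
                         data$modes, data$masks, cfg$alpha, cfg$beta,
                         cfg$epsilon, cfg$half_factor, weighted)
    }
  } else {
    fg <- function(x) {
      m <- unpack_parameters(x, template)
      ev <- coupled_fg(m, data, cfg, want_grad = TRUE)
      g <- c(unlist(lapply(ev$grad$factors, as.numeric), use.names = FALSE),
             unlist(ev$grad$weights, use.names = FALSE))
      list(f = ev$f, g = g)
    }
  }
  res <- fo_minimize(pack_parameters(init), fg, opts)
  structure(
    list(model = unpack_parameters(res$x, template),
         f_final = res$f,
         grad_norm_per_entry = sqrt(sum(res$g^2)) / length(res$g),
         iterations = res$iterations,
         exit = res$exit,
         start_seed = start_seed,
         model_type = if (weighted) "acmtf" else "cmtf",
         R = R, cfg = cfg, trace = res$trace),
    class = "coupled_fit")
}

#' Fit the ACMTF model from one starting point
#'
#' All-at-once first-order minimization of [acmtf_objective()] by nonlinear
#' conjugate gradients (Polak-Ribiere+ with restarts) under a strong-Wolfe
#' line search. Stops when the relative change in objective value or the
#' gradient 2-norm per entry drops below the tolerances in `opts`.
#' Blocks should normally be Frobenius-scaled first ([scale_blocks()]) so
#' that `alpha = 1` balances the objective terms.
#'
#' @param data a [coupled_data].
#' @param R number of components.
#' @param cfg a [penalty_config].
#' @param opts a [fit_options].
#' @param init a [factor_model] starting point, or `NULL` to draw one with
#'   [random_model()] using `seed`.
#' @param seed seed for the random start when `init` is `NULL`.
#' @return an object of class `coupled_fit`: `model`, `f_final`,
#'   `grad_norm_per_entry`, `iterations`, `exit` (one of `"f_tol"`,
#'   `"grad_tol"`, `"max_iter"`, `"line_search_failure"`), `start_seed`,
#'   `model_type`, and the optimization `trace`.
#' @export
fit_acmtf <- function(data, R, cfg = penalty_config(), opts = fit_options(),
                      init = NULL, seed = opts$seed) {
  fit_coupled(data, R, cfg, opts, init, weighted = TRUE, start_seed = seed)
}

#' Fit the unweighted CMTF model from one starting point
#'
#' Same optimizer as [fit_acmtf()] applied to [cmtf_objective()]; the model
#' carries no explicit component weights (extract them afterwards with
#' [extract_cmtf_weights()]).
#'
#' @inheritParams fit_acmtf
#' @return a `coupled_fit` (see [fit_acmtf()]) with `model_type = "cmtf"`.
#' @export
fit_cmtf <- function(data, R, cfg = penalty_config(), opts = fit_options(),
                     init = NULL, seed = opts$seed) {
  fit_coupled(data, R, cfg, opts, init, weighted = FALSE, start_seed = seed)
}

#' @export
print.coupled_fit <- function(x, ...) {
  cat(sprintf("%s fit: R = %d, f = %.10g, |g|/len = %.3g, %d iter (%s), seed %d\n",
              toupper(x$model_type), x$R, x$f_final, x$grad_norm_per_entry,
              x$iterations, x$exit, x$start_seed))
  invisible(x)
}

#' Multi-start fitting protocol
#'
#' Because the coupled factorization objective is non-convex, the standard
#' protocol fits from many random starts and keeps the minimum-function-value
#' solution. Start `s` uses the derived seed documented in [fit_options()],
#' so the whole protocol is deterministic in `opts$seed`.
#'
#' @inheritParams fit_acmtf
#' @param model `"acmtf"` (default) or `"cmtf"`.
#' @return a list of `coupled_fit` objects sorted by `f_final` (ascending),
#'   of class `multi_start_fits`. The best run is the first element.
#' @export
multi_start <- function(data, R, cfg = penalty_config(),
                        opts = fit_options(), model = c("acmtf", "cmtf")) {
  model <- match.arg(model)
  seeds <- vapply(seq_len(opts$n_starts), function(s)
    derived_seed(opts$seed, s), integer(1))
  runs <- vector("list", opts$n_starts)
  failed <- logical(opts$n_starts)
  for (s in seq_len(opts$n_starts)) {
    runs[[s]] <- tryCatch(
      fit_coupled(data, R, cfg, opts, init = NULL,
                  weighted = (model == "acmtf"), start_seed = seeds[s]),
      error = function(e) e)
    failed[s] <- inherits(runs[[s]], "error")
  }
  if (all(failed))
    stop("all ", opts$n_starts, " starts failed; first error: ",
         conditionMessage(runs[[1L]]))
  runs <- runs[!failed]
  runs <- runs[order(vapply(runs, function(r) r$f_final, numeric(1)))]
  structure(runs, class = c("multi_start_fits", "list"))
}

#' @export
print.multi_start_fits <- function(x, ...) {
  fs <- vapply(x, function(r) r$f_final, numeric(1))
  cat(sprintf("multi_start_fits: %d run(s), best f = %.10g, same-f group size %d\n",
              length(x), fs[1L], length(group_by_f(x)[[1L]])))
  invisible(x)
}

#' Group fit results by final objective value
#'
#' Runs whose final objective values agree are treated as "the same
#' solution" for uniqueness diagnostics. Two grouping dialects are
#' supported: `abs_diff` (default) chains runs whose consecutive sorted `f`
#' values differ by less than `tol`; `decimals` groups runs whose `f` values
#' have all digits identical up to the `decimals`-th decimal place.
#'
#' @param results a `multi_start_fits` list, a list of `coupled_fit`
#'   objects, or a numeric vector of `f` values.
#' @param mode `"abs_diff"` or `"decimals"`.
#' @param tol absolute tolerance for `mode = "abs_diff"` (default `1e-6`).
#' @param decimals decimal places for `mode = "decimals"` (default 6).
#' @return a list of integer index vectors into `results`, ordered so the
#'   first group contains the minimum `f` ("the same-f group"); grouping is
#'   invariant to the order of `results`.
#' @export
group_by_f <- function(results, mode = c("abs_diff", "decimals"),
                       tol = 1e-6, decimals = 6L) {
  mode <- match.arg(mode)
  fs <- if (is.numeric(results)) results
        else vapply(results, function(r) r$f_final, numeric(1))
  if (length(fs) == 0L) stop("`results` is empty")
  ord <- order(fs)
  sorted <- fs[ord]
  if (mode == "abs_diff") {
    brk <- c(FALSE, diff(sorted) >= tol)
  } else {
    key <- trunc(sorted * 10^decimals)
    brk <- c(FALSE, diff(key) != 0)
  }
  gid <- cumsum(brk)
  unname(split(ord, gid))
}

#' Runs in the minimum-f group
#'
#' Convenience wrapper: the subset of `results` whose final objective value
#' agrees with the overall minimum under [group_by_f()].
#'
#' @inheritParams group_by_f
#' @return list of `coupled_fit` objects.
#' @export
same_f_group <- function(results, mode = c("abs_diff", "decimals"),
                         tol = 1e-6, decimals = 6L) {
  idx <- group_by_f(results, mode, tol, decimals)[[1L]]
  results[idx]
}
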