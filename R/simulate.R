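#' Specify a synthetic coupled-data design
#'
#' Describes a coupled simulation: a third-order tensor
#' \eqn{[\![\lambda; A, B, C]\!]} (modes `I x J x K`) coupled in its first
#' mode with a matrix \eqn{Y = A \Sigma V^T} (`I x M`) and optionally a
#' second matrix \eqn{Z = A \Gamma S^T} (`I x L`). All factor matrices have
#' i.i.d. standard-normal entries with columns normalized to unit 2-norm,
#' so each block's signal is a weighted sum of unit-norm rank-one terms and
#' the weight patterns alone decide which components are shared across
#' blocks and which are confined to one block.
#'
#' @param weights named or unnamed list of numeric weight vectors, all of
#'   length `R`: first the tensor's (`lambda`), then one per matrix block
#'   (`sigma`, and `gamma` if a third block is wanted).
#' @param dims integer global mode sizes: `I`, `J`, `K` for the tensor, then
#'   the column dimension of each matrix block (`M`, and `L` for a third
#'   block). Defaults `c(50, 30, 40, 20)` (+`40` when three blocks).
#' @param noise_level nonnegative relative noise magnitude: Gaussian noise
#'   scaled so `|noise|_F / |signal|_F = noise_level` per block (default
#'   0.03).
#' @param seed integer seed.
#' @return an object of class `simulation_spec`.
#' @seealso [case_presets()] for the standard designs; [generate_case()].
#' @export
simulation_spec <- function(weights, dims = NULL, noise_level = 0.03,
                            seed = 1L) {
  if (!is.list(weights) || length(weights) < 1L)
    stop("`weights` must be a list with at least one weight vector")
  weights <- lapply(weights, as.numeric)
  R <- length(weights[[1L]])
  if (any(vapply(weights, length, integer(1)) != R))
    stop("all weight vectors must have the same length R")
  nb <- length(weights)
  if (is.null(dims)) dims <- c(50L, 30L, 40L, rep(c(20L, 40L), length.out = nb - 1L))
  dims <- as.integer(dims)
  if (length(dims) != 3L + (nb - 1L))
    stop("`dims` must have length 3 + number of matrix blocks")
  if (any(dims < 1L)) stop("`dims` must be positive")
  if (noise_level < 0) stop("`noise_level` must be >= 0")
  if (is.null(names(weights)))
    names(weights) <- c("lambda", "sigma", "gamma",
                        paste0("w", seq_len(max(0, nb - 3L)) + 3L))[seq_len(nb)]
  structure(list(weights = weights, dims = dims, R = R,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Standard simulation designs
#'
#' The canonical two-block and three-block sharing patterns used to probe
#' whether a coupled factorization reveals shared and unshared components
#' (`R` components, a `50 x 30 x 40` tensor and `50 x 20` matrix unless
#' noted):
#' \describe{
#'   \item{`case1`}{one shared and one unshared component in each block:
#'     `lambda = (1,0,1)`, `sigma = (1,1,0)`, `R = 3`.}
#'   \item{`case2`}{one unshared component in the matrix:
#'     `lambda = (1,1,0)`, `sigma = (1,1,1)`.}
#'   \item{`case3`}{one unshared component in the tensor:
#'     `lambda = (1,1,1)`, `sigma = (1,1,0)`.}
#'   \item{`case4`}{one shared plus one unshared in the tensor and two
#'     unshared in the matrix: `lambda = (1,1,0,0)`, `sigma = (1,0,1,1)`,
#'     `R = 4`.}
#'   \item{`case1_scaled`}{`case1` with `lambda = (100,0,100)` — probes
#'     invariance of the recovered pattern to block scale.}
#'   \item{`three_block`}{tensor plus two matrices (`50 x 20` and
#'     `50 x 40`), one component shared by all three and one unshared per
#'     block: `lambda = (1,1,0,0)`, `sigma = (1,0,1,0)`,
#'     `gamma = (1,0,0,1)`, `R = 4`.}
#' }
#'
#' @param name one of `"case1"`, `"case2"`, `"case3"`, `"case4"`,
#'   `"case1_scaled"`, `"three_block"`.
#' @param noise_level,seed passed to [simulation_spec()].
#' @return a [simulation_spec].
#' @export
case_presets <- function(name, noise_level = 0.03, seed = 1L) {
  presets <- list(
    case1 = list(weights = list(lambda = c(1, 0, 1), sigma = c(1, 1, 0))),
    case2 = list(weights = list(lambda = c(1, 1, 0), sigma = c(1, 1, 1))),
    case3 = list(weights = list(lambda = c(1, 1, 1), sigma = c(1, 1, 0))),
    case4 = list(weights = list(lambda = c(1, 1, 0, 0), sigma = c(1, 0, 1, 1))),
    case1_scaled = list(weights = list(lambda = c(100, 0, 100),
                                       sigma = c(1, 1, 0))),
    three_block = list(weights = list(lambda = c(1, 1, 0, 0),
                                      sigma = c(1, 0, 1, 0),
                                      gamma = c(1, 0, 0, 1)),
                       dims = c(50L, 30L, 40L, 20L, 40L)))
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop("unknown preset; choose one of: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  simulation_spec(p$weights, dims = p$dims, noise_level = noise_level,
                  seed = seed)
}

#' Draw unit-norm Gaussian factor matrices
#'
#' One factor matrix per global mode, entries i.i.d. standard normal,
#' columns normalized to unit 2-norm. Deterministic in `seed`.
#'
#' @param dims integer vector of mode sizes.
#' @param R number of components.
#' @param seed integer seed.
#' @return list of `dims[g] x R` matrices.
#' @export
generate_factors <- function(dims, R, seed) {
  stopifnot(all(dims >= 1), R >= 1)
  set.seed(seed)
  lapply(dims, function(n) {
    u <- matrix(stats::rnorm(n * R), n, R)
    u / rep(sqrt(colSums(u^2)), each = n)
  })
}

#' Generate a synthetic coupled dataset with known ground truth
#'
#' Builds the blocks of `spec` from freshly drawn unit-norm Gaussian factor
#' matrices: tensor \eqn{[\![\lambda; A,B,C]\!]}, matrices
#' \eqn{A\,\mathrm{diag}(w_b)V_b^T}, then adds per-block Gaussian noise
#' scaled to `noise_level` times the block's signal norm.
#'
#' @param spec a [simulation_spec] (or preset name, see [case_presets()]).
#' @return list with `data` (a [coupled_data]) and `truth` (class
#'   `simulation_truth`): the generating `factors`, `weights`, pre-noise
#'   `signal_norms`, noisy `block_norms`, and the `spec`.
#' @export
generate_case <- function(spec) {
  if (is.character(spec)) spec <- case_presets(spec)
  stopifnot(inherits(spec, "simulation_spec"))
  nb <- length(spec$weights)
  dims <- spec$dims
  factors <- generate_factors(dims, spec$R, spec$seed)
  modes <- c(list(c(1L, 2L, 3L)),
             lapply(seq_len(nb - 1L), function(b) c(1L, 3L + b)))
  blocks <- vector("list", nb)
  signal_norms <- numeric(nb)
  for (b in seq_len(nb)) {
    blocks[[b]] <- cp_reconstruct(factors[modes[[b]]], spec$weights[[b]])
    signal_norms[b] <- fnorm(blocks[[b]])
    if (spec$noise_level > 0) {
      noise <- array(stats::rnorm(length(blocks[[b]])), dim(blocks[[b]]))
      blocks[[b]] <- blocks[[b]] +
        noise * (spec$noise_level * signal_norms[b] / fnorm(noise))
    }
  }
  names(blocks) <- c("X", "Y", "Z", paste0("B", seq_len(max(0, nb - 3L)) + 3L))[seq_len(nb)]
  data <- coupled_data(blocks, modes)
  truth <- structure(
    list(factors = factors, weights = spec$weights,
         signal_norms = signal_norms, block_norms = data$norms, spec = spec),
    class = "simulation_truth")
  list(data = data, truth = truth)
}

#' Add uniform missingness masks to a coupled dataset
#'
#' Marks a `fraction` of each block's entries missing completely at random
#' (per block; exactly `round(fraction * length(block))` entries). Missing
#' entries are zeroed in the stored values and excluded from objectives and
#' gradients through the masks.
#'
#' @param data a [coupled_data].
#' @param fraction missing fraction per block in `[0, 1)`; recycled across
#'   blocks.
#' @param seed integer seed; the draw is deterministic in it.
#' @return a [coupled_data] with masks set.
#' @export
add_missing <- function(data, fraction, seed) {
  stopifnot(inherits(data, "coupled_data"))
  fraction <- rep_len(fraction, n_blocks(data))
  if (any(fraction < 0 | fraction >= 1))
    stop("`fraction` must be in [0, 1)")
  set.seed(seed)
  masks <- vector("list", n_blocks(data))
  for (b in seq_len(n_blocks(data))) {
    n <- length(data$blocks[[b]])
    w <- rep(1, n)
    n_miss <- round(fraction[b] * n)
    if (n_miss > 0) w[sample.int(n, n_miss)] <- 0
    dim(w) <- dim(data$blocks[[b]])
    masks[[b]] <- w
  }
  coupled_data(data$blocks, data$modes, masks = masks, norms = NULL)
}
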