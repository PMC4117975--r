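#' Write / read a coupled dataset as CSV slabs plus a JSON descriptor
#'
#' On-disk layout (one directory per dataset, plain text throughout): a
#' `descriptor.json` carrying block names, shapes, global mode ids,
#' recorded Frobenius norms and any provenance (`config`, e.g. a simulation
#' spec and seed); one `<name>.csv` per block holding the block's mode-1
#' unfolding (no headers); `<name>.mask.csv` for blocks with observation
#' masks; and, when a ground truth is attached, `truth.json` with the
#' generating factors and weights.
#'
#' @param data a [coupled_data].
#' @param path directory to create/populate.
#' @param truth optional `simulation_truth` to store alongside.
#' @param config optional list (run configuration, seeds, ...) embedded in
#'   the descriptor for provenance.
#' @return `write_coupled_data()`: `path`, invisibly.
#' @export
write_coupled_data <- function(data, path, truth = NULL, config = NULL) {
  stopifnot(inherits(data, "coupled_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  desc <- list(
    format = "acmtf-coupled-data", version = 1L,
    names = data$names,
    shapes = lapply(data$blocks, dim),
    modes = data$modes,
    mode_dims = data$mode_dims,
    norms = data$norms,
    has_mask = !vapply(data$masks, is.null, logical(1)),
    config = config)
  jsonlite::write_json(desc, file.path(path, "descriptor.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (b in seq_along(data$blocks)) {
    utils::write.table(unfold(data$blocks[[b]], 1L),
                       file.path(path, paste0(data$names[b], ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    if (!is.null(data$masks[[b]]))
      utils::write.table(unfold(data$masks[[b]], 1L),
                         file.path(path, paste0(data$names[b], ".mask.csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(factors = lapply(truth$factors, unclass),
           weights = truth$weights,
           signal_norms = truth$signal_norms,
           block_norms = truth$block_norms,
           spec = list(weights = truth$spec$weights, dims = truth$spec$dims,
                       R = truth$spec$R,
                       noise_level = truth$spec$noise_level,
                       seed = truth$spec$seed)),
      file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_coupled_data
#' @return `read_coupled_data()`: a [coupled_data]; any stored truth is
#'   attached as attribute `"truth"` and provenance as attribute `"config"`.
#' @export
read_coupled_data <- function(path) {
  desc <- jsonlite::read_json(file.path(path, "descriptor.json"),
                              simplifyVector = TRUE)
  if (!identical(desc$format, "acmtf-coupled-data"))
    stop("`", path, "` does not contain an acmtf coupled dataset")
  nb <- length(desc$names)
  blocks <- vector("list", nb); masks <- vector("list", nb)
  shapes <- desc$shapes
  if (is.data.frame(shapes)) shapes <- as.list(as.data.frame(t(shapes)))
  modes <- desc$modes
  if (is.matrix(modes)) modes <- as.list(as.data.frame(t(modes)))
  for (b in seq_len(nb)) {
    shape <- as.integer(unlist(shapes[[b]]))
    m <- as.matrix(utils::read.table(
      file.path(path, paste0(desc$names[b], ".csv")), sep = ","))
    blocks[[b]] <- fold(m, 1L, shape)
    if (isTRUE(desc$has_mask[b])) {
      w <- as.matrix(utils::read.table(
        file.path(path, paste0(desc$names[b], ".mask.csv")), sep = ","))
      masks[[b]] <- fold(w, 1L, shape)
    }
  }
  names(blocks) <- desc$names
  out <- coupled_data(blocks, lapply(modes, as.integer), masks = masks,
                      norms = desc$norms)
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- structure(
      list(factors = lapply(tr$factors, as.matrix),
           weights = as.list(as.data.frame(tr$weights)),
           signal_norms = tr$signal_norms, block_norms = tr$block_norms,
           spec = tr$spec),
      class = "simulation_truth")
    attr(out, "truth") <- truth
  }
  attr(out, "config") <- desc$config
  out
}

fit_to_list <- function(fit) {
  list(model_type = fit$model_type, R = fit$R,
       f_final = fit$f_final,
       grad_norm_per_entry = fit$grad_norm_per_entry,
       iterations = fit$iterations, exit = fit$exit,
       start_seed = fit$start_seed,
       factors = lapply(fit$model$factors, unclass),
       weights = fit$model$weights,
       cfg = unclass(fit$cfg))
}

#' Write / read fit results as JSON
#'
#' Serializes one `coupled_fit` or a `multi_start_fits` list (models,
#' objective values, exit conditions, seeds and the penalty configuration)
#' to a single JSON file. Optimization traces are not stored; see
#' [write_trace()].
#'
#' @param fits a `coupled_fit` or list of them.
#' @param path output file.
#' @param config optional run configuration embedded for provenance.
#' @return `write_fit_results()`: `path`, invisibly.
#' @export
write_fit_results <- function(fits, path, config = NULL) {
  if (inherits(fits, "coupled_fit")) fits <- list(fits)
  jsonlite::write_json(
    list(format = "acmtf-fits", version = 1L, config = config,
         runs = lapply(fits, fit_to_list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_results
#' @return `read_fit_results()`: list of `coupled_fit` objects (class
#'   `multi_start_fits`), in stored order; attribute `"config"` carries the
#'   stored configuration.
#' @export
read_fit_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "acmtf-fits")) stop("not an acmtf fit file")
  runs <- lapply(x$runs, function(run) {
    # jsonlite serializes a matrix as an array of rows
    factors <- lapply(run$factors, function(u)
      do.call(rbind, lapply(u, unlist)))
    weights <- if (length(run$weights) > 0)   # NULL serializes as {}
      lapply(run$weights, function(w) as.numeric(unlist(w)))
    structure(
      list(model = factor_model(factors, weights),
           f_final = run$f_final,
           grad_norm_per_entry = run$grad_norm_per_entry,
           iterations = run$iterations,
           exit = run$exit,
           start_seed = run$start_seed,
           model_type = run$model_type,
           R = run$R,
           cfg = penalty_config(run$cfg$alpha, run$cfg$beta,
                                run$cfg$epsilon, run$cfg$half_factor),
           trace = NULL),
      class = "coupled_fit")
  })
  attr(runs, "config") <- x$config
  class(runs) <- c("multi_start_fits", "list")
  runs
}

#' Write an optimization trace as CSV
#'
#' One row per accepted iteration with columns `iter`, `f`,
#' `gnorm_per_entry`.
#'
#' @param fit a `coupled_fit` with a stored trace.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  if (is.null(fit$trace)) stop("fit has no stored trace")
  df <- data.frame(iter = seq_len(nrow(fit$trace)) - 1L,
                   f = fit$trace[, "f"],
                   gnorm_per_entry = fit$trace[, "gnorm_per_entry"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
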