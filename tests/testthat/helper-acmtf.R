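# Small coupled instances used across test files.

# 4x3x2 tensor + 4x3 matrix, R = 2: the smallest coupled configuration
# with all structural features (shared mode, distinct unshared modes).
tiny_spec <- function(noise_level = 0.05, seed = 3L,
                      lambda = c(1, 0), sigma = c(1, 1)) {
  simulation_spec(list(lambda = lambda, sigma = sigma),
                  dims = c(4L, 3L, 2L, 3L), noise_level = noise_level,
                  seed = seed)
}

tiny_case <- function(...) generate_case(tiny_spec(...))

# Mid-size coupled instance for optimizer tests: big enough that the
# optimum is well separated, small enough to fit in milliseconds.
small_case <- function(noise_level = 0.03, seed = 7L) {
  generate_case(simulation_spec(
    list(lambda = c(1, 0, 1), sigma = c(1, 1, 0)),
    dims = c(15L, 10L, 8L, 6L), noise_level = noise_level, seed = seed))
}

# Central finite-difference gradient at a packed parameter point.
numeric_gradient <- function(fun, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fun(x + e) - fun(x - e)) / (2 * h)
  }, numeric(1))
}

# Triple-loop CP reconstruction, the brute-force oracle for the fast path.
cp_loops <- function(factors, weights) {
  shape <- vapply(factors, nrow, integer(1))
  out <- array(0, shape)
  R <- length(weights)
  idx <- as.matrix(expand.grid(lapply(shape, seq_len)))
  for (row in seq_len(nrow(idx))) {
    v <- 0
    for (r in seq_len(R)) {
      term <- weights[r]
      for (g in seq_along(factors)) term <- term * factors[[g]][idx[row, g], r]
      v <- v + term
    }
    out[matrix(idx[row, ], 1L)] <- v
  }
  out
}
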