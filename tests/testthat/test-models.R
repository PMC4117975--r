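test_that("smoothed_abs approximates |x| from above, symmetrically", {
  expect_equal(smoothed_abs(0, 1e-8), 1e-4)
  expect_equal(smoothed_abs(1, 1e-8), sqrt(1 + 1e-8))
  expect_lt(abs(smoothed_abs(1, 1e-8) - (1 + 5e-9)), 1e-12)
  expect_equal(smoothed_abs(-3), smoothed_abs(3))
  x <- seq(-2, 2, by = 0.25)
  expect_true(all(smoothed_abs(x) >= abs(x)))
  expect_error(smoothed_abs(1, 0), "positive")
  expect_error(smoothed_abs(1, -1), "positive")
})

test_that("cmtf objective matches residual sums computed by loops", {
  sim <- tiny_case(noise_level = 0)
  truth_model <- factor_model(sim$truth$factors)
  # scale the truth weights into the factor columns: an exact CMTF optimum
  m <- truth_model
  m$factors[[1]] <- m$factors[[1]]
  exact <- factor_model(list(
    sim$truth$factors[[1]],
    sweep(sim$truth$factors[[2]], 2, sim$truth$weights$lambda, "*"),
    sim$truth$factors[[3]],
    sweep(sim$truth$factors[[4]], 2, sim$truth$weights$sigma, "*")))
  expect_equal(cmtf_objective(exact, sim$data), 0)
  zero <- factor_model(lapply(sim$data$mode_dims, function(n) matrix(0, n, 2)))
  expect_equal(cmtf_objective(zero, sim$data),
               0.5 * sum(vapply(sim$data$blocks, function(b) sum(b^2),
                                numeric(1))))
  set.seed(8)
  rnd <- random_model(sim$data, 2, seed = 21, weighted = FALSE)
  xhat <- cp_reconstruct(rnd$factors[c(1, 2, 3)], c(1, 1))
  yhat <- cp_reconstruct(rnd$factors[c(1, 4)], c(1, 1))
  by_loops <- 0.5 * (sum((sim$data$blocks[[1]] - xhat)^2) +
                     sum((sim$data$blocks[[2]] - yhat)^2))
  expect_equal(cmtf_objective(rnd, sim$data), by_loops)
  # half_factor off doubles the value
  expect_equal(cmtf_objective(rnd, sim$data, penalty_config(half_factor = FALSE)),
               2 * by_loops)
})

test_that("acmtf objective decomposes into data fit, norm and sparsity terms", {
  sim <- tiny_case(noise_level = 0)
  cfg <- penalty_config(alpha = 1, beta = 1e-3, epsilon = 1e-8)
  truth <- factor_model(sim$truth$factors, sim$truth$weights)
  # noise-free data at the generating point: only the sparsity term remains
  expect_equal(acmtf_objective(truth, sim$data, cfg),
               cfg$beta * sum(smoothed_abs(unlist(sim$truth$weights),
                                           cfg$epsilon)))
  # all-zero model: closed form
  zero <- factor_model(lapply(sim$data$mode_dims, function(n) matrix(0, n, 2)),
                       list(c(0, 0), c(0, 0)))
  expect_equal(acmtf_objective(zero, sim$data, cfg),
               0.5 * sum(vapply(sim$data$blocks, function(b) sum(b^2),
                                numeric(1))) +
               cfg$alpha / 2 * 2 * 4 +            # 2 columns x 4 factor matrices
               cfg$beta * 4 * sqrt(cfg$epsilon))  # 4 weight entries
  # with alpha = beta = 0 and unit weights, reduces to CMTF
  rnd <- random_model(sim$data, 2, seed = 5)
  expect_equal(acmtf_objective(rnd, sim$data, penalty_config(alpha = 0, beta = 0)),
               cmtf_objective(rnd, sim$data))
})

test_that("acmtf objective is permutation invariant and monotone in beta", {
  sim <- tiny_case()
  rnd <- random_model(sim$data, 2, seed = 9)
  rnd$weights <- list(c(0.5, -1.2), c(2, 0.1))
  cfg <- penalty_config()
  f0 <- acmtf_objective(rnd, sim$data, cfg)
  perm <- c(2, 1)
  permuted <- factor_model(lapply(rnd$factors, function(u) u[, perm]),
                           lapply(rnd$weights, function(w) w[perm]))
  expect_equal(acmtf_objective(permuted, sim$data, cfg), f0)
  betas <- c(0, 1e-4, 1e-3, 1e-2, 1)
  fs <- vapply(betas, function(b)
    acmtf_objective(rnd, sim$data, penalty_config(beta = b)), numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("masks drop missing entries from the objective", {
  sim <- tiny_case()
  rnd <- random_model(sim$data, 2, seed = 11)
  cfg <- penalty_config()
  # all-ones masks: bit-for-bit equal to unmasked
  ones <- lapply(sim$data$blocks, function(b) array(1, dim(b)))
  data1 <- coupled_data(sim$data$blocks, sim$data$modes, masks = ones)
  expect_identical(acmtf_objective(rnd, data1, cfg),
                   acmtf_objective(rnd, sim$data, cfg))
  # a masked cell's value cannot influence the objective
  masks <- lapply(sim$data$blocks, function(b) array(1, dim(b)))
  masks[[1]][2, 1, 1] <- 0
  blocks2 <- sim$data$blocks
  data_a <- coupled_data(blocks2, sim$data$modes, masks = masks)
  blocks2[[1]][2, 1, 1] <- 1e6
  data_b <- coupled_data(blocks2, sim$data$modes, masks = masks)
  expect_identical(acmtf_objective(rnd, data_a, cfg),
                   acmtf_objective(rnd, data_b, cfg))
  # random 20% missing: objective equals the sum over observed entries
  dm <- add_missing(sim$data, 0.2, seed = 13)
  xhat <- cp_reconstruct(rnd$factors[c(1, 2, 3)], rnd$weights[[1]])
  yhat <- cp_reconstruct(rnd$factors[c(1, 4)], rnd$weights[[2]])
  fit_terms <- 0.5 * (sum(((sim$data$blocks[[1]] - xhat) * dm$masks[[1]])^2) +
                      sum(((sim$data$blocks[[2]] - yhat) * dm$masks[[2]])^2))
  expect_equal(acmtf_objective(rnd, dm, penalty_config(alpha = 0, beta = 0)),
               fit_terms)
  expect_error(apply_mask(array(1, c(2, 2)), array(1, c(2, 3))), "shape")
})

test_that("analytic gradient matches central finite differences", {
  cfgs <- list(penalty_config(beta = 0), penalty_config(beta = 1e-3))
  sims <- list(two_block = tiny_case(),
               three_block = generate_case(simulation_spec(
                 list(lambda = c(1, 0), sigma = c(1, 1), gamma = c(0, 1)),
                 dims = c(4L, 3L, 2L, 3L, 2L), noise_level = 0.05, seed = 5)),
               masked = local({
                 s <- tiny_case()
                 s$data <- add_missing(s$data, 0.25, seed = 2)
                 s
               }))
  set.seed(31)
  for (sim in sims) {
    for (cfg in cfgs) {
      for (rep in 1:4) {
        m <- random_model(sim$data, 2, seed = sample.int(1e6, 1))
        m$weights <- lapply(m$weights, function(w) w + stats::rnorm(2) * 0.5)
        x0 <- pack_parameters(m)
        g <- acmtf_gradient(m, sim$data, cfg)
        gn <- numeric_gradient(function(x)
          acmtf_objective(unpack_parameters(x, m), sim$data, cfg), x0)
        expect_lt(max(abs(g - gn) / pmax(abs(gn), 1e-6)), 1e-5)
      }
    }
  }
})

test_that("gradient is stationary at a noise-free optimum and linear in alpha", {
  sim <- tiny_case(noise_level = 0)
  truth <- factor_model(sim$truth$factors, sim$truth$weights)
  g <- acmtf_gradient(truth, sim$data, penalty_config(alpha = 1, beta = 0))
  expect_lt(sqrt(sum(g^2)), 1e-8 * length(g))
  rnd <- random_model(sim$data, 2, seed = 77)
  g0 <- acmtf_gradient(rnd, sim$data, penalty_config(alpha = 0))
  g1 <- acmtf_gradient(rnd, sim$data, penalty_config(alpha = 1))
  g2 <- acmtf_gradient(rnd, sim$data, penalty_config(alpha = 2))
  expect_equal(g2 - g0, 2 * (g1 - g0))
})

test_that("cmtf gradient matches finite differences", {
  sim <- tiny_case()
  m <- random_model(sim$data, 2, seed = 14, weighted = FALSE)
  x0 <- pack_parameters(m)
  g <- cmtf_gradient(m, sim$data)
  gn <- numeric_gradient(function(x)
    cmtf_objective(unpack_parameters(x, m), sim$data), x0)
  expect_lt(max(abs(g - gn) / pmax(abs(gn), 1e-6)), 1e-5)
})

test_that("parameter packing is a documented-order bijection", {
  sim <- tiny_case()
  m <- random_model(sim$data, 2, seed = 4)
  x <- pack_parameters(m)
  # R(I + J + K + M + 2) for the two-block three-way configuration
  expect_length(x, 2 * (4 + 3 + 2 + 3 + 2))
  m2 <- unpack_parameters(x, m)
  expect_equal(m2$factors, m$factors)
  expect_equal(m2$weights, m$weights)
  # factors first (mode order), then weights (block order)
  expect_equal(x[1:8], as.numeric(m$factors[[1]]))
  expect_equal(x[(length(x) - 3):length(x)],
               c(m$weights[[1]], m$weights[[2]]))
  # three-block case: R(I + J + K + M + L + 3)
  sim3 <- generate_case(simulation_spec(
    list(lambda = c(1, 0), sigma = c(1, 1), gamma = c(0, 1)),
    dims = c(4L, 3L, 2L, 3L, 2L), noise_level = 0, seed = 1))
  m3 <- random_model(sim3$data, 2, seed = 1)
  expect_length(pack_parameters(m3), 2 * (4 + 3 + 2 + 3 + 2 + 3))
  expect_error(unpack_parameters(x[-1], m), "length")
})

test_that("compiled and reference evaluators agree", {
  sims <- list(tiny_case(),
               local({ s <- tiny_case(); s$data <- add_missing(s$data, 0.3, seed = 1); s }))
  cfg <- penalty_config()
  for (sim in sims) {
    m <- random_model(sim$data, 2, seed = 17)
    m$weights <- list(c(0.9, -0.1), c(0.2, 1.4))
    a <- acmtf:::coupled_fg(m, sim$data, cfg)
    b <- acmtf:::coupled_fg_ref(m, sim$data, cfg)
    expect_equal(a$f, b$f, tolerance = 1e-14)
    expect_equal(a$grad$factors, b$grad$factors, tolerance = 1e-13,
                 ignore_attr = TRUE)
    expect_equal(a$grad$weights, b$grad$weights, tolerance = 1e-13,
                 ignore_attr = TRUE)
    mc <- m; mc$weights <- NULL
    expect_equal(acmtf:::coupled_fg(mc, sim$data, cfg)$f,
                 acmtf:::coupled_fg_ref(mc, sim$data, cfg)$f,
                 tolerance = 1e-14)
  }
})
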