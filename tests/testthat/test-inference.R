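test_that("likelihood is maximal at the model prediction and matches a direct oracle", {
  p <- stp_params(D = 0.4, F = 0.2, U = 0.45, f = 0.1, A = 1.3)
  times <- periodic_train(30, 5)
  mu <- simulate_psps(p, times)
  tr <- psp_train(times, mu, sigmas = 0.1 * abs(mu))
  ll_max <- log_likelihood(tr, p, amplitude = "fixed")
  expect_equal(ll_max, -sum(log(tr$sigmas * sqrt(2 * pi))),
               tolerance = 1e-12)
  # perturbing any observation strictly decreases the likelihood
  for (i in seq_along(mu)) {
    d2 <- mu
    d2[i] <- d2[i] + 0.05
    tr2 <- psp_train(times, d2, sigmas = tr$sigmas)
    expect_lt(log_likelihood(tr2, p, amplitude = "fixed"), ll_max)
  }
  # random case against an independently coded product of Gaussian pdfs
  set.seed(8)
  d <- mu * (1 + 0.3 * rnorm(5))
  trr <- psp_train(times, d, sigmas = 0.2 * abs(mu))
  oracle <- sum(log(dnorm(d, mean = mu, sd = 0.2 * abs(mu))))
  expect_equal(log_likelihood(trr, p, amplitude = "fixed"), oracle,
               tolerance = 1e-10)
})

test_that("amplitude profiling recovers the generating scale and minimizes weighted error", {
  p <- stp_params(D = 0.5, F = 0.05, U = 0.5, f = 0.05, A = 2)
  times <- periodic_train(30, 5)
  d <- simulate_psps(p, times)
  m <- d / 2
  sig <- 0.1 * d
  expect_equal(amplitude_map(d, m, sig), 2, tolerance = 1e-12)
  expect_equal(amplitude_map(3 * d, m, sig), 6, tolerance = 1e-12)
  # random case against a fine grid search of the weighted SSE
  set.seed(21)
  d2 <- d + rnorm(5, 0, 0.1)
  a_hat <- amplitude_map(d2, m, sig)
  grid <- seq(a_hat - 0.5, a_hat + 0.5, length.out = 200001)
  sse <- vapply(grid, function(a) sum((d2 - a * m)^2 / sig^2), numeric(1))
  expect_equal(a_hat, grid[which.min(sse)], tolerance = 1e-5)
  expect_error(amplitude_map(d, rep(0, 5), sig), "degenerate")
})

test_that("log-posterior is flat-prior likelihood inside the box, -Inf outside", {
  p_in <- stp_params(D = 0.5, F = 0.5, U = 0.5, f = 0.5)
  p_out <- stp_params(D = 3, F = 0.5, U = 0.5, f = 0.5)
  tr <- make_noisy_train(p_in, periodic_train(30, 5), seed = 1)
  expect_identical(log_posterior(tr, p_out), -Inf)
  expect_equal(log_posterior(tr, p_in),
               log_likelihood(tr, p_in) - log(4), tolerance = 1e-12)
  # ordering by posterior equals ordering by likelihood inside the box
  p2 <- stp_params(D = 0.8, F = 0.3, U = 0.4, f = 0.2)
  expect_identical(log_posterior(tr, p_in) > log_posterior(tr, p2),
                   log_likelihood(tr, p_in) > log_likelihood(tr, p2))
})

test_that("slice sampler targets uniform and truncated-normal densities correctly", {
  # flat target: retained samples uniform in the box
  res <- slice_sample(function(x) 0, lower = c(0, 0), upper = c(1, 2),
                      n_iter = 4250, n_burn = 500, n_chains = 2, seed = 1)
  s <- do.call(rbind, res$samples)
  expect_equal(nrow(s), 7500)
  expect_gt(ks.test(s[, 1], "punif")$p.value, 0.01)
  expect_gt(ks.test(s[, 2] / 2, "punif")$p.value, 0.01)
  # separable truncated Gaussian: means recovered
  logf <- function(x) -sum((x - 0.5)^2) / (2 * 0.1^2)
  res2 <- slice_sample(logf, lower = c(0, 0), upper = c(1, 1),
                       n_iter = 6000, n_burn = 1000, n_chains = 2,
                       seed = 2)
  m <- colMeans(do.call(rbind, res2$samples))
  expect_equal(unname(m), c(0.5, 0.5), tolerance = 0.01)
  # determinism
  r1 <- slice_sample(logf, c(0, 0), c(1, 1), n_iter = 200, n_burn = 50,
                     n_chains = 2, seed = 9)
  r2 <- slice_sample(logf, c(0, 0), c(1, 1), n_iter = 200, n_burn = 50,
                     n_chains = 2, seed = 9)
  expect_identical(r1, r2)
  expect_error(slice_sample(logf, c(0, 0), c(1, 1), n_iter = 10,
                            n_burn = 20), "exceed")
})

test_that("gelman-rubin flags separated chains and accepts well-mixed ones", {
  set.seed(3)
  n <- 5000
  same <- list(matrix(rnorm(n), ncol = 1), matrix(rnorm(n), ncol = 1))
  expect_lt(gelman_rubin(same), 1.05)
  ident <- matrix(rnorm(n), ncol = 1)
  expect_equal(gelman_rubin(list(ident, ident)), sqrt((n - 1) / n),
               tolerance = 1e-6)
  apart <- list(matrix(rnorm(n, 0), ncol = 1),
                matrix(rnorm(n, 10), ncol = 1))
  expect_gt(gelman_rubin(apart), 1.1)
  expect_error(gelman_rubin(list(ident)), "two chains")
})

test_that("posterior object keeps samples in the box and MAP is the best sample", {
  p <- preset_params("depression")
  tr <- make_noisy_train(p, periodic_train(30, 5), seed = 4)
  post <- quick_post(tr, seed = 4)
  expect_equal(nrow(post$samples), 2000)
  box <- post$prior
  for (j in colnames(post$samples)) {
    expect_true(all(post$samples[, j] >= box[j, "lower"] &
                      post$samples[, j] <= box[j, "upper"]))
  }
  map <- map_estimate(post, as_params = FALSE)
  expect_equal(map$log_post, max(post$log_post))
  i <- which.max(post$log_post)
  expect_equal(unname(map$theta), unname(post$samples[i, ]))
  # refinement can only improve the log-posterior
  map_ref <- map_estimate(post, refine = TRUE, as_params = FALSE)
  expect_gte(map_ref$log_post, map$log_post)
})

test_that("MAP log-posterior exceeds the per-marginal argmax vector", {
  p <- preset_params("depression")
  tr <- make_noisy_train(p, periodic_train(30, 5), seed = 6)
  post <- quick_post(tr, seed = 6)
  marg_peak <- vapply(colnames(post$samples), function(pn) {
    md <- marginal_density(post, pn)
    md$grid[which.max(md$density)]
  }, numeric(1))
  p_marg <- stp_params(marg_peak[["D"]], marg_peak[["F"]],
                       marg_peak[["U"]], marg_peak[["f"]])
  expect_gte(map_estimate(post, as_params = FALSE)$log_post,
             log_posterior(tr, p_marg))
})

test_that("marginal densities integrate to one and track the samples", {
  p <- preset_params("facilitation")
  tr <- make_noisy_train(p, periodic_train(30, 5), seed = 5)
  post <- quick_post(tr, seed = 5)
  for (pn in c("D", "U")) {
    md <- marginal_density(post, pn)
    h <- md$grid[2] - md$grid[1]
    expect_equal(sum((md$density[-1] + md$density[-length(md$density)]) / 2)
                 * h, 1, tolerance = 1e-6)
  }
  expect_error(marginal_density(post, "Z"), "unknown parameter")
  # uniform samples give a flat density away from the edges (enough
  # samples that Monte-Carlo ripple stays below the flatness bound)
  set.seed(1)
  fake <- structure(list(
    samples = cbind(U = runif(20000)),
    prior = prior_box("etm")), class = "stp_posterior")
  mu <- marginal_density(fake, "U")
  ctr <- mu$grid > 0.25 & mu$grid < 0.75
  expect_lt(max(mu$density[ctr]) / min(mu$density[ctr]), 1.1)
  # a tight cloud puts the mode within one grid step of the sample mean
  fake$samples[, "U"] <- pmin(pmax(rnorm(20000, 0.4, 0.01), 0), 1)
  mt <- marginal_density(fake, "U", n_grid = 512)
  expect_lt(abs(mt$grid[which.max(mt$density)] -
                  mean(fake$samples[, "U"])),
            2 * (mt$grid[2] - mt$grid[1]))
})

test_that("parameters are recovered from a long low-noise poisson train", {
  p <- preset_params("depression")
  times <- poisson_train(30, 200, seed = 10)
  tr <- make_noisy_train(p, times, cv = 0.01, n_sweeps = 1, seed = 10)
  post <- quick_post(tr, seed = 10)
  m <- colMeans(post$samples)
  expect_lt(abs(m[["D"]] - p$D) / p$D, 0.05)
  expect_lt(abs(m[["U"]] - p$U) / p$U, 0.05)
})

test_that("sampling the amplitude explicitly recovers the scale", {
  p <- stp_params(D = 0.5, F = 0.05, U = 0.5, f = 0.05, A = 2)
  times <- poisson_train(30, 60, seed = 12)
  tr <- make_noisy_train(p, times, cv = 0.2, n_sweeps = 30, seed = 12)
  post <- infer_stp(tr, n_iter = 1500, n_burn = 500, n_chains = 2,
                    seed = 12, amplitude = "sample")
  expect_true("A" %in% colnames(post$samples))
  expect_equal(mean(post$samples[, "A"]), 2, tolerance = 0.1)
})
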