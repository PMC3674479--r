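#' Flat prior box for the dynamics parameters
#'
#' Independent uniform priors: D, F in \[0, 2\] s and U, f in \[0, 1\],
#' restricted to the parameters that are free under the given model variant.
#'
#' @inheritParams simulate_psps
#' @return Matrix with one row per free parameter and columns `lower`,
#'   `upper`.
#' @export
prior_box <- function(variant = "etm") {
  full <- rbind(D = c(0, 2), F = c(0, 2), U = c(0, 1), f = c(0, 1))
  colnames(full) <- c("lower", "upper")
  full[.free_params(variant), , drop = FALSE]
}

#' Weighted least-squares amplitude estimate
#'
#' Closed-form optimum of the amplitude factor A given per-pulse data,
#' normalized model values and noise levels:
#' `A = sum(d m / sigma^2) / sum(m^2 / sigma^2)`. This is the minimizer of
#' the variance-weighted squared error between data and `A * m`.
#'
#' @param d Per-pulse mean amplitudes (mV).
#' @param m Per-pulse normalized model values (amplitudes at A = 1).
#' @param sigmas Per-pulse noise standard deviations (mV).
#' @return The scalar amplitude estimate.
#' @export
amplitude_map <- function(d, m, sigmas) {
  if (length(d) != length(m) || length(d) != length(sigmas))
    stop("d, m and sigmas must have equal length")
  w <- 1 / sigmas^2
  den <- sum(m^2 * w)
  if (den == 0) stop("degenerate model: all normalized amplitudes are zero")
  sum(d * m * w) / den
}

#' Gaussian log-likelihood of a PSP train under the model
#'
#' Independent Gaussian observation model per pulse: the mean amplitude d_i
#' is normal with mean equal to the model prediction and standard deviation
#' sigma_i. By default the amplitude factor A is profiled out analytically
#' (set to its closed-form optimum for the candidate dynamics parameters);
#' with `amplitude = "fixed"` the `A` stored in `params` is used.
#'
#' @inheritParams simulate_psps
#' @param train A [psp_train].
#' @param amplitude `"profile"` (default) or `"fixed"`.
#' @return The log-likelihood (natural log).
#' @export
log_likelihood <- function(train, params, variant = "etm",
                           amplitude = c("profile", "fixed")) {
  amplitude <- match.arg(amplitude)
  params <- as_stp_params(params)
  if (!inherits(train, "psp_train")) stop("train must be a psp_train")
  m <- simulate_psps(params, train$times, variant) / params$A
  A <- if (amplitude == "profile")
    amplitude_map(train$amplitudes, m, train$sigmas) else params$A
  sum(dnorm(train$amplitudes, mean = A * m, sd = train$sigmas, log = TRUE))
}

#' Log-posterior of dynamics parameters
#'
#' Log-likelihood plus the log of the flat prior density; minus infinity
#' outside the prior box.
#'
#' @inheritParams log_likelihood
#' @param prior Prior box as returned by [prior_box()].
#' @return The unnormalized log-posterior.
#' @export
log_posterior <- function(train, params, variant = "etm",
                          prior = prior_box(variant),
                          amplitude = c("profile", "fixed")) {
  params <- as_stp_params(params)
  free <- rownames(prior)
  theta <- unlist(params[free])
  if (any(theta < prior[, "lower"] | theta > prior[, "upper"]))
    return(-Inf)
  log_likelihood(train, params, variant, amplitude) -
    sum(log(prior[, "upper"] - prior[, "lower"]))
}

# fast closure over the train for use inside the sampler
.make_target <- function(train, variant, prior, amplitude = "profile") {
  d <- train$amplitudes
  sig <- train$sigmas
  times <- train$times
  inv_s2 <- 1 / sig^2
  const <- -sum(log(sig)) - 0.5 * length(d) * log(2 * pi) -
    sum(log(prior[, "upper"] - prior[, "lower"]))
  code <- .variant_code(variant)
  lower <- prior[, "lower"]
  upper <- prior[, "upper"]
  sample_A <- amplitude == "sample"
  function(theta) {
    if (any(theta < lower) || any(theta > upper)) return(-Inf)
    m <- switch(as.character(code),
      "0" = .psp_recursion(times, theta[1], theta[2], theta[3], theta[4], 0L),
      "1" = .psp_recursion(times, theta[1], theta[2], theta[3], theta[3], 1L),
      "2" = .psp_recursion(times, theta[1], 1.0, theta[2], 0.0, 2L))
    if (sample_A) {
      A <- theta[length(theta)]
    } else {
      den <- sum(m * m * inv_s2)
      if (den == 0) return(-Inf)
      A <- sum(d * m * inv_s2) / den
    }
    ll <- const - 0.5 * sum((d - A * m)^2 * inv_s2)
    if (is.nan(ll)) stop("log-posterior evaluated to NaN")
    ll
  }
}

#' Coordinate-wise slice sampler over a box
#'
#' Univariate slice sampling (stepping-out then shrinkage, Neal 2003)
#' applied to each coordinate in fixed order once per iteration. The
#' stepping-out interval is clipped to the box, so for a flat-prior target
#' the sampler is rejection-free by construction.
#'
#' @param log_fn Log-density function of a parameter vector; may return
#'   `-Inf` (e.g. outside the support) but not `NaN`.
#' @param lower,upper Box bounds per coordinate.
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations discarded from the front of each chain.
#' @param n_chains Number of independent chains.
#' @param widths Initial slice widths per coordinate; defaults to the box
#'   widths.
#' @param init Optional list of start vectors (one per chain); by default
#'   chains start from independent uniform draws inside the box
#'   (re-drawn while the target is `-Inf`).
#' @param seed Optional RNG seed.
#' @return List with `samples` (list of retained per-chain matrices) and
#'   `log_post` (list of matching log-density vectors).
#' @export
slice_sample <- function(log_fn, lower, upper, n_iter = 10000,
                         n_burn = 2500, n_chains = 3, widths = NULL,
                         init = NULL, seed = NULL) {
  k <- length(lower)
  if (length(upper) != k || any(upper <= lower))
    stop("invalid box bounds")
  if (n_iter <= n_burn) stop("n_iter must exceed n_burn")
  if (is.null(widths)) widths <- upper - lower
  if (any(widths <= 0)) stop("widths must be positive")
  if (!is.null(seed)) set.seed(seed)
  chains <- vector("list", n_chains)
  logs <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    if (!is.null(init)) {
      x <- init[[ch]]
      fx <- log_fn(x)
      if (!is.finite(fx)) stop("init point has -Inf target")
    } else {
      repeat {
        x <- runif(k, lower, upper)
        fx <- log_fn(x)
        if (is.finite(fx)) break
      }
    }
    out <- matrix(NA_real_, nrow = n_iter, ncol = k)
    lp <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      for (j in seq_len(k)) {
        y <- fx - rexp(1L)
        w <- widths[j]
        L <- x[j] - runif(1L) * w
        R <- L + w
        # step out until below the slice or at the box edge
        xt <- x
        while (L > lower[j]) {
          xt[j] <- L
          if (log_fn(xt) <= y) break
          L <- L - w
        }
        if (L < lower[j]) L <- lower[j]
        while (R < upper[j]) {
          xt[j] <- R
          if (log_fn(xt) <= y) break
          R <- R + w
        }
        if (R > upper[j]) R <- upper[j]
        # shrinkage
        repeat {
          x1 <- runif(1L, L, R)
          xt[j] <- x1
          f1 <- log_fn(xt)
          if (f1 > y) {
            x[j] <- x1
            fx <- f1
            break
          }
          if (x1 < x[j]) L <- x1 else R <- x1
          if (R - L < 1e-14) {  # numerical safety: keep current point
            xt[j] <- x[j]
            break
          }
        }
      }
      out[it, ] <- x
      lp[it] <- fx
    }
    keep <- seq.int(n_burn + 1L, n_iter)
    chains[[ch]] <- out[keep, , drop = FALSE]
    logs[[ch]] <- lp[keep]
  }
  list(samples = chains, log_post = logs)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance ratio per parameter,
#' `sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 are consistent with
#' convergence; the statistic can flag non-convergence but cannot confirm
#' convergence.
#'
#' @param chains List of at least two equal-size sample matrices (one per
#'   chain, columns = parameters).
#' @return Named numeric vector of per-parameter statistics.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("gelman_rubin requires at least two chains")
  n <- nrow(chains[[1]])
  if (any(vapply(chains, nrow, 0L) != n))
    stop("chains must have equal lengths")
  k <- ncol(chains[[1]])
  out <- numeric(k)
  for (j in seq_len(k)) {
    draws <- vapply(chains, function(m) m[, j], numeric(n))
    W <- mean(apply(draws, 2L, var))
    B_over_n <- var(colMeans(draws))
    out[j] <- sqrt(((n - 1) / n * W + B_over_n) / W)
  }
  names(out) <- colnames(chains[[1]])
  out
}

#' Posterior inference of STP parameters by slice-sampling MCMC
#'
#' Samples the posterior of the free dynamics parameters under flat priors,
#' with the amplitude factor A profiled out analytically at each likelihood
#' evaluation (default) or sampled as an extra coordinate. Runs multiple
#' chains from independent uniform starts, discards burn-in, and reports
#' the MAP (best retained sample, optionally refined by bounded local
#' optimization) and the Gelman-Rubin diagnostic.
#'
#' Defaults (10,000 iterations, 2,500 burn-in, 3 chains) retain 22,500
#' samples.
#'
#' @inheritParams log_likelihood
#' @param n_iter,n_burn,n_chains MCMC schedule.
#' @param widths Slice widths; default = prior box widths.
#' @param seed Optional RNG seed.
#' @param amplitude `"profile"` (default) or `"sample"` (adds A as a fifth
#'   coordinate with a flat prior up to 10 times the largest absolute data
#'   amplitude).
#' @param refine If `TRUE`, refine the MAP by L-BFGS-B within the box.
#' @return An object of class `stp_posterior` with elements `samples`
#'   (retained samples, rows stacked across chains), `log_post`, `chain`,
#'   `map` (list: `params`, `log_post`), `gelman_rubin`, `variant`,
#'   `prior`, and the input `train`.
#' @examples
#' tr <- make_noisy_train(preset_params("depression"),
#'                        periodic_train(30, 5), cv = 0.5, seed = 1)
#' post <- infer_stp(tr, n_iter = 400, n_burn = 100, n_chains = 2, seed = 1)
#' post$map$params
#' @export
infer_stp <- function(train, variant = "etm", n_iter = 10000,
                      n_burn = 2500, n_chains = 3, widths = NULL,
                      seed = NULL, amplitude = c("profile", "sample"),
                      refine = FALSE) {
  variant <- match.arg(variant, .stp_variants)
  amplitude <- match.arg(amplitude)
  prior <- prior_box(variant)
  if (amplitude == "sample") {
    a_up <- 10 * max(abs(train$amplitudes))
    prior <- rbind(prior, A = c(0, a_up))
  }
  target <- .make_target(train, variant, prior, amplitude)
  res <- slice_sample(target, lower = prior[, "lower"],
                      upper = prior[, "upper"], n_iter = n_iter,
                      n_burn = n_burn, n_chains = n_chains,
                      widths = widths, seed = seed)
  samples <- do.call(rbind, res$samples)
  colnames(samples) <- rownames(prior)
  log_post <- unlist(res$log_post)
  chain <- rep(seq_len(n_chains), each = n_iter - n_burn)
  post <- structure(list(
    samples = samples, log_post = log_post, chain = chain,
    n_iter = n_iter, n_burn = n_burn, n_chains = n_chains,
    variant = variant, amplitude = amplitude, prior = prior,
    gelman_rubin = if (n_chains >= 2L) gelman_rubin(res$samples) else NULL,
    train = train), class = "stp_posterior")
  post$map <- map_estimate(post, refine = refine, as_params = FALSE)
  post
}

#' @export
print.stp_posterior <- function(x, ...) {
  cat(sprintf(
    "STP posterior (%s): %d retained samples (%d chains x %d), %d burn-in\n",
    x$variant, nrow(x$samples), x$n_chains, x$n_iter - x$n_burn, x$n_burn))
  cat("posterior means:",
      paste(sprintf("%s = %.3f", colnames(x$samples), colMeans(x$samples)),
            collapse = ", "), "\n")
  if (!is.null(x$gelman_rubin))
    cat("Gelman-Rubin:",
        paste(sprintf("%.3f", x$gelman_rubin), collapse = ", "), "\n")
  invisible(x)
}

# assemble a full stp_params from a free-parameter vector
.theta_to_params <- function(theta, variant, train = NULL,
                             amplitude = "profile") {
  th <- as.list(theta)
  full <- switch(variant,
    etm    = stp_params(th$D, th$F, th$U, th$f),
    tm_fac = stp_params(th$D, th$F, th$U, th$U),
    tm     = stp_params(th$D, 1, th$U, 0))
  if (!is.null(th$A)) {
    full$A <- th$A
  } else if (!is.null(train)) {
    m <- simulate_psps(full, train$times, variant)
    full$A <- amplitude_map(train$amplitudes, m, train$sigmas)
  }
  full
}

#' MAP estimate from a posterior
#'
#' Returns the retained sample with the highest recorded log-posterior;
#' with `refine = TRUE`, a bounded local optimization (L-BFGS-B inside the
#' prior box) is started there and the refined point is returned if it
#' improves the log-posterior.
#'
#' @param posterior An `stp_posterior`.
#' @param refine Refine the best sample by local optimization.
#' @param as_params If `TRUE` (default) return an [stp_params] (with the
#'   profiled amplitude filled in); otherwise a list with the free
#'   parameter vector `theta`, `params` and `log_post`.
#' @return See `as_params`.
#' @export
map_estimate <- function(posterior, refine = FALSE, as_params = TRUE) {
  if (nrow(posterior$samples) == 0L) stop("posterior has no retained samples")
  i <- which.max(posterior$log_post)
  theta <- posterior$samples[i, ]
  lp <- posterior$log_post[i]
  if (refine) {
    target <- .make_target(posterior$train, posterior$variant,
                           posterior$prior, posterior$amplitude)
    eps <- 1e-8 * (posterior$prior[, "upper"] - posterior$prior[, "lower"])
    opt <- optim(pmin(pmax(theta, posterior$prior[, "lower"] + eps),
                      posterior$prior[, "upper"] - eps),
                 function(th) -target(th), method = "L-BFGS-B",
                 lower = posterior$prior[, "lower"] + eps,
                 upper = posterior$prior[, "upper"] - eps)
    if (-opt$value >= lp) {
      theta <- stats::setNames(opt$par, names(theta))
      lp <- -opt$value
    }
  }
  out <- list(theta = theta,
              params = .theta_to_params(theta, posterior$variant,
                                        posterior$train,
                                        posterior$amplitude),
              log_post = lp)
  if (as_params) out$params else out
}

#' Marginal posterior density of one parameter
#'
#' Gaussian kernel density estimate (Scott's bandwidth) of the retained
#' samples on a uniform grid spanning the prior support, truncated at the
#' bounds and renormalized to integrate to one (trapezoid rule).
#'
#' @param posterior An `stp_posterior`.
#' @param parameter Parameter name (one of the posterior's free
#'   parameters).
#' @param n_grid Number of grid points.
#' @return An object of class `stp_marginal`: list with `parameter`,
#'   `grid`, `density`.
#' @export
marginal_density <- function(posterior, parameter, n_grid = 256) {
  if (!parameter %in% colnames(posterior$samples))
    stop("unknown parameter '", parameter, "'")
  if (n_grid < 2L) stop("n_grid must be >= 2")
  x <- posterior$samples[, parameter]
  lo <- posterior$prior[parameter, "lower"]
  hi <- posterior$prior[parameter, "upper"]
  grid <- seq(lo, hi, length.out = n_grid)
  bw <- tryCatch(stats::bw.nrd(x), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) bw <- (hi - lo) / n_grid
  dens <- vapply(grid, function(g) mean(dnorm(g, mean = x, sd = bw)),
                 numeric(1))
  h <- grid[2] - grid[1]
  z <- sum((dens[-1] + dens[-n_grid]) / 2) * h
  structure(list(parameter = parameter, grid = grid, density = dens / z),
            class = "stp_marginal")
}
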