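# Root-mean-square error between data and model with the amplitude profiled
# by ordinary (unweighted) least squares, matching the unscaled objective.
.sa_rmse <- function(theta, target_env) {
  m <- switch(as.character(target_env$code),
    "0" = .psp_recursion(target_env$times, theta[1], theta[2], theta[3],
                         theta[4], 0L),
    "1" = .psp_recursion(target_env$times, theta[1], theta[2], theta[3],
                         theta[3], 1L),
    "2" = .psp_recursion(target_env$times, theta[1], 1.0, theta[2], 0.0, 2L))
  w <- target_env$w
  den <- sum(m * m * w)
  if (den == 0) return(Inf)
  A <- sum(target_env$d * m * w) / den
  sqrt(mean((target_env$d - A * m)^2 * target_env$obj_w))
}

#' Simulated-annealing least-squares fit (traditional baseline)
#'
#' Minimizes the (by default non-variance-scaled) RMSE between the data and
#' the model, constrained to the prior box, restarting the annealer from
#' independent random points and keeping the best-of-restarts solution.
#' The amplitude factor is profiled by least squares at every objective
#' evaluation. This is the point-estimate baseline against which the
#' posterior approach is compared; on short trains it typically attains
#' near-perfect fits with widely dispersed time-constant estimates across
#' restarts (a degenerate error landscape).
#'
#' @inheritParams log_likelihood
#' @param n_restarts Number of annealing restarts (best kept). Default 200.
#' @param seed Optional RNG seed.
#' @param n_steps Annealing steps per restart.
#' @param t0 Initial temperature.
#' @param cooling Geometric cooling factor per step.
#' @param scaled If `TRUE`, scale the squared errors by the per-pulse
#'   variances (weighted objective); default `FALSE`.
#' @param polish If `TRUE` (default), finish each restart with a
#'   Nelder-Mead local refinement of its best point (clipped to the box).
#' @return List with `params` ([stp_params], amplitude filled in), `rmse`,
#'   `r_squared`, and `restarts` (data frame of per-restart optima).
#' @export
sa_fit <- function(train, variant = "etm", n_restarts = 200, seed = NULL,
                   n_steps = 500, t0 = 1, cooling = 0.95, scaled = FALSE,
                   polish = TRUE) {
  variant <- match.arg(variant, .stp_variants)
  if (!inherits(train, "psp_train")) stop("train must be a psp_train")
  if (length(train$amplitudes) == 0L) stop("empty data")
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  prior <- prior_box(variant)
  lower <- prior[, "lower"]
  upper <- prior[, "upper"]
  # keep time constants strictly positive
  lower[rownames(prior) %in% c("D", "F")] <- 1e-6
  env <- list(times = train$times, d = train$amplitudes,
              w = 1 / train$sigmas^2,
              obj_w = if (scaled) 1 / train$sigmas^2 else
                rep(1, length(train$amplitudes)),
              code = .variant_code(variant))
  k <- length(lower)
  scale <- 0.1 * (upper - lower)
  best <- NULL
  trace <- matrix(NA_real_, nrow = n_restarts, ncol = k + 1L)
  for (r in seq_len(n_restarts)) {
    x <- runif(k, lower, upper)
    fx <- .sa_rmse(x, env)
    bx <- x
    bfx <- fx
    temp <- t0
    for (s in seq_len(n_steps)) {
      prop <- x + rnorm(k, 0, scale)
      prop <- pmin(pmax(prop, lower), upper)
      fp <- .sa_rmse(prop, env)
      if (fp < fx || runif(1L) < exp((fx - fp) / temp)) {
        x <- prop
        fx <- fp
        if (fx < bfx) {
          bx <- x
          bfx <- fx
        }
      }
      temp <- temp * cooling
    }
    if (polish) {
      obj <- function(th) .sa_rmse(pmin(pmax(th, lower), upper), env)
      o <- optim(bx, obj, method = "Nelder-Mead",
                 control = list(maxit = 800, reltol = 1e-12))
      bx <- pmin(pmax(o$par, lower), upper)
      bfx <- .sa_rmse(bx, env)
    }
    trace[r, ] <- c(bx, bfx)
    if (is.null(best) || bfx < best$rmse)
      best <- list(theta = stats::setNames(bx, rownames(prior)), rmse = bfx)
  }
  colnames(trace) <- c(rownames(prior), "rmse")
  params <- .theta_to_params(best$theta, variant, train)
  list(params = params, rmse = best$rmse,
       r_squared = r_squared(train, params, variant),
       restarts = as.data.frame(trace))
}

#' Coefficient of determination of a model fit
#'
#' `R^2 = 1 - SSE / SStot` of the model predictions against the per-pulse
#' mean amplitudes.
#'
#' @inheritParams log_likelihood
#' @return The R-squared value.
#' @export
r_squared <- function(train, params, variant = "etm") {
  if (length(train$amplitudes) < 2L) stop("R^2 requires at least two pulses")
  pred <- simulate_psps(params, train$times, variant)
  sst <- sum((train$amplitudes - mean(train$amplitudes))^2)
  if (sst == 0) stop("R^2 undefined: data have zero total variance")
  1 - sum((train$amplitudes - pred)^2) / sst
}
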