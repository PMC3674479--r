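# Independent oracles used across tests. These deliberately avoid the
# package's production code paths.

# Dense forward-Euler integration of the continuous-time resource/release
# ODEs, with the spike jumps applied using the pre-spike values.
euler_psps <- function(params, times, dt = 1e-5) {
  R <- 1
  u <- params$U
  amps <- numeric(length(times))
  t <- times[1]
  for (i in seq_along(times)) {
    amps[i] <- params$A * R * u
    dR <- u * R                      # depletion uses pre-jump u and R
    du <- params$f * (1 - u)         # facilitation jump
    R <- R - dR
    u <- u + du
    if (i < length(times)) {
      n_steps <- round((times[i + 1] - t) / dt)
      for (s in seq_len(n_steps)) {
        R <- R + dt * (1 - R) / params$D
        u <- u + dt * (params$U - u) / params$F
      }
      t <- times[i + 1]
    }
  }
  amps
}

# fixed-point of the between-spike recursion by brute-force iteration
iterate_steady_state <- function(params, rate, n = 10000) {
  dt <- 1 / rate
  R <- 1
  u <- params$U
  for (i in seq_len(n)) {
    R_new <- 1 - (1 - R * (1 - u)) * exp(-dt / params$D)
    u_new <- params$U +
      (u + params$f * (1 - u) - params$U) * exp(-dt / params$F)
    R <- R_new
    u <- u_new
  }
  c(R_inf = R, u_inf = u)
}

# reduced MCMC schedule used where a full run would be wasteful
quick_post <- function(train, ...) {
  infer_stp(train, n_iter = 1500, n_burn = 500, n_chains = 2, ...)
}

# fabricated cohort fit (posterior sample clouds with known structure),
# for classifier tests that do not need real MCMC
fake_cohort_fit <- function(centers, n_each, n_samp = 400, sd = 0.02,
                            seed = 1) {
  set.seed(seed)
  posteriors <- list()
  labels <- character(0)
  pars <- c("D", "F", "U", "f")
  for (cl in names(centers)) {
    for (i in seq_len(n_each)) {
      m <- matrix(rnorm(n_samp * 4, mean = rep(centers[[cl]], each = n_samp),
                        sd = sd), ncol = 4,
                  dimnames = list(NULL, pars))
      m[, c("U", "f")] <- pmin(pmax(m[, c("U", "f")], 0), 1)
      m[, c("D", "F")] <- pmin(pmax(m[, c("D", "F")], 0), 2)
      posteriors[[length(posteriors) + 1L]] <- list(samples = m)
      labels <- c(labels, cl)
    }
  }
  maps <- t(vapply(posteriors, function(p) colMeans(p$samples), numeric(4)))
  colnames(maps) <- pars
  structure(list(posteriors = posteriors, maps = maps, labels = labels,
                 ids = sprintf("c%02d", seq_along(labels))),
            class = "stp_cohort_fit")
}
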