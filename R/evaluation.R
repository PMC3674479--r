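#' Sample estimation error of a posterior against known parameters
#'
#' Mean over retained samples of the summed squared relative errors of the
#' free dynamics parameters:
#' `E = mean( sum_i ((theta_i - theta*_i) / theta*_i)^2 )`. In a
#' probabilistic reading this also penalizes posterior spread: tighter,
#' better-centered posteriors give smaller E.
#'
#' @param posterior An `stp_posterior`.
#' @param true_params The generating [stp_params] (strictly positive for
#'   the free parameters), or a named vector.
#' @param normalize `"truth"` (default; divide by the true values) or
#'   `"prior"` (divide by the prior widths, usable when a true parameter
#'   is zero).
#' @return Nonnegative scalar error E.
#' @export
estimation_error <- function(posterior, true_params,
                             normalize = c("truth", "prior")) {
  normalize <- match.arg(normalize)
  true_params <- as_stp_params(true_params)
  free <- colnames(posterior$samples)
  free <- setdiff(free, "A")
  truth <- unlist(true_params[free])
  denom <- if (normalize == "truth") truth else
    posterior$prior[free, "upper"] - posterior$prior[free, "lower"]
  if (any(denom == 0))
    stop("zero true parameter: use normalize = \"prior\"")
  S <- posterior$samples[, free, drop = FALSE]
  rel <- sweep(sweep(S, 2L, truth, "-"), 2L, denom, "/")
  mean(rowSums(rel^2))
}

#' Compare stimulation protocols by mean sample estimation error
#'
#' For every protocol, simulates noisy data under each parameter regime,
#' runs posterior inference, computes the sample estimation error E against
#' the generating parameters, and averages over regimes and seed
#' replicates. Smaller E means tighter recovery of the true parameters.
#'
#' @param protocols Named list of spike-time vectors (or functions of a
#'   seed returning spike times, for stochastic protocols such as Poisson
#'   trains regenerated per replicate).
#' @param presets Data frame of regimes as from [regime_presets()].
#' @param cv Sweep noise level used to generate the data.
#' @param seeds Integer vector of replicate seeds.
#' @param n_iter,n_burn,n_chains MCMC schedule passed to [infer_stp()].
#' @param data `"expected"` (default) evaluates protocols on the model's
#'   expected amplitudes with the assumed noise level, so E measures pure
#'   posterior spread; `"sample"` draws a noise realization per replicate.
#' @param n_sweeps Sweeps per pulse passed to [make_noisy_train()].
#' @return Data frame (protocol, mean_E, sd_E, n_runs) sorted by mean_E,
#'   with the per-run errors attached as attribute `"runs"`.
#' @export
compare_protocols <- function(protocols, presets = regime_presets(),
                              cv = 0.5, seeds = 1:3, n_iter = 2000,
                              n_burn = 500, n_chains = 2,
                              data = c("expected", "sample"),
                              n_sweeps = 30) {
  data <- match.arg(data)
  if (!length(protocols)) stop("need at least one protocol")
  if (is.null(names(protocols)))
    names(protocols) <- paste0("protocol_", seq_along(protocols))
  runs <- list()
  for (pn in names(protocols)) {
    for (i in seq_len(nrow(presets))) {
      p <- stp_params(presets$D[i], presets$F[i], presets$U[i],
                      presets$f[i])
      for (s in seeds) {
        res <- tryCatch({
          prot <- protocols[[pn]]
          times <- if (is.function(prot)) prot(s) else prot
          tr <- make_noisy_train(p, times, cv = cv, n_sweeps = n_sweeps,
                                 seed = s * 1000L + i, data = data)
          post <- infer_stp(tr, variant = "etm", n_iter = n_iter,
                            n_burn = n_burn, n_chains = n_chains,
                            seed = s * 1000L + i)
          estimation_error(post, p)
        }, error = function(e) {
          stop("inference failed for protocol '", pn, "': ",
               conditionMessage(e))
        })
        runs[[length(runs) + 1L]] <- data.frame(
          protocol = pn, preset = presets$name[i], seed = s, E = res)
      }
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$protocol), function(g) {
    data.frame(protocol = g$protocol[1], mean_E = mean(g$E),
               sd_E = sd(g$E), n_runs = nrow(g))
  }))
  agg <- agg[order(agg$mean_E), ]
  rownames(agg) <- NULL
  attr(agg, "runs") <- runs
  agg
}

#' Akaike information criterion from the MAP log-posterior
#'
#' `AIC = 2k - log P(theta_MAP | d)`, with k the number of free model
#' parameters and the log-posterior evaluated at the MAP on amplitude-
#' normalized data. With flat priors the posterior and likelihood differ
#' by a constant for fixed data, so rankings are unchanged; a conventional
#' `2k - 2 logL` variant is available.
#'
#' @param log_post_at_map Log-posterior (or log-likelihood) at the MAP.
#' @param k Number of free parameters (2, 3 or 4).
#' @param conventional If `TRUE`, use `2k - 2 * log_post_at_map`.
#' @return The AIC value (smaller is better).
#' @export
aic <- function(log_post_at_map, k, conventional = FALSE) {
  if (!k %in% 2:4) stop("k must be 2, 3 or 4")
  if (conventional) 2 * k - 2 * log_post_at_map else 2 * k - log_post_at_map
}

#' Akaike weights and pairwise evidence ratios
#'
#' Weights `w_m` proportional to `exp(-delta_m / 2)` with
#' `delta_m = AIC_m - min(AIC)`; the evidence ratio of model a over model b
#' is `w_a / w_b`.
#'
#' @param aics Named numeric vector of AIC values (>= 2 models).
#' @return List with `weights` (sums to 1) and `ratios` (matrix of
#'   pairwise weight ratios, rows over columns).
#' @export
evidence_ratios <- function(aics) {
  if (length(aics) < 2L) stop("need at least two models")
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ratios <- outer(w, w, "/")
  list(weights = w, ratios = ratios)
}

#' Rank model variants for a PSP train by AIC
#'
#' Runs full posterior inference for each variant, normalizes the data by
#' the MAP amplitude, evaluates the MAP log-posterior on the normalized
#' data, and ranks variants by the AIC with Akaike weights.
#'
#' @inheritParams infer_stp
#' @param variants Character vector of at least two model variants.
#' @param conventional Passed to [aic()].
#' @return Data frame (variant, k, log_post_map, aic, weight) sorted by
#'   AIC, with the per-variant posteriors attached as attribute
#'   `"posteriors"`.
#' @export
select_model <- function(train, variants = c("tm", "tm_fac", "etm"),
                         n_iter = 10000, n_burn = 2500, n_chains = 3,
                         seed = NULL, conventional = FALSE) {
  if (length(variants) < 2L) stop("need at least two variants to compare")
  rows <- list()
  posteriors <- list()
  for (v in variants) {
    v <- match.arg(v, .stp_variants)
    post <- infer_stp(train, variant = v, n_iter = n_iter, n_burn = n_burn,
                      n_chains = n_chains, seed = seed)
    map <- map_estimate(post, as_params = FALSE)
    A <- map$params$A
    # normalize data and noise by the MAP amplitude, then re-evaluate
    norm_train <- psp_train(train$times, train$amplitudes / A,
                            sigmas = train$sigmas / A)
    lp <- log_posterior(norm_train, map$params, variant = v,
                        prior = prior_box(v))
    k <- length(.free_params(v))
    rows[[v]] <- data.frame(variant = v, k = k, log_post_map = lp,
                            aic = aic(lp, k, conventional))
    posteriors[[v]] <- post
  }
  tab <- do.call(rbind, rows)
  ev <- evidence_ratios(stats::setNames(tab$aic, tab$variant))
  tab$weight <- ev$weights[tab$variant]
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  attr(tab, "posteriors") <- posteriors
  tab
}
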