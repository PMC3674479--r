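#' PSP amplitude train with per-pulse noise
#'
#' Container for the observed data of one connection: the eliciting spike
#' times, the per-pulse mean PSP amplitudes and their noise standard
#' deviations. Mean amplitudes may be negative (recording noise around small
#' responses); sigmas must be strictly positive.
#'
#' @param times Strictly increasing spike times (s).
#' @param amplitudes Per-pulse mean PSP amplitudes (mV).
#' @param sigmas Per-pulse noise standard deviations (mV). Exactly one of
#'   `sigmas` and `cv` must be given.
#' @param cv Per-pulse coefficient of variation from which sigmas are derived
#'   as `cv * abs(amplitudes)`; recycled to the train length.
#' @return An object of class `psp_train`.
#' @export
psp_train <- function(times, amplitudes, sigmas = NULL, cv = NULL) {
  times <- .check_times(times)
  if (length(amplitudes) != length(times))
    stop("amplitudes and spike times must have equal length")
  if (is.null(sigmas) == is.null(cv))
    stop("give exactly one of 'sigmas' or 'cv'")
  if (!is.null(cv)) {
    if (any(cv <= 0)) stop("cv must be positive")
    sigmas <- rep_len(cv, length(times)) * abs(amplitudes)
  }
  if (length(sigmas) != length(times))
    stop("sigmas must have one entry per pulse")
  if (any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop("sigmas must be finite and positive")
  structure(list(times = times, amplitudes = as.numeric(amplitudes),
                 sigmas = as.numeric(sigmas)),
            class = "psp_train")
}

#' @export
print.psp_train <- function(x, ...) {
  cat(sprintf("PSP train: %d pulses over %.3f s\n", length(x$times),
              diff(range(x$times))))
  cat("  amplitudes (mV):", paste(signif(x$amplitudes, 3), collapse = " "),
      "\n")
  invisible(x)
}

#' Simulated-regime presets
#'
#' The five canonical parameter regimes spanning strong depression to strong
#' facilitation, with the Every Pulse Ratio each produces for five pulses at
#' 30 Hz.
#'
#' @return A data frame with columns `name`, `D`, `F`, `U`, `f` and
#'   `reference_epr`.
#' @examples
#' regime_presets()
#' @export
regime_presets <- function() {
  data.frame(
    name = c("strong_depression", "depression", "facilitation_depression",
             "facilitation", "strong_facilitation"),
    D = c(1.70, 0.50, 0.20, 0.05, 0.02),
    F = c(0.02, 0.05, 0.20, 0.50, 1.70),
    U = c(0.7, 0.5, 0.25, 0.15, 0.1),
    f = c(0.05, 0.05, 0.3, 0.15, 0.11),
    reference_epr = c(0.45, 0.64, 0.94, 1.26, 1.43),
    stringsAsFactors = FALSE
  )
}

#' Look up one regime preset as an stp_params object
#'
#' @param name Preset name; one of `"strong_depression"`, `"depression"`,
#'   `"facilitation_depression"`, `"facilitation"`,
#'   `"strong_facilitation"`.
#' @param A Amplitude scale (mV).
#' @return An [stp_params] object.
#' @export
preset_params <- function(name, A = 1) {
  tab <- regime_presets()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown preset '", name, "'; see regime_presets()")
  stp_params(D = tab$D[i], F = tab$F[i], U = tab$U[i], f = tab$f[i], A = A)
}

#' Generate a noisy PSP train from the model
#'
#' Emulates the acquisition of STP data: `n_sweeps` i.i.d. Gaussian sweep
#' amplitudes per pulse with mean equal to the noiseless model amplitude
#' and standard deviation `cv * mean`, averaged across sweeps. Negative
#' draws are retained, mirroring apparently negative EPSPs recorded under
#' noise. Defaults follow a typical acquisition protocol: 30 sweeps
#' averaged per pulse with a sweep-to-sweep coefficient of variation of
#' 0.5.
#'
#' The per-pulse noise level stored in the train is, with
#' `sigma = "se"` (default), the standard error of the across-sweep mean,
#' `cv * amplitude / sqrt(n_sweeps)` — the statistically coherent noise
#' scale for mean amplitudes — or, with `sigma = "sd"`, the raw
#' sweep-level standard deviation `cv * amplitude`. Both are computed from
#' the known generative noise level, as an experimenter would estimate
#' them from the sweep histogram.
#'
#' With `data = "expected"` no noise is drawn: the per-pulse means are the
#' noiseless model amplitudes and only the assumed noise level is
#' attached. This is the design-stage idealization used when scoring
#' stimulation protocols, where the estimation error should measure
#' posterior spread rather than a particular noise realization.
#'
#' @inheritParams simulate_psps
#' @param cv Sweep-to-sweep coefficient of variation, > 0.
#' @param n_sweeps Number of sweeps averaged per pulse, >= 1.
#' @param seed Optional RNG seed.
#' @param sigma Noise level reported to inference: `"se"` (standard error
#'   of the mean, default) or `"sd"` (sweep-level standard deviation).
#' @param data `"sample"` (default; draw sweeps) or `"expected"`
#'   (noiseless means, assumed noise level only).
#' @return A [psp_train]; the noiseless amplitudes, sweep matrix (sample
#'   mode) and true parameters are attached as attributes `"noiseless"`,
#'   `"sweeps"` and `"true_params"`.
#' @examples
#' make_noisy_train(preset_params("depression"), periodic_train(30, 5),
#'                  cv = 0.5, seed = 1)
#' @export
make_noisy_train <- function(params, times, cv = 0.5, n_sweeps = 30,
                             seed = NULL, variant = "etm",
                             sigma = c("se", "sd"),
                             data = c("sample", "expected")) {
  sigma <- match.arg(sigma)
  data <- match.arg(data)
  if (!is.finite(cv) || cv <= 0) stop("cv must be positive")
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mu <- simulate_psps(params, times, variant)
  n <- length(mu)
  sig <- if (sigma == "se") cv * mu / sqrt(n_sweeps) else cv * mu
  if (data == "expected") {
    out <- psp_train(times, mu, sigmas = sig)
  } else {
    sweeps <- matrix(rnorm(n * n_sweeps, mean = rep(mu, n_sweeps),
                           sd = rep(cv * mu, n_sweeps)),
                     nrow = n)
    out <- psp_train(times, rowMeans(sweeps), sigmas = sig)
    attr(out, "sweeps") <- sweeps
  }
  attr(out, "noiseless") <- mu
  attr(out, "true_params") <- as_stp_params(params)
  out
}

#' Generate a PSP train from a stochastic vesicle-release model
#'
#' Simulates `n_sites` independent release sites per sweep: at spike n each
#' available site releases with probability u_n (the eTM release
#' probability), releasing sites become unavailable, and unavailable sites
#' recover independently between spikes with probability
#' 1 - exp(-dt / D). The sweep amplitude is the release count times
#' `quantal_amp`. For many sites/sweeps the mean train converges to
#' `n_sites * quantal_amp * R_n u_n`.
#'
#' @inheritParams make_noisy_train
#' @param n_sites Number of release sites, >= 1.
#' @param quantal_amp Quantal amplitude per released vesicle (mV).
#' @return A [psp_train] with across-sweep means and empirical standard
#'   errors; the sweep matrix is attached as attribute `"sweeps"`.
#' @export
make_stochastic_release_train <- function(params, times, n_sites,
                                          quantal_amp = 0.1, n_sweeps = 100,
                                          seed = NULL, variant = "etm") {
  params <- as_stp_params(params)
  times <- .check_times(times)
  variant <- match.arg(variant, .stp_variants)
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  if (quantal_amp <= 0) stop("quantal_amp must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (variant == "tm_fac") params$f <- params$U
  n <- length(times)
  # deterministic u_n sequence (facilitation acts on u as in the mean model)
  u <- numeric(n)
  u[1] <- params$U
  if (n > 1L) for (i in seq_len(n - 1L)) {
    dt <- times[i + 1L] - times[i]
    u[i + 1L] <- if (variant == "tm") params$U else
      params$U + (u[i] + params$f * (1 - u[i]) - params$U) *
        exp(-dt / params$F)
  }
  sweeps <- matrix(0, nrow = n, ncol = n_sweeps)
  for (s in seq_len(n_sweeps)) {
    avail <- n_sites
    for (i in seq_len(n)) {
      rel <- rbinom(1L, avail, u[i])
      sweeps[i, s] <- rel * quantal_amp
      avail <- avail - rel
      if (i < n) {
        p_rec <- 1 - exp(-(times[i + 1L] - times[i]) / params$D)
        avail <- avail + rbinom(1L, n_sites - avail, p_rec)
      }
    }
  }
  means <- rowMeans(sweeps)
  se <- apply(sweeps, 1L, sd) / sqrt(n_sweeps)
  se[se <= 0] <- quantal_amp / n_sweeps  # guard fully deterministic pulses
  out <- psp_train(times, means, sigmas = se)
  attr(out, "sweeps") <- sweeps
  attr(out, "true_params") <- params
  out
}

#' Labeled connection record
#'
#' @param id Connection identifier (string).
#' @param label Synapse class; one of `"PC-PC"`, `"PC-BC"`, `"PC-MC"`,
#'   `"unknown"`.
#' @param train A [psp_train].
#' @param n_sweeps Number of sweeps behind the means.
#' @return An object of class `connection_record`.
#' @export
connection_record <- function(id, label, train, n_sweeps = 1L) {
  label <- match.arg(label, c("PC-PC", "PC-BC", "PC-MC", "unknown"))
  if (!inherits(train, "psp_train")) stop("train must be a psp_train")
  structure(list(id = as.character(id), label = label, train = train,
                 n_sweeps = as.integer(n_sweeps)),
            class = "connection_record")
}

#' Default class-conditional parameter specifications for synthetic cohorts
#'
#' Emulates the three neocortical excitatory connection classes: depressing
#' pyramidal-to-pyramidal (PC-PC, medium U) and pyramidal-to-basket-cell
#' (PC-BC, high U) connections, and facilitating
#' pyramidal-to-Martinotti-cell (PC-MC, low U, D and f) connections. Class
#' means for U follow the reported experimental values (PC-BC 0.72, PC-PC
#' 0.53); remaining parameters follow the matching simulated regimes.
#'
#' @return Named list of per-class specs, each with elements `mean` (named
#'   parameter vector), `sd` (named vector of truncation-Gaussian spreads)
#'   and `cv` (sweep noise level).
#' @export
default_class_specs <- function() {
  list(
    "PC-PC" = list(mean = c(D = 0.50, F = 0.05, U = 0.53, f = 0.05),
                   sd   = c(D = 0.10, F = 0.02, U = 0.05, f = 0.02),
                   cv = 0.5),
    "PC-BC" = list(mean = c(D = 0.70, F = 0.05, U = 0.72, f = 0.05),
                   sd   = c(D = 0.10, F = 0.02, U = 0.04, f = 0.02),
                   cv = 0.5),
    "PC-MC" = list(mean = c(D = 0.05, F = 0.50, U = 0.15, f = 0.15),
                   sd   = c(D = 0.02, F = 0.10, U = 0.04, f = 0.04),
                   cv = 0.5)
  )
}

# one truncated-Gaussian draw per parameter, inside the prior box
.draw_params <- function(mean, sd) {
  box <- rbind(D = c(1e-3, 2), F = c(1e-3, 2), U = c(0.01, 1),
               f = c(0, 1))
  out <- numeric(4)
  names(out) <- rownames(box)
  for (p in rownames(box)) {
    repeat {
      x <- rnorm(1L, mean[[p]], sd[[p]])
      if (x >= box[p, 1] && x <= box[p, 2]) break
    }
    out[p] <- x
  }
  stp_params(out[["D"]], out[["F"]], out[["U"]], out[["f"]])
}

#' Generate a labeled synthetic cohort of connections
#'
#' Draws per-connection parameters from class-conditional truncated
#' Gaussians and generates noisy PSP trains under a common stimulation
#' protocol.
#'
#' @param n_per_class Named integer vector (names = class labels) or a
#'   single count applied to every class in `class_specs`.
#' @param class_specs Per-class parameter distributions; see
#'   [default_class_specs()].
#' @param times Stimulation protocol (spike times, s).
#' @param n_sweeps Sweeps averaged per pulse.
#' @param seed Optional RNG seed.
#' @return List of [connection_record]s; each record's train carries its
#'   true parameters as an attribute.
#' @examples
#' coh <- make_cohort(c("PC-PC" = 3, "PC-MC" = 3), seed = 1)
#' sapply(coh, function(r) r$label)
#' @export
make_cohort <- function(n_per_class, class_specs = default_class_specs(),
                        times = periodic_train(30, 5), n_sweeps = 30,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(n_per_class, length(class_specs)),
                                   names(class_specs))
  unknown <- setdiff(names(n_per_class), names(class_specs))
  if (length(unknown))
    stop("no class spec for label(s): ", paste(unknown, collapse = ", "))
  records <- list()
  for (lab in names(n_per_class)) {
    spec <- class_specs[[lab]]
    n <- n_per_class[[lab]]
    if (n < 0) stop("n_per_class must be >= 0")
    for (i in seq_len(n)) {
      p <- .draw_params(spec$mean, spec$sd)
      tr <- make_noisy_train(p, times, cv = spec$cv, n_sweeps = n_sweeps)
      records[[length(records) + 1L]] <- connection_record(
        id = sprintf("%s_%02d", lab, i), label = lab, train = tr,
        n_sweeps = n_sweeps)
    }
  }
  records
}
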