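#' Short-term plasticity parameter set
#'
#' Bundles the four dynamics parameters of the extended Tsodyks-Markram (eTM)
#' model together with an optional amplitude factor. `D` and `F` are the
#' depression and facilitation recovery time constants in seconds, `U` is the
#' baseline release probability, `f` the per-spike facilitation increment, and
#' `A` an amplitude scale in millivolts that subsumes the number of release
#' sites, receptor properties and cable filtering.
#'
#' @param D Depression time constant (s), > 0.
#' @param F Facilitation time constant (s), > 0.
#' @param U Baseline release probability in \[0, 1\].
#' @param f Facilitation increment in \[0, 1\].
#' @param A Amplitude scale (mV), > 0. Default 1.
#' @return An object of class `stp_params` (a named list).
#' @examples
#' stp_params(D = 0.5, F = 0.05, U = 0.5, f = 0.05)
#' @export
stp_params <- function(D, F, U, f, A = 1) {
  vals <- c(D = D, F = F, U = U, f = f, A = A)
  if (any(!is.finite(vals)))
    stop("all STP parameters must be finite numbers")
  # time constants below 1e-9 s would overflow exp(-dt/tau); reject outright
  if (D < 1e-9 || F < 1e-9)
    stop("time constants D and F must be positive (>= 1e-9 s)")
  if (U < 0 || U > 1) stop("U must lie in [0, 1]")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (A <= 0) stop("amplitude A must be positive")
  structure(list(D = D, F = F, U = U, f = f, A = A), class = "stp_params")
}

#' @export
print.stp_params <- function(x, ...) {
  cat(sprintf(
    "STP parameters: D = %.4g s, F = %.4g s, U = %.4g, f = %.4g, A = %.4g\n",
    x$D, x$F, x$U, x$f, x$A))
  invisible(x)
}

# coerce named vectors / lists to stp_params, filling defaults
as_stp_params <- function(x) {
  if (inherits(x, "stp_params")) return(x)
  x <- as.list(x)
  if (is.null(x$A)) x$A <- 1
  if (is.null(x$F)) x$F <- 1
  if (is.null(x$f)) x$f <- 0
  stp_params(D = x$D, F = x$F, U = x$U, f = x$f, A = x$A)
}

.check_times <- function(times) {
  if (length(times) < 1L || any(!is.finite(times)))
    stop("spike train must be a nonempty vector of finite times")
  if (times[1] < 0) stop("spike times must be >= 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  as.numeric(times)
}

#' Simulate postsynaptic potential amplitudes
#'
#' Computes the deterministic PSP amplitude train of the Tsodyks-Markram model
#' family for a given spike train, using the exact between-spike recursion.
#' The resource fraction starts at R = 1 and the release probability at
#' u = U; spike n releases with the pre-jump u, so PSP_1 = A U and the
#' facilitation jump f(1 - u) takes effect from the following spike.
#'
#' @param params An [stp_params] object (or coercible named list/vector).
#' @param times Numeric vector of strictly increasing spike times (s).
#' @param variant Model variant: `"etm"` (4 free parameters), `"tm_fac"`
#'   (facilitation tied, f = U) or `"tm"` (depression only, u fixed at U).
#' @return Numeric vector of PSP amplitudes (mV), one per spike.
#' @examples
#' p <- stp_params(D = 1.7, F = 0.02, U = 0.7, f = 0.05)
#' simulate_psps(p, periodic_train(30, 5))
#' @export
simulate_psps <- function(params, times, variant = "etm") {
  params <- as_stp_params(params)
  times <- .check_times(times)
  variant <- match.arg(variant, .stp_variants)
  if (variant == "tm_fac") params$f <- params$U
  params$A * .psp_recursion(times, params$D, params$F, params$U, params$f,
                            .variant_code(variant))
}

#' Steady-state resource and release probability under periodic stimulation
#'
#' Closed-form fixed point of the between-spike recursion for prolonged
#' periodic stimulation at a given rate.
#'
#' @inheritParams simulate_psps
#' @param rate Stimulation frequency (Hz), > 0.
#' @return Named numeric vector `c(R_inf, u_inf)`, both in \[0, 1\].
#' @examples
#' steady_state(stp_params(0.5, 0.05, 0.5, 0.05), rate = 30)
#' @export
steady_state <- function(params, rate, variant = "etm") {
  params <- as_stp_params(params)
  variant <- match.arg(variant, .stp_variants)
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive")
  if (variant == "tm_fac") params$f <- params$U
  eF <- exp(-1 / (rate * params$F))
  u_inf <- if (variant == "tm") params$U else
    (params$U + (params$f - params$U) * eF) / (1 - (1 - params$f) * eF)
  eD <- exp(-1 / (rate * params$D))
  R_inf <- (1 - eD) / (1 - (1 - u_inf) * eD)
  c(R_inf = R_inf, u_inf = u_inf)
}

#' Every Pulse Ratio
#'
#' Mean of successive amplitude ratios across a train,
#' EPR = mean(PSP\[i+1\] / PSP\[i\]). Values below 1 indicate net depression,
#' above 1 net facilitation. Unlike the paired-pulse ratio it uses all
#' pulses of the train.
#'
#' @param amplitudes Numeric vector of at least two nonzero PSP amplitudes.
#' @return The EPR (dimensionless scalar).
#' @examples
#' epr(c(1, 0.5, 0.25))  # 0.5
#' @export
epr <- function(amplitudes) {
  n <- length(amplitudes)
  if (n < 2L) stop("EPR requires at least two pulses")
  if (any(amplitudes == 0)) stop("EPR undefined for zero amplitudes")
  mean(amplitudes[-1] / amplitudes[-n])
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first PSP amplitude, PPR = PSP_2 / PSP_1.
#'
#' @param amplitudes Numeric vector of at least two PSP amplitudes with a
#'   nonzero first element.
#' @return The PPR (dimensionless scalar).
#' @examples
#' ppr(c(2, 1, 5))  # 0.5
#' @export
ppr <- function(amplitudes) {
  if (length(amplitudes) < 2L) stop("PPR requires at least two pulses")
  if (amplitudes[1] == 0) stop("PPR undefined when the first amplitude is 0")
  amplitudes[2] / amplitudes[1]
}
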