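#' Periodic stimulation train
#'
#' @param rate Stimulation frequency (Hz), > 0.
#' @param n_pulses Number of pulses, >= 1.
#' @param start Time of the first pulse (s).
#' @return Numeric vector of spike times (s).
#' @examples
#' periodic_train(30, 5)
#' @export
periodic_train <- function(rate, n_pulses, start = 0) {
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive")
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  start + seq_len(n_pulses) / rate - 1 / rate
}

#' Periodic train followed by recovery pulses
#'
#' A periodic segment followed by recovery pulses whose delays after the last
#' periodic pulse are log-uniformly (geometrically) spaced from one
#' inter-spike interval (1/rate) up to `recovery_span`, probing recovery at
#' multiple timescales. The total first-to-last duration is
#' (n_pulses - 1)/rate + recovery_span; with 8 pulses at 30 Hz and a 4 s
#' span this is approximately 4.23 s.
#'
#' @inheritParams periodic_train
#' @param n_recovery Number of recovery pulses, >= 1.
#' @param recovery_span Delay of the last recovery pulse after the periodic
#'   segment (s); must exceed 1/rate.
#' @return Numeric vector of spike times (s).
#' @examples
#' tr <- recovery_train(30, 8, 9, 4)
#' diff(range(tr))  # ~4.233 s
#' @export
recovery_train <- function(rate, n_pulses, n_recovery, recovery_span,
                           start = 0) {
  if (n_recovery < 1) stop("n_recovery must be >= 1")
  if (!is.finite(recovery_span) || recovery_span <= 1 / rate)
    stop("recovery_span must exceed one inter-spike interval (1/rate)")
  base <- periodic_train(rate, n_pulses, start)
  delays <- if (n_recovery == 1L) recovery_span else
    exp(seq(log(1 / rate), log(recovery_span), length.out = n_recovery))
  c(base, base[length(base)] + delays)
}

#' Parse a compact protocol specification string
#'
#' Formats: `"periodic:RATE:N"`, `"recovery:RATE:N:N_REC:SPAN"` and
#' `"poisson:RATE:N"` (rates in Hz, span in seconds). Used by the
#' command-line tools.
#'
#' @param spec Specification string.
#' @param seed RNG seed for stochastic protocols.
#' @return Numeric vector of spike times (s).
#' @examples
#' parse_protocol_spec("periodic:30:5")
#' @export
parse_protocol_spec <- function(spec, seed = NULL) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  num <- suppressWarnings(as.numeric(parts[-1]))
  if (any(is.na(num))) stop("malformed protocol spec '", spec, "'")
  switch(kind,
    periodic = {
      if (length(num) != 2) stop("periodic spec needs RATE:N")
      periodic_train(num[1], num[2])
    },
    recovery = {
      if (length(num) != 4) stop("recovery spec needs RATE:N:N_REC:SPAN")
      recovery_train(num[1], num[2], num[3], num[4])
    },
    poisson = {
      if (length(num) != 2) stop("poisson spec needs RATE:N")
      poisson_train(num[1], num[2], seed = seed)
    },
    stop("unknown protocol kind '", kind, "'")
  )
}

#' Poisson stimulation train
#'
#' Generates `n_pulses` events with i.i.d. exponential inter-spike intervals
#' of mean 1/rate, optionally offset by an absolute refractory period. The
#' train is defined by event count (not duration) so that protocols can be
#' compared at matched numbers of spikes.
#'
#' @inheritParams periodic_train
#' @param seed Optional RNG seed for reproducibility.
#' @param refractory Absolute refractory period added to every interval (s).
#' @return Numeric vector of spike times (s).
#' @examples
#' poisson_train(30, 10, seed = 1)
#' @export
poisson_train <- function(rate, n_pulses, seed = NULL, refractory = 0,
                          start = 0) {
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive")
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  if (refractory < 0) stop("refractory must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  isi <- rexp(n_pulses - 1L, rate) + refractory
  start + cumsum(c(0, isi))
}
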