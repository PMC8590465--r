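#' Construct a recorded or synthetic trace
#'
#' A trace is a regularly sampled signal: a voltage-clamp current (pA) or an
#' extracellular field potential (mV).
#'
#' @param samples numeric vector of finite sample values.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param signal_kind `"voltage_clamp_current"` or `"field_potential"`.
#' @return an object of class `synscale_trace`.
#' @export
trace <- function(samples,
                  sampling_rate = 10000,
                  signal_kind = c("voltage_clamp_current", "field_potential")) {
  signal_kind <- match.arg(signal_kind)
  samples <- as.numeric(samples)
  if (length(samples) == 0 || any(!is.finite(samples)))
    stopf("trace samples must be non-empty and finite")
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stopf("sampling_rate must be > 0")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 signal_kind = signal_kind),
            class = "synscale_trace")
}

#' @export
print.synscale_trace <- function(x, ...) {
  cat(sprintf("Trace: %s, %d samples at %.6g Hz (%.3f s)\n",
              x$signal_kind, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Trace synthesis model for miniature synaptic currents
#'
#' Kinetic and noise parameters used by [synth_trace()]. Events are rendered
#' with a difference-of-exponentials kernel normalised to unit peak; the
#' default 0.5 ms rise / 5 ms decay are typical AMPAR-mEPSC kinetics.
#' `polarity = -1` renders inward currents as negative deflections.
#'
#' @param sampling_rate Hz. Default 10000.
#' @param tau_rise_ms rise time constant, ms (> 0).
#' @param tau_decay_ms decay time constant, ms (> tau_rise_ms).
#' @param noise_sd Gaussian baseline noise SD in pA (>= 0).
#' @param event_rate mean event rate in Hz used by [simulate_mepsc_trace()].
#' @param polarity -1 for inward (negative) currents, +1 for outward.
#' @return an object of class `trace_model`.
#' @export
trace_model <- function(sampling_rate = 10000, tau_rise_ms = 0.5,
                        tau_decay_ms = 5, noise_sd = 2, event_rate = 1,
                        polarity = -1) {
  if (!is_number(tau_rise_ms) || tau_rise_ms <= 0) stopf("tau_rise_ms must be > 0")
  if (!is_number(tau_decay_ms) || tau_decay_ms <= tau_rise_ms)
    stopf("tau_decay_ms must exceed tau_rise_ms")
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stopf("sampling_rate must be > 0")
  if (!is_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!polarity %in% c(-1, 1)) stopf("polarity must be -1 or +1")
  structure(list(sampling_rate = sampling_rate, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, noise_sd = noise_sd,
                 event_rate = event_rate, polarity = polarity),
            class = "trace_model")
}

#' Unit-peak biexponential event kernel
#'
#' `k(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / k_max` for `t >= 0`,
#' zero before the event. The peak value is exactly 1 at
#' `t_peak = tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param t_s times in seconds relative to event onset.
#' @param tau_rise_ms,tau_decay_ms kernel time constants in ms.
#' @return kernel values, unit peak.
#' @export
event_kernel <- function(t_s, tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms / 1000
  td <- tau_decay_ms / 1000
  tp <- tr * td / (td - tr) * log(td / tr)
  kmax <- exp(-tp / td) - exp(-tp / tr)
  k <- ifelse(t_s < 0, 0, (exp(-t_s / td) - exp(-t_s / tr)) / kmax)
  k
}

#' Synthesise a voltage-clamp current trace from known events
#'
#' Each event contributes `amplitude * kernel(t - onset)` with the model's
#' polarity; contributions superpose linearly on Gaussian baseline noise.
#'
#' @param events data frame with columns `t_s` (onset, seconds, in
#'   `[0, duration)`) and `amp_pA` (positive magnitude).
#' @param model a [trace_model()].
#' @param duration_s trace duration in seconds.
#' @param seed optional integer seed for the noise.
#' @return a [trace()] of kind `voltage_clamp_current`.
#' @export
synth_trace <- function(events, model, duration_s, seed = NULL) {
  stopifnot(inherits(model, "trace_model"))
  if (!is_number(duration_s) || duration_s <= 0) stopf("duration_s must be > 0")
  if (is.null(events)) events <- data.frame(t_s = numeric(0), amp_pA = numeric(0))
  stopifnot(is.data.frame(events), all(c("t_s", "amp_pA") %in% names(events)))
  if (nrow(events) > 0 &&
      (any(events$t_s < 0) || any(events$t_s >= duration_s)))
    stopf("event times must lie in [0, duration)")
  n <- round(duration_s * model$sampling_rate)
  x <- with_seed_if(seed, {
    if (model$noise_sd > 0) rnorm(n, 0, model$noise_sd) else numeric(n)
  })
  if (nrow(events) > 0) {
    # render each event over a finite support of ~12 decay constants
    support <- ceiling(12 * model$tau_decay_ms / 1000 * model$sampling_rate)
    tk <- seq_len(support) / model$sampling_rate
    k <- event_kernel(tk, model$tau_rise_ms, model$tau_decay_ms)
    for (i in seq_len(nrow(events))) {
      i0 <- floor(events$t_s[i] * model$sampling_rate) + 1L
      idx <- i0 + seq_len(support) - 1L
      keep <- idx <= n
      x[idx[keep]] <- x[idx[keep]] +
        model$polarity * events$amp_pA[i] * k[keep]
    }
  }
  trace(x, model$sampling_rate, "voltage_clamp_current")
}

#' Simulate an mEPSC recording with ground truth
#'
#' Event onsets follow a Poisson process at `model$event_rate`; amplitudes
#' are drawn from an [amplitude_model()] (truncated at its detection floor).
#'
#' @param amp_model an [amplitude_model()].
#' @param model a [trace_model()].
#' @param duration_s duration in seconds.
#' @param seed optional integer seed.
#' @return list with `trace` (a [trace()]) and `truth` (data frame `t_s`,
#'   `amp_pA`).
#' @export
simulate_mepsc_trace <- function(amp_model, model, duration_s, seed = NULL) {
  stopifnot(inherits(amp_model, "amplitude_model"),
            inherits(model, "trace_model"))
  truth <- with_seed_if(seed, {
    n_ev <- rpois(1, model$event_rate * duration_s)
    t_s <- sort(runif(n_ev, 0, duration_s))
    amp <- if (n_ev > 0)
      draw_truncated(amp_model, 1, n_ev, 1000L) else numeric(0)
    data.frame(t_s = t_s, amp_pA = amp)
  })
  tr <- synth_trace(truth, model, duration_s, seed = child_seed(seed, 1) %||% NULL)
  list(trace = tr, truth = truth)
}
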