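#' Stimulus protocol
#'
#' A train of square current pulses injected into the excitatory (sensory)
#' cell. Each stimulus strength WE in \code{WE_grid} is delivered as
#' \code{n_pulses} pulses of \code{pulse_ms} duration at interstimulus
#' interval \code{isi_ms} (defaults: 2-ms pulses at 1-s intervals over
#' WE = 10, 15, ..., 60).
#'
#' @param WE_grid numeric vector of stimulus strengths (>= 0); may be empty
#'   for a stimulus-free protocol.
#' @param pulse_ms pulse duration (ms, > 0).
#' @param isi_ms interstimulus interval (ms, > pulse_ms).
#' @param n_pulses pulses delivered per strength (>= 1).
#' @return A list of class \code{"stimulus_protocol"}.
#' @export
stimulus_protocol <- function(WE_grid = seq(10, 60, by = 5), pulse_ms = 2,
                              isi_ms = 1000, n_pulses = 10) {
  if (length(WE_grid) > 0 && (any(!is.finite(WE_grid)) || any(WE_grid < 0))) {
    stop("stimulus_protocol: WE_grid values must be finite and >= 0")
  }
  if (!is.finite(pulse_ms) || pulse_ms <= 0) {
    stop("stimulus_protocol: pulse_ms must be > 0")
  }
  if (!is.finite(isi_ms) || isi_ms <= pulse_ms) {
    stop("stimulus_protocol: isi_ms must exceed pulse_ms")
  }
  if (n_pulses < 1 || n_pulses != round(n_pulses)) {
    stop("stimulus_protocol: n_pulses must be a positive integer")
  }
  structure(list(WE_grid = as.numeric(WE_grid), pulse_ms = pulse_ms,
                 isi_ms = isi_ms, n_pulses = as.integer(n_pulses)),
            class = "stimulus_protocol")
}

# Low-level wrapper around the compiled integrator. Raises on divergence.
run_segment <- function(cfg, state, t0, duration_ms, dt, pulse_onsets = numeric(0),
                        pulse_ms = 2, WE = 0, record_stride = 0L,
                        threshold_mV = 0, refractory_ms = 5, v_guard = 500) {
  res <- .sim_network_cpp(strip_classes(cfg), unname(state), t0, duration_ms,
                          dt, pulse_onsets, pulse_ms, WE,
                          as.integer(record_stride), threshold_mV,
                          refractory_ms, v_guard)
  if (res$diverged_at >= 0) {
    stop(sprintf("integration failure: |v| exceeded %g mV (or became non-finite) at t = %.4f ms",
                 v_guard, res$diverged_at))
  }
  names(res$final_state) <- STATE_NAMES
  res
}

#' Simulate the circuit and record a trace
#'
#' Integrates the full network with the classical fourth-order Runge-Kutta
#' scheme at fixed step \code{dt}: first \code{settle_ms} of stimulus-free
#' equilibration from the canonical initial state, then the stimulus
#' protocol. The protocol must contain at most one stimulus strength (use
#' [response_curve()] for sweeps over a WE grid).
#'
#' @param cfg a [network_config()].
#' @param protocol a [stimulus_protocol()] with 0 or 1 entries in
#'   \code{WE_grid}.
#' @param dt integration step (ms); must be <= 0.05 for stability.
#' @param settle_ms stimulus-free equilibration time (ms, >= 0). The default
#'   (30000 ms) is three time constants of the slowest state variable, the
#'   retrograde gain gI (rho = 10 s), so the protocol starts from the
#'   circuit's converged quiescent equilibrium.
#' @param record_dt sampling interval of the returned trace (ms); must be a
#'   multiple of \code{dt}.
#' @return A data frame of class \code{"mcell_trace"} with column
#'   \code{t_ms} followed by the 16 state variables, and attributes
#'   \code{config}, \code{protocol}, \code{dt}, \code{pulse_onsets},
#'   \code{bounds} (extrema of the bounded state variables over every
#'   integration step, not just recorded samples).
#' @export
#' @examples
#' \donttest{
#' cfg <- mcell_preset("dominant")
#' tr <- simulate_network(cfg, stimulus_protocol(WE_grid = 60, n_pulses = 2),
#'                        settle_ms = 1000)
#' range(tr$vM)
#' }
simulate_network <- function(cfg, protocol = stimulus_protocol(), dt = 0.01,
                             settle_ms = 30000, record_dt = 0.1) {
  stopifnot(inherits(cfg, "network_config"),
            inherits(protocol, "stimulus_protocol"))
  if (!is.finite(dt) || dt <= 0 || dt > 0.05) {
    stop("simulate_network: dt must be in (0, 0.05] ms")
  }
  if (settle_ms < 0) stop("simulate_network: settle_ms must be >= 0")
  stride <- record_dt / dt
  if (abs(stride - round(stride)) > 1e-8 || stride < 1) {
    stop("simulate_network: record_dt must be a positive multiple of dt")
  }
  if (length(protocol$WE_grid) > 1) {
    stop("simulate_network records a single stimulus strength; ",
         "use response_curve() for a WE sweep")
  }

  has_stim <- length(protocol$WE_grid) == 1 && protocol$n_pulses >= 1
  onsets <- if (has_stim) {
    settle_ms + (seq_len(protocol$n_pulses) - 1) * protocol$isi_ms
  } else {
    numeric(0)
  }
  duration <- settle_ms + if (has_stim) protocol$n_pulses * protocol$isi_ms else 0
  if (duration <= 0) stop("simulate_network: nothing to simulate")

  res <- run_segment(cfg, initial_state(cfg), 0, duration, dt,
                     pulse_onsets = onsets, pulse_ms = protocol$pulse_ms,
                     WE = if (has_stim) protocol$WE_grid else 0,
                     record_stride = as.integer(round(stride)))

  out <- as.data.frame(res$trace)
  names(out) <- STATE_NAMES
  out <- cbind(t_ms = res$t, out)
  structure(out,
            class = c("mcell_trace", "data.frame"),
            config = cfg, protocol = protocol, dt = dt,
            pulse_onsets = onsets, bounds = res$bounds,
            spikes = res$spikes)
}

#' Detect M-cell spikes in a recorded trace
#'
#' Upward crossings of \code{threshold_mV} in the M-cell membrane potential,
#' separated by at least \code{refractory_ms}. Crossing times are linearly
#' interpolated between samples.
#'
#' @param trace an \code{"mcell_trace"} from [simulate_network()], or any
#'   data frame with columns \code{t_ms} and \code{vM}.
#' @param threshold_mV spike threshold (mV), well above subthreshold
#'   dynamics in this parameter regime.
#' @param refractory_ms minimum separation of accepted spikes (ms).
#' @return Numeric vector of strictly increasing spike times (ms).
#' @export
detect_mcell_spikes <- function(trace, threshold_mV = 0, refractory_ms = 5) {
  if (is.null(trace$vM) || is.null(trace$t_ms) || nrow(trace) == 0) {
    stop("detect_mcell_spikes: trace must contain t_ms and vM samples")
  }
  v <- trace$vM
  t <- trace$t_ms
  up <- which(v[-length(v)] < threshold_mV & v[-1] >= threshold_mV)
  if (length(up) == 0) return(numeric(0))
  frac <- (threshold_mV - v[up]) / (v[up + 1] - v[up])
  cand <- t[up] + frac * (t[up + 1] - t[up])
  spikes <- numeric(0)
  last <- -Inf
  for (tc in cand) {
    if (tc - last >= refractory_ms) {
      spikes <- c(spikes, tc)
      last <- tc
    }
  }
  spikes
}

#' Score stimulus pulses for responses
#'
#' A pulse counts as a response when at least one spike falls in the
#' half-open window \[onset, onset + window_ms).
#'
#' @param spikes numeric vector of spike times (ms).
#' @param pulse_onsets strictly increasing pulse onset times (ms).
#' @param window_ms response window length (ms); windows must not overlap.
#' @return Logical vector, one element per pulse.
#' @export
score_responses <- function(spikes, pulse_onsets, window_ms = 50) {
  if (length(pulse_onsets) > 1) {
    if (any(diff(pulse_onsets) <= 0)) {
      stop("score_responses: pulse onsets must be strictly increasing")
    }
    if (any(diff(pulse_onsets) < window_ms)) {
      stop("score_responses: response windows overlap")
    }
  }
  vapply(pulse_onsets, function(on) {
    any(spikes >= on & spikes < on + window_ms)
  }, logical(1))
}
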