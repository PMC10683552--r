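PHARM_CONDITIONS <- c("control", "d1_block", "gaba_block", "gly_block")

#' Apply an in-silico receptor-blockade condition
#'
#' Returns a copy of the configuration with exactly the parameter overrides
#' the condition entails:
#' \describe{
#'   \item{control}{no change.}
#'   \item{d1_block}{D1 antagonism: \code{D1_M = 0}, \code{D1_GL = 0}.}
#'   \item{gaba_block}{GABA-A antagonism: \code{gGA_M = 0},
#'     \code{gGA_GL = 0}, and the glycinergic decay rate set to the
#'     status-specific value (beta = 0.024 dominant-like, 0.0072
#'     subordinate-like), which prolongs glycinergic inhibition of the
#'     M-cell.}
#'   \item{gly_block}{glycine-receptor antagonism: \code{gGL_M = 0}.}
#' }
#'
#' @param cfg a [network_config()]; for \code{gaba_block} its status label
#'   must be dominant or subordinate (or \code{beta_GL} given explicitly).
#' @param condition one of \code{"control"}, \code{"d1_block"},
#'   \code{"gaba_block"}, \code{"gly_block"}.
#' @param beta_GL optional explicit glycinergic decay rate under
#'   \code{gaba_block}, overriding the status-specific default.
#' @return A new [network_config()] with only the condition's overrides
#'   changed.
#' @export
apply_condition <- function(cfg, condition, beta_GL = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.character(condition) || length(condition) != 1 ||
      !condition %in% PHARM_CONDITIONS) {
    stop("apply_condition: unknown condition; must be one of ",
         paste(PHARM_CONDITIONS, collapse = ", "))
  }
  out <- cfg
  if (condition == "d1_block") {
    out$modulation$D1_M <- 0
    out$modulation$D1_GL <- 0
  } else if (condition == "gaba_block") {
    out$connections$gGA_M <- 0
    out$connections$gGA_GL <- 0
    if (is.null(beta_GL)) {
      beta_GL <- switch(cfg$status,
                        dominant = 0.024,
                        subordinate = 0.0072,
                        stop("apply_condition: gaba_block needs a dominant/",
                             "subordinate status label or an explicit beta_GL"))
    }
    out$kinetics$GL$beta <- beta_GL
  } else if (condition == "gly_block") {
    out$connections$gGL_M <- 0
  }
  out
}

#' M-cell response curve over a stimulus-strength grid
#'
#' For each stimulus strength WE in the protocol grid the circuit is started
#' from a freshly settled state (one shared stimulus-free equilibration per
#' configuration, since settling is deterministic and stimulus-independent),
#' driven with \code{n_pulses} pulses, and the fraction of pulses answered by
#' at least one M-cell spike inside the response window is tabulated. The
#' result is the model analogue of a behavioral startle-probability curve.
#'
#' @param cfg a [network_config()].
#' @param condition pharmacology condition applied before simulating (see
#'   [apply_condition()]).
#' @param protocol a [stimulus_protocol()].
#' @param dt integration step (ms, <= 0.05).
#' @param settle_ms stimulus-free equilibration (ms); the default (30 s)
#'   converges the slow retrograde gain gI (time constant 10 s).
#' @param window_ms response window after each pulse onset (ms, half-open);
#'   must not exceed the interstimulus interval. The default (NULL) uses the
#'   full interval, i.e., a pulse counts as a response when the M-cell fires
#'   at least once before the next pulse -- the all-or-none readout that
#'   matches the behavioral scoring, since first-spike latencies of the slow
#'   sensory cell range from ~20 to ~300 ms across the WE grid.
#' @param threshold_mV,refractory_ms spike-detection settings (see
#'   [detect_mcell_spikes()]).
#' @param beta_GL passed to [apply_condition()].
#' @return Data frame of class \code{"response_curve"} with columns
#'   \code{WE}, \code{n_pulses}, \code{n_responses},
#'   \code{response_fraction}; attributes \code{status}, \code{condition},
#'   \code{spike_counts} (per-WE-per-pulse spike counts) and \code{bounds}.
#' @export
response_curve <- function(cfg, condition = "control",
                           protocol = stimulus_protocol(), dt = 0.01,
                           settle_ms = 30000, window_ms = NULL,
                           threshold_mV = 0, refractory_ms = 5,
                           beta_GL = NULL) {
  stopifnot(inherits(cfg, "network_config"),
            inherits(protocol, "stimulus_protocol"))
  if (length(protocol$WE_grid) == 0) {
    stop("response_curve: protocol has an empty WE grid")
  }
  if (is.null(window_ms)) window_ms <- protocol$isi_ms
  if (window_ms > protocol$isi_ms) {
    stop("response_curve: window_ms must not exceed the interstimulus interval")
  }
  if (!is.finite(dt) || dt <= 0 || dt > 0.05) {
    stop("response_curve: dt must be in (0, 0.05] ms")
  }
  ccfg <- apply_condition(cfg, condition, beta_GL = beta_GL)

  settled <- if (settle_ms > 0) {
    run_segment(ccfg, initial_state(ccfg), 0, settle_ms, dt)$final_state
  } else {
    initial_state(ccfg)
  }

  onsets <- (seq_len(protocol$n_pulses) - 1) * protocol$isi_ms
  duration <- protocol$n_pulses * protocol$isi_ms
  bounds <- NULL
  spike_counts <- matrix(0L, nrow = length(protocol$WE_grid),
                         ncol = protocol$n_pulses)
  n_resp <- integer(length(protocol$WE_grid))

  for (i in seq_along(protocol$WE_grid)) {
    we <- protocol$WE_grid[i]
    res <- tryCatch(
      run_segment(ccfg, settled, 0, duration, dt, pulse_onsets = onsets,
                  pulse_ms = protocol$pulse_ms, WE = we,
                  threshold_mV = threshold_mV, refractory_ms = refractory_ms),
      error = function(e) stop("response_curve: WE = ", we, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    responded <- score_responses(res$spikes, onsets, window_ms)
    n_resp[i] <- sum(responded)
    spike_counts[i, ] <- vapply(onsets, function(on) {
      sum(res$spikes >= on & res$spikes < on + window_ms)
    }, integer(1))
    bounds <- if (is.null(bounds)) res$bounds else {
      c(n_min = min(bounds["n_min"], res$bounds["n_min"]),
        n_max = max(bounds["n_max"], res$bounds["n_max"]),
        s_min = min(bounds["s_min"], res$bounds["s_min"]),
        s_max = max(bounds["s_max"], res$bounds["s_max"]),
        ca_min = min(bounds["ca_min"], res$bounds["ca_min"]),
        gI_min = min(bounds["gI_min"], res$bounds["gI_min"]))
    }
  }

  out <- data.frame(WE = protocol$WE_grid,
                    n_pulses = protocol$n_pulses,
                    n_responses = n_resp,
                    response_fraction = n_resp / protocol$n_pulses)
  structure(out,
            class = c("response_curve", "data.frame"),
            status = cfg$status, condition = condition,
            spike_counts = spike_counts, bounds = bounds)
}

#' Compare a receptor-blockade condition against control
#'
#' Runs the control circuit and the blocked circuit on an identical protocol
#' and returns both response curves, the per-WE differences, and the
#' grid-summed difference (blocked minus control, in response-fraction
#' units). A positive summary means the blockade increased M-cell
#' excitability.
#'
#' @inheritParams response_curve
#' @param condition blockade condition; must not be \code{"control"}.
#' @return List with elements \code{control} and \code{blocked} (the two
#'   [response_curve()] results), \code{delta} (data frame with columns
#'   \code{WE}, \code{fraction_control}, \code{fraction_blocked},
#'   \code{delta}), and \code{summary_delta} (sum of per-WE deltas).
#' @export
compare_on_off <- function(cfg, condition, protocol = stimulus_protocol(),
                           dt = 0.01, settle_ms = 30000, window_ms = NULL,
                           threshold_mV = 0, refractory_ms = 5,
                           beta_GL = NULL) {
  if (identical(condition, "control")) {
    stop("compare_on_off: condition must be a blockade, not control")
  }
  on <- response_curve(cfg, "control", protocol, dt, settle_ms, window_ms,
                       threshold_mV, refractory_ms)
  off <- response_curve(cfg, condition, protocol, dt, settle_ms, window_ms,
                        threshold_mV, refractory_ms, beta_GL = beta_GL)
  delta <- data.frame(WE = on$WE,
                      fraction_control = on$response_fraction,
                      fraction_blocked = off$response_fraction,
                      delta = off$response_fraction - on$response_fraction)
  list(control = on, blocked = off, delta = delta,
       summary_delta = sum(delta$delta))
}
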