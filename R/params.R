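#' @useDynLib mcescape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Order of the 16 state variables used throughout the package (R and C++).
STATE_NAMES <- c(
  "vE", "nE", "CaE",
  "vGA", "nGA", "CaGA",
  "vGL", "nGL", "CaGL",
  "vM", "nM", "CaM",
  "sE", "sGA", "sGL",
  "gI"
)

CELL_IDS <- c("E", "GA", "GL", "M")

# Recursively drop S3 classes, yielding plain nested lists (for JSON/Rcpp).
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' Single-cell membrane parameters
#'
#' Parameters of the modified Morris-Lecar membrane model used for every cell
#' in the circuit: a calcium current with instantaneous activation
#' \eqn{m_\infty(v)}, a delayed-rectifier potassium current gated by \eqn{n},
#' a leak current, a calcium-gated potassium current saturating with
#' half-constant \code{k1}, and a slow intracellular calcium balance.
#'
#' Voltages are in mV, time in ms; conductances and currents follow the
#' dimensionless Morris-Lecar convention.
#'
#' @param C membrane capacitance (multiplies dv/dt).
#' @param gK,gL,gCa,gKCa maximal conductances (all >= 0).
#' @param vK,vL,vCa reversal potentials (mV).
#' @param k1 calcium half-saturation of the KCa current.
#' @param v1,v2 midpoint and slope of \eqn{m_\infty}.
#' @param v3,v4 midpoint and slope of \eqn{n_\infty} and \eqn{\tau_n}.
#' @param phi rate scale of the n dynamics.
#' @param eps,mu,kCa calcium-balance constants: d\[Ca\]/dt =
#'   eps * (-mu * ICa - kCa * \[Ca\]).
#' @return A list of class \code{"cell_params"}.
#' @export
cell_params <- function(C = 20, gK = 8, gL = 2, gCa = 4, gKCa = 0.25,
                        vK = -84, vL = -60, vCa = 120, k1 = 10,
                        v1 = -1.2, v2 = 18, v3 = 12, v4 = 17,
                        phi = 0.23, eps = 0.005, mu = 0.19, kCa = 1) {
  p <- list(C = C, gK = gK, gL = gL, gCa = gCa, gKCa = gKCa,
            vK = vK, vL = vL, vCa = vCa, k1 = k1,
            v1 = v1, v2 = v2, v3 = v3, v4 = v4,
            phi = phi, eps = eps, mu = mu, kCa = kCa)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop("cell_params: '", nm, "' must be a single finite number")
    }
  }
  if (any(c(p$gK, p$gL, p$gCa, p$gKCa) < 0)) {
    stop("cell_params: conductances must be >= 0")
  }
  if (p$C <= 0) stop("cell_params: C must be > 0")
  if (p$v2 == 0 || p$v4 == 0) stop("cell_params: v2 and v4 must be nonzero")
  if (p$eps <= 0) stop("cell_params: eps must be > 0")
  if (p$kCa <= 0) stop("cell_params: kCa must be > 0")
  structure(p, class = "cell_params")
}

#' Synaptic gating kinetics
#'
#' First-order kinetics of the fraction of activated postsynaptic channel,
#' ds/dt = alpha * s_inf(v_pre) * (1 - s) - beta * s, with presynaptic
#' activation s_inf(v) = 1 / (1 + exp(-(v - theta_s) / sigma_s)).
#'
#' @param alpha channel activation rate (> 0).
#' @param beta channel decay rate (> 0).
#' @param theta_s,sigma_s midpoint (mV) and steepness (mV, nonzero) of s_inf.
#' @return A list of class \code{"synapse_kinetics"}.
#' @export
synapse_kinetics <- function(alpha, beta, theta_s = 0, sigma_s = 4) {
  if (!is.finite(alpha) || alpha <= 0) stop("synapse_kinetics: alpha must be > 0")
  if (!is.finite(beta) || beta <= 0) stop("synapse_kinetics: beta must be > 0")
  if (!is.finite(sigma_s) || sigma_s == 0) stop("synapse_kinetics: sigma_s must be nonzero")
  if (!is.finite(theta_s)) stop("synapse_kinetics: theta_s must be finite")
  structure(list(alpha = alpha, beta = beta,
                 theta_s = theta_s, sigma_s = sigma_s),
            class = "synapse_kinetics")
}

#' Synaptic connection parameters of the four-cell circuit
#'
#' Maximal conductances and reversal potentials for every pathway in the
#' network: E -> GA, E -> GL, GA -> GL, E -> M, GA -> M, GL -> M, and the
#' constant drive from the contralateral M-cell (whose synaptic variable is
#' held at \code{sM_const}).
#'
#' @param gE_GA,vE_GA excitatory input to the GABAergic cell.
#' @param gE_GL,vE_GL excitatory input to the glycinergic cell.
#' @param gGA_GL,vGA_GL GABAergic input to the glycinergic cell.
#' @param gE_M,vE_M excitatory input to the M-cell.
#' @param gGA_M,gGL_M,vG_M inhibitory (GABAergic, glycinergic) inputs to the
#'   M-cell; both share the inhibitory reversal potential \code{vG_M}.
#' @param gM_M,vM_M contralateral M-cell input.
#' @param sM_const fixed synaptic variable of the contralateral M-cell,
#'   in \[0, 1\].
#' @return A list of class \code{"connection_params"}.
#' @export
connection_params <- function(gE_GA = 0.3, vE_GA = 40,
                              gE_GL = 0.3, vE_GL = 40,
                              gGA_GL = 0.2, vGA_GL = -50,
                              gE_M = 0.24, vE_M = 40,
                              gGA_M = 0.4, gGL_M = 0.2, vG_M = -50,
                              gM_M = 0.1, vM_M = -50,
                              sM_const = 0.029) {
  p <- list(gE_GA = gE_GA, vE_GA = vE_GA, gE_GL = gE_GL, vE_GL = vE_GL,
            gGA_GL = gGA_GL, vGA_GL = vGA_GL, gE_M = gE_M, vE_M = vE_M,
            gGA_M = gGA_M, gGL_M = gGL_M, vG_M = vG_M,
            gM_M = gM_M, vM_M = vM_M, sM_const = sM_const)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop("connection_params: '", nm, "' must be a single finite number")
    }
  }
  gs <- c(p$gE_GA, p$gE_GL, p$gGA_GL, p$gE_M, p$gGA_M, p$gGL_M, p$gM_M)
  if (any(gs < 0)) stop("connection_params: conductances must be >= 0")
  if (p$sM_const < 0 || p$sM_const > 1) {
    stop("connection_params: sM_const must lie in [0, 1]")
  }
  structure(p, class = "connection_params")
}

#' Neuromodulation parameters
#'
#' Dimensionless D1-receptor gains on the excitatory input to the M-cell
#' (\code{D1_M}) and to the glycinergic cell (\code{D1_GL}), and the slow
#' retrograde calcium-dependent gain gI on all presynaptic inputs to the
#' M-cell: dgI/dt = (gI_max / (\[Ca\] + k2) - gI) / rho by default (see
#' \code{gI_law} in [network_config()]).
#'
#' @param D1_M,D1_GL D1 gains (>= 0). \code{D1_GL} is 0.65 in the
#'   dominant-like preset and 0.25 in the subordinate-like preset.
#' @param gI_max maximal retrograde gain numerator.
#' @param k2 calcium half-constant of the gI law (> 0).
#' @param rho time constant of gI (ms, > 0).
#' @return A list of class \code{"modulation_params"}.
#' @export
modulation_params <- function(D1_M = 0.015, D1_GL = 0.65,
                              gI_max = 15, k2 = 10, rho = 10000) {
  p <- list(D1_M = D1_M, D1_GL = D1_GL, gI_max = gI_max, k2 = k2, rho = rho)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop("modulation_params: '", nm, "' must be a single finite number")
    }
  }
  if (p$D1_M < 0 || p$D1_GL < 0) stop("modulation_params: D1 gains must be >= 0")
  if (p$k2 <= 0) stop("modulation_params: k2 must be > 0")
  if (p$rho <= 0) stop("modulation_params: rho must be > 0")
  structure(p, class = "modulation_params")
}

#' Full network configuration
#'
#' Assembles the complete parameterization of the four-cell escape circuit:
#' per-cell membrane parameters, per-presynaptic-cell synapse kinetics,
#' connection table, neuromodulation, and baseline external drives.
#'
#' @param status one of \code{"dominant"}, \code{"subordinate"},
#'   \code{"custom"}; a label recording which social-status preset the
#'   configuration came from.
#' @param cells named list with elements E, GA, GL, M of [cell_params()].
#' @param kinetics named list with elements E, GA, GL of
#'   [synapse_kinetics()].
#' @param connections a [connection_params()].
#' @param modulation a [modulation_params()].
#' @param drives named numeric vector of baseline external inputs
#'   (E, GA, GL, M).
#' @param gI_law which reading of the retrograde-gain equation to integrate:
#'   \code{"saturating"} (default), dgI/dt = (gI_max/(\[Ca\]+k2) - gI)/rho, or
#'   \code{"linear_decay"}, dgI/dt = gI_max/(\[Ca\]+k2) - gI/rho.
#' @return A list of class \code{"network_config"}.
#' @seealso [mcell_preset()] for the shipped dominant/subordinate presets.
#' @export
network_config <- function(status = "custom",
                           cells = NULL, kinetics = NULL,
                           connections = connection_params(),
                           modulation = modulation_params(),
                           drives = c(E = 43.9, GA = 36, GL = 36, M = 19.5),
                           gI_law = c("saturating", "linear_decay")) {
  status <- match.arg(status, c("dominant", "subordinate", "custom"))
  gI_law <- match.arg(gI_law)
  if (is.null(cells)) {
    cells <- list(
      E  = cell_params(),
      GA = cell_params(),
      GL = cell_params(),
      M  = cell_params(C = 1, gKCa = 0.3, kCa = 0.9)
    )
  }
  if (is.null(kinetics)) {
    kinetics <- list(
      E  = synapse_kinetics(alpha = 15, beta = 0.1),
      GA = synapse_kinetics(alpha = 4, beta = 0.08),
      GL = synapse_kinetics(alpha = 8, beta = 0.08)
    )
  }
  stopifnot(identical(sort(names(cells)), sort(CELL_IDS)),
            identical(sort(names(kinetics)), sort(c("E", "GA", "GL"))))
  for (cc in cells) {
    if (!inherits(cc, "cell_params")) stop("network_config: cells must be cell_params")
  }
  for (kk in kinetics) {
    if (!inherits(kk, "synapse_kinetics")) {
      stop("network_config: kinetics must be synapse_kinetics")
    }
  }
  if (!inherits(connections, "connection_params")) {
    stop("network_config: connections must be connection_params")
  }
  if (!inherits(modulation, "modulation_params")) {
    stop("network_config: modulation must be modulation_params")
  }
  drives <- drives[CELL_IDS]
  if (any(is.na(drives)) || any(!is.finite(drives))) {
    stop("network_config: drives must be finite and named E, GA, GL, M")
  }
  structure(list(status = status, cells = cells[CELL_IDS],
                 kinetics = kinetics[c("E", "GA", "GL")],
                 connections = connections, modulation = modulation,
                 drives = drives, gI_law = gI_law),
            class = "network_config")
}

#' Social-status presets of the escape circuit
#'
#' The two parameterizations encoding stable social status: the dominant-like
#' circuit has a strong dopaminergic gain on the glycinergic cell
#' (D1_GL = 0.65) and a weak GABA->glycinergic connection (gGA_GL = 0.2);
#' the subordinate-like circuit has D1_GL = 0.25 and gGA_GL = 0.4. All other
#' parameters are shared.
#'
#' @param status \code{"dominant"} or \code{"subordinate"}.
#' @return A [network_config()].
#' @export
#' @examples
#' cfg <- mcell_preset("dominant")
#' cfg$modulation$D1_GL
mcell_preset <- function(status = c("dominant", "subordinate")) {
  status <- match.arg(status)
  if (status == "dominant") {
    network_config(status = "dominant",
                   connections = connection_params(gGA_GL = 0.2),
                   modulation = modulation_params(D1_GL = 0.65))
  } else {
    network_config(status = "subordinate",
                   connections = connection_params(gGA_GL = 0.4),
                   modulation = modulation_params(D1_GL = 0.25))
  }
}

#' Canonical initial state of the network
#'
#' Every state variable starts at its own conditional steady state: each cell
#' at its leak reversal potential with the potassium gate at the
#' voltage-clamped steady state, zero intracellular calcium, silent synapses,
#' and the retrograde gain at its zero-calcium fixed point gI_max / k2.
#' Simulations equilibrate from here during the stimulus-free settling
#' period; starting gI on its attractor matters because its time constant
#' (rho = 10 s) is far longer than the settling period.
#'
#' @param cfg a [network_config()].
#' @return Named numeric vector of the 16 state variables.
#' @export
initial_state <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  st <- stats::setNames(numeric(length(STATE_NAMES)), STATE_NAMES)
  for (cc in CELL_IDS) {
    p <- cfg$cells[[cc]]
    st[paste0("v", cc)] <- p$vL
    st[paste0("n", cc)] <- 0.5 * (1 + tanh((p$vL - p$v3) / p$v4))
    st[paste0("Ca", cc)] <- 0
  }
  st["gI"] <- cfg$modulation$gI_max / cfg$modulation$k2
  st
}

# Validate a full state vector against the dynamical invariants.
validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != length(STATE_NAMES)) {
    stop("state must be a numeric vector of length ", length(STATE_NAMES))
  }
  if (is.null(names(state))) names(state) <- STATE_NAMES
  if (any(!is.finite(state))) stop("state contains non-finite values")
  n <- state[grep("^n", names(state))]
  s <- state[grep("^s", names(state))]
  ca <- state[grep("^Ca", names(state))]
  if (any(n < 0 | n > 1)) stop("gating variables n must lie in [0, 1]")
  if (any(s < 0 | s > 1)) stop("synaptic variables s must lie in [0, 1]")
  if (any(ca < 0)) stop("calcium concentrations must be >= 0")
  if (state["gI"] < 0) stop("retrograde gain gI must be >= 0")
  invisible(state)
}
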