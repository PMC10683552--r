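#' Steady-state gating functions
#'
#' Voltage dependence of the instantaneous calcium activation
#' \eqn{m_\infty}, the potassium-gate steady state \eqn{n_\infty} and time
#' scale \eqn{\tau_n}, and the presynaptic synaptic activation
#' \eqn{s_\infty}:
#' \deqn{m_\infty(v) = 0.5 (1 + \tanh((v - v_1)/v_2))}
#' \deqn{n_\infty(v) = 0.5 (1 + \tanh((v - v_3)/v_4))}
#' \deqn{\tau_n(v) = 1 / \cosh((v - v_3)/(2 v_4))}
#' \deqn{s_\infty(v) = 1 / (1 + \exp(-(v - \theta_s)/\sigma_s))}
#'
#' @param v membrane potential (mV); may be a vector.
#' @param cell a [cell_params()].
#' @param kin a [synapse_kinetics()].
#' @return List with elements \code{m_inf}, \code{n_inf}, \code{tau_n},
#'   \code{s_inf}, each the length of \code{v}.
#' @export
#' @examples
#' gating_functions(-1.2, cell_params(), synapse_kinetics(15, 0.1))$m_inf # 0.5
gating_functions <- function(v, cell = cell_params(),
                             kin = synapse_kinetics(15, 0.1)) {
  if (any(!is.finite(v))) stop("gating_functions: v must be finite")
  stopifnot(inherits(cell, "cell_params"), inherits(kin, "synapse_kinetics"))
  list(
    m_inf = 0.5 * (1 + tanh((v - cell$v1) / cell$v2)),
    n_inf = 0.5 * (1 + tanh((v - cell$v3) / cell$v4)),
    tau_n = 1 / cosh((v - cell$v3) / (2 * cell$v4)),
    s_inf = 1 / (1 + exp(-(v - kin$theta_s) / kin$sigma_s))
  )
}

#' Ionic membrane currents of one cell
#'
#' The four intrinsic currents of the modified Morris-Lecar membrane:
#' IK = gK n (v - vK), ICa = gCa m_inf(v) (v - vCa),
#' IKCa = gKCa \[Ca\]/(\[Ca\] + k1) (v - vK), IL = gL (v - vL).
#'
#' @param v membrane potential (mV).
#' @param n potassium gating fraction in \[0, 1\].
#' @param Ca intracellular calcium concentration (>= 0).
#' @param cell a [cell_params()].
#' @return List with elements \code{IK}, \code{ICa}, \code{IKCa}, \code{IL}.
#' @export
ionic_currents <- function(v, n, Ca, cell = cell_params()) {
  stopifnot(inherits(cell, "cell_params"))
  if (any(!is.finite(c(v, n, Ca)))) stop("ionic_currents: non-finite state")
  if (any(Ca < 0)) stop("ionic_currents: Ca must be >= 0")
  if (any(n < 0 | n > 1)) stop("ionic_currents: n must lie in [0, 1]")
  m_inf <- 0.5 * (1 + tanh((v - cell$v1) / cell$v2))
  list(
    IK   = cell$gK * n * (v - cell$vK),
    ICa  = cell$gCa * m_inf * (v - cell$vCa),
    IKCa = cell$gKCa * (Ca / (Ca + cell$k1)) * (v - cell$vK),
    IL   = cell$gL * (v - cell$vL)
  )
}

#' Per-cell synaptic currents
#'
#' The synaptic input to each cell, given the current network state. The
#' excitatory cell receives none; the GABAergic cell receives the excitatory
#' input; the glycinergic cell receives the excitatory input scaled by its D1
#' gain (1 + D1_GL) plus the GABAergic input; the M-cell receives all three
#' plus a constant contralateral M-cell drive, every term multiplied by the
#' retrograde gain gI and the excitatory term additionally by (1 + D1_M):
#' \deqn{I_{syn,M} = g_{E \to M} g_I (1 + D1_M)(v_M - v_{E \to M}) s_E +
#'   g_I (g_{GA \to M} s_{GA} + g_{GL \to M} s_{GL})(v_M - v_{G \to M}) +
#'   g_{M \to M} g_I (v_M - v_{M \to M}) s_M}
#'
#' @param state named numeric state vector (see [initial_state()]).
#' @param cfg a [network_config()].
#' @return Named numeric vector of synaptic currents for E, GA, GL, M.
#' @export
synaptic_currents <- function(state, cfg) {
  stopifnot(inherits(cfg, "network_config"))
  if (is.null(names(state))) names(state) <- STATE_NAMES
  cn <- cfg$connections
  md <- cfg$modulation
  sE <- state[["sE"]]; sGA <- state[["sGA"]]; sGL <- state[["sGL"]]
  gI <- state[["gI"]]
  c(
    E = 0,
    GA = cn$gE_GA * (state[["vGA"]] - cn$vE_GA) * sE,
    GL = cn$gE_GL * (1 + md$D1_GL) * (state[["vGL"]] - cn$vE_GL) * sE +
      cn$gGA_GL * (state[["vGL"]] - cn$vGA_GL) * sGA,
    M = cn$gE_M * gI * (1 + md$D1_M) * (state[["vM"]] - cn$vE_M) * sE +
      gI * (cn$gGA_M * sGA + cn$gGL_M * sGL) * (state[["vM"]] - cn$vG_M) +
      cn$gM_M * gI * (state[["vM"]] - cn$vM_M) * cn$sM_const
  )
}

#' Time derivatives of the full network state
#'
#' Right-hand side of the circuit's ODE system. Each cell obeys the current
#' balance C dv/dt = -ICa - IK - IL - IKCa - Isyn + Iapp(t), the potassium
#' gate dn/dt = phi (n_inf(v) - n) / tau_n(v), and the calcium balance
#' d\[Ca\]/dt = eps (-mu ICa - kCa \[Ca\]). Each presynaptic cell drives its
#' synaptic variable ds/dt = alpha s_inf(v)(1 - s) - beta s, and the M-cell's
#' retrograde gain follows the configured gI law. The applied current is the
#' cell's baseline drive; the excitatory cell additionally receives
#' \code{stim} (the stimulus strength WE times the unit square pulse
#' indicator at time t).
#'
#' @param state named numeric state vector of length 16.
#' @param cfg a [network_config()].
#' @param t time (ms); the dynamics are autonomous given \code{stim}, so
#'   \code{t} only labels the evaluation.
#' @param stim instantaneous extra applied current to the excitatory cell
#'   (WE during a stimulus pulse, 0 otherwise); must be >= 0.
#' @return Named numeric vector of d(state)/dt.
#' @export
derivatives <- function(state, cfg, t = 0, stim = 0) {
  stopifnot(inherits(cfg, "network_config"))
  if (is.null(names(state))) names(state) <- STATE_NAMES
  if (any(!is.finite(state))) stop("derivatives: non-finite state")
  if (!is.finite(stim) || stim < 0) stop("derivatives: stim must be finite and >= 0")

  isyn <- synaptic_currents(state, cfg)
  d <- stats::setNames(numeric(length(STATE_NAMES)), STATE_NAMES)

  for (cc in CELL_IDS) {
    p <- cfg$cells[[cc]]
    v <- state[[paste0("v", cc)]]
    n <- state[[paste0("n", cc)]]
    Ca <- state[[paste0("Ca", cc)]]
    g <- gating_functions(v, p, cfg$kinetics$E)
    ic <- ionic_currents(v, n, Ca, p)
    iapp <- cfg$drives[[cc]] + if (cc == "E") stim else 0
    d[paste0("v", cc)] <-
      (-ic$ICa - ic$IK - ic$IL - ic$IKCa - isyn[[cc]] + iapp) / p$C
    d[paste0("n", cc)] <- p$phi * (g$n_inf - n) / g$tau_n
    d[paste0("Ca", cc)] <- p$eps * (-p$mu * ic$ICa - p$kCa * Ca)
  }

  for (cc in c("E", "GA", "GL")) {
    kin <- cfg$kinetics[[cc]]
    v <- state[[paste0("v", cc)]]
    s <- state[[paste0("s", cc)]]
    s_inf <- 1 / (1 + exp(-(v - kin$theta_s) / kin$sigma_s))
    d[paste0("s", cc)] <- kin$alpha * s_inf * (1 - s) - kin$beta * s
  }

  md <- cfg$modulation
  CaM <- state[["CaM"]]
  gI <- state[["gI"]]
  d["gI"] <- if (cfg$gI_law == "saturating") {
    (md$gI_max / (CaM + md$k2) - gI) / md$rho
  } else {
    md$gI_max / (CaM + md$k2) - gI / md$rho
  }
  d
}

#' One classical fourth-order Runge-Kutta step
#'
#' Advances any ODE system dy/dt = f(y, t) by one fixed step of the classical
#' four-stage Runge-Kutta scheme. This is the reference integrator used in
#' tests; long network simulations use the compiled equivalent inside
#' [simulate_network()].
#'
#' @param f derivative function taking \code{(y, t)} and returning dy/dt.
#' @param y current state (numeric vector).
#' @param t current time.
#' @param dt step size (> 0).
#' @return The state at \code{t + dt}.
#' @export
#' @examples
#' rk4_step(function(y, t) -y, 1, 0, 0.1) # ~ exp(-0.1)
rk4_step <- function(f, y, t, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("rk4_step: dt must be a single positive number")
  }
  k1 <- f(y, t)
  k2 <- f(y + dt / 2 * k1, t + dt / 2)
  k3 <- f(y + dt / 2 * k2, t + dt / 2)
  k4 <- f(y + dt * k3, t + dt)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Derivative closure for stepping the network with rk4_step() in R.
# stim_fn(t) must return the instantaneous extra drive to the E cell.
network_deriv_fn <- function(cfg, stim_fn = function(t) 0) {
  function(y, t) derivatives(y, cfg, t, stim_fn(t))
}
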