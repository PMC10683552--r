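# Independent oracles, deliberately written as literal scalar transcriptions
# (separate code path from the package implementation).

# Literal transcription of the circuit equations: one explicit block per
# cell, no loops, no shared helpers with the package.
oracle_derivs <- function(state, cfg, stim = 0) {
  vE <- state[["vE"]]; nE <- state[["nE"]]; CaE <- state[["CaE"]]
  vGA <- state[["vGA"]]; nGA <- state[["nGA"]]; CaGA <- state[["CaGA"]]
  vGL <- state[["vGL"]]; nGL <- state[["nGL"]]; CaGL <- state[["CaGL"]]
  vM <- state[["vM"]]; nM <- state[["nM"]]; CaM <- state[["CaM"]]
  sE <- state[["sE"]]; sGA <- state[["sGA"]]; sGL <- state[["sGL"]]
  gI <- state[["gI"]]

  pE <- cfg$cells$E; pGA <- cfg$cells$GA; pGL <- cfg$cells$GL; pM <- cfg$cells$M
  cn <- cfg$connections; md <- cfg$modulation

  # --- excitatory cell ---
  mE <- 0.5 * (1 + tanh((vE - pE$v1) / pE$v2))
  ICaE <- pE$gCa * mE * (vE - pE$vCa)
  IKE <- pE$gK * nE * (vE - pE$vK)
  IKCaE <- pE$gKCa * (CaE / (CaE + pE$k1)) * (vE - pE$vK)
  ILE <- pE$gL * (vE - pE$vL)
  dvE <- (-ICaE - IKE - ILE - IKCaE - 0 + cfg$drives[["E"]] + stim) / pE$C
  dnE <- pE$phi * (0.5 * (1 + tanh((vE - pE$v3) / pE$v4)) - nE) *
    cosh((vE - pE$v3) / (2 * pE$v4))
  dCaE <- pE$eps * (-pE$mu * ICaE - pE$kCa * CaE)

  # --- GABAergic cell ---
  mGA <- 0.5 * (1 + tanh((vGA - pGA$v1) / pGA$v2))
  ICaGA <- pGA$gCa * mGA * (vGA - pGA$vCa)
  IKGA <- pGA$gK * nGA * (vGA - pGA$vK)
  IKCaGA <- pGA$gKCa * (CaGA / (CaGA + pGA$k1)) * (vGA - pGA$vK)
  ILGA <- pGA$gL * (vGA - pGA$vL)
  IsynGA <- cn$gE_GA * (vGA - cn$vE_GA) * sE
  dvGA <- (-ICaGA - IKGA - ILGA - IKCaGA - IsynGA + cfg$drives[["GA"]]) / pGA$C
  dnGA <- pGA$phi * (0.5 * (1 + tanh((vGA - pGA$v3) / pGA$v4)) - nGA) *
    cosh((vGA - pGA$v3) / (2 * pGA$v4))
  dCaGA <- pGA$eps * (-pGA$mu * ICaGA - pGA$kCa * CaGA)

  # --- glycinergic cell (D1-scaled excitatory input) ---
  mGL <- 0.5 * (1 + tanh((vGL - pGL$v1) / pGL$v2))
  ICaGL <- pGL$gCa * mGL * (vGL - pGL$vCa)
  IKGL <- pGL$gK * nGL * (vGL - pGL$vK)
  IKCaGL <- pGL$gKCa * (CaGL / (CaGL + pGL$k1)) * (vGL - pGL$vK)
  ILGL <- pGL$gL * (vGL - pGL$vL)
  IsynGL <- cn$gE_GL * (1 + md$D1_GL) * (vGL - cn$vE_GL) * sE +
    cn$gGA_GL * (vGL - cn$vGA_GL) * sGA
  dvGL <- (-ICaGL - IKGL - ILGL - IKCaGL - IsynGL + cfg$drives[["GL"]]) / pGL$C
  dnGL <- pGL$phi * (0.5 * (1 + tanh((vGL - pGL$v3) / pGL$v4)) - nGL) *
    cosh((vGL - pGL$v3) / (2 * pGL$v4))
  dCaGL <- pGL$eps * (-pGL$mu * ICaGL - pGL$kCa * CaGL)

  # --- M-cell (all inputs scaled by the retrograde gain) ---
  mM <- 0.5 * (1 + tanh((vM - pM$v1) / pM$v2))
  ICaM <- pM$gCa * mM * (vM - pM$vCa)
  IKM <- pM$gK * nM * (vM - pM$vK)
  IKCaM <- pM$gKCa * (CaM / (CaM + pM$k1)) * (vM - pM$vK)
  ILM <- pM$gL * (vM - pM$vL)
  IsynM <- cn$gE_M * gI * (1 + md$D1_M) * (vM - cn$vE_M) * sE +
    gI * (cn$gGA_M * sGA + cn$gGL_M * sGL) * (vM - cn$vG_M) +
    cn$gM_M * gI * (vM - cn$vM_M) * cn$sM_const
  dvM <- (-ICaM - IKM - ILM - IKCaM - IsynM + cfg$drives[["M"]]) / pM$C
  dnM <- pM$phi * (0.5 * (1 + tanh((vM - pM$v3) / pM$v4)) - nM) *
    cosh((vM - pM$v3) / (2 * pM$v4))
  dCaM <- pM$eps * (-pM$mu * ICaM - pM$kCa * CaM)

  # --- synaptic variables ---
  kE <- cfg$kinetics$E; kGA <- cfg$kinetics$GA; kGL <- cfg$kinetics$GL
  dsE <- kE$alpha * (1 / (1 + exp(-(vE - kE$theta_s) / kE$sigma_s))) * (1 - sE) -
    kE$beta * sE
  dsGA <- kGA$alpha * (1 / (1 + exp(-(vGA - kGA$theta_s) / kGA$sigma_s))) * (1 - sGA) -
    kGA$beta * sGA
  dsGL <- kGL$alpha * (1 / (1 + exp(-(vGL - kGL$theta_s) / kGL$sigma_s))) * (1 - sGL) -
    kGL$beta * sGL

  # --- retrograde gain ---
  dgI <- if (cfg$gI_law == "saturating") {
    (md$gI_max / (CaM + md$k2) - gI) / md$rho
  } else {
    md$gI_max / (CaM + md$k2) - gI / md$rho
  }

  c(vE = dvE, nE = dnE, CaE = dCaE,
    vGA = dvGA, nGA = dnGA, CaGA = dCaGA,
    vGL = dvGL, nGL = dnGL, CaGL = dCaGL,
    vM = dvM, nM = dnM, CaM = dCaM,
    sE = dsE, sGA = dsGA, sGL = dsGL,
    gI = dgI)
}

# Draw a random valid network state.
random_state <- function() {
  st <- c(
    vE = runif(1, -80, 60), nE = runif(1), CaE = runif(1, 0, 20),
    vGA = runif(1, -80, 60), nGA = runif(1), CaGA = runif(1, 0, 20),
    vGL = runif(1, -80, 60), nGL = runif(1), CaGL = runif(1, 0, 20),
    vM = runif(1, -80, 60), nM = runif(1), CaM = runif(1, 0, 20),
    sE = runif(1), sGA = runif(1), sGL = runif(1),
    gI = runif(1, 0, 2)
  )
  st
}

# Brute-force swim-burst oracle: naive loops and an explicit state machine,
# same detection definition as detect_swim_bursts() but an independent path.
oracle_detect_bursts <- function(trace, min_amp_mV = 8,
                                 dur_range_ms = c(30, 200),
                                 enter_mV = 4, exit_mV = 2,
                                 env_ms = 25, merge_gap_ms = 10) {
  v <- trace$voltage_mV
  sr <- trace$sample_rate_hz
  msps <- 1000 / sr
  n <- length(v)
  base <- stats::median(v)
  dev <- abs(v - base)

  w <- round(env_ms / msps)
  if (w < 1) w <- 1
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  env <- numeric(n)
  for (i in 1:n) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    m <- dev[lo]
    if (hi > lo) for (j in (lo + 1):hi) if (dev[j] > m) m <- dev[j]
    env[i] <- m
  }

  segs <- list()
  i <- 1
  while (i <= n) {
    if (env[i] >= exit_mV) {
      j <- i
      while (j < n && env[j + 1] >= exit_mV) j <- j + 1
      hit <- FALSE
      for (k in i:j) if (env[k] >= enter_mV) { hit <- TRUE; break }
      if (hit) segs[[length(segs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }

  # merge
  if (length(segs) > 1) {
    merged <- list(segs[[1]])
    for (k in 2:length(segs)) {
      last <- merged[[length(merged)]]
      if (segs[[k]][1] - last[2] < merge_gap_ms / msps) {
        merged[[length(merged)]] <- c(last[1], segs[[k]][2])
      } else {
        merged[[length(merged) + 1]] <- segs[[k]]
      }
    }
    segs <- merged
  }

  out <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                    duration_ms = numeric(0), peak_to_peak_mV = numeric(0))
  for (sg in segs) {
    i0 <- NA; i1 <- NA
    for (k in sg[1]:sg[2]) {
      if (dev[k] >= exit_mV) { if (is.na(i0)) i0 <- k; i1 <- k }
    }
    if (is.na(i0)) next
    dur <- (i1 - i0) * msps
    p2p <- max(v[i0:i1]) - min(v[i0:i1])
    if (p2p >= min_amp_mV && dur >= dur_range_ms[1] && dur <= dur_range_ms[2]) {
      out <- rbind(out, data.frame(onset_ms = (i0 - 1) * msps,
                                   offset_ms = (i1 - 1) * msps,
                                   duration_ms = dur, peak_to_peak_mV = p2p))
    }
  }
  out
}
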