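test_that("gating functions hit their closed-form landmarks", {
  cp <- cell_params()
  kin <- synapse_kinetics(15, 0.1)

  g <- gating_functions(-1.2, cp, kin)   # v = v1
  expect_equal(g$m_inf, 0.5)

  g <- gating_functions(12, cp, kin)     # v = v3
  expect_equal(g$n_inf, 0.5)
  expect_equal(g$tau_n, 1)

  g <- gating_functions(0, cp, kin)      # s_inf midpoint at theta_s = 0
  expect_equal(g$s_inf, 0.5)

  g <- gating_functions(16.8, cp, kin)   # v = v1 + v2
  expect_equal(g$m_inf, 0.5 * (1 + tanh(1)), tolerance = 1e-12)

  v <- seq(-100, 80, by = 2.5)
  g <- gating_functions(v, cp, kin)
  expect_true(all(g$m_inf >= 0 & g$m_inf <= 1))
  expect_true(all(g$n_inf >= 0 & g$n_inf <= 1))
  expect_true(all(g$s_inf >= 0 & g$s_inf <= 1))
  expect_true(all(g$tau_n > 0))

  expect_error(gating_functions(NaN, cp, kin), "finite")
})

test_that("ionic currents vanish at reversal potentials and zero gates", {
  cp <- cell_params()
  expect_equal(ionic_currents(-60, 0.3, 2, cp)$IL, 0)    # v = vL
  expect_equal(ionic_currents(120, 0.3, 2, cp)$ICa, 0)   # v = vCa
  expect_equal(ionic_currents(-20, 0, 2, cp)$IK, 0)      # n = 0
  expect_equal(ionic_currents(-20, 0.3, 0, cp)$IKCa, 0)  # Ca = 0
  expect_error(ionic_currents(-20, 0.3, -1, cp), "Ca")
})

test_that("synaptic currents obey the circuit wiring", {
  cfg <- mcell_preset("dominant")
  st <- initial_state(cfg)

  # all synapses silent and no contralateral drive -> all currents zero
  cfg0 <- cfg
  cfg0$connections$sM_const <- 0
  expect_equal(unname(synaptic_currents(st, cfg0)), rep(0, 4))

  # the excitatory cell never receives synaptic input
  st2 <- st
  st2[c("sE", "sGA", "sGL")] <- c(0.5, 0.5, 0.5)
  expect_identical(synaptic_currents(st2, cfg)[["E"]], 0)

  # GABAergic term on the glycinergic cell vanishes at its reversal
  st3 <- st2
  st3["sE"] <- 0
  st3["vGL"] <- cfg$connections$vGA_GL
  expect_equal(synaptic_currents(st3, cfg)[["GL"]], 0)

  # the M-cell synaptic current is linear in the retrograde gain
  st4 <- st2
  st4["gI"] <- 0.7
  st5 <- st4
  st5["gI"] <- 1.4
  expect_equal(synaptic_currents(st5, cfg)[["M"]],
               2 * synaptic_currents(st4, cfg)[["M"]], tolerance = 1e-12)
})

test_that("derivatives respect flux bounds and fixed points", {
  cfg <- mcell_preset("dominant")
  st <- initial_state(cfg)

  # s = 1 decays; s = 0 with hyperpolarized presynaptic cell barely moves
  st1 <- st; st1["sE"] <- 1
  d <- derivatives(st1, cfg)
  expect_equal(d[["sE"]], -cfg$kinetics$E$beta, tolerance = 1e-6)
  st0 <- st; st0["vE"] <- -120; st0["sE"] <- 0
  expect_lt(abs(derivatives(st0, cfg)[["sE"]]), 1e-10)

  # isolated passive cell rests at the leak reversal
  pas <- network_config(
    cells = list(E = cell_params(gK = 0, gCa = 0, gKCa = 0),
                 GA = cell_params(), GL = cell_params(),
                 M = cell_params(C = 1, gKCa = 0.3, kCa = 0.9)),
    connections = connection_params(gE_GA = 0, gE_GL = 0, gGA_GL = 0,
                                    gE_M = 0, gGA_M = 0, gGL_M = 0,
                                    gM_M = 0, sM_const = 0),
    drives = c(E = 0, GA = 36, GL = 36, M = 19.5))
  stp <- initial_state(pas)   # vE = vL
  expect_equal(derivatives(stp, pas)[["vE"]], 0, tolerance = 1e-12)

  # gI fixed point: at Ca = 5, gI* = 15 / (5 + 10) = 1
  stg <- st; stg["CaM"] <- 5; stg["gI"] <- 1
  expect_equal(derivatives(stg, cfg)[["gI"]], 0, tolerance = 1e-15)
  stg["gI"] <- 0.5
  expect_gt(derivatives(stg, cfg)[["gI"]], 0)

  # alternative gI law is exposed and differs
  cfg2 <- cfg; cfg2$gI_law <- "linear_decay"
  expect_false(isTRUE(all.equal(derivatives(stg, cfg2)[["gI"]],
                                derivatives(stg, cfg)[["gI"]])))

  expect_error(derivatives(st, cfg, stim = -1), "stim")
})

test_that("rk4_step matches the exponential oracle and is pure", {
  f <- function(y, t) -y
  y1 <- rk4_step(f, 1, 0, 0.1)
  # 4th-order Taylor of exp(-0.1)
  expect_equal(y1, 1 - 0.1 + 0.1^2 / 2 - 0.1^3 / 6 + 0.1^4 / 24,
               tolerance = 1e-15)
  # one step already matches exp(-0.1) = 0.90483742 to ~8e-8
  expect_equal(y1, exp(-0.1), tolerance = 1e-6)

  expect_error(rk4_step(f, 1, 0, 0), "dt")
  expect_error(rk4_step(f, 1, 0, -0.1), "dt")

  # purity: repeated stepping gives identical results
  a <- rk4_step(f, rk4_step(f, 1, 0, 0.05), 0.05, 0.05)
  b <- rk4_step(f, rk4_step(f, 1, 0, 0.05), 0.05, 0.05)
  expect_identical(a, b)
})

test_that("compiled integrator agrees with R-level RK4 stepping", {
  cfg <- mcell_preset("subordinate")
  st <- initial_state(cfg)
  dt <- 0.02
  n_steps <- 500   # 10 ms, includes a stimulus pulse from t = 2 ms

  stim_fn <- function(t) if (t >= 2 && t < 4) 60 else 0
  f <- function(y, t) derivatives(y, cfg, t, stim_fn(t))
  y <- unname(st)
  for (k in seq_len(n_steps)) y <- rk4_step(f, y, (k - 1) * dt, dt)

  res <- mcescape:::run_segment(cfg, st, 0, n_steps * dt, dt,
                                pulse_onsets = 2, pulse_ms = 2, WE = 60)
  expect_equal(unname(res$final_state), unname(y), tolerance = 1e-10)
})

test_that("simulation is deterministic, bounded, and guards divergence", {
  cfg <- mcell_preset("dominant")
  proto <- stimulus_protocol(WE_grid = 60, n_pulses = 1)
  tr1 <- simulate_network(cfg, proto, dt = 0.02, settle_ms = 500)
  tr2 <- simulate_network(cfg, proto, dt = 0.02, settle_ms = 500)
  expect_identical(tr1$vM, tr2$vM)

  b <- attr(tr1, "bounds")
  expect_gte(b[["n_min"]], 0); expect_lte(b[["n_max"]], 1)
  expect_gte(b[["s_min"]], 0); expect_lte(b[["s_max"]], 1)
  expect_gte(b[["ca_min"]], 0); expect_gte(b[["gI_min"]], 0)

  # a zero-duration protocol covers only the settling period
  tr0 <- simulate_network(cfg, stimulus_protocol(WE_grid = numeric(0)),
                          dt = 0.02, settle_ms = 200)
  expect_equal(max(tr0$t_ms), 200)

  # decoupled cells settle to a stimulus-independent attractor
  dec <- network_config(
    connections = connection_params(gE_GA = 0, gE_GL = 0, gGA_GL = 0,
                                    gE_M = 0, gGA_M = 0, gGL_M = 0,
                                    gM_M = 0, sM_const = 0))
  s1 <- simulate_network(dec, stimulus_protocol(numeric(0)), dt = 0.02,
                         settle_ms = 300)
  s2 <- simulate_network(dec, stimulus_protocol(numeric(0)), dt = 0.02,
                         settle_ms = 300)
  expect_identical(unlist(s1[nrow(s1), ]), unlist(s2[nrow(s2), ]))

  # divergence guard: a pathological config errors instead of returning NaN
  bad <- mcell_preset("dominant")
  bad$drives["M"] <- 1e7
  expect_error(simulate_network(bad, stimulus_protocol(numeric(0)),
                                dt = 0.02, settle_ms = 100),
               "integration failure")

  expect_error(simulate_network(cfg, proto, dt = 0.2), "dt")
})

test_that("dominant control circuit fires the M-cell at strong stimulation", {
  cfg <- mcell_preset("dominant")
  tr <- simulate_network(cfg, stimulus_protocol(WE_grid = 60, n_pulses = 1))
  sp <- detect_mcell_spikes(tr)
  onset <- attr(tr, "pulse_onsets")[1]
  expect_gte(sum(sp > onset), 1)
  # and the compiled online detector agrees with the trace-based one
  expect_equal(attr(tr, "spikes")[attr(tr, "spikes") > onset],
               sp[sp > onset], tolerance = 1e-3)
})
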