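test_that("burst detector accepts and rejects by the printed criteria", {
  # noise-free flat baseline: no bursts
  flat <- field_potential_trace(rep(0, 10000), 1000)
  expect_equal(nrow(detect_swim_bursts(flat)), 0)

  # one 10 mV p2p, 100 ms packet in a quiet trace: exactly one burst
  g <- gen_swim_trace(duration_s = 5, burst_onsets_s = 2,
                      burst_durations_ms = 100, burst_amplitudes_mV = 10,
                      noise_sd_mV = 0, seed = 1)
  b <- detect_swim_bursts(g$trace)
  expect_equal(nrow(b), 1)
  expect_gte(b$peak_to_peak_mV, 8)
  expect_true(b$duration_ms >= 30 && b$duration_ms <= 200)
  expect_equal(b$onset_ms, 2000, tolerance = 20)
  expect_equal(attr(b, "bursts_per_min"), 12)   # 1 burst / 5 s

  # 25 ms and 250 ms packets (10 mV) are both rejected on duration
  g2 <- gen_swim_trace(duration_s = 5, burst_onsets_s = c(1, 3),
                       burst_durations_ms = c(25, 250),
                       burst_amplitudes_mV = 10, noise_sd_mV = 0, seed = 1)
  b2 <- detect_swim_bursts(g2$trace)
  expect_equal(nrow(b2), 0)
  expect_equal(attr(b2, "n_rejected"), 2)

  # sub-amplitude packet rejected on peak-to-peak
  g3 <- gen_swim_trace(duration_s = 5, burst_onsets_s = 2,
                       burst_durations_ms = 100, burst_amplitudes_mV = 7.5,
                       noise_sd_mV = 0, seed = 1)
  expect_equal(nrow(detect_swim_bursts(g3$trace)), 0)

  expect_error(field_potential_trace(c(NA, NA), 1000), "missing")
  expect_warning(field_potential_trace(rep(0, 100), 500), "1 kHz")
})

test_that("burst detector matches the brute-force oracle on random traces", {
  set.seed(42)
  for (rep in 1:25) {
    n_b <- sample(0:4, 1)
    onsets <- sort(runif(n_b, 0.2, 3.4))
    # enforce spacing so scheduled bursts never overlap
    if (n_b > 1) onsets <- onsets + (seq_len(n_b) - 1) * 0.45
    durs <- runif(max(n_b, 1), 15, 280)[seq_len(n_b)]
    amps <- runif(max(n_b, 1), 5, 18)[seq_len(n_b)]
    g <- gen_swim_trace(duration_s = 6, burst_onsets_s = onsets,
                        burst_durations_ms = durs, burst_amplitudes_mV = amps,
                        noise_sd_mV = 0.5, seed = rep)
    got <- detect_swim_bursts(g$trace)
    want <- oracle_detect_bursts(g$trace)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$onset_ms, want$onset_ms)
      expect_equal(got$offset_ms, want$offset_ms)
      expect_equal(got$duration_ms, want$duration_ms)
      expect_equal(got$peak_to_peak_mV, want$peak_to_peak_mV)
    }
  }
})

test_that("in-criteria bursts are recovered perfectly at 0.5 mV noise", {
  g <- gen_swim_trace(duration_s = 30,
                      burst_onsets_s = c(3, 8, 14, 20, 26),
                      burst_durations_ms = 80, burst_amplitudes_mV = 12,
                      noise_sd_mV = 0.5, seed = 11)
  b <- detect_swim_bursts(g$trace)
  expect_equal(nrow(b), 5)   # recall = 1, precision = 1
  # every detection overlaps exactly one scheduled burst
  hits <- vapply(seq_len(nrow(b)), function(i) {
    sum(b$onset_ms[i] < g$truth$onset_ms + g$truth$duration_ms &
          b$offset_ms[i] > g$truth$onset_ms)
  }, numeric(1))
  expect_true(all(hits == 1))
})

test_that("Mauthner latency filter applies the 5-15 ms rule", {
  tr <- data.frame(
    animal = 1,
    intensity_dB = c(80, 80, 85, 90, 95),
    responded = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    latency_ms = c(10, 16, 5, 4.9, NA)
  )
  out <- filter_mauthner_trials(tr)
  expect_equal(nrow(out), 3)                       # 16 and 4.9 ms excluded
  expect_true(all(out$latency_ms[out$responded] >= 5 &
                    out$latency_ms[out$responded] <= 15))
  expect_true(any(!out$responded))                 # non-responses retained
  expect_identical(filter_mauthner_trials(tr[0, ]), tr[0, ])
  bad <- tr; bad$latency_ms[1] <- -2
  expect_error(filter_mauthner_trials(bad), "non-negative")
})

test_that("startle probability averages within then across animals", {
  tr <- data.frame(
    animal = rep(c(1, 2), each = 4),
    intensity_dB = 100,
    responded = c(TRUE, TRUE, TRUE, TRUE,   # animal 1: 4/4
                  TRUE, TRUE, FALSE, FALSE),# animal 2: 2/4
    latency_ms = 10
  )
  sp <- startle_probability(tr, grid = c(95, 100))
  m <- sp$mean
  expect_equal(m$probability[m$intensity_dB == 100], 0.75)  # mean(1, 0.5)
  expect_true(is.na(m$probability[m$intensity_dB == 95]))

  # across-animal mean of per-animal fractions 0.2 and 0.4 is 0.3
  tr2 <- data.frame(
    animal = rep(c(1, 2), each = 5), intensity_dB = 85,
    responded = c(c(TRUE, FALSE, FALSE, FALSE, FALSE),
                  c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    latency_ms = 8)
  sp2 <- startle_probability(tr2, grid = 85)
  expect_equal(sp2$mean$probability, 0.3)

  # row order does not matter
  perm <- tr2[sample(nrow(tr2)), ]
  expect_equal(startle_probability(perm, grid = 85)$mean$probability, 0.3)

  expect_warning(startle_probability(
    data.frame(animal = 1, intensity_dB = 62, responded = TRUE,
               latency_ms = 8), grid = c(70, 75)), "outside the grid")
})

test_that("Boltzmann fit recovers noiseless parameters and flags degeneracy", {
  x <- seq(70, 100, by = 5)
  y <- boltzmann(x, 0, 1, 85, 3)
  f <- fit_boltzmann(x, y)
  expect_equal(f$Bottom, 0, tolerance = 1e-6)
  expect_equal(f$Top, 1, tolerance = 1e-6)
  expect_equal(f$V50, 85, tolerance = 1e-6)
  expect_equal(f$Slope, 3, tolerance = 1e-6)
  expect_gt(f$r_squared, 1 - 1e-10)

  # fitted curve is monotone and within [Bottom, Top] for positive slope
  pred <- boltzmann(seq(60, 110, 0.5), f$Bottom, f$Top, f$V50, f$Slope)
  expect_true(all(diff(pred) > 0))
  expect_true(all(pred >= f$Bottom - 1e-12 & pred <= f$Top + 1e-12))

  expect_warning(fd <- fit_boltzmann(x, rep(0.5, length(x))), "degenerate")
  expect_true(fd$degenerate)
  expect_equal(fd$Top, fd$Bottom)
  expect_true(is.na(fd$V50))

  expect_error(fit_boltzmann(c(70, 75, 80), c(0, 0.5, 1)), "4 distinct")
})

test_that("V50 is recovered within 1 dB from Bernoulli startle data", {
  trials <- gen_startle_trials(truth = c(Bottom = 0, Top = 1, V50 = 85,
                                         Slope = 3),
                               trials_per_intensity = 5, n_animals = 40,
                               seed = 20260924)
  sp <- startle_probability(trials)
  f <- fit_boltzmann(sp$mean$intensity_dB, sp$mean$probability)
  expect_lt(abs(f$V50 - 85), 1)
  expect_lt(abs(f$Slope - 3) / 3, 0.3)
})
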