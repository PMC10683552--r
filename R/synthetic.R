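# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators are pure functions of their inputs.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Tukey (tapered cosine) window of length n with taper fraction `a` per side.
tukey_window <- function(n, a = 0.1) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < a
  hi <- t > 1 - a
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1) / a + 1)))
  w
}

#' Generate a synthetic swim field-potential trace
#'
#' Renders scheduled swim bursts as Tukey-enveloped sinusoid packets on a
#' Gaussian noise baseline, returning both the trace and the ground-truth
#' burst schedule for detector-recovery tests. The carrier frequency mimics a
#' tail-beat field rhythm; detection depends only on envelope amplitude and
#' duration, so its exact value is cosmetic.
#'
#' @param duration_s recording length (s).
#' @param sample_rate_hz sampling rate (Hz).
#' @param burst_onsets_s burst onset times (s); bursts must not overlap.
#' @param burst_durations_ms burst durations (ms), recycled to the number of
#'   onsets.
#' @param burst_amplitudes_mV peak-to-peak amplitudes (mV), recycled.
#' @param carrier_hz carrier frequency of the packet (Hz).
#' @param noise_sd_mV standard deviation of the baseline noise (mV).
#' @param taper_frac Tukey taper fraction per packet edge.
#' @param seed RNG seed; identical inputs give bit-identical traces.
#' @return List with \code{trace} (a [field_potential_trace()]) and
#'   \code{truth} (data frame: onset_ms, duration_ms, amplitude_mV).
#' @export
gen_swim_trace <- function(duration_s = 60, sample_rate_hz = 1000,
                           burst_onsets_s = numeric(0),
                           burst_durations_ms = 80,
                           burst_amplitudes_mV = 12,
                           carrier_hz = 30, noise_sd_mV = 0.5,
                           taper_frac = 0.1, seed = NULL) {
  n_burst <- length(burst_onsets_s)
  dur <- rep_len(burst_durations_ms, max(n_burst, 1L))[seq_len(n_burst)]
  amp <- rep_len(burst_amplitudes_mV, max(n_burst, 1L))[seq_len(n_burst)]
  if (n_burst > 0) {
    if (any(dur <= 0) || any(amp <= 0)) {
      stop("gen_swim_trace: burst durations and amplitudes must be positive")
    }
    o <- order(burst_onsets_s)
    if (n_burst > 1) {
      ends <- burst_onsets_s[o] + dur[o] / 1000
      if (any(ends[-n_burst] > burst_onsets_s[o][-1])) {
        stop("gen_swim_trace: scheduled bursts overlap")
      }
    }
    if (burst_onsets_s[o][n_burst] + dur[o][n_burst] / 1000 > duration_s) {
      stop("gen_swim_trace: burst extends past the end of the recording")
    }
  }
  n <- round(duration_s * sample_rate_hz)
  v <- with_seed(seed, {
    if (noise_sd_mV > 0) stats::rnorm(n, 0, noise_sd_mV) else numeric(n)
  })
  for (b in seq_len(n_burst)) {
    i0 <- floor(burst_onsets_s[b] * sample_rate_hz) + 1L
    len <- max(1L, round(dur[b] / 1000 * sample_rate_hz))
    idx <- i0:min(n, i0 + len - 1L)
    tt <- (seq_along(idx) - 1) / sample_rate_hz
    packet <- (amp[b] / 2) * tukey_window(length(idx), taper_frac) *
      sin(2 * pi * carrier_hz * tt)
    v[idx] <- v[idx] + packet
  }
  list(trace = field_potential_trace(v, sample_rate_hz),
       truth = data.frame(onset_ms = burst_onsets_s * 1000,
                          duration_ms = dur, amplitude_mV = amp))
}

#' Generate synthetic startle trials from a known psychometric curve
#'
#' Draws Bernoulli startle outcomes per animal and intensity from a ground
#' truth [boltzmann()] curve; responded trials receive latencies from a
#' uniform distribution inside the Mauthner window, with an optional fraction
#' of long-latency (non-Mauthner) contaminants to exercise the latency
#' filter.
#'
#' @param truth named numeric vector with Bottom, Top, V50, Slope.
#' @param grid intensity grid (dB).
#' @param trials_per_intensity trials delivered per animal per intensity
#'   (3-5 in the behavioral protocol).
#' @param n_animals number of animals.
#' @param latency_range_ms range of the uniform Mauthner-latency
#'   distribution (ms).
#' @param contaminant_frac fraction of responded trials given a long
#'   (16-30 ms) non-Mauthner latency.
#' @param seed RNG seed.
#' @return Data frame (animal, intensity_dB, responded, latency_ms) with the
#'   truth parameters as attribute \code{truth}.
#' @export
gen_startle_trials <- function(truth = c(Bottom = 0, Top = 1, V50 = 85, Slope = 3),
                               grid = seq(70, 100, by = 5),
                               trials_per_intensity = 5, n_animals = 10,
                               latency_range_ms = c(6, 14),
                               contaminant_frac = 0, seed = NULL) {
  stopifnot(all(c("Bottom", "Top", "V50", "Slope") %in% names(truth)),
            trials_per_intensity >= 1, n_animals >= 1,
            contaminant_frac >= 0, contaminant_frac <= 1)
  p <- boltzmann(grid, truth["Bottom"], truth["Top"], truth["V50"], truth["Slope"])
  if (any(p < 0 | p > 1)) {
    stop("gen_startle_trials: truth curve gives probabilities outside [0, 1]")
  }
  with_seed(seed, {
    rows <- expand.grid(trial = seq_len(trials_per_intensity),
                        intensity_dB = grid, animal = seq_len(n_animals),
                        KEEP.OUT.ATTRS = FALSE)
    pr <- p[match(rows$intensity_dB, grid)]
    rows$responded <- stats::runif(nrow(rows)) < pr
    rows$latency_ms <- NA_real_
    nr <- sum(rows$responded)
    if (nr > 0) {
      lat <- stats::runif(nr, latency_range_ms[1], latency_range_ms[2])
      contam <- stats::runif(nr) < contaminant_frac
      lat[contam] <- stats::runif(sum(contam), 16, 30)
      rows$latency_ms[rows$responded] <- lat
    }
    out <- rows[, c("animal", "intensity_dB", "responded", "latency_ms")]
    attr(out, "truth") <- truth
    out
  })
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Builds Ct records whose group shifts encode known log2 fold changes under
#' the efficiency model: for amplification factor E, a fold change F in a
#' group lowers that group's Ct by log_E(F) cycles relative to the control
#' group. The reference gene is unshifted. Gaussian per-replicate Ct noise is
#' added, and each biological replicate is measured in technical duplicate.
#'
#' @param log2_folds data frame with columns \code{gene}, \code{group},
#'   \code{log2_fold}: true log2 fold change of each target gene in each
#'   non-control group.
#' @param efficiencies efficiency table as in [relative_expression()].
#' @param reference_gene housekeeping gene (unshifted; default "actb2").
#' @param control_group control group name (default "isolate").
#' @param baseline_ct named numeric of baseline Ct per gene; genes absent
#'   from the vector default to 24 (reference defaults to 20).
#' @param noise_sd per-biological-replicate Ct noise sd (cycles).
#' @param technical_sd technical-duplicate noise sd (cycles).
#' @param n_replicates biological replicates per group.
#' @param n_technical technical replicates per sample.
#' @param seed RNG seed.
#' @return Data frame of Ct records (sample_id, group, gene, replicate, Ct)
#'   with attribute \code{truth} (= \code{log2_folds}).
#' @export
gen_ct_table <- function(log2_folds,
                         efficiencies = primer_efficiencies(),
                         reference_gene = "actb2",
                         control_group = "isolate",
                         baseline_ct = NULL,
                         noise_sd = 0.2, technical_sd = 0.05,
                         n_replicates = 10, n_technical = 2, seed = NULL) {
  stopifnot(is.data.frame(log2_folds),
            all(c("gene", "group", "log2_fold") %in% names(log2_folds)),
            noise_sd >= 0, technical_sd >= 0, n_replicates >= 1,
            n_technical >= 1)
  if (!"amplification_factor" %in% names(efficiencies)) {
    efficiencies$amplification_factor <-
      1 + efficiencies$efficiency_percent / 100
  }
  eff <- stats::setNames(efficiencies$amplification_factor, efficiencies$gene)
  genes <- unique(c(reference_gene, log2_folds$gene))
  groups <- unique(c(control_group, log2_folds$group))
  miss <- setdiff(genes, names(eff))
  if (length(miss) > 0) {
    stop("missing efficiency for gene(s): ", paste(miss, collapse = ", "))
  }
  base <- stats::setNames(rep(24, length(genes)), genes)
  base[reference_gene] <- 20
  if (!is.null(baseline_ct)) base[names(baseline_ct)] <- baseline_ct

  with_seed(seed, {
    recs <- list()
    for (g in groups) {
      for (r in seq_len(n_replicates)) {
        sid <- paste0(g, "_", r)
        for (gn in genes) {
          shift <- 0
          if (gn != reference_gene && g != control_group) {
            row <- log2_folds$gene == gn & log2_folds$group == g
            if (any(row)) {
              fold <- 2^log2_folds$log2_fold[row][1]
              shift <- log(fold, base = eff[[gn]])
            }
          }
          ct_bio <- base[[gn]] - shift + stats::rnorm(1, 0, noise_sd)
          ct_tech <- ct_bio + stats::rnorm(n_technical, 0, technical_sd)
          recs[[length(recs) + 1L]] <- data.frame(
            sample_id = sid, group = g, gene = gn,
            replicate = seq_len(n_technical), Ct = ct_tech)
        }
      }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    attr(out, "truth") <- log2_folds
    out
  })
}
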