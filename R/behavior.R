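#' Field-potential trace container
#'
#' A far-field potential recording from the behavioral chamber: a regularly
#' sampled voltage series with its sample rate. Swimming bouts appear as
#' transient high-amplitude deflections ("swim bursts") on the baseline.
#'
#' @param voltage_mV numeric vector of samples (mV).
#' @param sample_rate_hz sampling rate (Hz, > 0); rates below 1 kHz trigger a
#'   warning since burst edges are then poorly resolved.
#' @return List of class \code{"field_potential_trace"} with elements
#'   \code{voltage_mV}, \code{sample_rate_hz}, \code{duration_s}.
#' @export
field_potential_trace <- function(voltage_mV, sample_rate_hz) {
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("field_potential_trace: sample_rate_hz must be a single positive number")
  }
  if (length(voltage_mV) == 0 || all(is.na(voltage_mV))) {
    stop("field_potential_trace: voltage series is empty or all missing")
  }
  if (any(!is.finite(voltage_mV))) {
    stop("field_potential_trace: voltage series contains non-finite samples")
  }
  if (sample_rate_hz < 1000) {
    warning("sample rate below 1 kHz; burst boundaries may be poorly resolved")
  }
  structure(list(voltage_mV = as.numeric(voltage_mV),
                 sample_rate_hz = sample_rate_hz,
                 duration_s = length(voltage_mV) / sample_rate_hz),
            class = "field_potential_trace")
}

# Centered running maximum with window of `w` samples (w odd).
running_max <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- max(x[max(1L, i - h):min(n, i + h)])
  }
  out
}

#' Detect swim bursts in a field-potential trace
#'
#' Swimming bouts are detected as deviations from the baseline (the median of
#' the trace): the absolute deviation is enveloped with a centered running
#' maximum of width \code{env_ms} (bridging the zero crossings of the
#' oscillatory carrier), candidate events are contiguous runs where the
#' envelope stays at or above \code{exit_mV} that reach \code{enter_mV} at
#' least once (hysteresis, preventing chatter), events closer than
#' \code{merge_gap_ms} are merged, and each event is then trimmed to the
#' first/last sample whose raw deviation reaches \code{exit_mV}. A trimmed
#' event is accepted as a swim burst when its peak-to-peak amplitude is at
#' least \code{min_amp_mV} (default 8 mV) and its duration falls within
#' \code{dur_range_ms} (default 30-200 ms).
#'
#' @param trace a [field_potential_trace()].
#' @param min_amp_mV minimum peak-to-peak amplitude of an accepted burst (mV).
#' @param dur_range_ms length-2 numeric, accepted duration range (ms).
#' @param enter_mV,exit_mV hysteresis thresholds on the deviation envelope
#'   (mV); \code{enter_mV > exit_mV}.
#' @param env_ms width of the running-maximum envelope window (ms).
#' @param merge_gap_ms events separated by less than this gap are merged
#'   before acceptance testing (ms).
#' @return Data frame with one accepted burst per row: \code{onset_ms},
#'   \code{offset_ms}, \code{duration_ms}, \code{peak_to_peak_mV}; attribute
#'   \code{bursts_per_min} (count normalized to the recording length) and
#'   attribute \code{n_rejected} (candidate events failing acceptance).
#' @export
detect_swim_bursts <- function(trace, min_amp_mV = 8,
                               dur_range_ms = c(30, 200),
                               enter_mV = 4, exit_mV = 2,
                               env_ms = 25, merge_gap_ms = 10) {
  stopifnot(inherits(trace, "field_potential_trace"))
  if (enter_mV <= exit_mV) stop("detect_swim_bursts: enter_mV must exceed exit_mV")
  v <- trace$voltage_mV
  sr <- trace$sample_rate_hz
  ms_per_sample <- 1000 / sr

  dev <- abs(v - stats::median(v))
  w <- max(1L, as.integer(round(env_ms / ms_per_sample)))
  if (w %% 2L == 0L) w <- w + 1L
  env <- running_max(dev, w)

  # Candidate segments: runs of env >= exit containing at least one
  # env >= enter sample.
  above <- env >= exit_mV
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) > 0) {
    keep <- vapply(seq_len(nrow(seg)), function(i) {
      any(env[seg[i, 1]:seg[i, 2]] >= enter_mV)
    }, logical(1))
    seg <- seg[keep, , drop = FALSE]
  }

  # Merge segments separated by < merge_gap_ms.
  if (nrow(seg) > 1) {
    gap_samples <- merge_gap_ms / ms_per_sample
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      if (seg[i, 1] - merged[nrow(merged), 2] < gap_samples) {
        merged[nrow(merged), 2] <- seg[i, 2]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }

  events <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                       duration_ms = numeric(0), peak_to_peak_mV = numeric(0))
  n_rejected <- 0L
  for (i in seq_len(nrow(seg))) {
    idx <- seg[i, 1]:seg[i, 2]
    hot <- idx[dev[idx] >= exit_mV]
    if (length(hot) == 0) { n_rejected <- n_rejected + 1L; next }
    i0 <- min(hot); i1 <- max(hot)
    dur <- (i1 - i0) * ms_per_sample
    p2p <- max(v[i0:i1]) - min(v[i0:i1])
    if (p2p >= min_amp_mV && dur >= dur_range_ms[1] && dur <= dur_range_ms[2]) {
      events <- rbind(events, data.frame(
        onset_ms = (i0 - 1) * ms_per_sample,
        offset_ms = (i1 - 1) * ms_per_sample,
        duration_ms = dur, peak_to_peak_mV = p2p))
    } else {
      n_rejected <- n_rejected + 1L
    }
  }
  structure(events,
            bursts_per_min = nrow(events) / trace$duration_s * 60,
            n_rejected = n_rejected)
}

#' Filter startle trials to Mauthner-mediated responses
#'
#' The Mauthner-initiated startle is an all-or-none response with 5-15 ms
#' latency; responded trials with latency outside the window are excluded as
#' non-Mauthner responses, and non-response trials are retained.
#'
#' @param trials data frame with columns \code{intensity_dB},
#'   \code{responded} (logical) and \code{latency_ms} (NA allowed for
#'   non-responses); extra columns (e.g. \code{animal}) are preserved.
#' @param window_ms length-2 numeric, inclusive latency window (ms).
#' @return The filtered trial table.
#' @export
filter_mauthner_trials <- function(trials, window_ms = c(5, 15)) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0) return(trials)
  req <- c("intensity_dB", "responded", "latency_ms")
  if (!all(req %in% names(trials))) {
    stop("filter_mauthner_trials: trials must have columns ",
         paste(req, collapse = ", "))
  }
  lat <- trials$latency_ms
  if (any(trials$responded & is.na(lat))) {
    stop("filter_mauthner_trials: responded trials must carry a latency")
  }
  if (any(lat < 0, na.rm = TRUE)) {
    stop("filter_mauthner_trials: latencies must be non-negative")
  }
  drop <- trials$responded & (lat < window_ms[1] | lat > window_ms[2])
  trials[!drop, , drop = FALSE]
}

#' Startle response probability per stimulus intensity
#'
#' Tabulates the per-animal response fraction at each requested intensity,
#' then averages across animals, mirroring the behavioral protocol (each
#' intensity delivered a few times per animal, probabilities averaged across
#' animals).
#'
#' @param trials trial table as in [filter_mauthner_trials()]; an
#'   \code{animal} column identifies animals (absent: one animal assumed).
#' @param grid intensities to tabulate (dB); defaults to the 70-100 dB grid
#'   in 5-dB steps. Trials at intensities outside the grid trigger a warning
#'   and are ignored.
#' @return List with \code{per_animal} (data frame: animal, intensity_dB,
#'   n_trials, probability) and \code{mean} (data frame: intensity_dB,
#'   n_animals, probability); intensities with no trials for an animal get
#'   \code{NA} and are dropped from that animal's average.
#' @export
startle_probability <- function(trials, grid = seq(70, 100, by = 5)) {
  stopifnot(is.data.frame(trials))
  if (!"animal" %in% names(trials)) trials$animal <- 1L
  extra <- setdiff(unique(trials$intensity_dB), grid)
  if (length(extra) > 0) {
    warning("ignoring trials at intensities outside the grid: ",
            paste(sort(extra), collapse = ", "))
    trials <- trials[trials$intensity_dB %in% grid, , drop = FALSE]
  }
  animals <- sort(unique(trials$animal))
  per <- expand.grid(animal = animals, intensity_dB = grid,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per$n_trials <- integer(nrow(per))
  per$probability <- rep(NA_real_, nrow(per))
  for (i in seq_len(nrow(per))) {
    sel <- trials$animal == per$animal[i] &
      trials$intensity_dB == per$intensity_dB[i]
    per$n_trials[i] <- sum(sel)
    if (per$n_trials[i] > 0) per$probability[i] <- mean(trials$responded[sel])
  }
  mean_df <- do.call(rbind, lapply(grid, function(g) {
    p <- per$probability[per$intensity_dB == g]
    p <- p[!is.na(p)]
    data.frame(intensity_dB = g, n_animals = length(p),
               probability = if (length(p)) mean(p) else NA_real_)
  }))
  list(per_animal = per[order(per$animal, per$intensity_dB), ],
       mean = mean_df)
}

#' Boltzmann sigmoid
#'
#' The four-parameter sigmoid used for startle psychometric curves:
#' Y = Bottom + (Top - Bottom) / (1 + exp((V50 - X) / Slope)).
#'
#' @param x stimulus intensity (dB).
#' @param Bottom,Top lower and upper asymptotes.
#' @param V50 intensity of half-maximal response (dB).
#' @param Slope slope factor (dB); positive for an increasing curve.
#' @return Predicted response probability.
#' @export
boltzmann <- function(x, Bottom, Top, V50, Slope) {
  Bottom + (Top - Bottom) / (1 + exp((V50 - x) / Slope))
}

#' Fit the Boltzmann sigmoid to a startle-probability curve
#'
#' Least-squares fit of [boltzmann()] by Levenberg-Marquardt. Initial values
#' follow a fixed rule for determinism: Bottom = min(y), Top = max(y), V50 =
#' the x whose y is closest to mid-range, Slope = 5 dB. Constant y is flagged
#' as degenerate (Top = Bottom, V50 and Slope unidentifiable) with a warning
#' rather than an error.
#'
#' @param x stimulus intensities (>= 4 distinct values).
#' @param y response probabilities, same length as \code{x}.
#' @return List of class \code{"boltzmann_fit"}: \code{Bottom}, \code{Top},
#'   \code{V50}, \code{Slope}, \code{r_squared}, \code{fitted},
#'   \code{degenerate}.
#' @export
#' @examples
#' x <- seq(70, 100, 5)
#' f <- fit_boltzmann(x, boltzmann(x, 0, 1, 85, 3))
#' c(f$V50, f$Slope)
fit_boltzmann <- function(x, y) {
  if (length(x) != length(y)) stop("fit_boltzmann: x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4) {
    stop("fit_boltzmann: need at least 4 distinct x values")
  }
  if (diff(range(y)) < 1e-9) {
    warning("fit_boltzmann: constant response; degenerate fit (Top = Bottom), ",
            "V50 and Slope unidentifiable")
    return(structure(list(Bottom = mean(y), Top = mean(y),
                          V50 = NA_real_, Slope = NA_real_,
                          r_squared = NA_real_, fitted = rep(mean(y), length(y)),
                          degenerate = TRUE),
                     class = "boltzmann_fit"))
  }
  start <- list(Bottom = min(y), Top = max(y),
                V50 = x[which.min(abs(y - (min(y) + max(y)) / 2))],
                Slope = 5)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Bottom + (Top - Bottom) / (1 + exp((V50 - x) / Slope)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("fit_boltzmann: fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  fitted <- boltzmann(x, cf["Bottom"], cf["Top"], cf["V50"], cf["Slope"])
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(list(Bottom = unname(cf["Bottom"]), Top = unname(cf["Top"]),
                 V50 = unname(cf["V50"]), Slope = unname(cf["Slope"]),
                 r_squared = r2, fitted = fitted, degenerate = FALSE),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("Boltzmann sigmoid fit\n")
  cat(sprintf("  Bottom = %.4g  Top = %.4g  V50 = %.4g dB  Slope = %.4g dB\n",
              x$Bottom, x$Top, x$V50, x$Slope))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared = %.4f\n", x$r_squared))
  if (x$degenerate) cat("  (degenerate: constant response)\n")
  invisible(x)
}
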