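#' Save a network configuration as JSON
#'
#' Numeric values are written at full precision so that
#' \code{load_config(save_config(cfg)) } reproduces the configuration
#' exactly.
#'
#' @param cfg a [network_config()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "network_config"))
  obj <- strip_classes(cfg)
  obj$drives <- as.list(cfg$drives)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

build_part <- function(ctor, values, what) {
  unknown <- setdiff(names(values), names(formals(ctor)))
  if (length(unknown) > 0) {
    stop("unknown key(s) in ", what, ": ", paste(unknown, collapse = ", "))
  }
  do.call(ctor, values)
}

#' Load and validate a network configuration
#'
#' Reads a JSON configuration written by [save_config()] (or hand-written in
#' the same shape), or resolves a named preset. Every parameter block is
#' rebuilt through its constructor, so invariant violations and unknown keys
#' are rejected with informative errors.
#'
#' @param path path to a JSON configuration, or a preset name
#'   (\code{"dominant"} or \code{"subordinate"}).
#' @return A [network_config()].
#' @export
load_config <- function(path) {
  if (path %in% c("dominant", "subordinate")) {
    return(mcell_preset(path))
  }
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("status", "cells", "kinetics", "connections", "modulation",
             "drives", "gI_law")
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0) {
    stop("unknown top-level key(s) in config: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(known, names(obj))
  if (length(missing) > 0) {
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  }
  cells <- lapply(stats::setNames(CELL_IDS, CELL_IDS), function(cc) {
    build_part(cell_params, as.list(obj$cells[[cc]]), paste0("cells$", cc))
  })
  kin_ids <- c("E", "GA", "GL")
  kinetics <- lapply(stats::setNames(kin_ids, kin_ids), function(cc) {
    build_part(synapse_kinetics, as.list(obj$kinetics[[cc]]),
               paste0("kinetics$", cc))
  })
  network_config(
    status = obj$status,
    cells = cells,
    kinetics = kinetics,
    connections = build_part(connection_params, as.list(obj$connections),
                             "connections"),
    modulation = build_part(modulation_params, as.list(obj$modulation),
                            "modulation"),
    drives = unlist(obj$drives),
    gI_law = obj$gI_law
  )
}

#' Export a simulation trace as CSV with a JSON metadata sidecar
#'
#' The CSV holds the time grid and all 16 state variables; the sidecar
#' (\code{<path>.json}) records the integration step, the stimulus protocol,
#' the pulse onsets, and the full configuration snapshot needed to reproduce
#' the run.
#'
#' @param trace an \code{"mcell_trace"} from [simulate_network()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "mcell_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  proto <- attr(trace, "protocol")
  meta <- list(
    dt = attr(trace, "dt"),
    protocol = unclass(proto),
    pulse_onsets = attr(trace, "pulse_onsets"),
    config = strip_classes(attr(trace, "config"))
  )
  meta$config$drives <- as.list(attr(trace, "config")$drives)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write analysis outputs with a run manifest
#'
#' Data frames are written as \code{<name>.csv}, other (list-like) objects as
#' \code{<name>.json}. A manifest (\code{manifest.json}) recording the
#' command label, seed, package version, timestamp and output paths is
#' written last, so a manifest's presence certifies a complete run.
#'
#' @param objects named list of data frames and/or lists.
#' @param dir output directory (created if needed).
#' @param command label of the producing command, stored in the manifest.
#' @param seed seed used by the run (or NULL).
#' @return Path of the manifest, invisibly.
#' @export
write_outputs <- function(objects, dir, command = "mcescape", seed = NULL) {
  stopifnot(is.list(objects), length(objects) > 0,
            !is.null(names(objects)), all(nzchar(names(objects))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.data.frame(obj)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(obj, f, row.names = FALSE)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- list(
    command = command,
    seed = seed,
    package = "mcescape",
    version = as.character(utils::packageVersion("mcescape")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(files)
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' Read a startle trial table from CSV
#'
#' @param path CSV with columns \code{intensity_dB}, \code{responded},
#'   \code{latency_ms} and optionally \code{animal}.
#' @return Data frame of trials.
#' @export
read_trials_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("intensity_dB", "responded", "latency_ms")
  if (!all(req %in% names(tr))) {
    stop("trial table must have columns ", paste(req, collapse = ", "))
  }
  tr$responded <- as.logical(tr$responded)
  tr
}

#' Read a field-potential trace from CSV
#'
#' Accepts either a two-column file (\code{t_s}, \code{mV}), from which the
#' sample rate is inferred, or a single-column file (\code{mV}) with the
#' sample rate given explicitly.
#'
#' @param path CSV path.
#' @param sample_rate_hz required for single-column input.
#' @return A [field_potential_trace()].
#' @export
read_field_potential_csv <- function(path, sample_rate_hz = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("t_s", "mV") %in% names(d))) {
    dt <- diff(d$t_s)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
      stop("time column must be uniformly increasing")
    }
    field_potential_trace(d$mV, 1 / mean(dt))
  } else if ("mV" %in% names(d)) {
    if (is.null(sample_rate_hz)) {
      stop("single-column input needs an explicit sample_rate_hz")
    }
    field_potential_trace(d$mV, sample_rate_hz)
  } else {
    stop("expected columns t_s,mV or mV")
  }
}

#' Read a Ct record table from CSV
#'
#' @param path CSV with columns \code{sample_id}, \code{group}, \code{gene},
#'   \code{replicate}, \code{Ct}.
#' @return Validated data frame of Ct records.
#' @export
read_ct_csv <- function(path) {
  check_ct_records(utils::read.csv(path, stringsAsFactors = FALSE))
}
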