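#' Primer efficiencies of the qPCR assay panel
#'
#' Efficiencies (percent) of the validated primer pairs for the reference
#' gene actb2 and the dopamine-signaling genes, as determined from standard
#' dilution curves. Values above 100% are commonly reported artifacts of the
#' standard-curve method and are retained as printed.
#'
#' @return Data frame with columns \code{gene}, \code{efficiency_percent},
#'   \code{amplification_factor} (= 1 + efficiency_percent / 100).
#' @export
primer_efficiencies <- function() {
  path <- system.file("extdata", "primer_efficiencies.csv",
                      package = "mcescape", mustWork = TRUE)
  # >100% efficiencies in the shipped panel are known standard-curve
  # artifacts; the warning is for user-supplied tables.
  suppressWarnings(read_efficiency_csv(path))
}

#' Read a primer-efficiency table
#'
#' @param path CSV with columns \code{gene}, \code{efficiency_percent}.
#' @return Data frame with an added \code{amplification_factor} column;
#'   factors above 2 (efficiency > 100%) trigger a warning, factors outside
#'   (1, 2.5] are rejected.
#' @export
read_efficiency_csv <- function(path) {
  eff <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "efficiency_percent") %in% names(eff))) {
    stop("efficiency table must have columns gene, efficiency_percent")
  }
  if (any(!is.finite(eff$efficiency_percent)) || any(eff$efficiency_percent <= 0)) {
    stop("efficiencies must be positive percentages")
  }
  eff$amplification_factor <- 1 + eff$efficiency_percent / 100
  if (any(eff$amplification_factor > 2.5)) {
    stop("amplification factor above 2.5; check the efficiency table")
  }
  if (any(eff$amplification_factor > 2)) {
    warning("efficiency above 100% for: ",
            paste(eff$gene[eff$amplification_factor > 2], collapse = ", "))
  }
  eff
}

check_ct_records <- function(records) {
  req <- c("sample_id", "group", "gene", "replicate", "Ct")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("Ct records must be a data frame with columns ",
         paste(req, collapse = ", "))
  }
  if (any(!is.finite(records$Ct)) || any(records$Ct <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  invisible(records)
}

#' Per-sample delta-Ct against the reference gene
#'
#' Technical replicates are averaged per sample and gene first; then
#' delta-Ct = Ct(gene) - Ct(reference) within each sample.
#'
#' @param records data frame of Ct measurements with columns
#'   \code{sample_id}, \code{group}, \code{gene}, \code{replicate},
#'   \code{Ct}.
#' @param reference_gene the internal housekeeping gene (default "actb2").
#' @return Data frame with one row per sample x gene: \code{sample_id},
#'   \code{group}, \code{gene}, \code{ct_gene} (replicate-averaged),
#'   \code{ct_ref}, \code{delta_ct}.
#' @export
delta_ct <- function(records, reference_gene = "actb2") {
  check_ct_records(records)
  if (!reference_gene %in% records$gene) {
    stop("reference gene '", reference_gene, "' absent from the records")
  }
  avg <- stats::aggregate(Ct ~ sample_id + group + gene, data = records,
                          FUN = mean)
  ref <- avg[avg$gene == reference_gene, c("sample_id", "Ct")]
  names(ref)[2] <- "ct_ref"
  missing_ref <- setdiff(unique(avg$sample_id), ref$sample_id)
  if (length(missing_ref) > 0) {
    stop("no reference-gene Ct for sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  out <- merge(avg, ref, by = "sample_id")
  names(out)[names(out) == "Ct"] <- "ct_gene"
  out$delta_ct <- out$ct_gene - out$ct_ref
  out[order(out$gene, out$group, out$sample_id),
      c("sample_id", "group", "gene", "ct_gene", "ct_ref", "delta_ct")]
}

#' Group delta-delta-Ct against the control group
#'
#' For each gene and group, delta-delta-Ct is the group mean delta-Ct minus
#' the control-group mean delta-Ct (the control's own value is 0 by
#' construction). The raw group Ct differences of the target and reference
#' genes are carried along for efficiency-corrected quantification.
#'
#' @param dcts output of [delta_ct()].
#' @param control_group the normalization group (default "isolate").
#' @return Data frame with one row per gene x group: \code{gene},
#'   \code{group}, \code{n}, \code{mean_delta_ct}, \code{delta_delta_ct},
#'   \code{d_ct_gene} and \code{d_ct_ref} (group-minus-control differences of
#'   the raw gene and reference Ct means).
#' @export
delta_delta_ct <- function(dcts, control_group = "isolate") {
  stopifnot(is.data.frame(dcts),
            all(c("group", "gene", "delta_ct", "ct_gene", "ct_ref") %in% names(dcts)))
  if (!control_group %in% dcts$group) {
    stop("control group '", control_group, "' absent from the data")
  }
  agg <- stats::aggregate(cbind(delta_ct, ct_gene, ct_ref) ~ gene + group,
                          data = dcts, FUN = mean)
  n <- stats::aggregate(sample_id ~ gene + group, data = dcts,
                        FUN = function(x) length(unique(x)))
  names(n)[3] <- "n"
  agg <- merge(agg, n, by = c("gene", "group"))
  ctrl <- agg[agg$group == control_group,
              c("gene", "delta_ct", "ct_gene", "ct_ref")]
  names(ctrl) <- c("gene", "dct_ctrl", "ctg_ctrl", "ctr_ctrl")
  miss <- setdiff(unique(agg$gene), ctrl$gene)
  if (length(miss) > 0) {
    stop("no control-group measurements for gene(s): ",
         paste(miss, collapse = ", "))
  }
  out <- merge(agg, ctrl, by = "gene")
  out$mean_delta_ct <- out$delta_ct
  out$delta_delta_ct <- out$delta_ct - out$dct_ctrl
  out$d_ct_gene <- out$ct_gene - out$ctg_ctrl
  out$d_ct_ref <- out$ct_ref - out$ctr_ctrl
  out[order(out$gene, out$group),
      c("gene", "group", "n", "mean_delta_ct", "delta_delta_ct",
        "d_ct_gene", "d_ct_ref")]
}

#' Efficiency-corrected relative expression
#'
#' Converts delta-delta-Ct values to fold changes using the primer
#' amplification factors E = 1 + efficiency/100. The default ratio method
#' corrects target and reference separately (Pfaffl form),
#' \deqn{fold = E_{target}^{-\Delta Ct_{target}} / E_{ref}^{-\Delta Ct_{ref}},}
#' where the exponents are the group-minus-control differences of the raw Ct
#' means; it collapses to \eqn{E^{-\Delta\Delta Ct}} when the efficiencies
#' are equal, and to the textbook \eqn{2^{-\Delta\Delta Ct}} when all
#' efficiencies are 100%. \code{method = "ddct"} applies the target's factor
#' to the delta-delta-Ct directly. Fold changes are log2-transformed for
#' reporting.
#'
#' @param ddct output of [delta_delta_ct()].
#' @param efficiencies data frame with \code{gene} and either
#'   \code{amplification_factor} or \code{efficiency_percent} (see
#'   [primer_efficiencies()]).
#' @param reference_gene the housekeeping gene (default "actb2").
#' @param method \code{"pfaffl"} (default) or \code{"ddct"}.
#' @return Data frame with one row per target gene x non-control group:
#'   \code{gene}, \code{group}, \code{delta_delta_ct}, \code{fold_change},
#'   \code{log2_fold_change}.
#' @export
relative_expression <- function(ddct, efficiencies,
                                reference_gene = "actb2",
                                method = c("pfaffl", "ddct")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(ddct),
            all(c("gene", "group", "delta_delta_ct") %in% names(ddct)))
  if (!"amplification_factor" %in% names(efficiencies)) {
    if (!"efficiency_percent" %in% names(efficiencies)) {
      stop("efficiencies need amplification_factor or efficiency_percent")
    }
    efficiencies$amplification_factor <-
      1 + efficiencies$efficiency_percent / 100
  }
  eff <- stats::setNames(efficiencies$amplification_factor, efficiencies$gene)
  targets <- ddct[ddct$gene != reference_gene, , drop = FALSE]
  need <- unique(c(targets$gene, reference_gene))
  miss <- setdiff(need, names(eff))
  if (length(miss) > 0) {
    stop("missing efficiency for gene(s): ", paste(miss, collapse = ", "))
  }
  if (method == "pfaffl") {
    if (!all(c("d_ct_gene", "d_ct_ref") %in% names(targets))) {
      stop("pfaffl method needs d_ct_gene and d_ct_ref from delta_delta_ct()")
    }
    fold <- eff[targets$gene]^(-targets$d_ct_gene) /
      eff[reference_gene]^(-targets$d_ct_ref)
  } else {
    fold <- eff[targets$gene]^(-targets$delta_delta_ct)
  }
  data.frame(gene = targets$gene, group = targets$group,
             delta_delta_ct = targets$delta_delta_ct,
             fold_change = unname(fold),
             log2_fold_change = unname(log2(fold)))
}

#' Full comparative delta-delta-Ct pipeline
#'
#' Convenience wrapper: replicate averaging, delta-Ct against the reference
#' gene, delta-delta-Ct against the control group, efficiency-corrected fold
#' change and log2 transform.
#'
#' @inheritParams delta_ct
#' @inheritParams relative_expression
#' @param control_group the normalization group (default "isolate").
#' @return See [relative_expression()].
#' @export
analyze_qpcr <- function(records, efficiencies = primer_efficiencies(),
                         reference_gene = "actb2", control_group = "isolate",
                         method = c("pfaffl", "ddct")) {
  dcts <- delta_ct(records, reference_gene)
  ddct <- delta_delta_ct(dcts, control_group)
  out <- relative_expression(ddct[ddct$group != control_group, , drop = FALSE],
                             efficiencies, reference_gene, method)
  out
}
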