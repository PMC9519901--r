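#' Run the full reference-gene analysis pipeline
#'
#' Orchestrates QC, optional efficiency estimation, stability analysis,
#' optimal reference-count determination, and fold-change validation as one
#' reproducible run. Input tables may be given as file paths (CSV/TSV) or
#' in-memory objects. The report records every intermediate table and the
#' exact thresholds applied; timestamps live in a separate field so two runs
#' with identical inputs produce identical analysis content.
#'
#' The reference panel used for validation is the top
#' \code{max(min_references, recommended_n)} aggregate-ranked candidates:
#' even when the pairwise-variation profile says two genes suffice, three
#' are used by default to increase resolution and robustness, a common
#' practical override that is configurable via \code{min_references}.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{ct}{CT table path or \code{\link{ct_dataset}} (required).}
#'     \item{layout}{\code{"long"} or \code{"wide"} (for file input).}
#'     \item{meta}{sample-metadata path or data frame.}
#'     \item{assays}{assay table path or data frame (\code{gene, role,
#'       efficiency} or \code{efficiency_percent}).}
#'     \item{dilutions}{optional dilution-series CSV
#'       (\code{gene, input_pg, replicate, ct}) for efficiency estimation.}
#'     \item{targets}{target gene symbols; default: assay rows with role
#'       \code{"target"}.}
#'     \item{calibrator_group}{label of the calibrator group (default
#'       \code{"young"}).}
#'     \item{sd_threshold, rin_min, purity_range, m_cutoff, v_cutoff,
#'       alpha, min_references}{thresholds; defaults 0.2 cycles, 9.0,
#'       c(2.0, 2.2), 1.0, 0.15, 0.05, 3.}
#'     \item{use_efficiency}{efficiency-correct the stability-stage relative
#'       quantities (default FALSE; validation always uses assay
#'       efficiencies when available).}
#'     \item{out_dir}{optional output directory for \code{report.json} and
#'       CSV mirrors of every table.}
#'   }
#' @return object of class \code{refstab_report}: a versioned list with
#'   elements \code{schema_version}, \code{thresholds}, \code{qc},
#'   \code{efficiency}, \code{stability}, \code{pairwise_variation},
#'   \code{recommended_n}, \code{selected_references}, \code{fold_changes},
#'   \code{warnings}, \code{generated} (timestamp).
#' @examples
#' sim <- simulate_ct_dataset(sim_config(seed = 3))
#' rep <- run_pipeline(list(ct = sim$dataset, assays = sim$assays))
#' rep$selected_references
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("[config] config must be a list or YAML path")
  if (is.null(config$ct)) stop("[config] a CT table ('ct') is required")

  thresholds <- list(
    sd_threshold = config$sd_threshold %||% 0.2,
    rin_min = config$rin_min %||% 9.0,
    purity_range = config$purity_range %||% c(2.0, 2.2),
    m_cutoff = config$m_cutoff %||% 1.0,
    v_cutoff = config$v_cutoff %||% 0.15,
    alpha = config$alpha %||% 0.05,
    min_references = config$min_references %||% 3
  )
  if (any(unlist(thresholds) <= 0)) stop("[config] thresholds must be positive")
  warnings_seen <- character(0)
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("[", stage, "] ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, paste0("[", stage, "] ",
                                                  conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  # --- load -----------------------------------------------------------------
  meta <- collect({
    if (is.character(config$meta)) read_sample_meta(config$meta) else config$meta
  }, "load")
  ds <- collect({
    if (inherits(config$ct, "ct_dataset")) config$ct
    else read_ct_table(config$ct, layout = config$layout %||% "long",
                       samples = meta,
                       sd_threshold = thresholds$sd_threshold)
  }, "load")
  assays <- collect({
    if (is.character(config$assays)) read_assay_table(config$assays)
    else config$assays
  }, "load")

  candidates <- config$references %||%
    (if (!is.null(assays)) assays$gene[assays$role == "reference"] else ds$genes)
  targets <- config$targets %||%
    (if (!is.null(assays)) assays$gene[assays$role == "target"] else character(0))
  if (length(intersect(targets, candidates)))
    stop("[config] targets and reference candidates must not overlap")

  # --- qc -------------------------------------------------------------------
  qc <- collect(qc_filter(ds, rin_min = thresholds$rin_min,
                          purity_range = thresholds$purity_range), "qc")
  ds <- qc$dataset

  # --- efficiency -----------------------------------------------------------
  eff_table <- NULL
  if (!is.null(config$dilutions)) {
    eff_table <- collect({
      dil <- if (is.character(config$dilutions))
        utils::read.csv(config$dilutions, stringsAsFactors = FALSE)
      else config$dilutions
      do.call(rbind, lapply(split(dil, dil$gene), function(d) {
        fit <- fit_standard_curve(d)
        data.frame(gene = d$gene[1], slope = fit$slope,
                   intercept = fit$intercept, efficiency = fit$efficiency,
                   r_squared = fit$r_squared, stringsAsFactors = FALSE)
      }))
    }, "efficiency")
  }
  efficiencies <- NULL
  if (!is.null(assays) && "efficiency" %in% names(assays))
    efficiencies <- stats::setNames(assays$efficiency, assays$gene)
  if (!is.null(eff_table)) {
    # standard-curve estimates override assay-table values gene by gene
    curve_eff <- stats::setNames(eff_table$efficiency, eff_table$gene)
    efficiencies <- efficiencies %||% stats::setNames(numeric(0), character(0))
    efficiencies[names(curve_eff)] <- curve_eff
  }

  # --- stability ------------------------------------------------------------
  cand_present <- intersect(candidates, ds$genes)
  fit <- collect({
    sub <- ct_dataset(ds$ct[, cand_present, drop = FALSE],
                      samples = ds$samples)
    ref_stability(sub, efficiencies = efficiencies,
                  use_efficiency = isTRUE(config$use_efficiency),
                  v_cutoff = thresholds$v_cutoff)
  }, "stability")
  n_use <- max(thresholds$min_references, fit$recommended_n)
  n_use <- min(n_use, nrow(fit$table))
  selected <- fit$table$gene[seq_len(n_use)]

  # --- validation -----------------------------------------------------------
  fold_changes <- NULL
  fc_objects <- list()
  targets_present <- intersect(targets, ds$genes)
  if (length(targets_present) && !is.null(ds$samples$group)) {
    calib <- config$calibrator_group %||% "young"
    fold_changes <- collect({
      do.call(rbind, lapply(targets_present, function(tg) {
        fc <- group_fold_change(ds, tg, selected, calib,
                                efficiencies = efficiencies)
        fc_objects[[tg]] <<- fc
        data.frame(target = tg, fold_change = fc$fold_change,
                   p_value = fc$p_value,
                   significant = fc$p_value < thresholds$alpha,
                   stringsAsFactors = FALSE)
      }))
    }, "validation")
  }

  report <- structure(list(
    schema_version = "1.0",
    thresholds = thresholds,
    qc = qc$report,
    efficiency = eff_table,
    describe = describe_ct(ds),
    stability = fit$table,
    pairwise_variation = as.list(fit$pairwise_variation$v),
    recommended_n = fit$recommended_n,
    selected_references = selected,
    fold_changes = fold_changes,
    fold_change_details = fc_objects,
    warnings = warnings_seen,
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "refstab_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, config$out_dir)
  }
  report
}

write_report <- function(report, dir) {
  body <- unclass(report)
  body$fold_change_details <- NULL
  jsonlite::write_json(body, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.csv(report$stability, file.path(dir, "stability_report.csv"),
                   row.names = FALSE)
  pv <- data.frame(comparison = names(report$pairwise_variation),
                   v = unlist(report$pairwise_variation))
  utils::write.csv(pv, file.path(dir, "pairwise_variation.csv"),
                   row.names = FALSE)
  utils::write.csv(report$qc, file.path(dir, "qc_report.csv"),
                   row.names = FALSE)
  if (!is.null(report$fold_changes))
    utils::write.csv(report$fold_changes, file.path(dir, "fold_changes.csv"),
                     row.names = FALSE)
  if (!is.null(report$efficiency))
    utils::write.csv(report$efficiency, file.path(dir, "efficiency.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @export
print.refstab_report <- function(x, ...) {
  cat("qPCR reference-gene pipeline report (schema", x$schema_version, ")\n")
  cat("  samples retained:", sum(x$qc$retained), "/", nrow(x$qc), "\n")
  cat("  recommended n references:", x$recommended_n,
      "| used:", length(x$selected_references), "\n")
  cat("  selected references:",
      paste(x$selected_references, collapse = ", "), "\n")
  if (!is.null(x$fold_changes)) {
    cat("  fold changes:\n")
    fc <- x$fold_changes
    for (i in seq_len(nrow(fc)))
      cat(sprintf("    %-6s %6.3f  p=%.4g%s\n", fc$target[i],
                  fc$fold_change[i], fc$p_value[i],
                  if (fc$significant[i]) " *" else ""))
  }
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "(see $warnings)\n")
  invisible(x)
}
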