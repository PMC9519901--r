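#' Efficiency-corrected fold variation for one sample
#'
#' Computes the fold variation
#' \deqn{FV = (1+E_T)^{\Delta CT(T)} / (1+E_R)^{\Delta CT(R)}}
#' where \eqn{\Delta CT = CT_{calibrator} - CT_{sample}} for the target (T)
#' and each reference (R). With several references the denominator is the
#' geometric mean of the per-reference factors, i.e. normalization against
#' the geometric mean abundance of the reference panel. With one reference
#' and E = 1 throughout this reduces to the classic \eqn{2^{-\Delta\Delta CT}}.
#'
#' @param ct_target_cal calibrator CT of the target gene.
#' @param ct_target sample CT of the target gene.
#' @param ct_refs_cal calibrator CTs of the reference genes (vector).
#' @param ct_refs sample CTs of the reference genes, same order.
#' @param e_target fractional amplification efficiency of the target assay.
#' @param e_refs per-reference fractional efficiencies (recycled).
#' @return positive scalar fold variation.
#' @examples
#' fold_variation(25, 24, 20, 20)   # one cycle earlier -> 2-fold
#' @export
fold_variation <- function(ct_target_cal, ct_target, ct_refs_cal, ct_refs,
                           e_target = 1, e_refs = 1) {
  if (length(ct_refs) == 0 || length(ct_refs_cal) == 0)
    stop("at least one reference gene is required")
  if (length(ct_refs_cal) != length(ct_refs))
    stop("calibrator and sample reference CT vectors differ in length")
  e_refs <- rep_len(e_refs, length(ct_refs))
  cts <- c(ct_target_cal, ct_target, ct_refs_cal, ct_refs)
  if (any(!is.finite(cts))) stop("all CT values must be finite")
  if (any(c(e_target, e_refs) <= 0)) stop("efficiencies must be > 0")
  dct_t <- ct_target_cal - ct_target
  dct_r <- ct_refs_cal - ct_refs
  num <- (1 + e_target)^dct_t
  den <- geo_mean((1 + e_refs)^dct_r)
  num / den
}

#' Two-group comparison of normalized quantities
#'
#' Two-sided unpaired Student's t-test (pooled variance), by default on the
#' log2 scale since normalized fold data are approximately log-normal. The
#' returned p-value is unadjusted; p < 0.05 is the conventional
#' significance level.
#'
#' @param values_a,values_b positive normalized quantities, >= 2 per group.
#' @param log perform the test on log2-transformed values (default).
#' @return two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b, log = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  if (log) {
    if (any(c(values_a, values_b) <= 0))
      stop("log-scale test requires positive values")
    values_a <- log2(values_a)
    values_b <- log2(values_b)
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
    stop("zero within-group variance in both groups; t-test undefined")
  stats::t.test(values_a, values_b, var.equal = TRUE)$p.value
}

#' Group fold change of a target gene by multi-reference delta-delta-CT
#'
#' The validation stage: for each sample, the fold variation of the target
#' relative to the calibrator group is computed with
#' \code{\link{fold_variation}}, using the per-gene mean CT of the
#' calibrator group as the calibrator CTs and normalizing against the
#' geometric mean of the reference genes. Quantities are then rescaled so
#' the calibrator-group mean is exactly 1; the reported fold change is the
#' mean normalized quantity of the non-calibrator group, with per-group SEM
#' on the linear scale and a p-value from \code{\link{compare_groups}}.
#'
#' @param ds a \code{\link{ct_dataset}} whose metadata has a \code{group}
#'   column with exactly two levels.
#' @param target target gene symbol.
#' @param references character vector of reference gene symbols (must not
#'   contain the target).
#' @param calibrator_group group label whose mean is set to 1.
#' @param efficiencies optional named fractional efficiencies or assay
#'   table covering target and references; default E = 1.
#' @param log_scale_test run the t-test on log2 quantities (default TRUE).
#' @return object of class \code{fold_change}: list with \code{target},
#'   \code{references}, \code{calibrator_group}, \code{samples} (data frame
#'   \code{sample_id, group, nrq}), \code{group_stats} (mean, sem, n per
#'   group), \code{fold_change}, \code{p_value}.
#' @export
group_fold_change <- function(ds, target, references, calibrator_group,
                              efficiencies = NULL, log_scale_test = TRUE) {
  stopifnot(inherits(ds, "ct_dataset"))
  if (target %in% references)
    stop("reference list must not contain the target gene")
  groups <- ds$samples$group
  if (is.null(groups)) stop("dataset metadata must contain a 'group' column")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("fold-change analysis expects exactly two groups")
  if (!calibrator_group %in% levels(groups))
    stop("calibrator group '", calibrator_group, "' not present")
  genes <- c(target, references)
  m <- ct_matrix(ds)
  miss <- setdiff(genes, colnames(m))
  if (length(miss))
    stop("gene(s) absent from the CT matrix: ", paste(miss, collapse = ", "))
  m <- m[, genes, drop = FALSE]
  eff <- resolve_efficiencies(efficiencies, genes)

  cal_idx <- groups == calibrator_group
  if (!any(cal_idx) || all(cal_idx)) stop("both groups must be non-empty")
  cal_ct <- colMeans(m[cal_idx, , drop = FALSE])

  fv <- vapply(seq_len(nrow(m)), function(s) {
    fold_variation(cal_ct[target], m[s, target],
                   cal_ct[references], m[s, references],
                   e_target = eff[target], e_refs = eff[references])
  }, numeric(1))
  nrq <- fv / mean(fv[cal_idx])        # calibrator-group mean exactly 1

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  gs <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- nrq[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sem = sem(v),
               stringsAsFactors = FALSE)
  }))
  other <- setdiff(levels(groups), calibrator_group)
  p <- compare_groups(nrq[cal_idx], nrq[!cal_idx], log = log_scale_test)

  structure(list(
    target = target, references = references,
    calibrator_group = calibrator_group,
    samples = data.frame(sample_id = rownames(m), group = as.character(groups),
                         nrq = nrq, stringsAsFactors = FALSE),
    group_stats = gs,
    fold_change = gs$mean[gs$group == other],
    p_value = p
  ), class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat("Fold change:", x$target, "vs references",
      paste(x$references, collapse = "+"), "\n")
  cat("  calibrator group:", x$calibrator_group, "(mean set to 1)\n")
  gs <- x$group_stats
  for (i in seq_len(nrow(gs)))
    cat(sprintf("  %-8s n=%-3d mean %.3f +/- %.3f (SEM)\n",
                gs$group[i], gs$n[i], gs$mean[i], gs$sem[i]))
  cat(sprintf("  fold change %.3f, p = %.4g%s\n", x$fold_change, x$p_value,
              if (x$p_value < 0.05) " (*)" else ""))
  invisible(x)
}
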