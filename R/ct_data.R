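#' CT dataset container
#'
#' Bundles a sample-by-gene matrix of (replicate-aggregated) cycle-threshold
#' values with per-sample metadata and, optionally, the underlying
#' replicate-level measurements. The matrix may contain \code{NA} where
#' replicate QC failed; analyses that need a complete matrix use
#' \code{\link{ct_matrix}} which errors listing the missing cells.
#'
#' @param ct numeric matrix of mean CT values, samples in rows (rownames =
#'   sample ids), genes in columns (colnames = gene symbols). Values are PCR
#'   cycles, typically 15--40.
#' @param samples data frame of per-sample metadata with at least a
#'   \code{sample_id} column; optional columns \code{group},
#'   \code{age_years}, \code{rin}, \code{a260_280}, \code{a260_230}. Defaults
#'   to a bare table of the matrix rownames.
#' @param replicates optional long data frame of replicate-level values with
#'   columns \code{sample_id, gene, replicate, ct}.
#' @param valid logical matrix flagging cells whose replicate set passed QC;
#'   defaults to \code{!is.na(ct)}.
#' @return an object of class \code{ct_dataset}: a list with elements
#'   \code{ct}, \code{samples}, \code{replicates}, \code{valid}, \code{genes}.
#' @export
ct_dataset <- function(ct, samples = NULL, replicates = NULL, valid = NULL) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("CT matrix must have sample rownames and gene colnames")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate sample ids in CT matrix")
  if (anyDuplicated(colnames(ct)))
    stop("duplicate gene symbols in CT matrix")
  if (any(ct[!is.na(ct)] <= 0))
    stop("CT values must be positive (cycles)")
  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(ct), stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(samples))
    stop("sample metadata must contain a 'sample_id' column")
  if (!all(rownames(ct) %in% samples$sample_id))
    stop("sample ids in measurements must be a subset of the metadata table")
  if ("rin" %in% names(samples)) {
    bad <- !is.na(samples$rin) & (samples$rin < 1 | samples$rin > 10)
    if (any(bad)) stop("RIN values must lie in [1, 10]")
  }
  samples <- samples[match(rownames(ct), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(valid)) valid <- !is.na(ct)
  structure(
    list(ct = ct, samples = samples, replicates = replicates,
         valid = valid, genes = colnames(ct)),
    class = "ct_dataset"
  )
}

#' @export
print.ct_dataset <- function(x, ...) {
  cat("CT dataset:", nrow(x$ct), "samples x", ncol(x$ct), "genes\n")
  if (!is.null(x$samples$group)) {
    tab <- table(x$samples$group)
    cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  }
  n_missing <- sum(is.na(x$ct))
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  if (n_missing > 0) {
    cat("  incomplete:", n_missing, "cell(s) failed replicate QC\n")
  } else {
    cat("  complete CT matrix (all cells valid)\n")
  }
  if (!is.null(x$replicates))
    cat("  replicate-level values retained (", nrow(x$replicates), " rows)\n", sep = "")
  invisible(x)
}

#' Extract the complete CT matrix from a dataset
#'
#' @param x a \code{ct_dataset} or a numeric matrix (returned as-is after
#'   checks).
#' @param complete require every sample-by-gene cell to hold a valid mean CT;
#'   if any cell is missing, the error names them.
#' @return numeric matrix, samples in rows.
#' @export
ct_matrix <- function(x, complete = TRUE) {
  m <- if (inherits(x, "ct_dataset")) x$ct else as.matrix(x)
  storage.mode(m) <- "double"
  if (complete && anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    cells <- paste0(rownames(m)[idx[, 1]] %||% idx[, 1], "/",
                    colnames(m)[idx[, 2]] %||% idx[, 2])
    stop("CT matrix is incomplete; missing cells (sample/gene): ",
         paste(utils::head(cells, 10), collapse = ", "),
         if (length(cells) > 10) sprintf(" ... and %d more", length(cells) - 10))
  }
  m
}

#' Aggregate technical replicates of one CT measurement
#'
#' Implements the quadruplicate QC rule: the mean CT is the average of all
#' replicates when their standard deviation is below \code{sd_threshold}
#' (default 0.2 cycles). Otherwise the single outlying replicate -- the one
#' with the largest absolute deviation from the median, later index winning
#' ties -- is removed, and the remaining values are accepted when at least
#' \code{min_replicates} survive and their SD is below the threshold. A set
#' that cannot be made compliant by this single removal is flagged invalid.
#'
#' @param values numeric vector of replicate CT values (>= 2, finite, > 0).
#' @param sd_threshold maximum admissible replicate SD, in cycles.
#' @param min_replicates minimum surviving replicates after outlier removal.
#' @return list with \code{mean_ct} (NA when invalid), \code{valid},
#'   \code{used} (indices kept), \code{removed} (index dropped, if any).
#' @examples
#' aggregate_replicates(c(20.10, 20.15, 20.05, 20.12))          # accepted
#' aggregate_replicates(c(20.10, 20.15, 20.05, 22.00))          # outlier dropped
#' aggregate_replicates(c(20.0, 21.0, 22.0, 23.0))$valid        # FALSE
#' @export
aggregate_replicates <- function(values, sd_threshold = 0.2, min_replicates = 3) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("at least two replicate CT values are required")
  if (any(!is.finite(values) | values <= 0))
    stop("replicate CT values must be finite and positive")
  if (stats::sd(values) < sd_threshold) {
    return(list(mean_ct = mean(values), valid = TRUE,
                used = seq_along(values), removed = integer(0)))
  }
  dev <- abs(values - stats::median(values))
  drop <- max(which(dev == max(dev)))   # tie -> later replicate index
  kept <- values[-drop]
  if (length(kept) >= min_replicates && stats::sd(kept) < sd_threshold) {
    list(mean_ct = mean(kept), valid = TRUE,
         used = setdiff(seq_along(values), drop), removed = drop)
  } else {
    list(mean_ct = NA_real_, valid = FALSE, used = integer(0), removed = drop)
  }
}

coerce_numeric_col <- function(x, what, rows) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad))
    stop("non-numeric ", what, " at ", rows[bad[1]])
  out
}

#' Read a CT table from CSV/TSV
#'
#' Long layout: columns \code{sample_id, gene, replicate, ct}, one row per
#' technical replicate; replicates are aggregated with
#' \code{\link{aggregate_replicates}}. Wide layout: one row per sample, first
#' column \code{sample_id}, one column per gene holding already
#' replicate-aggregated mean CTs.
#'
#' @param path file path (comma- or tab-separated, header required).
#' @param layout \code{"long"} or \code{"wide"}.
#' @param samples optional sample-metadata data frame or CSV path
#'   (\code{sample_id, group, age_years, rin, a260_280, a260_230}).
#' @param sd_threshold,min_replicates passed to
#'   \code{\link{aggregate_replicates}} (long layout only).
#' @return a \code{\link{ct_dataset}}.
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), samples = NULL,
                          sd_threshold = 0.2, min_replicates = 3) {
  layout <- match.arg(layout)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(samples)) samples <- read_sample_meta(samples)

  if (layout == "long") {
    need <- c("sample_id", "gene", "replicate", "ct")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("long CT table is missing column(s): ", paste(miss, collapse = ", "))
    rows <- sprintf("row %d (sample %s, gene %s)",
                    seq_len(nrow(df)), df$sample_id, df$gene)
    df$ct <- coerce_numeric_col(df$ct, "CT value", rows)
    if (anyNA(df$ct)) {
      i <- which(is.na(df$ct))[1]
      stop("missing CT value at ", rows[i])
    }
    key <- paste(df$sample_id, df$gene, df$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1]
      stop("duplicate (sample, gene, replicate) at ", rows[i])
    }
    samples_ids <- unique(df$sample_id)
    genes <- unique(df$gene)
    ct <- matrix(NA_real_, length(samples_ids), length(genes),
                 dimnames = list(samples_ids, genes))
    valid <- matrix(FALSE, length(samples_ids), length(genes),
                    dimnames = list(samples_ids, genes))
    for (cell in split(df, list(df$sample_id, df$gene), drop = TRUE)) {
      agg <- aggregate_replicates(cell$ct, sd_threshold, min_replicates)
      ct[cell$sample_id[1], cell$gene[1]] <- agg$mean_ct
      valid[cell$sample_id[1], cell$gene[1]] <- agg$valid
    }
    ct_dataset(ct, samples = samples, replicates = df, valid = valid)
  } else {
    if (names(df)[1] != "sample_id")
      stop("wide CT table must have 'sample_id' as its first column")
    if (ncol(df) < 2) stop("wide CT table has no gene columns")
    genes <- names(df)[-1]
    for (g in genes) {
      rows <- sprintf("row %d (sample %s, gene %s)",
                      seq_len(nrow(df)), df$sample_id, g)
      df[[g]] <- coerce_numeric_col(df[[g]], "CT value", rows)
      if (anyNA(df[[g]])) {
        i <- which(is.na(df[[g]]))[1]
        stop("missing CT value at ", rows[i])
      }
    }
    ct <- as.matrix(df[, genes, drop = FALSE])
    rownames(ct) <- df$sample_id
    ct_dataset(ct, samples = samples)
  }
}

#' Read sample metadata / assay tables
#'
#' @param path CSV with columns \code{sample_id, group, age_years, rin,
#'   a260_280, a260_230} (metadata) or \code{gene, role,
#'   efficiency_percent, r_squared, amplicon_bp} (assays). Only
#'   \code{sample_id} resp. \code{gene, role} are required.
#' @return data frame; for assays, an extra \code{efficiency} column holds
#'   the fractional efficiency (\code{efficiency_percent / 100}).
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("sample metadata must contain a 'sample_id' column")
  df
}

#' @rdname read_sample_meta
#' @export
read_assay_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("assay table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$role %in% c("reference", "target")))
    stop("assay role must be 'reference' or 'target'")
  if ("efficiency_percent" %in% names(df))
    df$efficiency <- efficiency_from_percent(df$efficiency_percent)
  df
}

#' Filter samples on RNA quality metadata
#'
#' Excludes samples whose RNA Integrity Number falls below \code{rin_min} or
#' whose absorbance ratios (A260/A280, A260/A230) fall outside
#' \code{purity_range}. Thresholds are only applied to metadata that is
#' present: samples with absent metadata pass with a warning, since quality
#' screening may have happened upstream of the CT table. CT values are never
#' altered, only sample membership.
#'
#' @param ds a \code{\link{ct_dataset}}.
#' @param rin_min minimum admissible RIN (1--10 scale).
#' @param purity_range admissible interval for both absorbance ratios.
#' @return list with \code{dataset} (filtered \code{ct_dataset}) and
#'   \code{report} (data frame \code{sample_id, retained, reason}).
#' @export
qc_filter <- function(ds, rin_min = 9.0, purity_range = c(2.0, 2.2)) {
  stopifnot(inherits(ds, "ct_dataset"))
  meta <- ds$samples
  ids <- rownames(ds$ct)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  reason <- character(length(ids))
  retained <- rep(TRUE, length(ids))
  has_any <- FALSE
  get_col <- function(col) if (col %in% names(meta)) meta[[col]] else rep(NA_real_, length(ids))
  rin <- get_col("rin"); r1 <- get_col("a260_280"); r2 <- get_col("a260_230")
  for (i in seq_along(ids)) {
    fails <- character(0)
    if (!is.na(rin[i]) && rin[i] < rin_min)
      fails <- c(fails, "RIN below threshold")
    if (!is.na(r1[i]) && (r1[i] < purity_range[1] || r1[i] > purity_range[2]))
      fails <- c(fails, "A260/A280 outside purity range")
    if (!is.na(r2[i]) && (r2[i] < purity_range[1] || r2[i] > purity_range[2]))
      fails <- c(fails, "A260/A230 outside purity range")
    if (length(fails)) {
      retained[i] <- FALSE
      reason[i] <- paste(fails, collapse = "; ")
    } else if (all(is.na(c(rin[i], r1[i], r2[i])))) {
      reason[i] <- "no QC metadata; retained"
      has_any <- TRUE
    }
  }
  if (has_any)
    warning("sample(s) without QC metadata retained: ",
            paste(ids[reason == "no QC metadata; retained"], collapse = ", "))
  report <- data.frame(sample_id = ids, retained = retained, reason = reason,
                       stringsAsFactors = FALSE)
  keep <- ids[retained]
  out <- ct_dataset(ds$ct[keep, , drop = FALSE],
                    samples = ds$samples[ds$samples$sample_id %in% keep, , drop = FALSE],
                    replicates = if (is.null(ds$replicates)) NULL else
                      ds$replicates[ds$replicates$sample_id %in% keep, , drop = FALSE],
                    valid = ds$valid[keep, , drop = FALSE])
  list(dataset = out, report = report)
}

#' Per-gene descriptive statistics of CT values
#'
#' Returns, per gene, the summary statistics behind a CT box plot: mean,
#' median, sample SD, extremes, quartile hinges (type-7 quantiles), IQR, and
#' whisker bounds (most extreme observed values within 1.5 x IQR of the
#' hinges). Genes are ordered by ascending mean CT, i.e. most abundant first.
#'
#' @param ds a \code{\link{ct_dataset}} with a complete matrix, or a matrix.
#' @return data frame, one row per gene.
#' @export
describe_ct <- function(ds) {
  m <- ct_matrix(ds)
  stats_one <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    c(n = length(x), mean = mean(x), median = q[2], sd = stats::sd(x),
      min = min(x), max = max(x), q1 = q[1], q3 = q[3], iqr = iqr,
      whisker_low = lo, whisker_high = hi)
  }
  out <- t(apply(m, 2, stats_one))
  out <- data.frame(gene = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$mean), , drop = FALSE]
}
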