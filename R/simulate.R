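#' Simulation configuration for a two-group qPCR study
#'
#' Defaults emulate a two-group reference-gene study in red deer antler
#' blood: 8 candidate reference genes plus 3 growth-related target genes,
#' 15 samples (5 young, 10 adult), quadruplicate technical replicates,
#' per-gene baseline CTs spanning ~18--32 cycles (B2M most abundant, G6PD
#' least), a shared per-sample loading factor, per-gene stability noise
#' increasing from B2M (most stable) to GAPDH (least), and adult-group
#' expression increases on the targets: ~2.5-fold for ANXA2, ~2.4-fold for
#' APOD (CT drops of 1.35 and 1.25 cycles) and ~23% for TPM1 (0.30 cycles).
#' Assay efficiencies default to realistic per-gene values in the
#' 95--102% range.
#'
#' @param reference_genes,target_genes gene symbols.
#' @param group_sizes named integer vector of samples per group.
#' @param baseline_ct named per-gene mean CT level, in cycles.
#' @param noise_sd named per-gene biological/technical stability noise SD
#'   (cycles); this is the quantity the stability algorithms rank.
#' @param group_effects list: per non-baseline group, a named vector of CT
#'   shifts (cycles; negative = higher expression). Reference candidates
#'   default to 0 shift.
#' @param loading_sd SD of the shared per-sample loading factor (cycles),
#'   mimicking differences in cDNA input.
#' @param replicate_sd SD of technical replicate noise (cycles).
#' @param replicates technical replicates per reaction.
#' @param efficiencies named per-gene fractional amplification efficiencies.
#' @param outlier_rate probability that a replicate is contaminated by a
#'   heavy shift (for testing the replicate QC rule); default 0.
#' @param outlier_shift mean absolute size of a contaminated replicate's
#'   shift, in cycles.
#' @param truncate_nondetect drop replicate values above 40 cycles as
#'   non-detects (with a warning); default off.
#' @param seed integer seed; fully determines the simulated dataset.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(
    reference_genes = c("B2M", "ACTB", "RPLP0", "SDHA", "PGK1", "GUSB",
                        "G6PD", "GAPDH"),
    target_genes = c("ANXA2", "APOD", "TPM1"),
    group_sizes = c(young = 5, adult = 10),
    baseline_ct = c(B2M = 18, ACTB = 19.5, RPLP0 = 21, SDHA = 25,
                    PGK1 = 23.5, GUSB = 27.5, G6PD = 31.5, GAPDH = 24,
                    ANXA2 = 22, APOD = 24.5, TPM1 = 26),
    noise_sd = c(B2M = 0.08, ACTB = 0.15, RPLP0 = 0.22, SDHA = 0.30,
                 PGK1 = 0.38, GUSB = 0.45, G6PD = 0.52, GAPDH = 0.60,
                 ANXA2 = 0.25, APOD = 0.25, TPM1 = 0.25),
    group_effects = list(adult = c(ANXA2 = -1.35, APOD = -1.25, TPM1 = -0.30)),
    loading_sd = 0.5, replicate_sd = 0.05, replicates = 4,
    efficiencies = c(SDHA = 0.987, PGK1 = 0.976, GAPDH = 0.996, ACTB = 0.965,
                     RPLP0 = 1.014, GUSB = 1.001, B2M = 0.987, G6PD = 0.965,
                     APOD = 0.982, TPM1 = 0.953, ANXA2 = 0.975),
    outlier_rate = 0, outlier_shift = 2.5,
    truncate_nondetect = FALSE, seed = 1) {
  genes <- c(reference_genes, target_genes)
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  if (is.null(names(group_sizes)) || any(group_sizes < 1))
    stop("group_sizes must be a named vector of positive counts")
  baseline_ct <- resolve_named(baseline_ct, genes, "baseline_ct")
  noise_sd <- resolve_named(noise_sd, genes, "noise_sd")
  efficiencies <- resolve_named(efficiencies, genes, "efficiencies")
  if (any(noise_sd < 0) || loading_sd < 0 || replicate_sd < 0)
    stop("standard deviations must be >= 0")
  if (replicates < 1) stop("need >= 1 replicate")
  for (g in names(group_effects)) {
    if (!g %in% names(group_sizes)) stop("group_effects names unknown group ", g)
    unknown <- setdiff(names(group_effects[[g]]), genes)
    if (length(unknown))
      stop("group_effects for unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(
    reference_genes = reference_genes, target_genes = target_genes,
    group_sizes = group_sizes, baseline_ct = baseline_ct,
    noise_sd = noise_sd, group_effects = group_effects,
    loading_sd = loading_sd, replicate_sd = replicate_sd,
    replicates = as.integer(replicates), efficiencies = efficiencies,
    outlier_rate = outlier_rate, outlier_shift = outlier_shift,
    truncate_nondetect = truncate_nondetect, seed = as.integer(seed)
  ), class = "sim_config")
}

resolve_named <- function(x, genes, what) {
  if (is.null(names(x))) {
    if (length(x) == 1) return(stats::setNames(rep(x, length(genes)), genes))
    if (length(x) != length(genes))
      stop(what, " must be named or match the gene count")
    return(stats::setNames(x, genes))
  }
  miss <- setdiff(genes, names(x))
  if (length(miss)) stop(what, " missing gene(s): ", paste(miss, collapse = ", "))
  x[genes]
}

#' Simulate a replicate-level CT dataset
#'
#' Generates CT values with the additive structure the stability analysis
#' assumes: \deqn{CT_{sgr} = baseline_g + effect_{g,group(s)} + loading_s +
#' \epsilon_{sg} + \eta_{sgr}} with the loading factor shared across genes
#' within a sample (\eqn{loading_s \sim N(0, loading\_sd^2)}), per-gene
#' stability noise (\eqn{\epsilon_{sg} \sim N(0, noise\_sd_g^2)}) and
#' replicate noise (\eqn{\eta \sim N(0, replicate\_sd^2)}). A single seeded
#' generator drives all draws in a fixed documented order (loading, gene
#' noise, replicate noise, contamination, metadata), so the seed fully
#' determines the output.
#'
#' Replicate sets are aggregated with \code{\link{aggregate_replicates}}
#' when \code{replicates >= 2} (applying the SD < 0.2 QC rule), otherwise
#' the single value is taken as already aggregated.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param seed optional override of \code{cfg$seed}.
#' @return list of class \code{ct_simulation} with \code{dataset} (a
#'   \code{\link{ct_dataset}} including group/age/RIN/absorbance metadata),
#'   \code{assays} (data frame \code{gene, role, efficiency, r_squared}),
#'   and \code{truth} (baselines, noise SDs, effects, true mean CTs, and
#'   the reference genes ordered from most to least stable).
#' @export
simulate_ct_dataset <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed %||% cfg$seed)
  genes <- c(cfg$reference_genes, cfg$target_genes)
  k <- length(genes)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n <- length(groups)
  ids <- unlist(lapply(names(cfg$group_sizes), function(g)
    paste0(toupper(substr(g, 1, 1)), seq_len(cfg$group_sizes[[g]]))),
    use.names = FALSE)

  effects <- matrix(0, n, k, dimnames = list(ids, genes))
  for (g in names(cfg$group_effects)) {
    e <- cfg$group_effects[[g]]
    effects[groups == g, names(e)] <-
      matrix(e, sum(groups == g), length(e), byrow = TRUE)
  }
  true_mean <- sweep(effects, 2, cfg$baseline_ct[genes], "+")

  # draw order: loading -> gene noise -> replicate noise -> contamination -> metadata
  loading <- stats::rnorm(n, 0, cfg$loading_sd)
  gnoise <- matrix(stats::rnorm(n * k, 0, rep(cfg$noise_sd[genes], each = n)),
                   n, k, dimnames = list(ids, genes))
  ct_true <- true_mean + loading + gnoise

  R <- cfg$replicates
  rep_noise <- array(stats::rnorm(n * k * R, 0, cfg$replicate_sd), c(n, k, R))
  ct_rep <- array(ct_true, c(n, k, R)) + rep_noise
  if (cfg$outlier_rate > 0) {
    contaminated <- stats::runif(n * k * R) < cfg$outlier_rate
    shift <- stats::rnorm(sum(contaminated), cfg$outlier_shift, 0.5) *
      sample(c(-1, 1), sum(contaminated), replace = TRUE)
    ct_rep[contaminated] <- ct_rep[contaminated] + shift
  }
  if (cfg$truncate_nondetect && any(ct_rep > 40)) {
    warning(sum(ct_rep > 40), " replicate value(s) above 40 cycles treated as non-detects")
    ct_rep[ct_rep > 40] <- NA_real_
  }

  meta <- data.frame(
    sample_id = ids, group = groups,
    age_years = ifelse(groups == names(cfg$group_sizes)[1],
                       stats::runif(n, 2, 4), stats::runif(n, 4, 6)),
    rin = round(stats::runif(n, 9, 10), 1),
    a260_280 = round(stats::runif(n, 2.0, 2.2), 2),
    a260_230 = round(stats::runif(n, 2.0, 2.2), 2),
    stringsAsFactors = FALSE
  )

  ct <- matrix(NA_real_, n, k, dimnames = list(ids, genes))
  valid <- matrix(TRUE, n, k, dimnames = list(ids, genes))
  long <- NULL
  if (R >= 2) {
    for (s in seq_len(n)) for (g in seq_len(k)) {
      vals <- ct_rep[s, g, ]
      vals <- vals[!is.na(vals)]
      if (length(vals) < 2) {
        valid[s, g] <- FALSE
        next
      }
      agg <- aggregate_replicates(vals)
      ct[s, g] <- agg$mean_ct
      valid[s, g] <- agg$valid
    }
    long <- data.frame(
      sample_id = rep(ids, times = k * R),
      gene = rep(rep(genes, each = n), times = R),
      replicate = rep(seq_len(R), each = n * k),
      ct = as.vector(ct_rep),
      stringsAsFactors = FALSE
    )
  } else {
    ct[] <- ct_rep[, , 1]
    valid[] <- !is.na(ct)
  }

  ds <- ct_dataset(ct, samples = meta, replicates = long, valid = valid)
  assays <- data.frame(
    gene = genes,
    role = c(rep("reference", length(cfg$reference_genes)),
             rep("target", length(cfg$target_genes))),
    efficiency = unname(cfg$efficiencies[genes]),
    r_squared = 0.99,
    stringsAsFactors = FALSE
  )
  ref_sd <- cfg$noise_sd[cfg$reference_genes]
  truth <- list(
    baseline_ct = cfg$baseline_ct, noise_sd = cfg$noise_sd,
    effects = effects, true_mean_ct = true_mean, loading = loading,
    stability_order = names(sort(ref_sd))
  )
  structure(list(dataset = ds, assays = assays, truth = truth, config = cfg),
            class = "ct_simulation")
}

#' @export
print.ct_simulation <- function(x, ...) {
  cat("Simulated qPCR study (seed", x$config$seed, ")\n")
  print(x$dataset)
  cat("  true stability order:",
      paste(x$truth$stability_order, collapse = " > "), "\n")
  invisible(x)
}

#' Simulate a dilution-series standard curve
#'
#' CT values follow \eqn{CT(a) = intercept + slope \cdot \log_{10}(a)} with
#' \eqn{slope = -1/\log_{10}(1+E)}; the intercept is set so the most dilute
#' point sits at \code{top_ct}. The default design is a tenfold series of 5
#' points from 20 pg upwards (20 to 2e5 pg).
#'
#' @param gene gene symbol carried into the output.
#' @param efficiency true fractional amplification efficiency (> 0).
#' @param top_ct CT at the most dilute point, cycles.
#' @param n_points number of dilution points (>= 3).
#' @param fold dilution factor between consecutive points.
#' @param min_pg input amount at the most dilute point, pg.
#' @param noise_sd SD of CT noise added to each observation, cycles.
#' @param replicates observations per dilution point.
#' @return data frame \code{gene, input_pg, replicate, ct} with the true
#'   slope/intercept in \code{attr(, "truth")}.
#' @export
simulate_dilution_series <- function(gene = "ASSAY", efficiency = 1,
                                     top_ct = 30, n_points = 5, fold = 10,
                                     min_pg = 20, noise_sd = 0,
                                     replicates = 1) {
  if (efficiency <= 0) stop("efficiency must be > 0")
  if (n_points < 3) stop("need at least 3 dilution points")
  if (fold <= 1 || min_pg <= 0 || noise_sd < 0) stop("invalid parameters")
  slope <- -1 / log10(1 + efficiency)
  amounts <- min_pg * fold^(0:(n_points - 1))
  intercept <- top_ct - slope * log10(amounts[1])
  df <- expand.grid(replicate = seq_len(replicates), input_pg = amounts)
  df$ct <- intercept + slope * log10(df$input_pg) +
    stats::rnorm(nrow(df), 0, noise_sd)
  out <- data.frame(gene = gene, input_pg = df$input_pg,
                    replicate = df$replicate, ct = df$ct,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             efficiency = efficiency)
  out
}
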