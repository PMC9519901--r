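#' Linear relative quantities from CT values
#'
#' Transforms CT values to linear relative quantities anchored at each
#' gene's lowest CT: \eqn{Q_{sg} = (1+E_g)^{CTmin_g - CT_{sg}}}, so the
#' sample with the lowest CT of a gene has Q = 1 and all other samples a
#' quantity in (0, 1]. With the default E = 1 (perfect doubling) this is the
#' usual \eqn{2^{-\Delta CT}} transform.
#'
#' @param ct a \code{\link{ct_dataset}} or complete CT matrix (samples x genes).
#' @param efficiency \code{NULL} (all E = 1), a named per-gene vector of
#'   fractional efficiencies, or an assay table with columns
#'   \code{gene, efficiency}.
#' @return matrix of relative quantities with the same dimnames as the input.
#' @export
relative_quantities <- function(ct, efficiency = NULL) {
  m <- ct_matrix(ct)
  eff <- resolve_efficiencies(efficiency, colnames(m))
  q <- m
  for (g in seq_len(ncol(m))) {
    q[, g] <- (1 + eff[g])^(min(m[, g]) - m[, g])
  }
  q
}

check_q <- function(q, min_genes = 3, min_samples = 2) {
  q <- as.matrix(q)
  if (ncol(q) < min_genes)
    stop("need at least ", min_genes, " genes")
  if (nrow(q) < min_samples)
    stop("need at least ", min_samples, " samples")
  if (any(!is.finite(q) | q <= 0))
    stop("relative quantities must be finite and > 0")
  q
}

#' geNorm expression-stability value M
#'
#' For each pair of genes (j, k) the pairwise variation \eqn{V_{jk}} is the
#' sample standard deviation (n-1 denominator) over samples of
#' \eqn{\log_2(Q_j / Q_k)}; the M value of gene j is the mean of
#' \eqn{V_{jk}} over all other genes k. Lower M means more stable
#' expression; M < 1.0 is the conventional acceptability cut-off and good
#' reference genes typically show M < 0.5.
#'
#' @param q matrix of positive relative quantities (see
#'   \code{\link{relative_quantities}}), samples x genes, >= 3 genes.
#' @return named per-gene vector of M values.
#' @export
genorm_m <- function(q) {
  q <- check_q(q)
  lq <- log2(q)
  k <- ncol(lq)
  m <- vapply(seq_len(k), function(j) {
    mean(vapply(setdiff(seq_len(k), j),
                function(g) stats::sd(lq[, j] - lq[, g]), numeric(1)))
  }, numeric(1))
  stats::setNames(m, colnames(q))
}

#' geNorm iterative stability ranking
#'
#' Repeatedly recomputes M on the remaining panel and removes the
#' highest-M (least stable) gene until two genes remain. The ranking is the
#' reverse of removal order; the final two genes cannot be ordered by the
#' algorithm and share the averaged rank 1.5. M ties during exclusion are
#' broken by removing the gene appearing later in the current column order,
#' which makes the trace deterministic.
#'
#' @inheritParams genorm_m
#' @return list with \code{ranking} (gene symbols, best first),
#'   \code{rank} (named numeric vector, 1.5 for the tied best pair),
#'   \code{removal_order}, and \code{m_trace} (list of M vectors at each
#'   exclusion step, full panel first).
#' @export
genorm_rank <- function(q) {
  q <- check_q(q)
  remaining <- colnames(q)
  removal <- character(0)
  m_trace <- list()
  while (length(remaining) > 2) {
    m <- genorm_m(q[, remaining, drop = FALSE])
    m_trace[[length(m_trace) + 1L]] <- m
    worst <- remaining[max(which(m == max(m)))]
    removal <- c(removal, worst)
    remaining <- setdiff(remaining, worst)
  }
  ranking <- c(remaining, rev(removal))
  rank <- stats::setNames(c(1.5, 1.5, seq(3, length.out = length(removal))),
                          ranking)
  list(ranking = ranking, rank = rank[colnames(q)],
       removal_order = removal, m_trace = m_trace)
}

#' geNorm pairwise variation V and optimal reference count
#'
#' The normalization factor \eqn{NF_n} of a sample is the geometric mean of
#' the relative quantities of the n top-ranked genes. \eqn{V_{n/n+1}} is the
#' sample standard deviation over samples of \eqn{\log_2(NF_n / NF_{n+1})},
#' computed for n = 2 .. k-1. The recommended reference count is the
#' smallest n whose V falls below the cut-off (0.15 by convention: adding a
#' further gene no longer improves normalization), or k when none does.
#'
#' @inheritParams genorm_m
#' @param ranking gene symbols ordered best to worst; defaults to
#'   \code{\link{genorm_rank}} of \code{q}.
#' @param cutoff V threshold for the recommendation.
#' @return object of class \code{pairwise_variation}: list with \code{v}
#'   (named V_{n/n+1} values), \code{recommended_n}, \code{cutoff},
#'   \code{ranking}.
#' @export
pairwise_variation <- function(q, ranking = NULL, cutoff = 0.15) {
  q <- check_q(q)
  if (is.null(ranking)) ranking <- genorm_rank(q)$ranking
  if (is.list(ranking)) ranking <- ranking$ranking
  if (length(ranking) < 3) stop("ranking must cover at least 3 genes")
  if (!all(ranking %in% colnames(q)))
    stop("ranking contains genes absent from the quantity matrix")
  k <- length(ranking)
  lognf <- vapply(2:k, function(n)
    rowMeans(log2(q[, ranking[1:n], drop = FALSE])), numeric(nrow(q)))
  v <- vapply(seq_len(k - 2), function(i)
    stats::sd(lognf[, i] - lognf[, i + 1]), numeric(1))
  names(v) <- paste0("V", 2:(k - 1), "/", 3:k)
  below <- which(v < cutoff)
  recommended_n <- if (length(below)) below[1] + 1L else k
  structure(list(v = v, recommended_n = as.integer(recommended_n),
                 cutoff = cutoff, ranking = ranking),
            class = "pairwise_variation")
}

#' @export
print.pairwise_variation <- function(x, ...) {
  cat("geNorm pairwise variation (cutoff", x$cutoff, ")\n")
  print(round(x$v, 4))
  cat("recommended number of reference genes:", x$recommended_n, "\n")
  invisible(x)
}

#' NormFinder-style model-based stability value
#'
#' Works on log2-scale expression (-CT; per-gene constants cancel). Each
#' sample is first centred across genes, removing the shared loading factor.
#' Without groups the stability value of a gene is the bias-corrected SD of
#' its centred values: the naive per-gene variance \eqn{v_i} of centred
#' values underestimates the true error variance because the centring mixes
#' in all genes, and the unbiased estimate is
#' \eqn{\hat\sigma^2_i = \frac{k}{k-2}\left(v_i - \frac{\bar v}{k-1}\right)}
#' (truncated at 0), with k the number of genes.
#'
#' With groups, \eqn{\hat\sigma^2_{ig}} is estimated per gene and group as
#' above, and the intergroup difference \eqn{d_{ig}} (deviation of a gene's
#' group mean of centred values from its overall mean across groups) is
#' shrunk towards zero by the factor
#' \eqn{\hat\gamma^2 / (\hat\gamma^2 + \mathrm{var}(d_{ig}))}, where
#' \eqn{\hat\gamma^2} is a method-of-moments estimate of the true
#' between-group variance across genes. The stability value combines both
#' error sources, averaged over groups:
#' \eqn{\rho_i = \mathrm{mean}_g\left(|\tilde d_{ig}| +
#' \sqrt{\hat\sigma^2_{ig}/n_g}\right)}. Smaller values indicate more stable
#' expression; genes whose expression shifts between groups are penalised
#' even when their within-group noise is low.
#'
#' @param ct a \code{\link{ct_dataset}} or complete CT matrix, >= 3 genes.
#' @param groups per-sample group labels (>= 2 samples per group), or
#'   \code{NULL} for the ungrouped estimator. When \code{ct} is a
#'   \code{ct_dataset} with a \code{group} metadata column, that column is
#'   the default.
#' @return named per-gene vector of stability values.
#' @export
normfinder_stability <- function(ct, groups = NULL) {
  if (inherits(ct, "ct_dataset") && is.null(groups))
    groups <- ct$samples$group
  m <- ct_matrix(ct)
  k <- ncol(m)
  if (k < 3) stop("need at least 3 genes")
  x <- -m                      # log2-scale expression
  z <- x - rowMeans(x)         # per-sample centring across genes

  corrected_var <- function(v, k) pmax(0, k / (k - 2) * (v - mean(v) / (k - 1)))

  if (is.null(groups)) {
    v <- apply(z, 2, stats::var)
    return(stats::setNames(sqrt(corrected_var(v, k)), colnames(m)))
  }

  groups <- as.factor(groups)
  if (length(groups) != nrow(m))
    stop("groups length must match the number of samples")
  ng <- table(groups)
  if (any(ng < 2)) stop("every group needs at least 2 samples")
  G <- nlevels(groups)
  a <- matrix(NA_real_, k, G, dimnames = list(colnames(m), levels(groups)))
  s2 <- a
  for (g in levels(groups)) {
    zg <- z[groups == g, , drop = FALSE]
    a[, g] <- colMeans(zg)
    s2[, g] <- corrected_var(apply(zg, 2, stats::var), k)
  }
  cvar <- sweep(s2, 2, as.numeric(ng), "/")      # var of a group mean
  d <- a - rowMeans(a)
  vard <- cvar * (1 - 1 / G)
  gamma2 <- max(0, mean((rowSums(d^2) - rowSums(vard)) / (G - 1)))
  w <- ifelse(gamma2 + vard > 0, gamma2 / (gamma2 + vard), 0)
  dshrunk <- d * w
  rho <- abs(dshrunk) + sqrt(cvar)
  stats::setNames(rowMeans(rho), colnames(m))
}

#' BestKeeper descriptive statistics
#'
#' BestKeeper judges candidate stability directly on raw CT values: per gene
#' it reports the sample SD (n-1 denominator), the coefficient of variation
#' (SD as a percentage of the arithmetic mean CT), geometric and arithmetic
#' mean, extremes, and the Pearson correlation r of the gene's CT vector
#' with the BestKeeper index -- the per-sample geometric mean CT over all
#' candidates. Genes with SD below 1.0 and r close to 1 are considered
#' stable; ranking is by ascending SD, with r reported for inspection. A
#' constant gene has r undefined (NA) and is ranked by SD alone.
#'
#' @param ct a \code{\link{ct_dataset}} or complete CT matrix (positive CTs,
#'   >= 2 samples).
#' @return object of class \code{bestkeeper}: list with \code{stats} (data
#'   frame, one row per gene: \code{gene, n, geo_mean, ar_mean, min, max,
#'   sd, cv_pct, r}) and \code{index} (per-sample geometric mean CT).
#' @export
bestkeeper <- function(ct) {
  m <- ct_matrix(ct)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(m <= 0)) stop("CT values must be positive")
  index <- exp(rowMeans(log(m)))
  one <- function(x) {
    s <- stats::sd(x)
    c(n = length(x), geo_mean = exp(mean(log(x))), ar_mean = mean(x),
      min = min(x), max = max(x), sd = s, cv_pct = 100 * s / mean(x),
      r = if (s > 0) stats::cor(x, index) else NA_real_)
  }
  st <- t(apply(m, 2, one))
  stats <- data.frame(gene = rownames(st), st, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(stats = stats, index = index), class = "bestkeeper")
}

#' @export
print.bestkeeper <- function(x, ...) {
  cat("BestKeeper statistics (raw CT scale)\n")
  df <- x$stats
  df[-1] <- lapply(df[-1], function(col) round(col, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Comparative delta-CT stability score
#'
#' For every gene pair, the per-sample CT difference
#' \eqn{\Delta CT_s = CT_{sj} - CT_{sk}} is formed and its sample SD over
#' samples computed; a gene's score is the mean of the pair SDs over all
#' pairs involving it. Under perfect doubling this is algebraically the
#' geNorm M value (the log2 quantity ratio equals the CT difference up to
#' sign), but it is computed directly on CTs with no transformation.
#'
#' @param ct a \code{\link{ct_dataset}} or complete CT matrix, >= 3 genes.
#' @return named per-gene vector of mean pairwise SD(delta CT), in cycles.
#' @export
delta_ct_stability <- function(ct) {
  m <- ct_matrix(ct)
  k <- ncol(m)
  if (k < 3) stop("need at least 3 genes")
  if (nrow(m) < 2) stop("need at least 2 samples")
  score <- vapply(seq_len(k), function(j) {
    mean(vapply(setdiff(seq_len(k), j),
                function(g) stats::sd(m[, j] - m[, g]), numeric(1)))
  }, numeric(1))
  stats::setNames(score, colnames(m))
}

#' Aggregate per-method ranks by geometric mean
#'
#' Combines the rank vectors of the four stability methods into a
#' comprehensive ranking: each gene's aggregate score is the geometric mean
#' of its four ranks, and the final order is by ascending score, ties broken
#' by geNorm rank and then gene symbol so the output is deterministic.
#'
#' @param ranks named list or data frame with components \code{genorm},
#'   \code{normfinder}, \code{bestkeeper}, \code{deltact}: equally long rank
#'   vectors sharing gene names (averaged ranks allowed).
#' @return data frame \code{gene, genorm, normfinder, bestkeeper, deltact,
#'   geomean, rank}, ordered by final rank.
#' @export
aggregate_ranks <- function(ranks) {
  need <- c("genorm", "normfinder", "bestkeeper", "deltact")
  miss <- setdiff(need, names(ranks))
  if (length(miss))
    stop("missing rank vector(s): ", paste(miss, collapse = ", "))
  lens <- vapply(ranks[need], length, integer(1))
  if (length(unique(lens)) != 1)
    stop("rank vectors have unequal lengths")
  genes <- names(ranks$genorm)
  if (is.null(genes)) stop("rank vectors must be named by gene")
  rm <- sapply(need, function(n) {
    v <- ranks[[n]]
    if (!is.null(names(v))) {
      if (!setequal(names(v), genes)) stop("rank vectors name different genes")
      v <- v[genes]
    }
    v
  })
  geomean <- exp(rowMeans(log(rm)))
  ord <- order(geomean, rm[, "genorm"], genes)
  out <- data.frame(gene = genes, rm, geomean = geomean,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out[order(out$rank), , drop = FALSE]
}

#' Reference-gene stability analysis
#'
#' The package's central fit: runs the four stability algorithms
#' (\code{\link{genorm_m}} with iterative \code{\link{genorm_rank}},
#' \code{\link{normfinder_stability}}, \code{\link{bestkeeper}},
#' \code{\link{delta_ct_stability}}), aggregates their rankings by geometric
#' mean (\code{\link{aggregate_ranks}}), and computes the geNorm pairwise
#' variation profile that recommends how many reference genes to use.
#'
#' Stability analysis is performed on linear relative quantities with
#' assumed perfect doubling (E = 1) by default; set
#' \code{use_efficiency = TRUE} to anchor quantities with per-gene assay
#' efficiencies instead. BestKeeper and the delta-CT method always operate
#' on raw CTs, as defined.
#'
#' @param x a \code{\link{ct_dataset}} (complete matrix required) or a
#'   numeric CT matrix, samples x genes.
#' @param groups optional per-sample labels for the grouped NormFinder
#'   estimator; defaults to the dataset's \code{group} metadata column.
#' @param efficiencies optional named per-gene fractional efficiencies or
#'   assay table; required when \code{use_efficiency} is set.
#' @param use_efficiency use per-gene efficiencies when forming relative
#'   quantities (default: E = 1 for all genes).
#' @param v_cutoff pairwise-variation threshold for the recommended
#'   reference count.
#' @return object of class \code{ref_stability}: list with \code{table}
#'   (per-gene statistics and ranks, ordered by aggregate rank),
#'   \code{genorm} (iterative ranking trace), \code{pairwise_variation},
#'   \code{recommended_n}, \code{bestkeeper_index}, \code{n_samples},
#'   \code{groups}.
#' @seealso \code{\link{plot.ref_stability}}, \code{\link{run_pipeline}}
#' @examples
#' sim <- simulate_ct_dataset(sim_config(seed = 7))
#' fit <- ref_stability(sim$dataset)
#' fit
#' @export
ref_stability <- function(x, groups = NULL, efficiencies = NULL,
                          use_efficiency = FALSE, v_cutoff = 0.15) {
  if (inherits(x, "ct_dataset") && is.null(groups))
    groups <- x$samples$group
  m <- ct_matrix(x)
  if (use_efficiency && is.null(efficiencies))
    stop("use_efficiency = TRUE requires per-gene efficiencies")
  q <- relative_quantities(m, if (use_efficiency) efficiencies else NULL)

  gm <- genorm_m(q)
  gr <- genorm_rank(q)
  pv <- pairwise_variation(q, gr$ranking, cutoff = v_cutoff)
  nf <- normfinder_stability(m, groups)
  bk <- bestkeeper(m)
  dc <- delta_ct_stability(m)

  bk_sd <- stats::setNames(bk$stats$sd, bk$stats$gene)[colnames(m)]
  bk_r <- stats::setNames(bk$stats$r, bk$stats$gene)[colnames(m)]
  bk_cv <- stats::setNames(bk$stats$cv_pct, bk$stats$gene)[colnames(m)]
  ranks <- list(genorm = gr$rank,
                normfinder = rank(nf, ties.method = "average"),
                bestkeeper = rank(bk_sd, ties.method = "average"),
                deltact = rank(dc, ties.method = "average"))
  agg <- aggregate_ranks(ranks)

  tab <- data.frame(
    gene = agg$gene,
    genorm_m = gm[agg$gene],
    genorm_rank = ranks$genorm[agg$gene],
    normfinder = nf[agg$gene],
    normfinder_rank = ranks$normfinder[agg$gene],
    bestkeeper_sd = bk_sd[agg$gene],
    bestkeeper_cv = bk_cv[agg$gene],
    bestkeeper_r = bk_r[agg$gene],
    bestkeeper_rank = ranks$bestkeeper[agg$gene],
    deltact_sd = dc[agg$gene],
    deltact_rank = ranks$deltact[agg$gene],
    geomean_rank = agg$geomean,
    rank = agg$rank,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, genorm = gr, pairwise_variation = pv,
                 recommended_n = pv$recommended_n,
                 bestkeeper_index = bk$index,
                 n_samples = nrow(m), groups = groups,
                 use_efficiency = use_efficiency),
            class = "ref_stability")
}

#' @export
print.ref_stability <- function(x, digits = 3, ...) {
  cat("Reference-gene stability analysis (", x$n_samples, " samples, ",
      nrow(x$table), " genes", sep = "")
  if (!is.null(x$groups)) cat(", grouped NormFinder")
  cat(")\n\n")
  df <- x$table[, c("gene", "genorm_m", "normfinder", "bestkeeper_sd",
                    "deltact_sd", "geomean_rank", "rank")]
  names(df) <- c("gene", "geNorm.M", "NormFinder", "BestKeeper.SD",
                 "deltaCT.SD", "geomean.rank", "rank")
  df[-1] <- lapply(df[-1], function(col) round(col, digits))
  print(df, row.names = FALSE)
  cat("\nPairwise variation: ",
      paste(sprintf("%s=%.3f", names(x$pairwise_variation$v),
                    x$pairwise_variation$v), collapse = "  "), "\n", sep = "")
  cat("Recommended number of reference genes:", x$recommended_n,
      sprintf("(V cutoff %.2f)\n", x$pairwise_variation$cutoff))
  invisible(x)
}

#' @export
summary.ref_stability <- function(object, ...) {
  structure(list(fit = object), class = "summary.ref_stability")
}

#' @export
print.summary.ref_stability <- function(x, ...) {
  print(x$fit)
  gr <- x$fit$genorm
  cat("\ngeNorm exclusion order (least stable first): ",
      paste(gr$removal_order, collapse = " > "), "\n", sep = "")
  cat("Best pair (tied):", paste(gr$ranking[1:2], collapse = ", "), "\n")
  invisible(x)
}

#' Plot a stability analysis
#'
#' Two base-graphics panels: aggregate geometric-mean ranks per gene (most
#' stable left) and the pairwise-variation profile with its cut-off line.
#'
#' @param x a \code{\link{ref_stability}} object.
#' @param ... passed to \code{barplot}.
#' @export
plot.ref_stability <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(6, 4, 3, 1))
  on.exit(graphics::par(op))
  tab <- x$table
  graphics::barplot(tab$geomean_rank, names.arg = tab$gene, las = 2,
                    ylab = "geometric mean of ranks",
                    main = "Comprehensive stability ranking", ...)
  pv <- x$pairwise_variation
  bp <- graphics::barplot(pv$v, names.arg = names(pv$v), las = 2,
                          ylab = "pairwise variation V",
                          main = "Optimal number of references")
  graphics::abline(h = pv$cutoff, lty = 2)
  invisible(x)
}
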