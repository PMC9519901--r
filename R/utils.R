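# internal helpers shared across modules

geo_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a per-gene efficiency vector against the columns of a CT matrix.
# `eff` may be NULL (all E = 1), a single number, an unnamed vector matching
# the gene count, or a named vector / assay table covering all genes.
resolve_efficiencies <- function(eff, genes) {
  k <- length(genes)
  if (is.null(eff)) return(stats::setNames(rep(1, k), genes))
  if (is.data.frame(eff)) {
    if (!all(c("gene", "efficiency") %in% names(eff)))
      stop("assay table must have columns 'gene' and 'efficiency'")
    eff <- stats::setNames(eff$efficiency, eff$gene)
  }
  if (length(eff) == 1L && is.null(names(eff))) eff <- rep(eff, k)
  if (is.null(names(eff))) {
    if (length(eff) != k) stop("efficiency vector length does not match gene count")
    names(eff) <- genes
  }
  missing <- setdiff(genes, names(eff))
  if (length(missing))
    stop("missing amplification efficiency for gene(s): ",
         paste(missing, collapse = ", "))
  out <- eff[genes]
  if (any(!is.finite(out) | out <= 0))
    stop("amplification efficiencies must be finite and > 0")
  out
}
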