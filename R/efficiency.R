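#' Fit a standard curve and estimate amplification efficiency
#'
#' Ordinary least-squares fit of CT against log10 of the input amount of a
#' dilution series. The amplification efficiency is derived from the slope
#' as \eqn{E = 10^{-1/slope} - 1}: a perfect assay doubles its product each
#' cycle (E = 1, slope = -1/log10(2) = -3.3219 cycles per tenfold dilution).
#'
#' @param input_pg input amounts per reaction, in pg, or a data frame with
#'   columns \code{input_pg} and \code{ct} (replicate rows allowed).
#' @param ct observed CT values, one per row of \code{input_pg}.
#' @param gene optional gene symbol carried into the result.
#' @return object of class \code{standard_curve} with elements \code{slope}
#'   (cycles per log10 pg), \code{intercept}, \code{r_squared} (squared
#'   Pearson correlation of CT with log10 amount), \code{efficiency}
#'   (fraction), \code{n}, \code{gene}. Efficiencies outside (0.8, 1.1)
#'   trigger a warning; a non-negative slope or fewer than three distinct
#'   amounts are errors.
#' @examples
#' s <- simulate_dilution_series(efficiency = 1, noise_sd = 0)
#' fit_standard_curve(s)   # E = 1, R^2 = 1
#' @export
fit_standard_curve <- function(input_pg, ct = NULL, gene = NULL) {
  if (is.data.frame(input_pg)) {
    df <- input_pg
    if (!all(c("input_pg", "ct") %in% names(df)))
      stop("dilution series needs columns 'input_pg' and 'ct'")
    gene <- gene %||% df$gene[1]
    ct <- df$ct
    input_pg <- df$input_pg
  }
  if (length(input_pg) != length(ct))
    stop("input_pg and ct lengths differ")
  if (any(!is.finite(input_pg) | input_pg <= 0))
    stop("invalid standard curve: input amounts must be positive")
  if (length(unique(input_pg)) < 3)
    stop("invalid standard curve: need >= 3 distinct input amounts")
  x <- log10(input_pg)
  fit <- stats::lm(ct ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid standard curve: slope must be negative (CT falls with input)")
  if (any(diff(ct[order(input_pg)]) > 0) && stats::cor(ct, x) > -0.99)
    warning("CT does not decrease monotonically with input amount")
  efficiency <- 10^(-1 / slope) - 1
  r2 <- stats::cor(ct, x)^2
  if (efficiency > 1.1 || efficiency < 0.8)
    warning(sprintf("amplification efficiency %.1f%% outside the usual 80-110%% range",
                    100 * efficiency))
  structure(list(gene = gene, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency = efficiency,
                 n = length(ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Standard curve", if (!is.null(x$gene)) paste0("(", x$gene, ")"), "\n")
  cat(sprintf("  slope      %8.4f cycles / log10(pg)\n", x$slope))
  cat(sprintf("  intercept  %8.4f cycles\n", x$intercept))
  cat(sprintf("  efficiency %8.1f %%\n", 100 * x$efficiency))
  cat(sprintf("  R-squared  %8.4f   (n = %d)\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.standard_curve <- function(object, input_pg, ...) {
  object$intercept + object$slope * log10(input_pg)
}

#' Convert between percent and fractional amplification efficiency
#'
#' Assay tables conventionally store efficiency as a percentage (100% =
#' perfect doubling); internally the package works with fractions.
#'
#' @param pct efficiency in percent (> 0).
#' @return fraction \code{pct / 100}.
#' @export
efficiency_from_percent <- function(pct) {
  if (any(!is.finite(pct) | pct <= 0))
    stop("efficiency percent must be positive")
  pct / 100
}

#' @rdname efficiency_from_percent
#' @param e efficiency as a fraction.
#' @export
percent_from_efficiency <- function(e) 100 * e
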