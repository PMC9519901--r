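# Independent brute-force oracles, computed directly from the definitions.
# These deliberately share no code with the package internals.

oracle_genorm_m <- function(q) {
  k <- ncol(q)
  out <- numeric(k)
  for (j in 1:k) {
    vs <- c()
    for (g in setdiff(1:k, j)) {
      ratios <- log2(q[, j]) - log2(q[, g])
      vs <- c(vs, sd(ratios))
    }
    out[j] <- mean(vs)
  }
  names(out) <- colnames(q)
  out
}

oracle_deltact <- function(ct) {
  k <- ncol(ct)
  out <- numeric(k)
  for (j in 1:k) {
    sds <- c()
    for (g in setdiff(1:k, j)) sds <- c(sds, sd(ct[, j] - ct[, g]))
    out[j] <- mean(sds)
  }
  names(out) <- colnames(ct)
  out
}

oracle_bestkeeper <- function(ct) {
  idx <- apply(ct, 1, function(r) prod(r)^(1 / length(r)))
  data.frame(
    gene = colnames(ct),
    sd = apply(ct, 2, sd),
    cv_pct = 100 * apply(ct, 2, sd) / colMeans(ct),
    geo_mean = apply(ct, 2, function(x) prod(x)^(1 / length(x))),
    r = apply(ct, 2, function(x) if (sd(x) > 0) cor(x, idx) else NA_real_),
    stringsAsFactors = FALSE
  )
}

oracle_v_profile <- function(q, ranking) {
  k <- length(ranking)
  nf <- function(n) apply(q[, ranking[1:n], drop = FALSE], 1,
                          function(r) prod(r)^(1 / n))
  vapply(2:(k - 1), function(n) sd(log2(nf(n) / nf(n + 1))), numeric(1))
}

oracle_fv <- function(ct_t_cal, ct_t, ct_r_cal, ct_r, e_t, e_r) {
  num <- (1 + e_t)^(ct_t_cal - ct_t)
  dens <- (1 + e_r)^(ct_r_cal - ct_r)
  num / prod(dens)^(1 / length(dens))
}

# Replicate QC rule by exhaustive enumeration: accept iff the full set passes
# the SD threshold, or the prescribed single removal (max |value - median|,
# later index on ties) leaves >= min_n values that pass.
oracle_replicate_rule <- function(v, thr = 0.2, min_n = 3) {
  if (sd(v) < thr) return(list(valid = TRUE, mean = mean(v)))
  dev <- abs(v - median(v))
  drop <- max(which(dev == max(dev)))
  kept <- v[-drop]
  if (length(kept) >= min_n && sd(kept) < thr)
    list(valid = TRUE, mean = mean(kept))
  else list(valid = FALSE, mean = NA_real_)
}

random_ct_matrix <- function(n = 6, k = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n * k, mean = rep(runif(k, 18, 32), each = n), sd = 0.6),
              n, k, dimnames = list(paste0("S", 1:n), paste0("G", 1:k)))
  m
}

write_temp_csv <- function(df, ext = ".csv") {
  f <- tempfile(fileext = ext)
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}
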