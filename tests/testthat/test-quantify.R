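test_that("fold variation follows the efficiency-weighted ratio", {
  # one-cycle advantage on the target, steady reference, E = 1: doubles
  expect_equal(fold_variation(25, 24, 20, 20), 2)
  # equal shifts on target and reference cancel (loading)
  expect_equal(fold_variation(25, 24, 20, 19), 1)
  expect_equal(fold_variation(25, 25 - 2.7, 20, 20 - 2.7), 1)

  # three references with unequal efficiencies: matches the plug-in oracle
  e_r <- c(0.987, 0.965, 1.014)
  got <- fold_variation(25, 23.5, c(20, 21, 22), c(19.5, 20.6, 21.4),
                        e_target = 0.975, e_refs = e_r)
  expect_equal(got, oracle_fv(25, 23.5, c(20, 21, 22), c(19.5, 20.6, 21.4),
                              0.975, e_r), tolerance = 1e-12)

  expect_error(fold_variation(25, 24, numeric(0), numeric(0)),
               "at least one reference")
  expect_error(fold_variation(25, NA, 20, 20), "finite")
})

test_that("fold variation is loading-invariant at equal efficiencies", {
  set.seed(3)
  for (i in 1:20) {
    cal <- runif(4, 18, 30)
    smp <- cal + rnorm(4, 0, 1)
    shift <- rnorm(1, 0, 2)
    f0 <- fold_variation(cal[1], smp[1], cal[-1], smp[-1],
                         e_target = 0.95, e_refs = 0.95)
    f1 <- fold_variation(cal[1], smp[1] + shift, cal[-1], smp[-1] + shift,
                         e_target = 0.95, e_refs = 0.95)
    expect_equal(f1, f0, tolerance = 1e-10)
  }
})

make_fc_dataset <- function(effect = 0, seed = 1, noise = 0.25) {
  cfg <- sim_config(
    reference_genes = c("R1", "R2", "R3"), target_genes = "TG",
    baseline_ct = c(R1 = 20, R2 = 22, R3 = 24, TG = 26),
    noise_sd = c(R1 = 0.1, R2 = 0.1, R3 = 0.1, TG = noise),
    group_effects = list(adult = c(TG = effect)),
    efficiencies = c(R1 = 1, R2 = 1, R3 = 1, TG = 1),
    replicates = 1, replicate_sd = 0, seed = seed
  )
  simulate_ct_dataset(cfg)$dataset
}

test_that("group_fold_change normalizes the calibrator mean to exactly 1", {
  ds <- make_fc_dataset(effect = -1, seed = 5)
  fc <- group_fold_change(ds, "TG", c("R1", "R2", "R3"), "young")
  gs <- fc$group_stats
  expect_equal(gs$mean[gs$group == "young"], 1, tolerance = 1e-12)
  expect_equal(fc$fold_change, gs$mean[gs$group == "adult"])
  expect_error(group_fold_change(ds, "TG", c("TG", "R1"), "young"),
               "must not contain the target")
  expect_error(group_fold_change(ds, "TG", c("R1"), "elderly"),
               "not present")
})

test_that("with one reference and E = 1 the fit reduces to 2^(-ddCT)", {
  ds <- make_fc_dataset(effect = -1, seed = 8)
  fc <- group_fold_change(ds, "TG", "R1", "young")
  m <- ct_matrix(ds)
  young <- ds$samples$group == "young"
  ddct <- (m[, "TG"] - m[, "R1"]) -
    (mean(m[young, "TG"]) - mean(m[young, "R1"]))
  manual <- 2^(-ddct)
  manual <- manual / mean(manual[young])
  expect_equal(fc$samples$nrq, unname(manual), tolerance = 1e-12)
})

test_that("a true 1-cycle drop recovers a ~2-fold change within its SEM", {
  folds <- ses <- numeric(20)
  for (s in 1:20) {
    ds <- make_fc_dataset(effect = -1, seed = 400 + s)
    fc <- group_fold_change(ds, "TG", c("R1", "R2", "R3"), "young")
    folds[s] <- fc$fold_change
    gs <- fc$group_stats
    # total SE of the ratio estimate (delta method): the calibrator mean is
    # itself estimated from n = 5, so its SEM scales into the fold change
    ses[s] <- sqrt(gs$sem[gs$group == "adult"]^2 +
                     (folds[s] * gs$sem[gs$group == "young"])^2)
  }
  expect_lt(abs(mean(folds) - 2), 0.1)
  expect_gt(mean(abs(folds - 2) <= 2 * ses), 0.8)
})

test_that("rescaling to the calibrator never changes the p-value", {
  ds <- make_fc_dataset(effect = -0.5, seed = 12)
  fc <- group_fold_change(ds, "TG", c("R1", "R2"), "young")
  # the test on the log scale is shift-invariant, so recomputing it from
  # un-rescaled fold variations gives the same p
  m <- ct_matrix(ds)
  young <- ds$samples$group == "young"
  cal <- colMeans(m[young, ])
  fv <- sapply(seq_len(nrow(m)), function(s)
    fold_variation(cal["TG"], m[s, "TG"], cal[c("R1", "R2")],
                   m[s, c("R1", "R2")]))
  expect_equal(fc$p_value, compare_groups(fv[young], fv[!young]),
               tolerance = 1e-12)
})

test_that("compare_groups implements the unpaired Student's t-test", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)), 1)

  a <- c(1, 1, 1, 1, 1)
  b <- c(4, 4, 4, 4.1, 3.9, 4, 4, 4, 4, 4)
  p <- compare_groups(a, b)
  # textbook pooled-variance t on log2 values
  la <- log2(a); lb <- log2(b)
  sp <- sqrt(((length(la) - 1) * var(la) + (length(lb) - 1) * var(lb)) /
               (length(la) + length(lb) - 2))
  tstat <- (mean(la) - mean(lb)) / (sp * sqrt(1 / length(la) + 1 / length(lb)))
  p_manual <- 2 * pt(-abs(tstat), length(la) + length(lb) - 2)
  expect_equal(p, p_manual, tolerance = 1e-12)
  expect_lt(p, 0.001)

  expect_error(compare_groups(c(1, 1), c(2, 2)), "zero within-group variance")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
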