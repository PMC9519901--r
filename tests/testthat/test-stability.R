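ct3 <- cbind(A = c(20, 21, 22, 23), B = c(20, 21, 22, 23),
             C = c(20, 22, 21, 23))
rownames(ct3) <- paste0("S", 1:4)

test_that("relative quantities anchor each gene's lowest CT at 1", {
  q <- relative_quantities(cbind(G = c(20, 21, 22)))
  expect_equal(unname(q[, 1]), c(1, 0.5, 0.25))

  q2 <- relative_quantities(cbind(SDHA = c(20, 21)),
                            efficiency = c(SDHA = 0.987))
  expect_equal(unname(q2[, 1]), c(1, 1 / 1.987))

  q3 <- relative_quantities(cbind(G = rep(25, 5)))
  expect_true(all(q3 == 1))

  expect_error(relative_quantities(cbind(G = c(20, 21)),
                                   efficiency = c(OTHER = 1)),
               "missing amplification efficiency")
})

test_that("geNorm M matches the hand-worked three-gene example", {
  q <- relative_quantities(ct3)
  m <- genorm_m(q)
  # log2(QA/QC) per sample is (0, 1, -1, 0): sd = 0.8165; V_AB = 0
  expect_equal(unname(m["A"]), mean(c(0, sd(c(0, 1, -1, 0)))), tolerance = 1e-12)
  expect_equal(unname(m["A"]), 0.4082483, tolerance = 1e-6)
  expect_equal(unname(m["B"]), unname(m["A"]))
  expect_equal(unname(m["C"]), 0.8164966, tolerance = 1e-6)

  # identical genes: all M = 0
  qid <- relative_quantities(cbind(A = c(20, 21, 22), B = c(20, 21, 22),
                                   C = c(20, 21, 22)))
  expect_equal(unname(genorm_m(qid)), c(0, 0, 0))
})

test_that("geNorm M and V match brute-force oracles on random matrices", {
  for (seed in 1:10) {
    m <- random_ct_matrix(6, 4, seed = seed)
    q <- relative_quantities(m)
    expect_equal(genorm_m(q), oracle_genorm_m(q), tolerance = 1e-10)
    r <- genorm_rank(q)$ranking
    expect_equal(unname(pairwise_variation(q, r)$v), oracle_v_profile(q, r),
                 tolerance = 1e-10)
  }
})

test_that("geNorm iterative ranking removes the least stable gene first", {
  q <- relative_quantities(ct3)
  gr <- genorm_rank(q)
  expect_equal(gr$removal_order, "C")
  expect_setequal(gr$ranking[1:2], c("A", "B"))
  expect_equal(unname(gr$rank[c("A", "B")]), c(1.5, 1.5))
  expect_equal(unname(gr$rank["C"]), 3)

  # degenerate identical-profile panel: deterministic later-column tie-break
  qid <- relative_quantities(matrix(rep(c(20, 21, 22), 4), 3, 4,
                                    dimnames = list(NULL, c("W", "X", "Y", "Z"))))
  gr2 <- genorm_rank(qid)
  expect_equal(gr2$removal_order, c("Z", "Y"))
  expect_equal(gr2$ranking, c("W", "X", "Y", "Z"))
})

test_that("a gene with far larger noise ranks last by geNorm", {
  hits <- 0
  for (seed in 1:30) {
    set.seed(seed)
    ct <- sapply(1:5, function(g) rnorm(12, 25, if (g == 3) 1.0 else 0.1))
    colnames(ct) <- paste0("G", 1:5)
    gr <- genorm_rank(relative_quantities(ct))
    if (gr$removal_order[1] == "G3") hits <- hits + 1
  }
  expect_gte(hits, 29)
})

test_that("pairwise variation recommends 2 genes for identical panels", {
  qid <- relative_quantities(matrix(rep(c(20, 21, 22, 23), 4), 4, 4,
                                    dimnames = list(NULL, paste0("G", 1:4))))
  pv <- pairwise_variation(qid)
  expect_equal(unname(pv$v), c(0, 0))
  expect_equal(pv$recommended_n, 2L)
})

test_that("NormFinder is zero for constant panels and flags group shifts", {
  ctc <- matrix(rep(c(20, 24, 28), each = 6), 6, 3,
                dimnames = list(paste0("S", 1:6), paste0("G", 1:3)))
  expect_equal(unname(normfinder_stability(ctc)), c(0, 0, 0))
  expect_equal(unname(normfinder_stability(ctc, rep(c("a", "b"), each = 3))),
               c(0, 0, 0))

  # a 1-cycle group shift on one gene must dominate the stability value
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    groups <- rep(c("young", "adult"), c(5, 10))
    ct <- sapply(1:8, function(g) rnorm(15, 20 + g, 0.1))
    colnames(ct) <- paste0("G", 1:8)
    ct[groups == "adult", 4] <- ct[groups == "adult", 4] + 1
    nf <- normfinder_stability(ct, groups)
    if (which.max(nf) == 4) hits <- hits + 1
  }
  expect_gte(hits, 48)

  expect_error(normfinder_stability(ctc, c("a", rep("b", 5))),
               "at least 2 samples")
})

test_that("BestKeeper statistics match a spreadsheet-style oracle", {
  set.seed(5)
  ct <- random_ct_matrix(4, 3)
  bk <- bestkeeper(ct)
  o <- oracle_bestkeeper(ct)
  expect_equal(bk$stats$sd, o$sd, tolerance = 1e-10)
  expect_equal(bk$stats$cv_pct, o$cv_pct, tolerance = 1e-10)
  expect_equal(bk$stats$geo_mean, o$geo_mean, tolerance = 1e-10)
  expect_equal(bk$stats$r, o$r, tolerance = 1e-10)
  expect_equal(unname(bk$index),
               unname(apply(ct, 1, function(r) prod(r)^(1 / 3))),
               tolerance = 1e-10)

  # constant gene: SD 0, CV 0, r undefined
  ct2 <- cbind(ct, CONST = rep(25, 4))
  bk2 <- bestkeeper(ct2)
  row <- bk2$stats[bk2$stats$gene == "CONST", ]
  expect_equal(row$sd, 0)
  expect_equal(row$cv_pct, 0)
  expect_true(is.na(row$r))
})

test_that("delta-CT scores equal geNorm pair SDs under perfect doubling", {
  dc <- delta_ct_stability(ct3)
  expect_equal(unname(dc), c(0.4082483, 0.4082483, 0.8164966),
               tolerance = 1e-6)
  for (seed in 1:10) {
    m <- random_ct_matrix(5, 4, seed = seed + 100)
    expect_equal(delta_ct_stability(m), oracle_deltact(m), tolerance = 1e-10)
    expect_equal(unname(delta_ct_stability(m)),
                 unname(genorm_m(relative_quantities(m))), tolerance = 1e-10)
  }
})

test_that("rank aggregation takes the geometric mean with stated tie-breaks", {
  ranks <- list(
    genorm = c(A = 1, B = 2, C = 3),
    normfinder = c(A = 1, B = 2, C = 3),
    bestkeeper = c(A = 1, B = 2, C = 3),
    deltact = c(A = 2, B = 1, C = 3)
  )
  agg <- aggregate_ranks(ranks)
  expect_equal(agg$geomean[agg$gene == "A"], 2^(1 / 4), tolerance = 1e-12)
  expect_equal(agg$gene, c("A", "B", "C"))

  # idempotence: identical rank vectors reproduce the common ranking
  same <- list(genorm = c(X = 2, Y = 1, Z = 3),
               normfinder = c(X = 2, Y = 1, Z = 3),
               bestkeeper = c(X = 2, Y = 1, Z = 3),
               deltact = c(X = 2, Y = 1, Z = 3))
  agg2 <- aggregate_ranks(same)
  expect_equal(agg2$rank[match(c("X", "Y", "Z"), agg2$gene)], c(2L, 1L, 3L))

  bad <- ranks
  bad$deltact <- c(A = 1, B = 2)
  expect_error(aggregate_ranks(bad), "unequal length")
})

test_that("stability scores respect loading-factor invariance where defined", {
  set.seed(9)
  ct <- random_ct_matrix(8, 5)
  load <- rnorm(8, 0, 1.5)
  ct_shift <- ct + load   # per-sample constant added to every gene
  q <- relative_quantities(ct); qs <- relative_quantities(ct_shift)

  expect_equal(genorm_m(qs), genorm_m(q), tolerance = 1e-10)
  expect_equal(delta_ct_stability(ct_shift), delta_ct_stability(ct),
               tolerance = 1e-10)
  r <- genorm_rank(q)$ranking
  expect_equal(pairwise_variation(qs, r)$v, pairwise_variation(q, r)$v,
               tolerance = 1e-10)
  expect_equal(normfinder_stability(ct_shift), normfinder_stability(ct),
               tolerance = 1e-10)
  # BestKeeper works on raw CT and must NOT be loading-invariant
  expect_gt(max(abs(bestkeeper(ct_shift)$stats$sd - bestkeeper(ct)$stats$sd)),
            0.1)
})

test_that("all four methods are invariant to gene and sample order", {
  set.seed(33)
  ct <- random_ct_matrix(7, 5)
  gp <- sample(ncol(ct)); sp <- sample(nrow(ct))
  ctp <- ct[sp, gp]
  q <- relative_quantities(ct); qp <- relative_quantities(ctp)
  expect_equal(genorm_m(qp)[colnames(ct)], genorm_m(q), tolerance = 1e-12)
  expect_equal(delta_ct_stability(ctp)[colnames(ct)], delta_ct_stability(ct),
               tolerance = 1e-12)
  expect_equal(normfinder_stability(ctp)[colnames(ct)],
               normfinder_stability(ct), tolerance = 1e-12)
  bk <- bestkeeper(ct)$stats; bkp <- bestkeeper(ctp)$stats
  expect_equal(bkp$sd[match(bk$gene, bkp$gene)], bk$sd, tolerance = 1e-12)
})

test_that("ref_stability assembles a coherent report object", {
  sim <- simulate_ct_dataset(sim_config(seed = 21))
  refs <- sim$assays$gene[sim$assays$role == "reference"]
  sub <- ct_dataset(sim$dataset$ct[, refs], samples = sim$dataset$samples)
  fit <- ref_stability(sub)
  tab <- fit$table
  expect_equal(nrow(tab), 8)
  expect_setequal(tab$rank, 1:8)
  expect_equal(sort(tab$genorm_rank), c(1.5, 1.5, 3:8))
  expect_equal(tab$geomean_rank,
               (tab$genorm_rank * tab$normfinder_rank *
                  tab$bestkeeper_rank * tab$deltact_rank)^(1 / 4),
               tolerance = 1e-12)
  expect_true(all(diff(tab$geomean_rank) >= 0))
  expect_s3_class(fit$pairwise_variation, "pairwise_variation")
  expect_true(fit$recommended_n >= 2 && fit$recommended_n <= 8)
  expect_error(ref_stability(sub, use_efficiency = TRUE), "requires")
  expect_output(print(fit), "Recommended number")
})
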