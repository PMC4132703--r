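test_that("gene templates split the locus into equal exons with the stated isoforms", {
  t3 <- gene_template("cassette3", 1200)
  expect_equal(t3$exon_lengths, rep(400L, 3))
  expect_equal(t3$isoforms$A, c(1L, 3L))  # isoform A skips the cassette exon
  expect_equal(t3$isoforms$B, c(1L, 2L, 3L))

  t4 <- gene_template("altcassette4", 1200)
  expect_equal(t4$exon_lengths, rep(300L, 4))
  expect_equal(t4$isoforms$A, c(1L, 2L, 4L))  # shared first/last, distinct middles
  expect_equal(t4$isoforms$B, c(1L, 3L, 4L))

  expect_equal(gene_template("cassette3", 3)$exon_lengths, rep(1L, 3))
  expect_error(gene_template("cassette3", 1000), "divisible")
})

test_that("sim_config validates its parameters", {
  expect_error(sim_config(mu = -1))
  expect_error(sim_config(p1 = c(0.3, 0.3)))
  expect_error(sim_config(d = 1000, template = "cassette3"), "divisible")
})

test_that("simulated coverage matches its expectation structure", {
  cfg <- sim_config()  # baseline: mixes 1:3 vs 3:1, mu = 100, phi = 0.179
  m <- simulate_dataset(cfg, seed = 12)
  expect_s3_class(m, "coverage_matrix")
  expect_equal(dim(m$counts), c(100L, 1200L))
  expect_equal(m$truth, rep(1:2, each = 50))

  # constitutive exons (1 and 3) have expected depth mu in BOTH subpopulations
  const_cols <- c(1:400, 801:1200)
  mean_depth <- function(rows) mean(m$counts[rows, const_cols])
  # NB(mean 25) + NB(mean 75) per sample: per-sample SD ~ 35, so the mean
  # over 50 samples has SE ~ 5; assert within 3 SE
  expect_lt(abs(mean_depth(1:50) - cfg$mu), 15)
  expect_lt(abs(mean_depth(51:100) - cfg$mu), 15)

  # cassette exon: expected depth 0.75 mu in subpop 1 vs 0.25 mu in subpop 2
  cass <- 401:800
  ratio <- mean(m$counts[1:50, cass]) / mean(m$counts[51:100, cass])
  expect_gt(ratio, 2.4)
  expect_lt(ratio, 3.6)
})

test_that("the dispersion-free equal-mix limit gives identical expected curves", {
  cfg <- sim_config(n1 = 15, n2 = 15, d = 300, mu = 200, phi = 0,
                    p1 = c(0.5, 0.5), p2 = c(0.5, 0.5))
  m <- simulate_dataset(cfg, seed = 3)
  col_means <- colMeans(m$counts)
  # expected: mu on constitutive exons, mu/2 on the cassette exon
  expect_equal(mean(col_means[1:100]), 200, tolerance = 0.05)
  expect_equal(mean(col_means[101:200]), 100, tolerance = 0.05)
  expect_equal(mean(col_means[201:300]), 200, tolerance = 0.05)
})

test_that("study runs are reproducible and honour alpha", {
  cfg <- sim_config(n1 = 10, n2 = 10, d = 150, mu = 60)
  sp <- sigclust_params(n_null_sims = 20)
  s1 <- run_setting(cfg, n_reps = 4, sp = sp, master_seed = 123)
  s2 <- run_setting(cfg, n_reps = 4, sp = sp, master_seed = 123)
  expect_identical(s1$pvalue, s2$pvalue)  # end-to-end determinism
  expect_identical(s1$seed, 123L + 0:3)

  cfg0 <- sim_config(n1 = 10, n2 = 10, d = 150, mu = 60, alpha = 0)
  s0 <- run_setting(cfg0, n_reps = 3, sp = sp, master_seed = 9)
  expect_equal(attr(s0, "n_significant"), 0L)  # alpha = 0 rejects nothing

  g <- glance(s1)
  expect_equal(g$n_reps, 4L)
  expect_equal(g$n_significant, sum(s1$pvalue < cfg$alpha, na.rm = TRUE))
})

test_that("joint study mixes null and non-null loci with recoverable signal", {
  sp <- sigclust_params(n_null_sims = 30)
  fp <- filter_params(min_samples = 5)
  small_null <- sim_config(n1 = 10, n2 = 10, d = 150, mu = 80,
                           p1 = c(0.5, 0.5), p2 = c(0.5, 0.5))
  small_alt <- sim_config(n1 = 10, n2 = 10, d = 150, mu = 80)
  js <- joint_study(12, 8, null_cfg = small_null,
                    nonnull_cfgs = list(small_alt), fp = fp, sp = sp,
                    master_seed = 77)
  expect_equal(nrow(js), 20L)
  expect_equal(sum(js$truth), 8L)
  roc <- roc_auc(-js$pvalue, js$truth)
  expect_gt(roc$auc, 0.75)  # differential usage is recoverable

  js2 <- joint_study(12, 8, null_cfg = small_null,
                     nonnull_cfgs = list(small_alt), fp = fp, sp = sp,
                     master_seed = 77)
  expect_identical(js$pvalue, js2$pvalue)

  # all-null study: BH at 5% rejects (almost) nothing
  js0 <- joint_study(15, 0, null_cfg = small_null, fp = fp, sp = sp,
                     master_seed = 31)
  expect_lte(sum(bh_adjust(js0$pvalue, 0.05)$reject), 1)
})

test_that("ROC summaries match brute-force pair counting", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)

  perfect <- roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$tpr_95, 1)
  expect_equal(perfect$f1_90, 1)

  set.seed(61)
  for (i in 1:15) {
    n <- sample(6:30, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    scores <- round(rnorm(n), 1)             # ties likely
    expect_equal(roc_auc(scores, truth)$auc, brute_auc(scores, truth))
  }

  # random labels: AUC centred on 1/2
  set.seed(62)
  aucs <- replicate(200, {
    scores <- rnorm(20)
    roc_auc(scores, sample(rep(0:1, each = 10)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)

  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})
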