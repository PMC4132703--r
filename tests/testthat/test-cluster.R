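test_that("two_means reproduces hand-derived cluster indices", {
  # perfect split: zero within-cluster scatter
  x <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  fit <- two_means(x, seed = 1)
  expect_equal(fit$CI, 0)
  expect_equal(unname(fit$labels), c(1L, 1L, 2L, 2L))

  # 1-D {0,1,2,3}: best split {0,1}|{2,3}, WSS 1, TSS 5
  expect_equal(two_means(matrix(0:3, 4, 1), seed = 1)$CI, 0.2)
  # 1-D {0,1,2,9}: best split {0,1,2}|{9}, WSS 2, TSS 50
  expect_equal(two_means(matrix(c(0, 1, 2, 9), 4, 1), seed = 1)$CI, 0.04)
})

test_that("two_means equals the exhaustive-enumeration optimum for small n", {
  set.seed(301)
  for (case in 1:8) {
    n <- sample(4:10, 1)
    d <- sample(c(1, 2, 5, 20), 1)
    x <- matrix(rnorm(n * d), n, d)
    if (case %% 2 == 0)  # mixture cases too, not just pure noise
      x[seq_len(floor(n / 2)), ] <- x[seq_len(floor(n / 2)), ] + 2
    oracle <- enumerate_two_means(x)
    fit <- two_means(x, restarts = 50, seed = case)
    expect_equal(fit$within_ss, oracle$within_ss, tolerance = 1e-9)
    expect_equal(fit$CI, oracle$CI, tolerance = 1e-9)
  }
})

test_that("two_means agrees with stats::kmeans as an independent cross-check", {
  set.seed(55)
  x <- rbind(matrix(rnorm(20 * 5), 20, 5), matrix(rnorm(20 * 5, mean = 4), 20, 5))
  fit <- two_means(x, restarts = 25, seed = 1)
  km <- stats::kmeans(x, centers = 2, nstart = 25, algorithm = "Lloyd")
  expect_equal(fit$within_ss, km$tot.withinss, tolerance = 1e-9)
  expect_equal(fit$CI, km$tot.withinss / km$totss, tolerance = 1e-9)
})

test_that("cluster index is invariant to translation, rotation and scaling", {
  set.seed(77)
  x <- matrix(rnorm(15 * 6), 15, 6)
  base <- two_means(x, restarts = 30, seed = 3)$CI
  # translation
  expect_equal(two_means(x + 5, restarts = 30, seed = 3)$CI, base,
               tolerance = 1e-9)
  # orthogonal rotation
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(two_means(x %*% q, restarts = 30, seed = 3)$CI, base,
               tolerance = 1e-9)
  # uniform positive scaling
  expect_equal(two_means(x * 3.7, restarts = 30, seed = 3)$CI, base,
               tolerance = 1e-9)
  expect_true(base >= 0 && base < 1)
})

test_that("two_means canonicalizes labels and handles degenerate input", {
  set.seed(4)
  x <- matrix(rnorm(12 * 3), 12, 3)
  expect_equal(unname(two_means(x, seed = 9)$labels[1]), 1L)
  expect_error(two_means(x[1, , drop = FALSE]), "at least 2")
  const <- two_means(matrix(5, 6, 4), seed = 1)
  expect_true(is.na(const$CI))
  expect_equal(unname(const$labels), rep(1L, 6))
})

test_that("gram-domain null sampling matches direct data-space simulation", {
  # the null CIs drawn via Wishart + rank-1 Gram sampling must be
  # distributed like CIs of explicitly simulated n x d Gaussian data
  n <- 20; d <- 150
  lam_est <- c(12, 4, rep(0.5, n - 3))
  sigma2 <- 0.5
  lam_full <- c(lam_est, rep(sigma2, d - length(lam_est)))
  nsim <- 300
  direct <- withr::with_seed(101, vapply(seq_len(nsim), function(s) {
    z <- matrix(rnorm(n * d), n, d) * rep(sqrt(lam_full), each = n)
    fit <- sigfuge:::cpp_two_means_gram(tcrossprod(z),
                                        sigfuge:::draw_inits(n, 10))
    fit$within_ss / fit$total_ss
  }, numeric(1)))
  gram <- withr::with_seed(202, sigfuge:::cpp_null_cis(lam_est, sigma2, d, n,
                                                       nsim, 10))
  expect_equal(mean(gram), mean(direct), tolerance = 0.02)
  expect_equal(sd(gram), sd(direct), tolerance = 0.25)
  ks <- suppressWarnings(stats::ks.test(gram, direct))
  expect_gt(ks$p.value, 0.001)
})

test_that("sigclust p-value flags degenerate input and zero-spread nulls", {
  const <- sigclust_pvalue(matrix(5, 10, 8), sigclust_params(rng_seed = 1))
  expect_equal(const$flag, "degenerate_no_variance")
  expect_true(is.na(const$pvalue))
})

test_that("strong two-cluster curve data is significant, one-cluster data is not", {
  m <- simulate_dataset(sim_config(), seed = 31)  # baseline differential usage
  nc <- normalize_curves(m, filter_low_expression(m))
  sig <- sigclust_pvalue(nc, sigclust_params(rng_seed = 17))
  expect_lt(sig$pvalue, 0.001)
  expect_length(sig$null_fit$null_CIs, 100)
  expect_equal(length(sig$null_fit$eigenvalues_used), 1200)

  null_cfg <- sim_config(p1 = c(0.5, 0.5), p2 = c(0.5, 0.5))
  m0 <- simulate_dataset(null_cfg, seed = 32)
  nc0 <- normalize_curves(m0, filter_low_expression(m0))
  sig0 <- sigclust_pvalue(nc0, sigclust_params(rng_seed = 18))
  expect_gt(sig0$pvalue, 0.01)
})

test_that("sigfuge_gene composes the pipeline with three-way labels and flags", {
  # 9 samples passing the filter with min_samples = 10: no clustering
  m <- coverage_matrix(matrix(rpois(9 * 50, 30), 9, 50))
  res <- sigfuge_gene(m)
  expect_equal(res$flag, "too_few_samples")
  expect_true(is.na(res$pvalue))
  expect_equal(res$n_low, 9)  # nothing clustered; all labelled low

  # all-zero matrix: everything low, locus flagged
  m0 <- coverage_matrix(matrix(0L, 12, 30))
  res0 <- sigfuge_gene(m0)
  expect_equal(res0$flag, "too_few_samples")
  expect_equal(unname(res0$labels), rep("low", 12))

  # simulated two-cluster locus with 20 all-zero spike-ins: exactly the
  # spike-ins are labelled low, the rest split into the two clusters
  sim <- simulate_dataset(sim_config(), seed = 41)
  spik <- coverage_matrix(rbind(sim$counts, matrix(0L, 20, 1200)),
                          c(sim$sample_ids, paste0("low", 1:20)),
                          gene_id = "spiked")
  res2 <- sigfuge_gene(spik, sp = sigclust_params(rng_seed = 5))
  lab <- tidy(res2)
  expect_equal(lab$sample_id[lab$label == "low"], paste0("low", 1:20))
  expect_equal(res2$n_c1 + res2$n_c2, 100)
  expect_equal(res2$n_low, 20)
  g <- glance(res2)
  expect_equal(g$n_total, 120)
  expect_true(g$pvalue < 0.001)
})

test_that("BH step-up matches hand and brute-force evaluation", {
  r1 <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r1$reject))  # p_(4) = 0.04 <= 4/4 * 0.05
  r2 <- bh_adjust(c(0.04, 0.9), q = 0.05)
  expect_false(any(r2$reject))  # 0.04 > 1/2 * 0.05
  r3 <- bh_adjust(0.05, q = 0.05)
  expect_true(r3$reject)  # boundary: non-strict comparison

  expect_equal(nrow(bh_adjust(numeric(0))), 0L)
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")

  set.seed(90)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    got <- bh_adjust(p, q)
    want <- brute_bh(p, q)
    expect_equal(got$reject, want$reject)
    expect_equal(got$qvalue, want$qvalues, tolerance = 1e-12)
  }
})

test_that("chi-square tests match their closed forms and contracts", {
  flat <- chisq_uniform_gof(c(10, 10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$pvalue, 1)

  # with df = 2 the upper tail is exactly exp(-statistic / 2)
  for (counts in list(c(0, 29, 3), c(1, 36, 12), c(5, 9, 40), c(2, 2, 17))) {
    got <- chisq_uniform_gof(counts)
    expect_equal(got$df, 2)
    expect_equal(got$pvalue, exp(-got$statistic / 2), tolerance = 1e-12)
  }

  # r x c independence for matrix input
  tab <- cbind(c(46, 0, 1, 1), c(0, 29, 0, 36), c(8, 3, 41, 12))
  whole <- chisq_uniform_gof(tab)
  expect_equal(whole$df, 6)
  expect_lt(whole$pvalue, 1e-20)

  expect_error(chisq_uniform_gof(c(0, 0, 0)), "all zero")
  expect_error(chisq_uniform_gof(c(-1, 2)), "non-negative")
})
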