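#' Significance-test parameters
#'
#' Controls the simulation-based clustering test: the number of null
#' datasets drawn from the single-Gaussian null (the genome-wide default is
#' 100 per locus, trading exactness for throughput), the number of random
#' restarts of the 2-means search (the same policy is applied to the
#' observed and every null dataset, keeping the indices comparable), and an
#' optional RNG seed for full reproducibility.
#'
#' @param n_null_sims Number of null simulations (>= 2, default 100).
#' @param kmeans_restarts Restarts per 2-means fit (default 10; each
#'   restart seeds Lloyd iteration with two distinct data rows).
#' @param rng_seed Optional integer seed; `NULL` uses the ambient RNG
#'   stream.
#' @param background Background-noise variance estimator for the null
#'   covariance: `"diff"` (default; robust spread of first differences
#'   between genomically adjacent positions, which cancels the biological
#'   signal and isolates read-sampling noise), `"mad"` (robust spread of
#'   all matrix entries about their global median) or `"mad_centered"`
#'   (the same after removing position means).
#' @param thresholding Eigenvalue regularisation: `"soft"` (default;
#'   shift-and-floor preserving the observed total variance) or `"hard"`
#'   (floor only).  See the methods vignette for why soft thresholding is
#'   the calibrated choice when d >> n.
#' @return A list of class `sigclust_params`.
#' @export
sigclust_params <- function(n_null_sims = 100, kmeans_restarts = 10,
                            rng_seed = NULL,
                            background = c("diff", "mad", "mad_centered"),
                            thresholding = c("soft", "hard")) {
  stopifnot(n_null_sims >= 2, kmeans_restarts >= 1)
  structure(list(n_null_sims = as.integer(n_null_sims),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 rng_seed = rng_seed,
                 background = match.arg(background),
                 thresholding = match.arg(thresholding)),
            class = "sigclust_params")
}

# Draw restart seed pairs (two distinct rows each) from the current RNG
# stream; returns a 2 x restarts matrix of 0-based indices for the C++ core.
draw_inits <- function(n, restarts) {
  vapply(seq_len(restarts),
         function(r) sample.int(n, 2L) - 1L,
         integer(2))
}

#' 2-means clustering of expression curves
#'
#' Best-of-restarts Lloyd K-means with K = 2 under Euclidean distance.
#' Each restart seeds the two centroids with two distinct data rows; an
#' empty cluster is repaired by moving in the point farthest from its
#' centroid; the restart with the smallest within-cluster sum of squares
#' wins.  The tightness of the split is summarized by the 2-means cluster
#' index \eqn{CI = WSS / TSS}, the within-cluster sum of squares divided
#' by the total sum of squares about the grand mean — a scale of 0
#' (perfectly tight clusters) to just under 1 (no cluster structure).
#' Labels are canonicalized so that cluster 1 contains the first row.
#'
#' @param x Numeric matrix (rows = samples), [normalize_curves()] output,
#'   or a wide data frame with a `sample_id` column.
#' @param restarts Number of random restarts (default 10).
#' @param seed Optional RNG seed; `NULL` uses the ambient stream.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (named integer vector in \{1, 2\}), `centroids` (2 x d), `within_ss`,
#'   `total_ss` and `CI`.  Constant input (zero total SS) yields `CI = NA`
#'   with all samples in cluster 1.
#' @examples
#' x <- rbind(a = c(0, 0), b = c(0, 1), c = c(10, 10), d = c(10, 11))
#' two_means(x, seed = 1)$CI
#' @export
two_means <- function(x, restarts = 10, seed = NULL) {
  x <- curves_matrix(x)
  n <- nrow(x)
  if (n < 2) abort("two_means requires at least 2 samples")
  if (any(!is.finite(x))) abort("two_means requires finite values")
  fit <- with_seed_if(seed, {
    inits <- draw_inits(n, restarts)
    cpp_two_means_gram(tcrossprod(x), inits)
  })
  labels <- fit$labels
  if (fit$total_ss <= 1e-12 * n) {
    ci <- NA_real_
    labels <- rep(1L, n)
  } else {
    ci <- fit$within_ss / fit$total_ss
    if (labels[1] == 2L) labels <- 3L - labels  # cluster 1 holds sample 1
  }
  centroids <- rbind(colMeans(x[labels == 1L, , drop = FALSE]),
                     colMeans(x[labels == 2L, , drop = FALSE]))
  names(labels) <- rownames(x)
  structure(
    list(labels = labels, centroids = centroids,
         within_ss = fit$within_ss, total_ss = fit$total_ss, CI = ci),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> sizes %d/%d, CI = %s\n",
              sum(x$labels == 1), sum(x$labels == 2),
              format(x$CI, digits = 4)))
  invisible(x)
}

# coerce the various curve containers to a plain numeric matrix
curves_matrix <- function(x) {
  if (inherits(x, "normalized_curves")) return(x$values)
  if (inherits(x, "coverage_matrix")) {
    m <- x$counts
    storage.mode(m) <- "double"
    return(m)
  }
  if (is.data.frame(x)) {
    ids <- if ("sample_id" %in% names(x)) as.character(x$sample_id) else NULL
    m <- as.matrix(x[setdiff(names(x), "sample_id")])
    if (!is.null(ids)) rownames(m) <- ids
    return(m)
  }
  as.matrix(x)
}

# Background (measurement) noise variance of the curve matrix.
#
# "diff" exploits the curve structure: adjacent exonic positions share the
# biological signal (isoform usage varies at exon scale) but carry
# independent read-sampling noise, so the robust spread of first
# differences over contiguous positions estimates sqrt(2) times the noise
# SD — the classical difference-based variance estimator of nonparametric
# regression.  "mad" is the robust spread of all matrix entries about
# their global median (the classical significance-of-clustering recipe; it
# absorbs exon-level offsets and dense factor structure and therefore
# overestimates noise for curve data).  "mad_centered" removes the
# position means first.
estimate_background_var <- function(x, positions = NULL,
                                    method = c("diff", "mad", "mad_centered")) {
  method <- match.arg(method)
  if (method == "mad")
    return(mad(as.vector(x), constant = 1 / 0.6745)^2)
  if (method == "mad_centered")
    return(mad(as.vector(scale(x, center = TRUE, scale = FALSE)),
               constant = 1 / 0.6745)^2)
  pos <- if (!is.null(positions)) positions$pos else seq_len(ncol(x))
  adj <- which(diff(pos) == 1L)  # pairs of genomically adjacent columns
  if (length(adj) < 10)  # too few contiguous positions (e.g. exon-level data)
    return(mad(as.vector(scale(x, center = TRUE, scale = FALSE)),
               constant = 1 / 0.6745)^2)
  dx <- x[, adj + 1L, drop = FALSE] - x[, adj, drop = FALSE]
  (mad(as.vector(dx), constant = 1 / 0.6745) / sqrt(2))^2
}

# Eigenvalue regularisation for the single-Gaussian null.
#
# Sample eigenvalues of the covariance when d >> n concentrate the noise
# variance of all d dimensions into the n - 1 estimable components
# (Marchenko-Pastur inflation by ~d/n).  "hard" thresholding (floor every
# eigenvalue, and every unestimated trailing dimension, at sigma2) keeps
# that inflation and adds the background again, overstating the null total
# variance and making the test anti-conservative for curve data.  "soft"
# thresholding shifts the estimated eigenvalues down by a common tau >= 0,
# floors at sigma2, and chooses tau so that the null total variance equals
# the observed total variance; when the floor alone already exceeds the
# total (background overestimated), an isotropic spectrum at the average
# variance is the limiting case.
threshold_eigenvalues <- function(lam, d, sigma2,
                                  method = c("soft", "hard")) {
  method <- match.arg(method)
  k <- length(lam)
  if (method == "hard")
    return(c(pmax(lam, sigma2), rep(sigma2, d - k)))
  total <- sum(lam)
  if (d * sigma2 >= total || total <= 0)
    return(rep(max(total, d * .Machine$double.eps) / d, d))
  f <- function(tau) sum(pmax(lam - tau, sigma2)) + (d - k) * sigma2 - total
  tau <- stats::uniroot(f, c(0, max(lam)), tol = 1e-9 * max(lam))$root
  c(pmax(lam - tau, sigma2), rep(sigma2, d - k))
}

# Null covariance eigenvalues: background noise variance plus
# sample-covariance eigenvalues (via the Gram matrix of the column-centered
# data), regularised by soft (default) or hard thresholding.
null_eigenvalues <- function(x, positions = NULL,
                             background = "diff", thresholding = "soft") {
  n <- nrow(x)
  d <- ncol(x)
  sigma2 <- estimate_background_var(x, positions, background)
  xc <- scale(x, center = TRUE, scale = FALSE)
  gram <- tcrossprod(xc)
  ev <- eigen(gram, symmetric = TRUE, only.values = TRUE)$values / (n - 1)
  k <- min(n - 1L, d)
  lam <- threshold_eigenvalues(pmax(ev[seq_len(k)], 0), d, sigma2, thresholding)
  list(eigenvalues = lam, background_var = sigma2)
}

#' Simulation-based p-value for significance of clustering
#'
#' Tests whether the observed two-cluster split is tighter than expected
#' for draws from a *single* Gaussian.  The null covariance eigenstructure
#' is estimated from the data: sample-covariance eigenvalues via the Gram
#' matrix, regularised against a background noise variance (difference-based
#' by default, see [sigclust_params()]) by total-variance-preserving soft
#' thresholding.  Null datasets of the same
#' shape are simulated in the principal basis — valid because the 2-means
#' cluster index is rotation invariant — and each is clustered with exactly
#' the same 2-means policy as the observed data.  Because the cluster index
#' depends on a dataset only through its Gram matrix, each null Gram matrix
#' is drawn directly (eigenvalue-weighted rank-one terms plus a
#' Bartlett-sampled Wishart for the isotropic remainder), an exact
#' distributional identity that avoids materialising the n-by-d null data.  A Gaussian is fitted to
#' the null cluster indices by their sample mean and SD, and the lower-tail
#' probability of the observed index under that fit is reported as the
#' p-value.  The fitted tail keeps ordering information even when the
#' empirical count of null indices below the observed one is zero.
#'
#' @param x Numeric matrix, [normalize_curves()] output, or wide data
#'   frame; rows are samples.
#' @param params A [sigclust_params()] object.
#' @return List with `pvalue`, `ci_obs`, `null_fit` (list: `null_CIs`,
#'   `mean`, `sd`, `background_var`, `eigenvalues_used`), `assignment`
#'   (the observed [two_means()] fit) and `flag` (`"ok"`,
#'   `"degenerate_no_variance"` for constant input, or `"null_sd_zero"`).
#' @export
sigclust_pvalue <- function(x, params = sigclust_params()) {
  positions <- if (inherits(x, "normalized_curves")) x$positions else NULL
  x <- curves_matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2) abort("sigclust_pvalue requires at least 2 samples")
  if (any(!is.finite(x))) abort("sigclust_pvalue requires finite values")

  run <- function() {
    obs <- two_means(x, restarts = params$kmeans_restarts)
    if (is.na(obs$CI)) {
      return(list(pvalue = NA_real_, ci_obs = NA_real_, null_fit = NULL,
                  assignment = obs, flag = "degenerate_no_variance"))
    }
    ne <- null_eigenvalues(x, positions, params$background, params$thresholding)
    k <- min(n - 1L, d)
    null_cis <- cpp_null_cis(ne$eigenvalues[seq_len(k)], ne$background_var,
                             d, n, params$n_null_sims,
                             params$kmeans_restarts)
    m <- mean(null_cis)
    s <- stats::sd(null_cis)
    if (s == 0) {
      pvalue <- if (obs$CI >= m) 1 else 0
      flag <- "null_sd_zero"
    } else {
      pvalue <- min(max(pnorm(obs$CI, mean = m, sd = s), 0), 1)
      flag <- "ok"
    }
    list(pvalue = pvalue, ci_obs = obs$CI,
         null_fit = list(null_CIs = null_cis, mean = m, sd = s,
                         background_var = ne$background_var,
                         eigenvalues_used = ne$eigenvalues),
         assignment = obs, flag = flag)
  }
  with_seed_if(params$rng_seed, run())
}

#' Full per-locus analysis: filter, normalize, cluster, test
#'
#' Composes the whole pipeline for one locus: low-expression filtering
#' ([filter_low_expression()]), count normalization and log transform
#' ([normalize_curves()]), 2-means clustering and the simulation-based
#' significance test ([sigclust_pvalue()]).  Every input sample receives
#' one of three labels: `"low"` (filtered out), `"cluster1"` or
#' `"cluster2"`.  When fewer than `min_samples` samples survive the filter,
#' the locus is flagged `too_few_samples` and no clustering or p-value is
#' attempted.
#'
#' @param m A [coverage_matrix()] or wide data frame.
#' @param fp [filter_params()].
#' @param sp [sigclust_params()].
#' @param log_base Log base for the transform (immaterial to the
#'   clustering; default 2).
#' @return An object of class `sigfuge_result`; see [tidy.sigfuge_result()]
#'   and [glance.sigfuge_result()] for tibble views.
#' @export
sigfuge_gene <- function(m, fp = filter_params(), sp = sigclust_params(),
                         log_base = 2) {
  m <- as_coverage_matrix(m)
  report <- filter_low_expression(m, fp)
  labels <- stats::setNames(rep("low", length(m$sample_ids)), m$sample_ids)
  base <- list(gene_id = m$gene_id, filter_report = report,
               n_total = length(m$sample_ids))

  if (attr(report, "gene_flag") == "too_few_samples") {
    return(new_sigfuge_result(base, labels, flag = "too_few_samples"))
  }
  nc <- normalize_curves(m, report, log_base = log_base)
  sig <- tryCatch(
    sigclust_pvalue(nc, sp),
    error = function(e) abort(sprintf("gene %s: %s", m$gene_id, conditionMessage(e)))
  )
  labels[nc$sample_ids] <- paste0("cluster", sig$assignment$labels)
  new_sigfuge_result(base, labels, flag = sig$flag, ci_obs = sig$ci_obs,
                     null_fit = sig$null_fit, pvalue = sig$pvalue,
                     assignment = sig$assignment, curves = nc)
}

new_sigfuge_result <- function(base, labels, flag, ci_obs = NA_real_,
                               null_fit = NULL, pvalue = NA_real_,
                               assignment = NULL, curves = NULL) {
  structure(
    c(base, list(
      labels = labels,
      n_low = sum(labels == "low"),
      n_c1 = sum(labels == "cluster1"),
      n_c2 = sum(labels == "cluster2"),
      ci_obs = ci_obs, null_fit = null_fit,
      pvalue = if (endsWith(flag, "ok")) pvalue else NA_real_,
      flag = flag, assignment = assignment, curves = curves
    )),
    class = "sigfuge_result"
  )
}

#' @export
print.sigfuge_result <- function(x, ...) {
  cat(sprintf("<sigfuge_result> %s: %d low / %d + %d clustered; flag = %s\n",
              x$gene_id, x$n_low, x$n_c1, x$n_c2, x$flag))
  if (identical(x$flag, "ok"))
    cat(sprintf("  CI = %.4f, null %.4f (sd %.4f), p = %.3g\n",
                x$ci_obs, x$null_fit$mean, x$null_fit$sd, x$pvalue))
  invisible(x)
}

#' Benjamini-Hochberg FDR control across loci
#'
#' Standard step-up procedure: with sorted p-values \eqn{p_{(1)} \le \dots
#' \le p_{(m)}}, find the largest \eqn{i} with \eqn{p_{(i)} \le i q / m}
#' and reject hypotheses 1..i.  Adjusted q-values are the monotone
#' \eqn{p \cdot m / rank} (cumulative minimum from the largest rank), as
#' computed by [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NAs pass through).
#' @param q Target FDR level (default 0.05).
#' @return Tibble with columns `pvalue`, `qvalue`, `reject`, in input
#'   order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04), q = 0.05)  # all rejected
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0)
    return(tibble::tibble(pvalue = numeric(), qvalue = numeric(),
                          reject = logical()))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  qv <- p.adjust(pvalues, method = "BH")
  tibble::tibble(pvalue = pvalues, qvalue = qv,
                 reject = !is.na(qv) & qv <= q)
}

#' Pearson chi-square tests for label concordance tables
#'
#' For a vector of category counts, a goodness-of-fit test against equal
#' expected proportions across the categories (statistic
#' \eqn{\sum_j (o_j - T/k)^2 / (T/k)}, df = k - 1).  For a matrix, the
#' standard r x c test of independence.  Used to ask whether cluster labels
#' distribute uniformly across categories of an external annotation (e.g.
#' alteration status), row by row, or whether the whole table shows
#' association.
#'
#' @param counts Non-negative integer vector (goodness of fit) or matrix
#'   (independence).
#' @return One-row tibble with `statistic`, `df`, `pvalue`.
#' @examples
#' chisq_uniform_gof(c(10, 10, 10))  # statistic 0, p = 1
#' @export
chisq_uniform_gof <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    if (sum(counts) <= 0) abort("counts must not be all zero")
    ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  } else {
    if (any(counts < 0)) abort("counts must be non-negative")
    if (sum(counts) <= 0) abort("counts must not be all zero")
    k <- length(counts)
    ct <- suppressWarnings(chisq.test(counts, p = rep(1 / k, k)))
  }
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 pvalue = unname(ct$p.value))
}
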