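#' Two-isoform gene-model templates for simulation
#'
#' Two canonical alternative-splicing layouts, each splitting a gene of
#' total exonic length `d` into equal-length exons:
#'
#' * `cassette3`: three exons; isoform A skips the middle (cassette) exon
#'   (A = \{e1, e3\}), isoform B contains all three.
#' * `altcassette4`: four exons; the two isoforms share the first and last
#'   exon but use distinct middle exons (A = \{e1, e2, e4\},
#'   B = \{e1, e3, e4\}).
#'
#' @param kind `"cassette3"` or `"altcassette4"`.
#' @param d Total gene length in bp; must be divisible by the exon count.
#' @return A list of class `iso_spec` with `kind`, `exon_lengths` and
#'   `isoforms` (a 2-element list of exon-index vectors, named A and B).
#' @examples
#' gene_template("cassette3", 1200)  # three 400 bp exons
#' @export
gene_template <- function(kind = c("cassette3", "altcassette4"), d = 1200) {
  kind <- match.arg(kind)
  n_exons <- switch(kind, cassette3 = 3L, altcassette4 = 4L)
  if (d %% n_exons != 0)
    abort(sprintf("gene length %d is not divisible into %d equal exons", d, n_exons))
  isoforms <- switch(kind,
    cassette3 = list(A = c(1L, 3L), B = c(1L, 2L, 3L)),
    altcassette4 = list(A = c(1L, 2L, 4L), B = c(1L, 3L, 4L))
  )
  structure(list(kind = kind,
                 exon_lengths = rep(d %/% n_exons, n_exons),
                 isoforms = isoforms),
            class = "iso_spec")
}

#' Simulation configuration for one experimental setting
#'
#' Describes a single-locus experiment with two sample subpopulations that
#' share the same expected expression on constitutive exons but mix the two
#' isoforms in different proportions.  The defaults are the baseline
#' condition of the power study: 50 + 50 samples, a 1200 bp three-exon
#' cassette gene, per-base depth 100, negative-binomial dispersion 0.179
#' (the middle quartile of dispersions estimated from a published human
#' RNA-seq dataset), and isoform mixes 1:3 versus 3:1.
#'
#' @param n1,n2 Subpopulation sample sizes.
#' @param d Gene length in bp.
#' @param mu Expected gene-level per-base read depth.
#' @param phi NB dispersion (variance = mean + phi * mean^2); 0 gives
#'   Poisson isoform depths.
#' @param template `"cassette3"` or `"altcassette4"`.
#' @param p1,p2 Isoform mixing proportions (A, B) for subpopulations 1 and
#'   2; each must sum to 1.  Identical mixes give a null setting.
#' @param alpha Significance level used when counting detections.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n1 = 50, n2 = 50, d = 1200, mu = 100, phi = 0.179,
                       template = c("cassette3", "altcassette4"),
                       p1 = c(0.25, 0.75), p2 = c(0.75, 0.25),
                       alpha = 0.05) {
  template <- match.arg(template)
  stopifnot(n1 + n2 >= 2, n1 >= 0, n2 >= 0, mu > 0, phi >= 0,
            length(p1) == 2, length(p2) == 2,
            abs(sum(p1) - 1) < 1e-8, abs(sum(p2) - 1) < 1e-8,
            all(p1 >= 0), all(p2 >= 0), alpha >= 0, alpha <= 1)
  spec <- gene_template(template, d)  # validates divisibility
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), d = as.integer(d),
                 mu = mu, phi = phi, template = template, spec = spec,
                 p1 = p1, p2 = p2, alpha = alpha),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s: n = %d + %d, d = %d, mu = %g, phi = %g, mixes (%g, %g) vs (%g, %g)\n",
    x$template, x$n1, x$n2, x$d, x$mu, x$phi, x$p1[1], x$p1[2], x$p2[1], x$p2[2]))
  invisible(x)
}

# 0/1 membership matrix: 2 isoforms x d positions
membership_matrix <- function(spec) {
  d <- sum(spec$exon_lengths)
  ends <- cumsum(spec$exon_lengths)
  starts <- c(0L, utils::head(ends, -1L)) + 1L
  memb <- matrix(0, nrow = 2, ncol = d)
  for (k in 1:2) {
    for (e in spec$isoforms[[k]]) memb[k, starts[e]:ends[e]] <- 1
  }
  memb
}

# NB draws with variance = mean + phi * mean^2, vectorized over means;
# phi = 0 degenerates to Poisson, mean 0 to exact zero
rnb_disp <- function(means, phi) {
  out <- integer(length(means))
  pos <- means > 0
  if (any(pos)) {
    out[pos] <- if (phi == 0) rpois(sum(pos), means[pos])
                else rnbinom(sum(pos), size = 1 / phi, mu = means[pos])
  }
  out
}

#' Simulate a per-base coverage matrix with two-isoform structure
#'
#' For each sample, an integer expression depth is drawn independently for
#' each of the two isoforms from a negative binomial with mean
#' `mu * p_k` (the gene-level depth times the isoform's mixing proportion
#' in that sample's subpopulation) and dispersion `phi`.  The expected
#' coverage at a position is the sum of the depths of the isoforms whose
#' exons contain it; the realised per-base count is an independent Poisson
#' draw around that level, modelling the read-sampling (shot) noise of
#' sequencing coverage.  Expected depth on constitutive exons is `mu` in
#' both subpopulations; only the isoform balance differs between them.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional RNG seed.
#' @return A [coverage_matrix()] with an extra field `truth` giving the
#'   hidden subpopulation of each sample (1 or 2); samples are named
#'   `p1_*` / `p2_*`.
#' @export
simulate_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed_if(seed, {
    memb <- membership_matrix(cfg$spec)
    n <- cfg$n1 + cfg$n2
    truth <- rep(1:2, c(cfg$n1, cfg$n2))
    mixes <- rbind(cfg$p1, cfg$p2)[truth, , drop = FALSE]
    lam <- matrix(0, nrow = n, ncol = 2)
    for (k in 1:2) lam[, k] <- rnb_disp(cfg$mu * mixes[, k], cfg$phi)
    depth <- lam %*% memb  # expected coverage: piecewise constant over exons
    counts <- matrix(rpois(length(depth), depth), nrow = n)
    ids <- paste0("p", truth, "_", unlist(lapply(c(cfg$n1, cfg$n2), seq_len)))
    out <- coverage_matrix(counts, ids, gene_id = paste0("sim_", cfg$template))
    out$truth <- truth
    out
  })
}

#' Run one simulation setting through the full pipeline
#'
#' Repeatedly simulates a dataset under `cfg` and analyses it with
#' [sigfuge_gene()], recording the per-replicate p-value.  Per-replicate
#' seeds are `master_seed + rep - 1`, so results are fully reproducible and
#' individual replicates can be re-run in isolation.
#'
#' @param cfg A [sim_config()].
#' @param n_reps Number of replications (default 100).
#' @param fp,sp Pipeline parameters ([filter_params()],
#'   [sigclust_params()]).
#' @param master_seed Integer seed governing every replicate.
#' @return A tibble of class `sigfuge_study` with columns `rep`, `seed`,
#'   `pvalue`, `ci`, `flag`, and attributes `n_significant`
#'   (#\{p < alpha\}), `alpha` and `config`.
#' @export
run_setting <- function(cfg, n_reps = 100, fp = filter_params(),
                        sp = sigclust_params(), master_seed = 1) {
  stopifnot(n_reps >= 1)
  seeds <- as.integer(master_seed) + seq_len(n_reps) - 1L
  rows <- purrr::map(seq_len(n_reps), function(r) {
    res <- tryCatch(
      withr::with_seed(seeds[r], {
        m <- simulate_dataset(cfg)
        sigfuge_gene(m, fp = fp, sp = sp)
      }),
      error = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(rep = r, seed = seeds[r], pvalue = NA_real_,
                     ci = NA_real_, flag = "error")
    } else {
      tibble::tibble(rep = r, seed = seeds[r], pvalue = res$pvalue,
                     ci = res$ci_obs, flag = res$flag)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sigfuge_study", class(out))
  attr(out, "alpha") <- cfg$alpha
  attr(out, "config") <- cfg
  attr(out, "n_significant") <- sum(out$pvalue < cfg$alpha, na.rm = TRUE)
  out
}

#' @export
print.sigfuge_study <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<sigfuge_study> %s: %d / %d replications significant at alpha = %g\n",
              cfg$template, attr(x, "n_significant"), nrow(x), attr(x, "alpha")))
  NextMethod()
}

#' Joint multi-locus simulation
#'
#' Simulates a mixture of null loci (no subpopulation structure) and
#' non-null loci (differential isoform usage, drawn round-robin from
#' `nonnull_cfgs`), scores each independently with the full pipeline, and
#' returns per-locus p-values with truth labels — the input for ROC and
#' FDR-calibration summaries.
#'
#' @param n_null,n_nonnull Numbers of null and non-null loci.
#' @param null_cfg [sim_config()] used for null loci (identical mixes).
#' @param nonnull_cfgs List of [sim_config()]s cycled over the non-null
#'   loci.
#' @param fp,sp Pipeline parameters.
#' @param master_seed Integer seed.
#' @return Tibble with columns `gene`, `truth` (0 null / 1 non-null),
#'   `pvalue`, `flag`.
#' @export
joint_study <- function(n_null, n_nonnull,
                        null_cfg = sim_config(n1 = 50, n2 = 50,
                                              p1 = c(0.5, 0.5), p2 = c(0.5, 0.5)),
                        nonnull_cfgs = list(sim_config()),
                        fp = filter_params(), sp = sigclust_params(),
                        master_seed = 1) {
  stopifnot(n_null >= 0, n_nonnull >= 0, n_null + n_nonnull >= 1)
  cfgs <- c(rep(list(null_cfg), n_null),
            rep(nonnull_cfgs, length.out = n_nonnull))
  truth <- rep(c(0L, 1L), c(n_null, n_nonnull))
  seeds <- as.integer(master_seed) + seq_along(cfgs) - 1L
  rows <- purrr::map(seq_along(cfgs), function(g) {
    res <- tryCatch(
      withr::with_seed(seeds[g], {
        sigfuge_gene(simulate_dataset(cfgs[[g]]), fp = fp, sp = sp)
      }),
      error = function(e) NULL
    )
    tibble::tibble(gene = sprintf("gene_%05d", g), truth = truth[g],
                   pvalue = if (is.null(res)) NA_real_ else res$pvalue,
                   flag = if (is.null(res)) "error" else res$flag)
  })
  dplyr::bind_rows(rows)
}

#' ROC summary: AUC, TPR and F1 at fixed specificity
#'
#' Area under the ROC curve in the Mann-Whitney form — the fraction of
#' (positive, negative) pairs whose scores are correctly ordered, ties
#' counted 1/2 — plus the true-positive rate and F1 measure at the
#' operating points where specificity first reaches 90% and 95%.
#'
#' @param scores Numeric scores, larger = more significant (use
#'   `-pvalue` for p-values).
#' @param truth Binary labels (1 = positive class).
#' @return One-row tibble with `auc`, `tpr_90`, `tpr_95`, `f1_90`,
#'   `f1_95`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # AUC 0.75
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth != 0)
  if (!any(truth == 1) || !any(truth == 0))
    abort("both classes must be present to compute a ROC curve")
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))

  at_spec <- function(target) {
    # smallest threshold (over observed scores) with specificity >= target;
    # predict positive when score >= threshold
    cand <- sort(unique(scores), decreasing = TRUE)
    best <- c(tpr = 0, f1 = 0)
    for (t in cand) {
      spec <- mean(neg < t)
      if (spec < target) break
      tp <- sum(pos >= t)
      fp <- sum(neg >= t)
      fn <- length(pos) - tp
      best <- c(tpr = tp / length(pos),
                f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
    }
    best
  }
  s90 <- at_spec(0.90)
  s95 <- at_spec(0.95)
  tibble::tibble(auc = auc, tpr_90 = s90[["tpr"]], tpr_95 = s95[["tpr"]],
                 f1_90 = s90[["f1"]], f1_95 = s95[["f1"]])
}
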