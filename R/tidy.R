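#' Tidy per-sample labels from a per-locus result
#'
#' @param x A `sigfuge_result` from [sigfuge_gene()] or [sigfuge_exon()].
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `label` (`"low"`,
#'   `"cluster1"`, `"cluster2"`).
#' @export
tidy.sigfuge_result <- function(x, ...) {
  tibble::tibble(sample_id = names(x$labels), label = unname(x$labels))
}

#' One-row summary of a per-locus result
#'
#' @param x A `sigfuge_result`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, sample counts per class, the observed
#'   cluster index, the fitted null mean/SD, `pvalue` and `flag`.
#' @export
glance.sigfuge_result <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, n_total = x$n_total, n_low = x$n_low,
    n_c1 = x$n_c1, n_c2 = x$n_c2, ci = x$ci_obs,
    null_mean = if (is.null(x$null_fit)) NA_real_ else x$null_fit$mean,
    null_sd = if (is.null(x$null_fit)) NA_real_ else x$null_fit$sd,
    pvalue = x$pvalue, flag = x$flag
  )
}

#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::tibble(sample_id = names(x$labels) %||%
                   paste0("s", seq_along(x$labels)),
                 cluster = unname(x$labels))
}

#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(n1 = sum(x$labels == 1), n2 = sum(x$labels == 2),
                 within_ss = x$within_ss, total_ss = x$total_ss, ci = x$CI)
}

#' @export
tidy.sigfuge_study <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sigfuge_study")
  out
}

#' @export
glance.sigfuge_study <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    template = cfg$template, n1 = cfg$n1, n2 = cfg$n2, d = cfg$d,
    mu = cfg$mu, phi = cfg$phi, n_reps = nrow(x),
    alpha = attr(x, "alpha"), n_significant = attr(x, "n_significant")
  )
}

#' @export
tidy.filter_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "filter_report")
  out
}
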