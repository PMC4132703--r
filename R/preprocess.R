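#' Filtering parameters for low-expression samples
#'
#' A sample is excluded from the clustering of a locus when more than
#' `max_zero_fraction` of its base-positions have zero coverage, or when the
#' median coverage over its covered (strictly positive) positions is below
#' `min_covered_median`.  Both boundaries are strict: a zero fraction of
#' exactly 0.90 or a covered median of exactly 5 is retained.  When fewer
#' than `min_samples` samples survive, the locus is flagged and no
#' clustering is attempted.
#'
#' @param max_zero_fraction Exclusion threshold on the fraction of
#'   zero-coverage positions (default 0.90; exclusion requires strictly
#'   greater).
#' @param min_covered_median Minimum median read depth over covered
#'   positions (default 5 reads; exclusion requires strictly less).
#' @param min_samples Minimum number of retained samples for the locus to
#'   be analysed (default 10).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(max_zero_fraction = 0.90, min_covered_median = 5,
                          min_samples = 10) {
  stopifnot(max_zero_fraction > 0, max_zero_fraction < 1,
            min_covered_median >= 0, min_samples >= 2)
  structure(list(max_zero_fraction = max_zero_fraction,
                 min_covered_median = min_covered_median,
                 min_samples = min_samples),
            class = "filter_params")
}

#' Identify and exclude lowly expressed samples at a locus
#'
#' Computes per-sample diagnostics (fraction of zero-coverage positions and
#' median depth over covered positions) and applies the exclusion rule of
#' [filter_params()].  Excluded samples form the separate "low expression"
#' class of the three-way output labels; they are never clustered.
#'
#' @param m A [coverage_matrix()] or wide data frame
#'   (`sample_id` + one column per position).
#' @param params A [filter_params()] object.
#' @return A tibble of class `filter_report` with columns `sample_id`,
#'   `zero_fraction`, `covered_median` (NA for all-zero samples) and
#'   `retained`, plus attributes `gene_flag` (`"ok"` or
#'   `"too_few_samples"`) and `gene_id`.
#' @examples
#' m <- coverage_matrix(rbind(a = rep(10L, 10), b = rep(0L, 10)))
#' filter_low_expression(m)  # b is excluded (all-zero)
#' @export
filter_low_expression <- function(m, params = filter_params()) {
  m <- as_coverage_matrix(m)
  stopifnot(inherits(params, "filter_params"))
  if (nrow(m$counts) < 1) abort("coverage matrix has no samples")
  zero_fraction <- rowMeans(m$counts == 0)
  covered_median <- apply(m$counts, 1, function(row) {
    cov <- row[row > 0]
    if (length(cov) == 0) NA_real_ else median(cov)
  })
  retained <- zero_fraction <= params$max_zero_fraction &
    !is.na(covered_median) & covered_median >= params$min_covered_median
  out <- tibble::tibble(sample_id = m$sample_ids,
                        zero_fraction = unname(zero_fraction),
                        covered_median = unname(covered_median),
                        retained = unname(retained))
  class(out) <- c("filter_report", class(out))
  attr(out, "gene_id") <- m$gene_id
  attr(out, "gene_flag") <- if (sum(retained) < params$min_samples)
    "too_few_samples" else "ok"
  out
}

#' Count-normalize and log-transform expression curves
#'
#' Removes whole-gene expression differences between the retained samples so
#' that clustering responds to curve *shape* (isoform usage) rather than
#' overall level.  Each retained row is scaled to a common total coverage
#' `C` (the median of the retained row sums), then mapped through
#' `log(x + 1)` so zero counts remain exactly zero.  Any positive choice of
#' `C`, and any log base, yields the same downstream clustering and cluster
#' index; base 2 is the genomics convention.
#'
#' @param m A [coverage_matrix()] or wide data frame.
#' @param retained Character vector of sample ids to keep, or a
#'   `filter_report` from [filter_low_expression()].  Default keeps all.
#' @param log_base Base of the log transform (default 2).
#' @return An object of class `normalized_curves`: list with `values`
#'   (matrix, retained samples x positions), `sample_ids`,
#'   `scale_constant`, `log_base`, `gene_id`, `positions`.
#' @examples
#' m <- coverage_matrix(rbind(a = rep(1L, 4), b = rep(2L, 4)))
#' nc <- normalize_curves(m)
#' nc$values[1, 1]  # log2(1 * 6/4 + 1) = log2(2.5)
#' @export
normalize_curves <- function(m, retained = NULL, log_base = 2) {
  m <- as_coverage_matrix(m)
  if (inherits(retained, "filter_report"))
    retained <- retained$sample_id[retained$retained]
  if (is.null(retained)) retained <- m$sample_ids
  if (length(retained) == 0) abort("no retained samples to normalize")
  missing <- setdiff(retained, m$sample_ids)
  if (length(missing) > 0)
    abort(sprintf("retained sample(s) not in matrix: %s",
                  paste(missing, collapse = ", ")))
  x <- m$counts[match(retained, m$sample_ids), , drop = FALSE]
  r <- rowSums(x)
  if (any(r == 0))
    abort("retained sample with zero total coverage; filter before normalizing")
  C <- median(r)
  scaled <- x * (C / r)  # rows now sum exactly to C
  values <- log(scaled + 1, base = log_base)
  structure(
    list(values = values, sample_ids = retained, scale_constant = C,
         log_base = log_base, gene_id = m$gene_id, positions = m$positions),
    class = "normalized_curves"
  )
}

#' @export
print.normalized_curves <- function(x, ...) {
  cat(sprintf(
    "<normalized_curves> %s: %d sample(s) x %d position(s), C = %g, log base %g\n",
    x$gene_id, nrow(x$values), ncol(x$values), x$scale_constant, x$log_base))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.normalized_curves <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$values), .name_repair = "minimal")
  names(out) <- paste0(x$positions$chrom, ":", x$positions$pos)
  dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids), out)
}
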