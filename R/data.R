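#' Published CDKN2A cluster / alteration concordance table
#'
#' The published contingency table comparing the three-way per-locus labels
#' (red = low expression, green / blue = the two expression clusters) at
#' the CDKN2A tumor-suppressor locus in 177 lung squamous cell carcinoma
#' samples against the three major modes of CDKN2A inactivation from the
#' TCGA integrative analysis: homozygous deletion, epigenetic silencing by
#' methylation, and point mutation.  Useful as a worked example for
#' [chisq_uniform_gof()] and for label-composition summaries: its diagonal
#' structure (deleted samples land in the low-expression class, methylated
#' samples in one expression cluster) is what validates the three-way
#' labelling on real data.
#'
#' @return Tibble with columns `alteration` (homozygous_deleted, mutated,
#'   methylated, none) and integer counts `red`, `green`, `blue`.
#' @examples
#' tab <- cdkn2a_alterations()
#' chisq_uniform_gof(as.numeric(tab[2, c("red", "green", "blue")]))
#' @export
cdkn2a_alterations <- function() {
  tibble::tibble(
    alteration = c("homozygous_deleted", "mutated", "methylated", "none"),
    red   = c(46L, 0L, 1L, 1L),
    green = c(0L, 29L, 0L, 36L),
    blue  = c(8L, 3L, 41L, 12L)
  )
}
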