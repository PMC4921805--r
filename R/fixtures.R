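#' Published cluster summary for the LTR 2 / LTR 24 acceptor loci
#'
#' The 16 clusters of phylogenetically equivalent SNPs reported by the
#' Y-chromosome LTR resequencing study the package's defaults are
#' calibrated against: outermost member coordinates (1-based inclusive,
#' hg19 chrY), the printed cluster length, the minimum/maximum
#' conversion-tract bounds, and the donor regions identified by exact
#' identity of the derived tract. `NA` tract bounds mark clusters the
#' donor search excluded (span < 3 bp) or with too many candidate
#' donors. Used by consistency checks that recompute the printed
#' arithmetic (spans, tract-length summaries) from the raw coordinates.
#'
#' @return A data.frame with columns `cluster`, `element`, `snps`,
#'   `n_snps`, `haplogroup`, `chrom`, `start`, `end`, `printed_span`,
#'   `min_tract`, `max_tract`, `donors` (semicolon-separated
#'   `chrom:start-end`), `note`.
#' @export
ltr_cluster_summary <- function() {
  read.delim(
    system.file("extdata", "ltr_cluster_summary.tsv", package = "ltrconv"),
    stringsAsFactors = FALSE
  )
}

#' Clustered-vs-conventional SNP counts across resequencing studies
#'
#' Contingency counts of clustered and conventional (solitary) SNPs in
#' the LTR acceptor panel and in three whole-MSY resequencing callsets,
#' as published; inputs to the Fisher comparisons of clustered-SNP
#' proportions between the LTR panel and genome-scale surveys.
#'
#' @return A data.frame with columns `study`, `region`, `clustered`,
#'   `conventional`.
#' @export
clustered_snp_studies <- function() {
  read.delim(
    system.file("extdata", "clustered_snp_studies.tsv", package = "ltrconv"),
    stringsAsFactors = FALSE
  )
}
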