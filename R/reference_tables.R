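ref_path <- function(file)
  system.file("extdata", file, package = "sgsfam", mustWork = TRUE)

#' Reference tables from a published familial suicide study
#'
#' Small plain-text tables transcribed from the printed results of a
#' genome-wide study of completed suicide in 43 extended Utah high-risk
#' families.  They serve as desk-scale reference inputs: family
#' characteristics (FSIR, observed/expected counts, genotyped cases,
#' meioses, per-family genome-wide thresholds), the reported shared
#' genomic regions, the four population-associated variants with their
#' allele-count data, and the printed demographic/enrichment summary
#' statistics.
#'
#' Two printed region rows are internally inconsistent (their printed
#' length differs slightly from `end - start`); they are kept exactly as
#' printed.
#'
#' @return a data frame.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
highrisk_families <- function() {
  utils::read.delim(ref_path("highrisk_families.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c(family = "character",
                                   fsir_p = "character"))
}

#' @rdname reference_tables
#' @export
sgs_regions <- function() {
  utils::read.delim(ref_path("sgs_regions.tsv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
assoc_variants <- function() {
  utils::read.delim(ref_path("assoc_variants.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
study_summaries <- function() {
  tab <- utils::read.delim(ref_path("study_summaries.tsv"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$value, tab$name)
}
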