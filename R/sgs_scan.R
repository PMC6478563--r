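#' Subset scan configuration
#'
#' @param min_subset_size smallest case subset scanned (default 3; must be
#'   >= 2).
#' @param min_markers_per_run runs spanning fewer markers are suppressed
#'   (default 1: every maximal run is reported).
#' @param missing_policy `"compatible"` (a missing genotype never breaks a
#'   run; default) or `"break"` (any missing genotype interrupts sharing).
#' @param max_subsets refusal cap on the number of subsets enumerated,
#'   guarding against accidental 2^n blowup (default 10000).
#' @return a `scan_config` list.
#' @export
scan_config <- function(min_subset_size = 3, min_markers_per_run = 1,
                        missing_policy = c("compatible", "break"),
                        max_subsets = 10000) {
  stopifnot(min_subset_size >= 2, min_markers_per_run >= 1)
  structure(list(min_subset_size = as.integer(min_subset_size),
                 min_markers_per_run = as.integer(min_markers_per_run),
                 missing_policy = match.arg(missing_policy),
                 max_subsets = as.integer(max_subsets)),
            class = "scan_config")
}

#' Single-marker sharing indicator
#'
#' Is there one allele that every individual could carry?  For biallelic
#' dosages this fails only when both homozygote classes (0 and 2) are
#' present; heterozygotes carry both alleles and are compatible with
#' anything.  Missing genotypes are compatible by default, or break sharing
#' under the `"break"` policy.
#'
#' @param genotypes vector of dosages in `{0, 1, 2, NA}`.
#' @param missing_policy `"compatible"` or `"break"`.
#' @return `TRUE` if all individuals can share an allele identical by state.
#' @export
sharing_indicator <- function(genotypes,
                              missing_policy = c("compatible", "break")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(length(genotypes) > 0)
  if (missing_policy == "break" && anyNA(genotypes)) return(FALSE)
  g <- genotypes[!is.na(genotypes)]
  !(any(g == 0) && any(g == 2))
}

# runs matrix (subset, chrom, start, end with global marker indices) ->
# segment data frame with bp coordinates
runs_to_segments <- function(runs, map, subsets, case_ids) {
  if (nrow(runs) == 0)
    return(data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), length_bp = integer(0),
                      start_index = integer(0), end_index = integer(0),
                      n_markers = integer(0), subset = character(0),
                      size = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  members <- vapply(runs[, "subset"], function(s)
    paste(case_ids[subsets[[s]]], collapse = ","), character(1))
  sizes <- vapply(runs[, "subset"], function(s)
    length(subsets[[s]]), integer(1))
  seg <- data.frame(
    chrom = map$chrom[runs[, "start"]],
    start_bp = map$bp[runs[, "start"]],
    end_bp = map$bp[runs[, "end"]],
    start_index = runs[, "start"],
    end_index = runs[, "end"],
    subset = members, size = sizes,
    stringsAsFactors = FALSE)
  seg$length_bp <- seg$end_bp - seg$start_bp
  seg$n_markers <- seg$end_index - seg$start_index + 1L
  seg$p_value <- NA_real_
  o <- order(seg$chrom, seg$start_bp, seg$end_bp, seg$subset)
  seg <- seg[o, c("chrom", "start_bp", "end_bp", "length_bp", "start_index",
                  "end_index", "n_markers", "subset", "size", "p_value")]
  rownames(seg) <- NULL
  seg
}

#' Maximal shared segments for one case subset
#'
#' Finds, per chromosome, every maximal run of consecutive markers at which
#' all subset members share at least one allele identical by state.  Segment
#' coordinates are the bp positions of the first and last sharing marker;
#' `length_bp = end_bp - start_bp`.
#'
#' @param gm genotype matrix (individuals x markers; rownames are ids).
#' @param map marker map matching `gm` columns, sorted by chromosome and bp.
#' @param subset character vector of member ids (all rows of `gm`).
#' @param cfg a [scan_config()].
#' @return data frame of segments (one row per maximal run).
#' @export
maximal_shared_segments <- function(gm, map, subset, cfg = scan_config()) {
  missing <- setdiff(subset, rownames(gm))
  if (length(missing) > 0)
    stop(structure(
      class = c("sgsfam_membership_error", "error", "condition"),
      list(message = paste0("subset members absent from genotype matrix: ",
                            paste(missing, collapse = ", ")),
           call = sys.call())))
  validate_map(map)
  rows <- match(subset, rownames(gm))
  g <- gm[rows, , drop = FALSE]
  g[is.na(g)] <- -1L
  runs <- cpp_run_scan(g, list(seq_along(rows)), as.integer(map$chrom),
                       if (cfg$missing_policy == "break") 1L else 0L,
                       cfg$min_markers_per_run)
  runs_to_segments(runs, map, list(seq_along(subset)), subset)
}

#' Scan all case subsets for shared segments
#'
#' Runs [maximal_shared_segments()] for every subset of the case universe of
#' size at least `cfg$min_subset_size`, adjusting for within-family
#' heterogeneity: a region need not be shared by every case to count.
#' Segments from nested subsets are all retained.
#'
#' @param gm genotype matrix (individuals x markers).
#' @param map marker map.
#' @param cases character vector of genotyped case ids (the subset
#'   universe).
#' @param cfg a [scan_config()].
#' @return data frame of segments with subset labels, sorted by position.
#' @export
subset_scan <- function(gm, map, cases, cfg = scan_config()) {
  cases <- sort(unique(as.character(cases)))
  if (length(cases) < cfg$min_subset_size)
    stop("need at least ", cfg$min_subset_size, " genotyped cases")
  missing <- setdiff(cases, rownames(gm))
  if (length(missing) > 0)
    stop(structure(
      class = c("sgsfam_membership_error", "error", "condition"),
      list(message = paste0("cases absent from genotype matrix: ",
                            paste(missing, collapse = ", ")),
           call = sys.call())))
  validate_map(map)
  subsets <- enumerate_subsets(length(cases), cfg$min_subset_size,
                               cfg$max_subsets)
  rows <- match(cases, rownames(gm))
  g <- gm[rows, , drop = FALSE]
  g[is.na(g)] <- -1L
  runs <- cpp_run_scan(g, subsets, as.integer(map$chrom),
                       if (cfg$missing_policy == "break") 1L else 0L,
                       cfg$min_markers_per_run)
  runs_to_segments(runs, map, subsets, cases)
}

enumerate_subsets <- function(n, min_size, max_subsets) {
  total <- sum(choose(n, min_size:n))
  if (total > max_subsets)
    stop(sprintf(
      "refusing to scan %d subsets (cap %d); raise max_subsets deliberately",
      total, max_subsets))
  out <- list()
  for (k in min_size:n)
    out <- c(out, utils::combn(n, k, simplify = FALSE))
  lapply(out, as.integer)
}

#' Distinct segments of a scan
#'
#' Collapses duplicate rows describing the same genomic run at the same
#' subset size (different same-size subsets can produce identical runs).
#' This is the unit in which the gene-drop null records segments, so
#' per-genome segment counts should be compared on this scale.
#'
#' @param segments segment data frame.
#' @return `segments` with duplicates removed.
#' @export
distinct_segments <- function(segments) {
  key <- paste(segments$size, segments$chrom, segments$start_index,
               segments$end_index)
  segments[!duplicated(key), , drop = FALSE]
}

#' Write segments as BED and full-fidelity TSV
#'
#' The BED file uses half-open 0-based starts, name `family:subset` and
#' score `-log10(p)`; the TSV keeps every column.
#'
#' @param segments segment data frame.
#' @param family_id family identifier for the BED name column.
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @export
write_segments <- function(segments, family_id, bed_path = NULL,
                           tsv_path = NULL) {
  if (!is.null(bed_path)) {
    score <- ifelse(is.na(segments$p_value), 0,
                    round(-log10(segments$p_value), 3))
    bed <- data.frame(paste0("chr", segments$chrom),
                      segments$start_bp - 1L, segments$end_bp,
                      paste0(family_id, ":", segments$subset), score)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    utils::write.table(segments, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(segments)
}
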