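#' Fisher's combined probability test
#'
#' Combines independent p-values as X = -2 * sum(log p), referred to a
#' chi-square distribution with 2k degrees of freedom.  Identity for k = 1.
#'
#' @param pvals vector of p-values in (0, 1]; independence is the caller's
#'   responsibility (see [dedup_cases()]).
#' @return combined p-value.
#' @export
fisher_combined <- function(pvals) {
  if (length(pvals) == 0) stop("no p-values to combine")
  if (any(pvals <= 0))
    stop("p-values must be strictly positive; use the (c+1)/(n+1) ",
         "empirical estimator floor upstream")
  if (any(pvals > 1)) stop("p-values above 1")
  x <- -2 * sum(log(pvals))
  stats::pchisq(x, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Cross-family region overlap
#'
#' Retains single-family segments meeting the family's genome-wide
#' significant threshold, and forms multi-family candidate regions as the
#' base-pair intersections of suggestive-or-better segments from two or more
#' families.  Intersections are found by a sweep over segment endpoints:
#' each maximal interval covered by suggestive segments of at least two
#' families becomes one region, reported with each family's best covering
#' p-value.
#'
#' @param segments_by_family named list (family id -> segment data frame
#'   with filled `p_value`).
#' @param thresholds_by_family named list (family id -> `threshold_pair`).
#' @return data frame of regions: `chrom`, `start_bp`, `end_bp`,
#'   `length_bp`, `families` (comma-joined), `n_families`, per-family
#'   p-values (`p_values`, comma-joined), `subsets` and `sizes`
#'   (comma-joined), `tier` (`"significant"`/`"suggestive"` describing the
#'   weakest contributing family), `combined_p` (`NA` for single-family
#'   rows; fill with [fisher_combined()] after [dedup_cases()]).
#' @export
overlap_regions <- function(segments_by_family, thresholds_by_family) {
  stopifnot(all(names(segments_by_family) %in%
                  names(thresholds_by_family)))
  sugg <- list()
  out <- list()
  for (fam in names(segments_by_family)) {
    seg <- segments_by_family[[fam]]
    if (is.null(seg) || nrow(seg) == 0) next
    if (anyNA(seg$p_value)) stop("family ", fam, " has unfilled p-values")
    thr <- thresholds_by_family[[fam]]
    keep <- seg$p_value <= thr$suggestive
    if (any(keep)) {
      s <- seg[keep, , drop = FALSE]
      s$family <- fam
      s$tier <- ifelse(s$p_value <= thr$significant, "significant",
                       "suggestive")
      sugg[[fam]] <- s
    }
    sig <- seg[seg$p_value <= thr$significant, , drop = FALSE]
    if (nrow(sig) > 0)
      out[[length(out) + 1L]] <- data.frame(
        chrom = sig$chrom, start_bp = sig$start_bp, end_bp = sig$end_bp,
        length_bp = sig$end_bp - sig$start_bp, families = fam,
        n_families = 1L, p_values = format_num(sig$p_value),
        subsets = sig$subset, sizes = as.character(sig$size),
        tier = "significant", combined_p = NA_real_,
        stringsAsFactors = FALSE)
  }
  all_sugg <- do.call(rbind, unname(sugg))
  if (!is.null(all_sugg) && nrow(all_sugg) > 0) {
    for (ch in unique(all_sugg$chrom)) {
      s <- all_sugg[all_sugg$chrom == ch, , drop = FALSE]
      cuts <- sort(unique(c(s$start_bp, s$end_bp)))
      if (length(cuts) < 2) next
      open <- FALSE; reg_start <- NA; reg_fams <- character(0)
      flush <- function(start, end) {
        cover <- s$start_bp <= start & s$end_bp >= end
        fams <- sort(unique(s$family[cover]))
        rows <- lapply(fams, function(f) {
          sf <- s[cover & s$family == f, , drop = FALSE]
          sf[which.min(sf$p_value), , drop = FALSE]
        })
        best <- do.call(rbind, rows)
        data.frame(
          chrom = ch, start_bp = start, end_bp = end,
          length_bp = end - start, families = paste(fams, collapse = ","),
          n_families = length(fams),
          p_values = paste(format_num(best$p_value), collapse = ","),
          subsets = paste(best$subset, collapse = ";"),
          sizes = paste(best$size, collapse = ","),
          tier = if (all(best$tier == "significant")) "significant"
                 else "suggestive",
          combined_p = NA_real_, stringsAsFactors = FALSE)
      }
      # merge consecutive elementary intervals covered by the same family
      # set; nested and partially overlapping combinations are all
      # reported, each with its own intersection interval
      prev_set <- ""
      for (i in seq_len(length(cuts) - 1)) {
        lo <- cuts[i]; hi <- cuts[i + 1]
        fams <- sort(unique(s$family[s$start_bp <= lo & s$end_bp >= hi]))
        set <- paste(fams, collapse = ",")
        if (length(fams) >= 2) {
          if (!open || set != prev_set) {
            if (open) out[[length(out) + 1L]] <- flush(reg_start, lo)
            open <- TRUE; reg_start <- lo
          }
        } else if (open) {
          out[[length(out) + 1L]] <- flush(reg_start, lo)
          open <- FALSE
        }
        prev_set <- set
      }
      if (open) out[[length(out) + 1L]] <- flush(reg_start,
                                                 cuts[length(cuts)])
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), length_bp = integer(0),
                      families = character(0), n_families = integer(0),
                      p_values = character(0), subsets = character(0),
                      sizes = character(0), tier = character(0),
                      combined_p = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp, res$end_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

format_num <- function(x) formatC(x, format = "g", digits = 6)

#' Repair independence across families sharing individuals
#'
#' Individuals appearing in more than one contributing family violate the
#' independence assumption of Fisher's combination.  Each such individual is
#' kept in exactly one family: preferentially a family whose sharing subset
#' does not contain the individual (removal is then harmless); otherwise the
#' family with the larger sharing subset (ties: larger pedigree, then first
#' by name).  Families whose subset drops below two members are excluded
#' from the combination.
#'
#' @param families named list of `pedigree` objects for the contributing
#'   families.
#' @param subsets named list (family id -> character vector of sharing-case
#'   ids for the region).
#' @return list with `subsets` (adjusted), `flagged` (families needing
#'   p-value/threshold recomputation), `excluded` (families dropped), and
#'   `removed` (data frame individual/family of removals).
#' @export
dedup_cases <- function(families, subsets) {
  stopifnot(all(names(subsets) %in% names(families)))
  fams <- names(subsets)
  all_ids <- unlist(lapply(fams, function(f) unique(families[[f]]$id)))
  shared <- unique(all_ids[duplicated(all_ids)])
  removed <- data.frame(individual = character(0), family = character(0))
  flagged <- character(0)
  for (ind in shared) {
    present <- fams[vapply(fams, function(f)
      ind %in% families[[f]]$id, logical(1))]
    if (length(present) < 2) next
    in_subset <- vapply(present, function(f)
      ind %in% subsets[[f]], logical(1))
    keep <- if (any(!in_subset)) {
      # keep where removal elsewhere is harmless: prefer a family whose
      # subset NEEDS the individual; if none needs it, keep in the first
      if (any(in_subset)) present[in_subset][1] else present[1]
    } else {
      sz <- vapply(present, function(f) length(subsets[[f]]), integer(1))
      ps <- vapply(present, function(f) nrow(families[[f]]), integer(1))
      present[order(-sz, -ps, present)][1]
    }
    for (f in setdiff(present, keep)) {
      if (ind %in% subsets[[f]]) {
        subsets[[f]] <- setdiff(subsets[[f]], ind)
        flagged <- union(flagged, f)
        removed <- rbind(removed,
                         data.frame(individual = ind, family = f))
      }
    }
  }
  # only families whose subset was reduced can drop out of the combination
  excluded <- flagged[vapply(flagged, function(f)
    length(subsets[[f]]) < 2, logical(1))]
  list(subsets = subsets[setdiff(fams, excluded)], flagged = flagged,
       excluded = excluded, removed = removed)
}
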