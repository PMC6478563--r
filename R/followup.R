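#' Genes targeted by significant regions
#'
#' A gene is targeted when any of its coding or regulatory intervals
#' intersects any region; blacklisted genes (clusters known to generate
#' false positives, such as olfactory-receptor arrays) are removed after
#' intersection.  The result is deduplicated and sorted, so the operation is
#' idempotent and order-invariant.
#'
#' @param regions data frame with `chrom`, `start_bp`, `end_bp`.
#' @param genes gene models: data frame with one row per interval, columns
#'   `gene`, `chrom`, `start`, `end`, `type` (`"coding"`/`"regulatory"`)
#'   and logical `blacklist`.
#' @return sorted character vector of targeted gene ids.
#' @export
target_genes <- function(regions, genes) {
  if (nrow(regions) == 0 || nrow(genes) == 0) return(character(0))
  hit <- logical(nrow(genes))
  for (i in seq_len(nrow(regions)))
    hit <- hit | (genes$chrom == regions$chrom[i] &
                    genes$start <= regions$end_bp[i] &
                    genes$end >= regions$start_bp[i])
  sort(unique(genes$gene[hit & !genes$blacklist]))
}

#' Literature enrichment of targeted genes
#'
#' Compares the fraction of targeted genes with prior literature support to
#' the genome-wide background fraction: `expected` is the count of
#' supported genes expected if regions were a random sample of the genome,
#' and the one-sided z-statistic tests whether the observed proportion
#' exceeds the background.
#'
#' @param n_target number of targeted genes.
#' @param n_hit targeted genes with literature support.
#' @param n_genome genes in the genome (about 19,000 for human).
#' @param n_literature genes with literature support genome-wide.
#' @param method `"pooled"` (two-sample pooled-proportion z) or `"fixed"`
#'   (background treated as known: sqrt(p0 (1-p0) / n_target) denominator).
#' @return list with `expected`, `proportion`, `background`, `z`, `p`
#'   (upper normal tail).
#' @export
enrichment_test <- function(n_target, n_hit, n_genome, n_literature,
                            method = c("pooled", "fixed")) {
  method <- match.arg(method)
  if (n_target <= 0 || n_genome <= 0) stop("zero denominator")
  stopifnot(n_hit <= n_target, n_target <= n_genome,
            n_literature <= n_genome)
  p0 <- n_literature / n_genome
  ph <- n_hit / n_target
  se <- if (method == "pooled") {
    pp <- (n_hit + n_literature) / (n_target + n_genome)
    sqrt(pp * (1 - pp) * (1 / n_target + 1 / n_genome))
  } else {
    sqrt(p0 * (1 - p0) / n_target)
  }
  z <- (ph - p0) / se
  list(expected = n_target * p0, proportion = ph, background = p0, z = z,
       p = stats::pnorm(z, lower.tail = FALSE))
}

#' Screen familial variants inside regions
#'
#' For each region, lists the non-synonymous variants strictly within the
#' region boundaries with reference minor allele frequency below
#' `maf_cutoff` whose minor allele is carried (at least one copy) by every
#' case of the region's sharing subset.  An empty report means no available
#' array variant explains the observed sharing.
#'
#' @param regions data frame with `chrom`, `start_bp`, `end_bp` and
#'   `subsets` (comma-joined sharing-case ids; `;` separates families).
#' @param annotations variant annotation table: `variant_id`, `chrom`,
#'   `bp`, `gene`, `consequence`, `sift_call`, `polyphen_call`, `ref_maf`.
#'   The genotype column counted in `gm` must be the minor allele.
#' @param gm genotype matrix (individuals x markers, columns named by
#'   `variant_id`).
#' @param maf_cutoff reference MAF gate (default 0.10).
#' @return data frame `region`, `variant_id`, `gene`, `ref_maf`; zero rows
#'   when nothing qualifies.
#' @export
familial_variant_screen <- function(regions, annotations, gm,
                                    maf_cutoff = 0.10) {
  out <- list()
  nonsyn <- annotations$consequence %in% c("missense", "frameshift")
  for (i in seq_len(nrow(regions))) {
    cases <- unique(unlist(strsplit(regions$subsets[i], "[,;]")))
    cases <- intersect(cases, rownames(gm))
    cand <- which(nonsyn &
                    annotations$chrom == regions$chrom[i] &
                    annotations$bp >= regions$start_bp[i] &
                    annotations$bp <= regions$end_bp[i] &
                    annotations$ref_maf < maf_cutoff &
                    annotations$variant_id %in% colnames(gm))
    for (j in cand) {
      g <- gm[cases, annotations$variant_id[j]]
      if (length(g) > 0 && all(!is.na(g)) && all(g >= 1))
        out[[length(out) + 1L]] <- data.frame(
          region = i, variant_id = annotations$variant_id[j],
          gene = annotations$gene[j], ref_maf = annotations$ref_maf[j],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(region = integer(0), variant_id = character(0),
                      gene = character(0), ref_maf = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Select candidate variants for population association
#'
#' Keeps variants in the coding sequence of targeted genes that are
#' non-synonymous (missense or frameshift), predicted damaging by at least
#' one of the two predictors (logical OR over non-missing calls), with
#' reference minor allele frequency below `maf_cutoff`.
#'
#' @param annotations variant annotation table (see
#'   [familial_variant_screen()]).
#' @param target_gene_ids genes from [target_genes()].
#' @param maf_cutoff reference MAF gate (default 0.20).
#' @return the qualifying rows of `annotations`.
#' @export
select_assoc_variants <- function(annotations, target_gene_ids,
                                  maf_cutoff = 0.20) {
  damaging <- function(x) !is.na(x) & x == "damaging"
  keep <- annotations$gene %in% target_gene_ids &
    annotations$consequence %in% c("missense", "frameshift") &
    (damaging(annotations$sift_call) |
       damaging(annotations$polyphen_call)) &
    annotations$ref_maf < maf_cutoff
  annotations[keep, , drop = FALSE]
}

#' Case versus reference-population allele-count association
#'
#' Builds the 2x2 minor/major allele-count table for cases against the
#' reference population.  A Pearson chi-square test (no continuity
#' correction) is used when both groups have more than `min_chroms_chi`
#' chromosomes carrying the minor allele; otherwise Fisher's exact test
#' (two-sided, minimum-likelihood method).  Significance is Bonferroni:
#' p < alpha / m.
#'
#' @param case_minor,case_total minor-allele and total chromosome counts in
#'   cases (after excluding, upstream, any cases responsible for the
#'   original sharing evidence).
#' @param ref_minor,ref_total counts in the reference population.
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests for the Bonferroni correction.
#' @param min_chroms_chi chi-square branch gate (default 10).
#' @return data frame row: `p_value`, `test` (`"fisher_exact"` or
#'   `"chi_square"`), `threshold`, `significant`.
#' @export
popfreq_association <- function(case_minor, case_total, ref_minor,
                                ref_total, alpha = 0.05, m = 1,
                                min_chroms_chi = 10) {
  if (case_total <= 0 || ref_total <= 0)
    stop("zero total chromosome count")
  stopifnot(case_minor <= case_total, ref_minor <= ref_total,
            case_minor >= 0, ref_minor >= 0)
  tab <- matrix(c(case_minor, case_total - case_minor,
                  ref_minor, ref_total - ref_minor), nrow = 2,
                byrow = TRUE)
  if (case_minor > min_chroms_chi && ref_minor > min_chroms_chi) {
    test <- "chi_square"
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
  } else {
    test <- "fisher_exact"
    p <- stats::fisher.test(tab)$p.value
  }
  thr <- alpha / m
  data.frame(p_value = p, test = test, threshold = thr,
             significant = p < thr, stringsAsFactors = FALSE)
}

#' Association screen over selected variants
#'
#' Applies [popfreq_association()] to each row of a selected annotation
#' table carrying count columns `case_minor`, `case_total`, `ref_minor`,
#' `ref_total`; `m` defaults to the number of variants tested.
#'
#' @param variants selected annotation rows with count columns.
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests (default `nrow(variants)`).
#' @param min_chroms_chi chi-square branch gate (default 10).
#' @return `variants` with `p_value`, `test`, `threshold`, `significant`
#'   appended.
#' @export
assoc_screen <- function(variants, alpha = 0.05, m = nrow(variants),
                         min_chroms_chi = 10) {
  res <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i)
    popfreq_association(variants$case_minor[i], variants$case_total[i],
                        variants$ref_minor[i], variants$ref_total[i],
                        alpha = alpha, m = m,
                        min_chroms_chi = min_chroms_chi)))
  cbind(variants, res)
}

#' Two-sample t from summary statistics
#'
#' Pooled-variance two-sample t-statistic computed from printed means,
#' standard deviations and group sizes, for comparing demographic summaries
#' without unit-record data.
#'
#' @param m1,sd1,n1,m2,sd2,n2 group summaries.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
t_pooled <- function(m1, sd1, n1, m2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for two proportions from counts
#'
#' 2x2 Pearson chi-square without continuity correction, from event counts
#' and group sizes.
#'
#' @param x1,n1,x2,n2 event counts and group sizes.
#' @return list with `chisq`, `df`, `p`.
#' @export
prop_chisq <- function(x1, n1, x2, n2) {
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
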