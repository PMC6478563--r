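#' Shared genomic segment analysis of one family
#'
#' The core fitting function: scans every case subset for maximal runs of
#' identity-by-state allele sharing, builds the family's gene-drop null
#' distribution from the haplotype panel, assigns each observed segment an
#' empirical p-value, and derives the family-specific genome-wide
#' significant and suggestive thresholds from the fitted null exceedance
#' curve.
#'
#' @param ped a `pedigree`.
#' @param genotypes genotype matrix (individuals x markers, 0/1/2/NA
#'   counting the panel's 1 allele; rownames are ids) for at least the
#'   genotyped cases.
#' @param panel a [hap_panel()] whose map matches the genotype columns.
#' @param cases case ids to analyse (default: genotyped cases of `ped`).
#' @param cfg a [scan_config()]; the pipeline default raises
#'   `min_markers_per_run` to 10 so that only runs long enough to carry
#'   evidence are scored and stored.
#' @param n_sims gene-drop simulations for the null (default 10000; the
#'   full-study setting of 500000 is reachable here).
#' @param seed RNG seed for the null.
#' @param targets expected false positives per genome defining the
#'   (significant, suggestive) thresholds; default `c(0.5, 1)`.
#' @param checkpoint_path optional checkpoint RDS for long null runs.
#' @return object of class `sgs`: list with `segments` (observed segments
#'   with `p_value` and `tier`), `thresholds` (a `threshold_pair`), `null`
#'   (the `sgs_null`), `fit` (the `sgs_nullfit`), `family_id`, `cases`,
#'   `cfg`, `seed`.
#' @seealso [simulate_null()], [fit_null_model()],
#'   [genomewide_thresholds()], [overlap_regions()]
#' @export
sgs <- function(ped, genotypes, panel, cases = genotyped_cases(ped),
                cfg = scan_config(min_markers_per_run = 10),
                n_sims = 10000, seed = 1, targets = c(0.5, 1),
                checkpoint_path = NULL) {
  cases <- sort(unique(as.character(cases)))
  segments <- subset_scan(genotypes, panel$map, cases, cfg)
  null <- simulate_null(ped, panel, cases = cases, cfg = cfg,
                        n_sims = n_sims, seed = seed,
                        checkpoint_path = checkpoint_path)
  segments <- empirical_pvalue(segments, null)
  fit <- fit_null_model(null)
  thr <- genomewide_thresholds(fit, targets = targets)
  segments$tier <- ifelse(segments$p_value <= thr$significant,
                          "significant",
                          ifelse(segments$p_value <= thr$suggestive,
                                 "suggestive", "none"))
  structure(list(segments = segments, thresholds = thr, null = null,
                 fit = fit, family_id = attr(ped, "family_id"),
                 cases = cases, cfg = cfg, seed = seed, ped = ped,
                 panel = panel),
            class = "sgs")
}

#' @method print sgs
#' @export
print.sgs <- function(x, ...) {
  cat(sprintf("SGS analysis of family %s: %d cases, %d subsets scanned\n",
              x$family_id, length(x$cases),
              length(enumerate_subsets(length(x$cases),
                                       x$cfg$min_subset_size,
                                       x$cfg$max_subsets))))
  cat(sprintf("  null: %d gene-drop simulations (seed %s)\n",
              x$null$n_sims, format(x$seed)))
  cat(sprintf("  thresholds: significant %.3g, suggestive %.3g\n",
              x$thresholds$significant, x$thresholds$suggestive))
  cat(sprintf("  segments: %d observed, %d significant, %d suggestive\n",
              nrow(x$segments), sum(x$segments$tier == "significant"),
              sum(x$segments$tier == "suggestive")))
  invisible(x)
}

#' @method summary sgs
#' @export
summary.sgs <- function(object, ...) {
  print(object)
  called <- object$segments[object$segments$tier != "none", , drop = FALSE]
  if (nrow(called) > 0) {
    cat("\nSegments at or beyond the suggestive threshold:\n")
    print(called[order(called$p_value),
                 c("chrom", "start_bp", "end_bp", "length_bp", "size",
                   "p_value", "tier")], row.names = FALSE)
  }
  invisible(object)
}

#' Plot observed sharing evidence along the genome
#'
#' Plots -log10 empirical p-values of the observed segments at their
#' midpoints, one panel strip per chromosome, with the family's
#' significant and suggestive thresholds as horizontal lines.
#'
#' @param x an `sgs` object.
#' @param ... passed to [graphics::plot()].
#' @method plot sgs
#' @export
plot.sgs <- function(x, ...) {
  seg <- x$segments
  if (nrow(seg) == 0) {
    plot.new(); title("no observed segments"); return(invisible(x))
  }
  chroms <- sort(unique(x$panel$map$chrom))
  span <- vapply(chroms, function(ch)
    max(x$panel$map$bp[x$panel$map$chrom == ch]), numeric(1))
  offs <- stats::setNames(c(0, cumsum(span))[seq_along(chroms)],
                          chroms)
  mid <- (seg$start_bp + seg$end_bp) / 2 + offs[as.character(seg$chrom)]
  y <- -log10(seg$p_value)
  graphics::plot(mid, y, pch = 16, cex = 0.6,
                 col = c(none = "grey50", suggestive = "orange",
                         significant = "red")[seg$tier],
                 xlab = "genome position (bp, chromosomes concatenated)",
                 ylab = expression(-log[10](italic(p))),
                 main = paste("Shared segments, family", x$family_id),
                 ...)
  graphics::abline(v = offs[-1], col = "grey85")
  graphics::abline(h = -log10(x$thresholds$significant), col = "red",
                   lty = 2)
  graphics::abline(h = -log10(x$thresholds$suggestive), col = "orange",
                   lty = 3)
  invisible(x)
}

#' Simulate genotype matrices under the fitted null
#'
#' Draws new gene-drop replicates for the family: founder haplotypes
#' resampled from the panel and transmitted with recombination, returning
#' one genotype matrix (cases x markers) per replicate.
#'
#' @param object an `sgs` object.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of genotype matrices.
#' @method simulate sgs
#' @export
simulate.sgs <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    fh <- assign_founder_haplotypes(object$ped, object$panel)
    drop_genes(object$ped, fh, object$panel,
               individuals = object$cases)
  })
}
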