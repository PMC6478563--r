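#' Fit the null exceedance curve
#'
#' Every recorded null run is itself assigned an empirical p-value against
#' the whole null (same covering-run counting as for observed segments),
#' and the expected number of distinct null segments per simulated genome
#' with p at or below a cutoff is tabulated on a log-spaced cutoff grid.
#' Threshold inversion uses the monotone hull of this empirical curve
#' directly wherever the target is observable; a log-log linear model
#' fitted to the lowest usable decade of the curve provides controlled
#' extrapolation below the resolution `1/n_sims` of the simulation.
#'
#' @param null an `sgs_null` from [simulate_null()].
#' @param grid_points number of cutoff grid points (default 25).
#' @param fit_max_count only grid points with expected count at or below
#'   this value (and above zero) enter the tail fit (default 50).
#' @param fit_sims number of simulations whose runs are scored for the
#'   exceedance curve (default 2000; tail counts always use the full
#'   null).  An unbiased cost control for very large nulls.
#' @return object of class `sgs_nullfit`: list with `grid` (cutoff,
#'   expected count), `coef` (intercept/slope on log10 scales),
#'   `diagnostics` (r-squared, in-sample relative error, counts), and the
#'   originating `n_sims`.
#' @export
fit_null_model <- function(null, grid_points = 25, fit_max_count = 50,
                           fit_sims = 2000) {
  stopifnot(inherits(null, "sgs_null"))
  if (null$n_sims < 1000)
    warning("null has fewer than 1000 simulations; thresholds will be crude")
  runs <- null$runs
  if (nrow(runs) == 0)
    stop(fit_degeneracy("null contains no recorded runs"))
  pv <- null_run_pvalues(null, fit_sims)
  p <- pv$p
  n <- null$n_sims
  cutoffs <- 10^seq(log10(1 / n), 0, length.out = grid_points)
  counts <- vapply(cutoffs, function(x) sum(p <= x), numeric(1)) / pv$n_used
  grid <- data.frame(cutoff = cutoffs, expected = counts)
  # monotone hull of the empirical curve, for direct inversion in range
  mono <- cummax(counts)
  use <- counts > 0 & counts <= fit_max_count
  if (sum(use) < 3)
    stop(fit_degeneracy(sprintf(
      "only %d grid points with usable counts (need >= 3)", sum(use))))
  # tail line for extrapolation below the observable range: lowest usable
  # decade of points (the curve is only locally log-log linear)
  tail_pts <- utils::head(which(use), 8)
  if (length(tail_pts) < 3) tail_pts <- which(use)
  fit <- stats::lm(log10(expected) ~ log10(cutoff),
                   data = grid[tail_pts, ])
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b <= 0)
    stop(fit_degeneracy("exceedance curve is not increasing in the cutoff"))
  pred <- 10^(a + b * log10(grid$cutoff[tail_pts]))
  diag <- list(
    r_squared = summary(fit)$r.squared,
    max_rel_err = max(abs(pred - grid$expected[tail_pts]) /
                        grid$expected[tail_pts]),
    mean_segments_per_sim = nrow(runs) / n,
    n_fit_points = length(tail_pts))
  structure(list(grid = grid, mono = mono,
                 sorted_p = sort.int(p), n_used = pv$n_used,
                 coef = c(intercept = a, slope = b),
                 diagnostics = diag, n_sims = n),
            class = "sgs_nullfit")
}

# invert the exceedance curve at one target expected count.  In the
# observable range the inversion is exact on the sorted null-run p-values:
# the largest attained p-value whose per-genome count of runs at or below
# it does not exceed the target (ties resolved conservatively).  Below the
# simulation's resolution the fitted log-log tail line extrapolates.
invert_exceedance <- function(fit, target) {
  s <- fit$sorted_p
  K <- floor(target * fit$n_used)
  if (K >= 1 && length(s) >= 1) {
    v <- s[min(K, length(s))]
    # ties may push the count at v past K; step down to the previous
    # attained value
    while (findInterval(v, s) > K) {
      below <- s[s < v]
      if (length(below) == 0) {
        v <- NA_real_
        break
      }
      v <- below[length(below)]
    }
    if (!is.na(v)) return(v)
  }
  unname(10^((log10(target) - fit$coef["intercept"]) /
               fit$coef["slope"]))
}

fit_degeneracy <- function(msg) {
  structure(class = c("sgsfam_fit_degeneracy_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

# empirical p-values of recorded null runs against the whole null; the
# queried runs are restricted to a deterministic subsample of simulations
# (tail counts still use every simulation), which is an unbiased and much
# cheaper estimate of the per-genome exceedance curve
null_run_pvalues <- function(null, fit_sims = null$n_sims) {
  runs <- null$runs
  n <- null$n_sims
  n_used <- min(n, fit_sims)
  qrows <- which(runs$sim <= n_used)
  p <- numeric(length(qrows))
  map <- null$map
  for (ci in seq_along(null$chrom_levels)) {
    ch <- null$chrom_levels[ci]
    m <- sum(map$chrom == ch)
    sel <- runs$chrom == ci
    gq <- which(runs$chrom[qrows] == ci)
    if (length(gq) == 0) next
    rq <- qrows[gq]
    cnt <- cpp_cover_tail_counts(runs$sim[sel], runs$start[sel],
                                 runs$end[sel],
                                 as.numeric(runs$len_bp[sel]),
                                 runs$size[sel], n, m,
                                 (runs$start[rq] + runs$end[rq]) %/% 2L,
                                 as.numeric(runs$len_bp[rq]),
                                 runs$size[rq])
    # leave-self-out: the run's own simulation always covers it, so the
    # comparable estimator over the other n - 1 simulations is cnt / n
    p[gq] <- cnt / n
  }
  list(p = p, n_used = n_used)
}

#' @method print sgs_nullfit
#' @export
print.sgs_nullfit <- function(x, ...) {
  cat(sprintf(
    "Null exceedance fit: E[count] = 10^%.3f * p^%.3f (R^2 = %.4f)\n",
    x$coef["intercept"], x$coef["slope"], x$diagnostics$r_squared))
  cat(sprintf("  mean segments per simulated genome: %.2f\n",
              x$diagnostics$mean_segments_per_sim))
  invisible(x)
}

#' Family-specific genome-wide thresholds
#'
#' Inverts the fitted exceedance curve at the target false-positive rates:
#' the significant threshold yields 0.5 expected false-positive segments per
#' genome per family, the suggestive threshold 1.0.
#'
#' @param fit an `sgs_nullfit` from [fit_null_model()].
#' @param targets expected false positives per genome for the
#'   (significant, suggestive) thresholds; default `c(0.5, 1)`.
#' @param max_extrapolation_decades how far below the smallest observable
#'   p-value the inversion may reach before a warning is recorded in the
#'   diagnostics (default 2).
#' @return object of class `threshold_pair`: list with `significant`,
#'   `suggestive`, `targets` and `diagnostics`.
#' @export
genomewide_thresholds <- function(fit, targets = c(0.5, 1),
                                  max_extrapolation_decades = 2) {
  stopifnot(inherits(fit, "sgs_nullfit"), length(targets) == 2,
            targets[1] <= targets[2])
  thr <- vapply(targets, function(t) invert_exceedance(fit, t),
                numeric(1))
  thr <- pmin(pmax(thr, .Machine$double.xmin), 1 - 1e-12)
  if (thr[1] > thr[2]) thr[1] <- thr[2]
  floor_p <- 2 / (fit$n_sims + 1)
  extrap <- log10(floor_p) - log10(thr[1])
  diag <- c(fit$diagnostics,
            list(extrapolation_decades = max(0, extrap),
                 extrapolation_warning =
                   extrap > max_extrapolation_decades))
  structure(list(significant = unname(thr[1]), suggestive = unname(thr[2]),
                 targets = targets, diagnostics = diag),
            class = "threshold_pair")
}

#' @method print threshold_pair
#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(
    "Genome-wide thresholds: significant %.3g (%.1f FP/genome), suggestive %.3g (%.1f FP/genome)\n",
    x$significant, x$targets[1], x$suggestive, x$targets[2]))
  if (isTRUE(x$diagnostics$extrapolation_warning))
    cat(sprintf("  note: significant threshold extrapolates %.1f decades below the simulation floor\n",
                x$diagnostics$extrapolation_decades))
  invisible(x)
}

#' Write a threshold table
#'
#' @param thresholds named list of `threshold_pair` objects (names are
#'   family ids).
#' @param path output TSV path.
#' @param diagnostics_path optional JSON path for fit diagnostics.
#' @export
write_thresholds <- function(thresholds, path, diagnostics_path = NULL) {
  tab <- data.frame(
    family_id = names(thresholds),
    significant = vapply(thresholds, `[[`, numeric(1), "significant"),
    suggestive = vapply(thresholds, `[[`, numeric(1), "suggestive"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(diagnostics_path))
    jsonlite::write_json(lapply(thresholds, `[[`, "diagnostics"),
                         diagnostics_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
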