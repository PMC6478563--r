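test_that("Fisher's combined probability matches closed forms", {
  expect_equal(fisher_combined(0.05), 0.05)
  expect_equal(fisher_combined(c(1, 1, 1)), 1)
  # k = 2: closed form exp(-X/2) (1 + X/2)
  x <- -2 * sum(log(c(0.01, 0.01)))
  expect_equal(fisher_combined(c(0.01, 0.01)), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-12)
  expect_equal(round(fisher_combined(c(0.01, 0.01)), 6), 0.001021)
  expect_error(fisher_combined(c(0.1, 0)), "positive")
  expect_error(fisher_combined(numeric(0)), "no p-values")
})

test_that("combined p is order-invariant, weakened by null evidence, and
           matches Monte-Carlo combination of uniforms", {
  p <- c(0.02, 0.3, 0.07)
  expect_equal(fisher_combined(p), fisher_combined(rev(p)))
  expect_gt(fisher_combined(c(p, 1)), fisher_combined(p) * 0.99)

  set.seed(107)
  for (k in 2:5) {
    n <- 200000
    u <- matrix(stats::runif(n * k), n, k)
    x <- -2 * rowSums(log(u))
    xobs <- -2 * sum(log(seq(0.05, 0.5, length.out = k)))
    mc <- mean(x >= xobs)
    an <- fisher_combined(seq(0.05, 0.5, length.out = k))
    se <- sqrt(mc * (1 - mc) / n)
    expect_lt(abs(mc - an), 3 * se + 1e-6, label = paste("k =", k))
  }
})

make_seg <- function(chrom, s, e, p, subset = "a,b,c", size = 3) {
  data.frame(chrom = chrom, start_bp = s, end_bp = e, length_bp = e - s,
             start_index = 1L, end_index = 2L, n_markers = 2L,
             subset = subset, size = size, p_value = p,
             stringsAsFactors = FALSE)
}

thr_pair <- function(sig, sugg)
  structure(list(significant = sig, suggestive = sugg,
                 targets = c(0.5, 1), diagnostics = list()),
            class = "threshold_pair")

test_that("overlap_regions intersects suggestive evidence across families", {
  thrs <- list(A = thr_pair(1e-4, 1e-2), B = thr_pair(1e-4, 1e-2))
  # disjoint segments: no multi-family region
  segs <- list(A = make_seg(1, 100, 500, 5e-3),
               B = make_seg(1, 600, 900, 5e-3))
  out <- overlap_regions(segs, thrs)
  expect_equal(nrow(out[out$n_families > 1, ]), 0)

  # overlapping suggestive segments intersect to [300, 500]
  segs <- list(A = make_seg(1, 100, 500, 5e-3),
               B = make_seg(1, 300, 900, 2e-3))
  out <- overlap_regions(segs, thrs)
  multi <- out[out$n_families > 1, ]
  expect_equal(nrow(multi), 1)
  expect_equal(multi$start_bp, 300)
  expect_equal(multi$end_bp, 500)
  expect_equal(multi$length_bp, 200)
  expect_equal(multi$families, "A,B")

  # single-family segments survive only at the significant tier
  segs <- list(A = make_seg(1, 100, 500, 5e-5),
               B = make_seg(2, 100, 500, 5e-3))
  out <- overlap_regions(segs, thrs)
  expect_equal(out$families, "A")
  expect_equal(out$tier, "significant")

  # sub-suggestive evidence contributes nothing
  segs <- list(A = make_seg(1, 100, 500, 0.5),
               B = make_seg(1, 300, 900, 0.5))
  expect_equal(nrow(overlap_regions(segs, thrs)), 0)
})

test_that("three-family planted overlap recovers the common interval", {
  thrs <- list(A = thr_pair(1e-4, 1e-2), B = thr_pair(1e-4, 1e-2),
               C = thr_pair(1e-4, 1e-2))
  segs <- list(A = make_seg(5, 1000, 9000, 1e-3),
               B = make_seg(5, 3000, 12000, 2e-3),
               C = make_seg(5, 2500, 8000, 9e-3))
  out <- overlap_regions(segs, thrs)
  three <- out[out$n_families == 3, ]
  expect_equal(nrow(three), 1)
  expect_equal(three$start_bp, 3000)   # intersection of all three
  expect_equal(three$end_bp, 8000)
  # combining the per-family p-values is the caller's final step
  ps <- as.numeric(strsplit(three$p_values, ",")[[1]])
  expect_equal(fisher_combined(ps),
               fisher_combined(c(1e-3, 2e-3, 9e-3)), tolerance = 1e-6)
})

test_that("dedup_cases keeps each shared individual in exactly one family", {
  pedA <- pedigree(c("F", "M", "x", "y", "q"),
                   c(NA, NA, "F", "F", "F"), c(NA, NA, "M", "M", "M"),
                   c("male", "female", "male", "male", "male"),
                   is_case = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                   is_genotyped = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                   family_id = "A")
  pedB <- pedigree(c("F2", "M2", "x", "z", "w"),
                   c(NA, NA, "F2", "F2", "F2"),
                   c(NA, NA, "M2", "M2", "M2"),
                   c("male", "female", "male", "male", "male"),
                   is_case = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                   is_genotyped = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                   family_id = "B")
  fams <- list(A = pedA, B = pedB)

  # no shared subset members: identity
  r0 <- dedup_cases(fams, list(A = c("y"), B = c("z", "w")))
  expect_equal(r0$subsets, list(A = "y", B = c("z", "w")))
  expect_equal(nrow(r0$removed), 0)

  # x removable from A without breaking A's subset (x not in it)
  r1 <- dedup_cases(fams, list(A = c("y"), B = c("x", "z")))
  expect_equal(r1$subsets$B, c("x", "z"))
  expect_equal(r1$flagged, character(0))

  # x essential to both: kept in the larger sharing subset; the other
  # family is flagged for p-value and threshold recomputation
  r2 <- dedup_cases(fams, list(A = c("x", "y"), B = c("x", "z", "w")))
  expect_equal(r2$subsets$B, c("x", "z", "w"))
  expect_equal(r2$flagged, "A")
  expect_equal(r2$removed$individual, "x")
  # A fell below two sharing cases and leaves the combination
  expect_false("A" %in% names(r2$subsets))
  expect_equal(r2$excluded, "A")

  # with three sharing cases on each side, both families survive
  r3 <- dedup_cases(fams, list(A = c("x", "y", "q"),
                               B = c("x", "z", "w")))
  # tie on subset and pedigree size: the first family by name keeps x
  expect_equal(r3$subsets$A, c("x", "y", "q"))
  expect_equal(r3$subsets$B, c("z", "w"))
  expect_equal(r3$flagged, "B")
})
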