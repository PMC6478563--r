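gene_tab <- function() {
  data.frame(
    gene = rep(c("G1", "G2", "G3", "OR5X"), each = 2),
    chrom = 1,
    start = c(100, 80, 500, 480, 900, 880, 240, 230),
    end = c(200, 95, 600, 495, 1000, 895, 260, 238),
    type = rep(c("coding", "regulatory"), 4),
    blacklist = rep(c(FALSE, FALSE, FALSE, TRUE), each = 2),
    stringsAsFactors = FALSE)
}

test_that("target_genes uses coding and regulatory overlap minus blacklist", {
  regions <- data.frame(chrom = 1, start_bp = 90, end_bp = 300)
  # G1 coding inside; G1 regulatory overlaps; OR5X inside but blacklisted
  expect_equal(target_genes(regions, gene_tab()), "G1")

  # regulatory-only overlap still targets the gene
  regions2 <- data.frame(chrom = 1, start_bp = 470, end_bp = 490)
  expect_equal(target_genes(regions2, gene_tab()), "G2")

  # idempotent and order-invariant
  regions3 <- data.frame(chrom = 1, start_bp = c(90, 470, 90),
                         end_bp = c(300, 490, 300))
  expect_equal(target_genes(regions3, gene_tab()), c("G1", "G2"))
  expect_equal(target_genes(regions3[c(2, 1, 3), ], gene_tab()),
               c("G1", "G2"))
  expect_equal(target_genes(regions3[0, ], gene_tab()), character(0))
})

test_that("literature enrichment reproduces the reported arithmetic", {
  e <- enrichment_test(207, 18, 19000, 755)
  expect_equal(round(100 * e$proportion, 1), 8.7)
  expect_equal(round(e$expected), 8)
  expect_equal(round(100 * e$background), 4)
  expect_gt(e$z, 0)
  expect_lt(e$p, 0.05)

  # null case: observed proportion at background
  e0 <- enrichment_test(100, 4, 19000, 760)
  expect_lt(abs(e0$z), 0.2)
  expect_gt(e0$p, 0.4)
  # z positive iff proportion above background
  e_neg <- enrichment_test(100, 1, 19000, 760)
  expect_lt(e_neg$z, 0)
  expect_error(enrichment_test(0, 0, 19000, 755), "zero")
})

test_that("familial screen reports only in-region shared rare variants", {
  ann <- data.frame(
    variant_id = c("v_in", "v_out", "v_common", "v_syn", "v_unshared"),
    chrom = 1, bp = c(150, 950, 160, 170, 180),
    gene = "G1",
    consequence = c("missense", "missense", "missense", "synonymous",
                    "frameshift"),
    sift_call = "damaging", polyphen_call = "benign",
    ref_maf = c(0.05, 0.05, 0.15, 0.05, 0.05),
    stringsAsFactors = FALSE)
  gm <- matrix(1L, 3, 5, dimnames = list(c("a", "b", "c"), ann$variant_id))
  gm["b", "v_unshared"] <- 0L
  regions <- data.frame(chrom = 1, start_bp = 100, end_bp = 200,
                        subsets = "a,b,c", stringsAsFactors = FALSE)

  rep <- familial_variant_screen(regions, ann, gm)
  expect_equal(rep$variant_id, "v_in")
  # outside the boundary, above the MAF gate, synonymous and unshared
  # variants are all excluded
  expect_false(any(c("v_out", "v_common", "v_syn", "v_unshared") %in%
                     rep$variant_id))
  # raising the MAF gate admits the common variant
  rep2 <- familial_variant_screen(regions, ann, gm, maf_cutoff = 0.2)
  expect_setequal(rep2$variant_id, c("v_in", "v_common"))
  # an empty report means nothing explains the sharing
  regions_empty <- data.frame(chrom = 1, start_bp = 300, end_bp = 400,
                              subsets = "a,b,c", stringsAsFactors = FALSE)
  expect_equal(nrow(familial_variant_screen(regions_empty, ann, gm)), 0)
})

test_that("association variant selection applies all four criteria", {
  ann <- data.frame(
    variant_id = paste0("v", 1:6),
    chrom = 1, bp = 1:6, gene = c("G1", "G1", "G2", "G9", "G1", "G1"),
    consequence = c("missense", "synonymous", "missense", "missense",
                    "missense", "frameshift"),
    sift_call = c("damaging", "damaging", NA, "damaging", "benign",
                  "benign"),
    polyphen_call = c(NA, NA, "damaging", NA, "benign", "damaging"),
    ref_maf = c(0.05, 0.01, 0.1, 0.05, 0.05, 0.25),
    stringsAsFactors = FALSE)
  sel <- select_assoc_variants(ann, c("G1", "G2"))
  # v1: damaging by one predictor, in target, rare -> in
  # v2 synonymous; v3 damaging polyphen in target -> in; v4 gene not
  # targeted; v5 benign by both; v6 MAF 0.25 fails the 20% gate
  expect_setequal(sel$variant_id, c("v1", "v3"))
})

test_that("population association picks its test branch and Bonferroni", {
  expect_equal(signif(0.05 / 352, 3), 1.42e-4)

  # large balanced counts: chi-square branch, non-significant
  r <- popfreq_association(300, 10000, 3000, 100000, m = 352)
  expect_equal(r$test, "chi_square")
  expect_gt(r$p_value, 0.5)
  expect_false(r$significant)

  # sparse counts fall back to Fisher's exact
  r2 <- popfreq_association(5, 2624, 4, 66714, m = 352)
  expect_equal(r2$test, "fisher_exact")
  expect_true(r2$significant)

  # boundary: exactly 10 minor chromosomes stays exact
  r3 <- popfreq_association(10, 1000, 500, 50000, m = 1)
  expect_equal(r3$test, "fisher_exact")
  expect_error(popfreq_association(1, 0, 1, 100), "zero total")
})

test_that("Fisher branch equals hypergeometric enumeration on small tables", {
  set.seed(109)
  for (i in 1:60) {
    tot <- sample(20:500, 1)
    n1 <- sample(5:(tot - 5), 1)
    k <- sample(1:min(n1, tot - n1), 1)
    a <- sample(0:min(k, n1), 1)
    r <- popfreq_association(a, n1, k - a, tot - n1, m = 1,
                             min_chroms_chi = 1e9)
    expect_equal(r$p_value, oracle_fisher(a, n1 - a, k - a,
                                          tot - n1 - (k - a)),
                 tolerance = 1e-9, info = paste(a, n1, k - a, tot - n1))
  }
})

test_that("chi-square branch equals the closed-form Pearson statistic", {
  a <- 65; n1 <- 2622; b <- 986; n2 <- 66668
  r <- popfreq_association(a, n1, b, n2, m = 352)
  expect_equal(r$test, "chi_square")
  tab <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  expect_equal(r$p_value, stats::pchisq(x2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("null association tables produce about alpha false positives", {
  set.seed(113)
  n_rep <- 500
  m <- 352
  fp <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    # common variants with identical frequencies in both groups so the
    # chi-square branch dominates and p-values are nearly continuous
    maf <- stats::runif(m, 0.05, 0.4)
    ref_minor <- stats::rbinom(m, 60000, maf)
    case_minor <- stats::rbinom(m, 2600, maf)
    sig <- vapply(seq_len(m), function(i)
      popfreq_association(case_minor[i], 2600, ref_minor[i], 60000,
                          m = m)$significant, logical(1))
    fp[r] <- sum(sig)
  }
  se <- sd(fp) / sqrt(n_rep)
  expect_lt(abs(mean(fp) - 0.05), 3 * se + 0.02)
})

test_that("summary t and chi-square utilities match reported statistics", {
  tt <- t_pooled(40.01, 17.39, 4370, 34.28, 16.28, 215)
  expect_equal(tt$t, 4.74, tolerance = 0.005)
  expect_lt(tt$p, 1e-4)

  cc <- prop_chisq(round(0.372 * 215), 215, round(0.289 * 4370), 4370)
  expect_equal(cc$chisq, 6.82, tolerance = 0.01)
  expect_lt(cc$p, 0.01)

  # the personality-disorder comparison from the same demographic table
  cc2 <- prop_chisq(round(0.144 * 215), 215, round(0.097 * 4370), 4370)
  expect_equal(cc2$chisq, 5.06, tolerance = 0.03)
})
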