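test_that("Hardy-Weinberg exact test agrees with full enumeration", {
  expect_equal(hwe_exact_test(0, 0, 10), 1)
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(3, 5, 1), oracle_hwe(3, 5, 1),
               tolerance = 1e-12)
  # extreme heterozygote deficit fails the 0.001 screen
  expect_lt(hwe_exact_test(57, 14, 50), 1e-3)
  expect_equal(hwe_exact_test(57, 14, 50), oracle_hwe(57, 14, 50),
               tolerance = 1e-12)

  set.seed(17)
  for (i in 1:50) {
    n <- sample(3:200, 1)
    x <- stats::rmultinom(1, n, c(0.3, 0.5, 0.2))
    expect_equal(hwe_exact_test(x[1], x[2], x[3]),
                 oracle_hwe(x[1], x[2], x[3]), tolerance = 1e-12,
                 info = paste(x, collapse = "/"))
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("qc_filter applies ordered filters and reports planted failures", {
  set.seed(23)
  cfg <- sim_config(n_chrom = 1, markers_per_chrom = 120, chrom_cM = 50,
                    n_cohort = 150, n_bad_missing_markers = 4,
                    n_hwe_bad_markers = 3, plant_segment = FALSE)
  b <- simulate_study(cfg)
  res <- qc_filter(b$cohort, b$map)
  rep <- res$report
  expect_equal(rep$filter,
               c("marker_missing", "hwe", "non_polymorphic",
                 "sample_missing"))
  expect_equal(rep$removed[rep$filter == "marker_missing"], 4L)
  expect_equal(rep$removed[rep$filter == "hwe"], 3L)
  expect_false(any(b$manifest$cohort_bad_missing %in% colnames(res$genotypes)))
  expect_false(any(b$manifest$cohort_hwe_bad %in% colnames(res$genotypes)))

  # a fully observed matrix built at exact Hardy-Weinberg proportions
  # loses nothing
  set.seed(29)
  pan2 <- make_panel(sim_config(n_chrom = 1, markers_per_chrom = 60,
                                chrom_cM = 30))
  clean <- vapply(seq_len(60), function(j)
    sample(rep(c(0L, 1L, 2L), c(50, 100, 50))), integer(200))
  dimnames(clean) <- list(paste0("C", 1:200), pan2$map$id)
  res2 <- qc_filter(clean, pan2$map)
  expect_equal(sum(res2$report$removed), 0L)

  # one marker just above the missingness gate is removed
  gm <- clean
  gm[1:17, 5] <- NA  # 8.5% > 5%
  res3 <- qc_filter(gm, pan2$map)
  expect_equal(res3$report$removed[1], 1L)
  expect_false(colnames(clean)[5] %in% colnames(res3$genotypes))

  # strand-ambiguous markers dropped only when flagged
  res4 <- qc_filter(clean, pan2$map, ambiguous = pan2$map$id[2:3])
  expect_equal(
    res4$report$removed[res4$report$filter == "strand_ambiguous"], 2L)

  # sample-missingness filter runs after marker filters
  gm2 <- clean
  gm2[3, ] <- NA
  res5 <- qc_filter(gm2, pan2$map)
  expect_equal(res5$report$removed[res5$report$filter == "sample_missing"],
               1L)
  expect_false("C3" %in% rownames(res5$genotypes))
})

test_that("qc_filter is deterministic and errors on degenerate output", {
  set.seed(31)
  panel <- make_panel(sim_config(n_chrom = 1, markers_per_chrom = 40,
                                 chrom_cM = 20))
  gm <- make_cohort_genotypes(panel, 60)
  r1 <- qc_filter(gm, panel$map)
  r2 <- qc_filter(gm, panel$map)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$genotypes, r2$genotypes)

  allmiss <- gm
  allmiss[] <- NA_integer_
  expect_error(qc_filter(allmiss, panel$map),
               class = "sgsfam_degenerate_error")
})

test_that("PLINK text and VCF readers round-trip generated genotypes", {
  set.seed(37)
  cfg <- sim_config(n_chrom = 2, markers_per_chrom = 30, chrom_cM = 20,
                    n_cases = 4, n_carrier_cases = 2)
  b <- simulate_study(cfg, dir = td <- tempfile("bundle_"))

  map <- read_plink_map(file.path(td, "markers.map"))
  expect_equal(map$bp, b$map$bp)
  expect_equal(map$cM, b$map$cM)

  got <- read_plink_ped(file.path(td, "genotypes.ped"), map)
  # allele coding may flip where a1/a2 are inferred from data; compare
  # dosages up to per-marker orientation
  for (j in seq_len(ncol(b$genotypes))) {
    g0 <- b$genotypes[, j]
    g1 <- got$genotypes[rownames(b$genotypes), j]
    expect_true(all(g1 == g0) || all(g1 == 2 - g0), info = paste("col", j))
  }

  pan <- read_haplotype_panel(file.path(td, "panel.vcf"), "vcf",
                              map = b$map)
  expect_equal(do.call(cbind, pan$haplotypes),
               do.call(cbind, b$panel$haplotypes),
               ignore_attr = TRUE)

  ped2 <- read_pedigree(file.path(td, "family.ped"))
  expect_equal(sort(genotyped_cases(ped2)),
               sort(genotyped_cases(b$ped)))
})

test_that("tped reader matches the ped reader on the same data", {
  set.seed(41)
  panel <- make_panel(sim_config(n_chrom = 1, markers_per_chrom = 12,
                                 chrom_cM = 10))
  gm <- make_cohort_genotypes(panel, 5)
  ids <- rownames(gm)
  tf <- tempfile(fileext = ".tped")
  rows <- lapply(seq_len(nrow(panel$map)), function(j) {
    al <- ifelse(gm[, j] >= 1, panel$map$a2[j], panel$map$a1[j])
    al2 <- ifelse(gm[, j] == 2, panel$map$a2[j], panel$map$a1[j])
    paste(panel$map$chrom[j], panel$map$id[j], panel$map$cM[j],
          panel$map$bp[j], paste(as.vector(rbind(al, al2)), collapse = " "))
  })
  writeLines(unlist(rows), tf)
  got <- read_tped(tf, ids)
  for (j in seq_len(ncol(gm))) {
    g0 <- gm[, j]
    g1 <- got$genotypes[, j]
    expect_true(all(g1 == g0) || all(g1 == 2 - g0))
  }
})
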