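test_that("generated pedigrees honour shape and case-rule settings", {
  # two generations with fixed sibship of one couple: a nuclear family
  set.seed(127)
  ped <- make_pedigree(sim_config(n_generations = 2, sibship_mean = 1,
                                  n_cases = 1, n_carrier_cases = 1))
  expect_gte(nrow(ped), 3)
  expect_equal(length(founders(ped)), sum(is.na(ped$father)))

  # penetrance 1: every designated carrier is a case
  set.seed(131)
  ped2 <- make_pedigree(sim_config(penetrance = 1, n_cases = 6,
                                   n_carrier_cases = 4))
  carriers <- attr(ped2, "carriers")
  expect_equal(length(carriers), 4)
  expect_true(all(ped2$is_case[match(carriers, ped2$id)]))

  # penetrance 0: no carrier is a case, sporadic cases fill the quota
  set.seed(137)
  ped3 <- make_pedigree(sim_config(penetrance = 0, n_cases = 5,
                                   n_carrier_cases = 3))
  expect_false(any(ped3$is_case[match(attr(ped3, "carriers"), ped3$id)]))

  # carrier lineage edges climb from every carrier to the top founder
  lin <- attr(ped2, "lineage")
  expect_true(all(carriers %in% lin$child))
  expect_true("F1" %in% lin$parent)
})

test_that("default family shape matches the study scale within 20%", {
  set.seed(139)
  ncase <- integer(100)
  nmei <- integer(100)
  for (i in 1:100) {
    ped <- make_pedigree(sim_config())
    cases <- genotyped_cases(ped)
    ncase[i] <- length(cases)
    nmei[i] <- if (length(cases) >= 2) count_meioses(ped, cases) else 0L
  }
  # reported averages: 6.2 genotyped cases, 29.6 meioses per family
  expect_lt(abs(mean(ncase) - 6.2) / 6.2, 0.2)
  expect_lt(abs(mean(nmei) - 29.6) / 29.6, 0.2)
})

test_that("panels are polymorphic, LD-blocked and map-consistent", {
  set.seed(149)
  cfg <- sim_config(n_chrom = 2, markers_per_chrom = 200, chrom_cM = 40)
  panel <- make_panel(cfg)
  H <- do.call(cbind, panel$haplotypes)
  freq <- colMeans(H)
  expect_true(all(freq > 0 & freq < 1))
  expect_silent(validate_map(panel$map))
  expect_true(all(diff(panel$map$bp[panel$map$chrom == 1]) > 0))

  # within-block r^2 far exceeds long-range r^2
  h1 <- panel$haplotypes[[1]]
  r2 <- function(a, b) stats::cor(a, b)^2
  near <- vapply(seq_len(ncol(h1) - 1), function(j)
    r2(h1[, j], h1[, j + 1]), numeric(1))
  far <- vapply(seq_len(ncol(h1) - 50), function(j)
    r2(h1[, j], h1[, j + 50]), numeric(1))
  expect_gt(mean(near, na.rm = TRUE), 5 * mean(far, na.rm = TRUE))

  # degenerate one-haplotype pools still yield polymorphic markers
  set.seed(151)
  p1 <- make_panel(sim_config(n_chrom = 1, markers_per_chrom = 50,
                              chrom_cM = 20, block_pool_size = 1))
  expect_true(all(colMeans(p1$haplotypes[[1]]) > 0 &
                    colMeans(p1$haplotypes[[1]]) < 1))
})

test_that("study bundles carry their ground truth and self-validate", {
  cfg <- sim_config(seed = 157, n_chrom = 1, markers_per_chrom = 400,
                    chrom_cM = 40, n_cases = 5, n_carrier_cases = 3,
                    plant_start_cM = 20, plant_length_cM = 3)
  b <- simulate_study(cfg)
  ps <- b$manifest$planted_segment
  expect_false(is.null(ps))
  # every carrier genotype holds the planted founder haplotype: all
  # carriers share an allele at every marker inside the interval
  sel <- which(b$map$bp >= ps$start_bp & b$map$bp <= ps$end_bp)
  carr <- intersect(b$manifest$carriers, rownames(b$genotypes))
  expect_equal(length(carr), 3)
  for (j in sel)
    expect_true(sharing_indicator(b$genotypes[carr, j]))
  # the planted explanatory variant is carried by every carrier
  ev <- b$manifest$explanatory_variant
  if (!is.null(ev)) {
    expect_true(all(b$genotypes[carr, ev] >= 1))
    ann <- b$annotations[b$annotations$variant_id == ev, ]
    expect_equal(ann$consequence, "missense")
    expect_lt(ann$ref_maf, 0.10)
  }
  # planted association variant has the configured frequency regime
  av <- b$annotations[b$annotations$variant_id == b$manifest$assoc_variant, ]
  expect_lt(av$ref_minor / av$ref_total, 0.001)
  expect_gt(av$case_minor / av$case_total, av$ref_minor / av$ref_total)

  # null bundles carry no planted signals
  b0 <- simulate_study(sim_config(seed = 163, plant_segment = FALSE,
                                  n_chrom = 1, markers_per_chrom = 100,
                                  chrom_cM = 30))
  expect_null(b0$manifest$planted_segment)
  expect_null(b0$manifest$explanatory_variant)
})

test_that("bundles are bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 167, n_chrom = 1, markers_per_chrom = 120,
                    chrom_cM = 40, n_cases = 4, n_carrier_cases = 2,
                    plant_start_cM = 20, plant_length_cM = 3)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1$genotypes, b2$genotypes)
  expect_identical(b1$panel$haplotypes, b2$panel$haplotypes)
  expect_identical(b1$annotations, b2$annotations)
  expect_identical(as.data.frame(b1$ped), as.data.frame(b2$ped))
})

test_that("written bundles pass every reader validation", {
  cfg <- sim_config(seed = 173, n_chrom = 2, markers_per_chrom = 40,
                    chrom_cM = 20, n_cases = 4, n_carrier_cases = 2,
                    plant_start_cM = 10, plant_length_cM = 3)
  td <- tempfile("bundle_")
  b <- simulate_study(cfg, dir = td)
  expect_true(all(file.exists(file.path(td, c(
    "family.ped", "markers.map", "panel.vcf", "rates.tsv",
    "membership.tsv", "genes.tsv", "annotations.tsv",
    "literature_genes.txt", "genotypes.ped", "manifest.json")))))
  expect_s3_class(read_pedigree(file.path(td, "family.ped")), "pedigree")
  map <- read_plink_map(file.path(td, "markers.map"))
  expect_silent(validate_map(map))
  expect_s3_class(read_haplotype_panel(file.path(td, "panel.vcf"), "vcf",
                                       map = b$map), "hap_panel")
  expect_silent(read_stratum_rates(file.path(td, "rates.tsv")))
  man <- jsonlite::read_json(file.path(td, "manifest.json"))
  expect_equal(man$seed, 173)
})

test_that("planted associated variant is flagged under 0.05/352", {
  set.seed(179)
  # the configured frequency regime: about 0.9% in roughly 1300 cases
  # against about 0.007% in the reference
  hits <- logical(20)
  for (i in 1:20) {
    case_minor <- stats::rbinom(1, 2600, 0.009)
    ref_minor <- max(1, stats::rbinom(1, 66000, 7e-5))
    hits[i] <- popfreq_association(case_minor, 2600, ref_minor, 66000,
                                   m = 352)$significant
  }
  expect_gte(mean(hits), 0.95)
})
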