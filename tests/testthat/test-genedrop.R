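test_that("degenerate one-haplotype panel makes all founders homozygous", {
  map <- toy_map(12)
  H <- matrix(rep(c(0L, 1L), each = 6), 1, 12)
  panel <- hap_panel(H, map, validate = FALSE)
  ped <- ped_siblings()
  set.seed(67)
  fh <- assign_founder_haplotypes(ped, panel)
  gm <- drop_genes(ped, fh, panel, individuals = c("A", "B"))
  expect_true(all(gm == matrix(rep(c(0L, 2L), each = 6), 2, 12,
                               byrow = TRUE)))
})

test_that("founder assignment reproduces panel allele frequencies", {
  set.seed(71)
  panel <- make_panel(sim_config(n_chrom = 1, markers_per_chrom = 40,
                                 chrom_cM = 20))
  ped <- ped_siblings()
  draws <- 800
  tot <- numeric(40)
  for (i in seq_len(draws)) {
    fh <- assign_founder_haplotypes(ped, panel)
    tot <- tot + colSums(panel$haplotypes[[1]][fh[[1]], , drop = FALSE])
  }
  est <- tot / (draws * 4)  # two founders x two haplotypes
  truth <- colMeans(panel$haplotypes[[1]])
  se <- sqrt(truth * (1 - truth) / (draws * 4))
  expect_true(all(abs(est - truth) < 3.5 * se + 1e-9))
})

test_that("complete-LD two-marker panel never yields recombinant founders", {
  map <- toy_map(2)
  H <- rbind(c(0L, 0L), c(1L, 1L))
  panel <- hap_panel(H, map)
  ped <- ped_siblings()
  set.seed(73)
  for (i in 1:200) {
    fh <- assign_founder_haplotypes(ped, panel)
    haps <- panel$haplotypes[[1]][fh[[1]], , drop = FALSE]
    expect_true(all(haps[, 1] == haps[, 2]))  # only 00 and 11 exist
  }
})

test_that("meiosis respects Mendelian rules and the no-recombination limit", {
  # 0 cM chromosome: transmitted haplotype is one parent copy intact
  cm0 <- rep(0, 20)
  hA <- rep(0L, 20); hB <- rep(1L, 20)
  set.seed(79)
  for (i in 1:50) {
    tr <- meiosis(hA, hB, cm0)
    expect_true(all(tr == 0L) || all(tr == 1L))
  }
  # the intact copy is chosen with probability 1/2
  picks <- replicate(2000, meiosis(hA, hB, cm0)[1])
  expect_lt(abs(mean(picks) - 0.5), 3 * sqrt(0.25 / 2000))

  # homozygous parent always transmits that allele
  tr <- meiosis(rep(1L, 20), rep(1L, 20), seq(0, 50, length.out = 20))
  expect_true(all(tr == 1L))
})

test_that("recombination fraction over 10 cM matches the Haldane closed form", {
  theta <- (1 - exp(-0.2)) / 2           # 0.0906 for d = 0.1 Morgan
  cm <- c(0, 10)
  hA <- c(0L, 0L); hB <- c(1L, 1L)
  set.seed(83)
  n <- 100000
  rec <- 0L
  for (i in seq_len(n)) {
    tr <- meiosis(hA, hB, cm)
    rec <- rec + (tr[1] != tr[2])
  }
  se <- sqrt(theta * (1 - theta) / n)
  expect_lt(abs(rec / n - theta), 3 * se)
})

test_that("null simulation is reproducible and respects IBD bounds", {
  set.seed(89)
  cfg <- sim_config(n_chrom = 1, markers_per_chrom = 100, chrom_cM = 50,
                    plant_segment = FALSE)
  panel <- make_panel(cfg)
  ped <- ped_siblings()
  sc <- scan_config(min_subset_size = 2, min_markers_per_run = 1)
  n1 <- simulate_null(ped, panel, cases = c("A", "B"), cfg = sc,
                      n_sims = 300, seed = 5)
  n2 <- simulate_null(ped, panel, cases = c("A", "B"), cfg = sc,
                      n_sims = 300, seed = 5)
  expect_identical(as.data.frame(n1$runs), as.data.frame(n2$runs))

  # sibling-pair IBS non-sharing at a marker cannot exceed P(IBD0) = 1/4
  covered <- matrix(FALSE, 300, 100)
  for (i in seq_len(nrow(n1$runs)))
    covered[n1$runs$sim[i], n1$runs$start[i]:n1$runs$end[i]] <- TRUE
  nonshare <- 1 - colMeans(covered)
  # column-wise Monte-Carlo bound with 3 SE slack
  expect_true(all(nonshare < 0.25 + 3 * sqrt(0.25 * 0.75 / 300)))
})

test_that("checkpointed null simulation resumes to identical results", {
  set.seed(97)
  cfg <- sim_config(n_chrom = 1, markers_per_chrom = 60, chrom_cM = 30,
                    plant_segment = FALSE)
  panel <- make_panel(cfg)
  ped <- ped_siblings()
  sc <- scan_config(min_subset_size = 2, min_markers_per_run = 1)
  direct <- simulate_null(ped, panel, cases = c("A", "B"), cfg = sc,
                          n_sims = 500, seed = 6)
  ck <- tempfile(fileext = ".rds")
  # simulate an interruption: abort the run at its first checkpoint
  try(withCallingHandlers(
    simulate_null(ped, panel, cases = c("A", "B"), cfg = sc,
                  n_sims = 500, seed = 6, checkpoint_path = ck,
                  checkpoint_every = 200),
    sgsfam_checkpoint = function(c) stop("interrupted")), silent = TRUE)
  expect_true(file.exists(ck))
  resumed <- simulate_null(ped, panel, cases = c("A", "B"), cfg = sc,
                           n_sims = 500, seed = 6, checkpoint_path = ck,
                           checkpoint_every = 200)
  expect_identical(as.data.frame(resumed$runs), as.data.frame(direct$runs))
})

test_that("empirical p-values hit their bounds and are monotone in length", {
  set.seed(101)
  cfg <- sim_config(n_chrom = 1, markers_per_chrom = 150, chrom_cM = 40,
                    plant_segment = FALSE)
  panel <- make_panel(cfg)
  ped <- ped_siblings()
  sc <- scan_config(min_subset_size = 2, min_markers_per_run = 5)
  nl <- simulate_null(ped, panel, cases = c("A", "B"), cfg = sc,
                      n_sims = 400, seed = 7)
  mkseg <- function(s, e, size = 2) data.frame(
    chrom = 1, start_bp = panel$map$bp[s], end_bp = panel$map$bp[e],
    length_bp = panel$map$bp[e] - panel$map$bp[s], start_index = s,
    end_index = e, n_markers = e - s + 1, subset = "A,B", size = size,
    p_value = NA_real_)
  # minimal-length segment at the floor: nearly always matched
  pshort <- empirical_pvalue(mkseg(70, 74), nl)$p_value
  expect_gt(pshort, 0.5)
  # a segment longer than any attainable run is never matched:
  # estimator floor 1 / (n_sims + 1)
  imp <- mkseg(1, 150)
  imp$length_bp <- 9e9
  plong <- empirical_pvalue(imp, nl)$p_value
  expect_equal(plong, 1 / 401)
  # monotone non-increasing in length at fixed midpoint
  ps <- vapply(c(2, 10, 25, 60), function(w)
    empirical_pvalue(mkseg(75 - w, 75 + w), nl)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
  # a subset size with no null support errors out of range checks
  expect_error(empirical_pvalue(
    within(mkseg(10, 20), chrom <- 99), nl),
    class = "sgsfam_coverage_error")
})

test_that("null distributions persist to TSV + JSON and reload intact", {
  set.seed(251)
  cfg <- sim_config(n_chrom = 1, markers_per_chrom = 80, chrom_cM = 30,
                    plant_segment = FALSE)
  panel <- make_panel(cfg)
  ped <- ped_siblings()
  sc <- scan_config(min_subset_size = 2, min_markers_per_run = 4)
  nl <- simulate_null(ped, panel, cases = c("A", "B"), cfg = sc,
                      n_sims = 200, seed = 9)
  pre <- tempfile()
  write_null_distribution(nl, pre)
  nl2 <- read_null_distribution(pre, panel$map)
  expect_equal(as.data.frame(nl2$runs), as.data.frame(nl$runs))
  expect_equal(nl2$n_sims, nl$n_sims)
  expect_equal(nl2$cfg$min_markers_per_run, sc$min_markers_per_run)
  # p-values computed from the restored null match the original
  seg <- data.frame(chrom = 1, start_bp = panel$map$bp[30],
                    end_bp = panel$map$bp[50],
                    length_bp = panel$map$bp[50] - panel$map$bp[30],
                    start_index = 30L, end_index = 50L, n_markers = 21L,
                    subset = "A,B", size = 2L, p_value = NA_real_)
  expect_equal(empirical_pvalue(seg, nl2)$p_value,
               empirical_pvalue(seg, nl)$p_value)
})

test_that("stronger panel LD stochastically lengthens null sharing runs", {
  set.seed(103)
  base <- list(n_chrom = 1, markers_per_chrom = 200, chrom_cM = 50,
               plant_segment = FALSE)
  weak <- make_panel(do.call(sim_config, c(base, block_markers_mean = 2)))
  strong_cfg <- do.call(sim_config, c(base, block_markers_mean = 15))
  # same marker map so run lengths are comparable
  strong <- make_panel(strong_cfg)
  # three mutually unrelated genotyped cases: their IBS runs carry no
  # identity by descent, so run length is driven purely by panel LD
  ped <- pedigree(
    c("F1", "M1", "F2", "M2", "F3", "M3", "A", "B", "C"),
    c(rep(NA, 6), "F1", "F2", "F3"), c(rep(NA, 6), "M1", "M2", "M3"),
    c(rep(c("male", "female"), 3), rep("male", 3)),
    is_case = c(rep(FALSE, 6), TRUE, TRUE, TRUE),
    is_genotyped = c(rep(FALSE, 6), TRUE, TRUE, TRUE))
  sc <- scan_config(min_subset_size = 3, min_markers_per_run = 1)
  nw <- simulate_null(ped, weak, cfg = sc, n_sims = 300, seed = 8)
  ns <- simulate_null(ped, strong, cfg = sc, n_sims = 300, seed = 8)
  lw <- nw$runs$end - nw$runs$start + 1
  ls <- ns$runs$end - ns$runs$start + 1
  expect_gt(mean(ls), mean(lw))
  # the long-run tail thickens with LD
  expect_gt(stats::quantile(ls, 0.9), stats::quantile(lw, 0.9))
})
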