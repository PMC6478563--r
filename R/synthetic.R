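#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator.  Defaults emulate a
#' single deep high-risk pedigree genotyped on a sparse genome-wide array,
#' with a planted shared haplotype segment in a subset of the cases, an
#' LD-structured haplotype panel standing in for a population reference,
#' sex/age-stratified incidence rates, and a variant annotation table with
#' planted explanatory and associated variants.
#'
#' @param seed RNG seed (`NULL`: leave the RNG state alone).
#' @param n_generations pedigree depth including the founder generation.
#' @param sibship_mean mean sibship size (sibships are `1 + Poisson`).
#' @param sibship_first mean sibship of the founding couple, historically
#'   larger, which creates the deep branches that separate distant cases.
#' @param n_cases genotyped cases per family.
#' @param n_carrier_cases cases carrying the planted segment.
#' @param penetrance probability that a designated carrier is affected.
#' @param case_rule `"planted"` (carrier-driven) or `"random"`.
#' @param case_rate case probability under the `"random"` rule.
#' @param n_chrom,markers_per_chrom,chrom_cM genome shape; bp positions are
#'   drawn at an average density of 1 cM per Mb.
#' @param n_haplotypes,block_markers_mean,block_pool_size panel shape: LD is
#'   produced by concatenating block haplotypes drawn from small
#'   within-block pools.
#' @param plant_segment plant a shared segment (`TRUE`/`FALSE`).
#' @param plant_chrom,plant_start_cM,plant_length_cM planted interval.
#' @param n_variants annotated variants (drawn from the marker map).
#' @param genes_per_chrom gene models tiling each chromosome.
#' @param assoc_case_total,assoc_ref_total,assoc_case_freq,assoc_ref_freq
#'   chromosome counts and minor-allele frequencies of the planted
#'   associated variant in the follow-up cohort and the reference
#'   population.
#' @param marker_missing_rate background genotype missingness.
#' @param n_bad_missing_markers,n_hwe_bad_markers QC failures planted into
#'   the unrelated cohort matrix.
#' @param n_cohort unrelated cohort individuals (genotypes drawn directly
#'   from the panel; used for QC exercises).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = NULL, n_generations = 7, sibship_mean = 2.2,
                       sibship_first = 3.5,
                       n_cases = 6, n_carrier_cases = 4, penetrance = 1,
                       case_rule = c("planted", "random"), case_rate = 0.1,
                       n_chrom = 2, markers_per_chrom = 300, chrom_cM = 120,
                       n_haplotypes = 200, block_markers_mean = 10,
                       block_pool_size = 6, plant_segment = TRUE,
                       plant_chrom = 1, plant_start_cM = NULL,
                       plant_length_cM = 3, n_variants = 80,
                       genes_per_chrom = 12, assoc_case_total = 2600,
                       assoc_ref_total = 66000, assoc_case_freq = 0.009,
                       assoc_ref_freq = 0.00007,
                       marker_missing_rate = 0,
                       n_bad_missing_markers = 0, n_hwe_bad_markers = 0,
                       n_cohort = 0) {
  cfg <- as.list(environment())
  cfg$case_rule <- match.arg(case_rule)
  if (is.null(cfg$plant_start_cM))  # default: centre the planted interval
    cfg$plant_start_cM <- max(0, (chrom_cM - plant_length_cM) / 2)
  stopifnot(n_generations >= 2, n_carrier_cases <= n_cases,
            penetrance >= 0, penetrance <= 1,
            !plant_segment ||
              cfg$plant_start_cM + plant_length_cM <= chrom_cM)
  structure(cfg, class = "sim_config")
}

new_id <- local({
  function(prefix, n) paste0(prefix, seq_len(n))
})

#' Generate a synthetic pedigree
#'
#' Expands a founder couple by sibship draws for `n_generations`
#' generations; children of intermediate generations marry founder spouses.
#' Under the `"planted"` rule, `n_carrier_cases` members of the last two
#' generations are designated carriers of the planted founder haplotype
#' (each becomes a case with probability `penetrance`) and further random
#' members are affected until `n_cases` genotyped cases exist.  The carrier
#' descent lineage from the top founder is recorded as ground truth.
#'
#' @param cfg a [sim_config()].
#' @return a `pedigree` with attributes `carriers` (ids),
#'   `lineage` (data frame child/parent of forced descent edges) and
#'   `plant_founder` (id).
#' @export
make_pedigree <- function(cfg) {
  id <- c("F1", "M1")
  father <- c(NA, NA); mother <- c(NA, NA)
  sex <- c("male", "female")
  gen <- c(1L, 1L)
  blood <- c(TRUE, FALSE)  # descent traced through F1's line
  couples <- data.frame(f = "F1", m = "M1", stringsAsFactors = FALSE)
  ctr <- 0L
  for (g in 2:cfg$n_generations) {
    nxt <- NULL
    for (ci in seq_len(nrow(couples))) {
      mu <- if (g == 2) cfg$sibship_first else cfg$sibship_mean
      k <- 1L + stats::rpois(1, max(mu - 1, 0))
      for (j in seq_len(k)) {
        ctr <- ctr + 1L
        kid <- paste0("I", ctr)
        ksex <- if (stats::runif(1) < 0.5) "male" else "female"
        id <- c(id, kid); father <- c(father, couples$f[ci])
        mother <- c(mother, couples$m[ci]); sex <- c(sex, ksex)
        gen <- c(gen, g); blood <- c(blood, TRUE)
        if (g < cfg$n_generations) {
          ctr <- ctr + 1L
          sp <- paste0("S", ctr)
          spsex <- if (ksex == "male") "female" else "male"
          id <- c(id, sp); father <- c(father, NA); mother <- c(mother, NA)
          sex <- c(sex, spsex); gen <- c(gen, g); blood <- c(blood, FALSE)
          nxt <- rbind(nxt, data.frame(
            f = if (ksex == "male") kid else sp,
            m = if (ksex == "male") sp else kid,
            stringsAsFactors = FALSE))
        }
      }
    }
    couples <- nxt
    if (is.null(couples) || nrow(couples) == 0) break
  }
  n <- length(id)
  is_case <- rep(FALSE, n)
  carriers <- character(0)
  if (cfg$case_rule == "random") {
    nonf <- which(!is.na(father))
    is_case[nonf] <- stats::runif(length(nonf)) < cfg$case_rate
  } else {
    deep <- which(blood & gen >= max(gen) - 1 & !is.na(father))
    ncar <- min(cfg$n_carrier_cases, length(deep))
    # spread carriers across distinct second-generation branches, as
    # distantly related as the pedigree allows (the study design selects
    # dispersed cases to maximise meioses between them)
    branch_of <- function(i) {
      while (gen[i] > 2) {
        p <- father[i]
        if (is.na(p)) break
        if (!blood[match(p, id)]) p <- mother[i]
        i <- match(p, id)
      }
      i
    }
    br <- vapply(deep, branch_of, integer(1))
    samp1 <- function(x) x[sample.int(length(x), 1)]
    ubr <- unique(br)
    picked <- integer(0)
    for (b in ubr[sample.int(length(ubr))]) {
      if (length(picked) >= ncar) break
      picked <- c(picked, samp1(deep[br == b]))
    }
    while (length(picked) < ncar)
      picked <- c(picked, samp1(setdiff(deep, picked)))
    carriers <- id[picked]
    becomes <- stats::runif(ncar) < cfg$penetrance
    is_case[match(carriers[becomes], id)] <- TRUE
    need <- cfg$n_cases - sum(is_case)
    # sporadic cases appear in the recent generations, where vital
    # records exist, keeping cases dispersed across deep branches
    pool <- setdiff(which(!is.na(father) & !is_case &
                            gen >= max(gen) - 2),
                    match(carriers, id))
    if (need > 0 && length(pool) > 0)
      is_case[sample(pool, min(need, length(pool)))] <- TRUE
  }
  ped <- pedigree(id, father, mother, sex, is_case,
                  is_genotyped = is_case, family_id = "SYN1")
  # carrier descent lineage: blood-parent chain up to F1
  lin <- NULL
  bloodv <- stats::setNames(blood, id)
  for (cid in carriers) {
    cur <- cid
    while (cur != "F1") {
      fa <- ped$father[match(cur, ped$id)]
      mo <- ped$mother[match(cur, ped$id)]
      par <- if (!is.na(fa) && bloodv[fa]) fa else mo
      lin <- rbind(lin, data.frame(child = cur, parent = par,
                                   stringsAsFactors = FALSE))
      cur <- par
    }
  }
  if (!is.null(lin)) lin <- unique(lin)
  attr(ped, "carriers") <- carriers
  attr(ped, "lineage") <- lin
  attr(ped, "plant_founder") <- "F1"
  ped
}

#' Generate an LD-structured haplotype panel and marker map
#'
#' Markers are placed uniformly at an average density of 1 cM/Mb; panel
#' haplotypes are assembled by concatenating, block by block, haplotypes
#' drawn from small within-block pools, which creates strong within-block
#' and weak between-block linkage disequilibrium.  Monomorphic panel
#' columns are repaired by flipping one haplotype's allele, so every
#' retained marker is polymorphic.
#'
#' @param cfg a [sim_config()].
#' @return a [hap_panel()].
#' @export
make_panel <- function(cfg) {
  maps <- list()
  for (ch in seq_len(cfg$n_chrom)) {
    bp <- sort(sample.int(cfg$chrom_cM * 1e6, cfg$markers_per_chrom))
    maps[[ch]] <- data.frame(
      chrom = ch, id = paste0("rs", ch, "_", seq_along(bp)), bp = bp,
      cM = bp / 1e6,
      a1 = sample(c("A", "C"), length(bp), replace = TRUE),
      a2 = NA_character_, stringsAsFactors = FALSE)
    maps[[ch]]$a2 <- ifelse(maps[[ch]]$a1 == "A", "G", "T")
  }
  map <- do.call(rbind, maps)
  H <- matrix(0L, cfg$n_haplotypes, nrow(map))
  for (ch in seq_len(cfg$n_chrom)) {
    cols <- which(map$chrom == ch)
    pos <- 1L
    while (pos <= length(cols)) {
      len <- min(1L + stats::rpois(1, max(cfg$block_markers_mean - 1, 0)),
                 length(cols) - pos + 1L)
      # common variants: per-marker pool allele frequency away from 0/1
      pf <- stats::runif(len, 0.25, 0.75)
      pool <- matrix(stats::rbinom(cfg$block_pool_size * len, 1,
                                   rep(pf, each = cfg$block_pool_size)),
                     cfg$block_pool_size, len)
      pick <- sample.int(cfg$block_pool_size, cfg$n_haplotypes,
                         replace = TRUE)
      H[, cols[pos:(pos + len - 1L)]] <- pool[pick, , drop = FALSE]
      pos <- pos + len
    }
  }
  mono <- which(colMeans(H) %in% c(0, 1))
  for (j in mono) H[sample.int(nrow(H), 1), j] <- 1L - H[1, j]
  hap_panel(H, map)
}

#' Default stratified incidence rates
#'
#' Sex-by-age-band per-person probabilities of the outcome, on the scale of
#' lifetime risks in a high-incidence population (male rates roughly three
#' times female rates, mildly age-dependent).
#'
#' @return a stratum rate data frame (`sex`, `age_min`, `age_max`, `rate`).
#' @export
default_stratum_rates <- function() {
  bands <- data.frame(age_min = c(10, 25, 40, 55, 70),
                      age_max = c(24, 39, 54, 69, 120))
  rbind(
    data.frame(sex = "male", bands,
               rate = c(0.010, 0.014, 0.015, 0.013, 0.012)),
    data.frame(sex = "female", bands,
               rate = c(0.004, 0.005, 0.005, 0.004, 0.003)))
}

#' Gene models tiling a synthetic genome
#'
#' Tiles each chromosome with equally sized genes; each gene contributes a
#' central coding interval and two flanking regulatory intervals.  A small
#' number of genes are blacklist-flagged.
#'
#' @param map marker map defining chromosome extents.
#' @param genes_per_chrom genes per chromosome.
#' @param blacklist_frac fraction of genes flagged (default 0.05).
#' @return data frame `gene`, `chrom`, `start`, `end`, `type`, `blacklist`.
#' @export
make_gene_models <- function(map, genes_per_chrom = 12,
                             blacklist_frac = 0.05) {
  out <- list()
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    edges <- round(seq(min(bp), max(bp), length.out = genes_per_chrom + 1))
    for (i in seq_len(genes_per_chrom)) {
      g <- sprintf("GENE%d_%02d", ch, i)
      lo <- edges[i]; hi <- edges[i + 1]
      w <- hi - lo
      black <- stats::runif(1) < blacklist_frac
      out[[length(out) + 1L]] <- data.frame(
        gene = g, chrom = ch,
        start = c(round(lo + 0.3 * w), lo, round(lo + 0.8 * w)),
        end = c(round(lo + 0.7 * w), round(lo + 0.1 * w), hi),
        type = c("coding", "regulatory", "regulatory"),
        blacklist = black, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline consumes, with ground truth recorded
#' in a manifest: a pedigree with a planted shared segment forced through
#' the carrier lineage by a real gene drop, the haplotype panel and maps,
#' stratified incidence rates and family membership, gene models, a variant
#' annotation table with a planted explanatory variant (inside the planted
#' segment, carried by every carrier) and a planted associated variant, a
#' literature gene list, and optionally an unrelated genotype cohort with
#' planted QC failures.
#'
#' @param cfg a [sim_config()].
#' @param dir optional directory; when given, all inputs are also written
#'   as plain-text files (LINKAGE pedigree, PLINK map, panel VCF, TSV
#'   tables, manifest JSON).
#' @return list with `ped`, `genotypes`, `map`, `panel`, `rates`,
#'   `membership`, `genes`, `annotations`, `literature`, `cohort` (or
#'   `NULL`) and `manifest`.
#' @export
simulate_study <- function(cfg = sim_config(), dir = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ped <- make_pedigree(cfg)
  panel <- make_panel(cfg)
  founder_haps <- assign_founder_haplotypes(ped, panel)

  plant <- NULL
  if (cfg$plant_segment && length(attr(ped, "carriers")) > 0) {
    sel <- which(panel$map$chrom == cfg$plant_chrom &
                   panel$map$cM >= cfg$plant_start_cM &
                   panel$map$cM <= cfg$plant_start_cM + cfg$plant_length_cM)
    offs <- match(TRUE, panel$map$chrom == cfg$plant_chrom) - 1L
    if (length(sel) > 0)
      plant <- list(chrom = cfg$plant_chrom,
                    start_index = min(sel) - offs,
                    end_index = max(sel) - offs,
                    founder = attr(ped, "plant_founder"),
                    lineage = attr(ped, "lineage"))
  }
  geno <- drop_genes(ped, founder_haps, panel,
                     individuals = ped$id[ped$is_genotyped], plant = plant)
  if (cfg$marker_missing_rate > 0) {
    mask <- matrix(stats::runif(length(geno)) < cfg$marker_missing_rate,
                   nrow(geno))
    geno[mask] <- NA_integer_
  }

  membership <- data.frame(
    family_id = attr(ped, "family_id"), person_id = ped$id,
    sex = ifelse(ped$sex == "unknown",
                 sample(c("male", "female"), nrow(ped), replace = TRUE),
                 ped$sex),
    age = round(stats::runif(nrow(ped), 15, 90)),
    is_case = ped$is_case, stringsAsFactors = FALSE)
  rates <- default_stratum_rates()
  genes <- make_gene_models(panel$map, cfg$genes_per_chrom)

  # annotation table over a marker subset
  vsel <- sort(sample.int(nrow(panel$map), min(cfg$n_variants,
                                               nrow(panel$map))))
  freq1 <- colMeans(do.call(cbind, lapply(panel$haplotypes, identity))
                    [, vsel, drop = FALSE])
  cons <- sample(c("missense", "synonymous", "frameshift", "other"),
                 length(vsel), replace = TRUE,
                 prob = c(0.45, 0.35, 0.05, 0.15))
  calls <- function(n) sample(c("damaging", "benign", NA), n,
                              replace = TRUE, prob = c(0.3, 0.55, 0.15))
  ann <- data.frame(
    variant_id = panel$map$id[vsel], chrom = panel$map$chrom[vsel],
    bp = panel$map$bp[vsel],
    gene = vapply(seq_along(vsel), function(i) {
      hit <- genes$chrom == panel$map$chrom[vsel[i]] &
        genes$start <= panel$map$bp[vsel[i]] &
        genes$end >= panel$map$bp[vsel[i]]
      if (any(hit)) genes$gene[hit][1] else NA_character_
    }, character(1)),
    consequence = cons, sift_call = calls(length(vsel)),
    polyphen_call = calls(length(vsel)),
    ref_maf = round(pmin(pmin(freq1, 1 - freq1) +
                           stats::runif(length(vsel), -0.02, 0.02), 0.5),
                    4),
    stringsAsFactors = FALSE)
  ann$ref_maf[ann$ref_maf < 0] <- 0.0005
  ann$ref_total <- cfg$assoc_ref_total
  ann$ref_minor <- stats::rbinom(nrow(ann), cfg$assoc_ref_total,
                                 pmax(ann$ref_maf, 1e-4))
  ann$case_total <- cfg$assoc_case_total
  ann$case_minor <- stats::rbinom(nrow(ann), cfg$assoc_case_total,
                                  pmax(ann$ref_maf, 1e-4))

  manifest <- list(seed = cfg$seed, family_id = attr(ped, "family_id"),
                   carriers = attr(ped, "carriers"))
  if (!is.null(plant)) {
    offs <- match(TRUE, panel$map$chrom == cfg$plant_chrom) - 1L
    manifest$planted_segment <- list(
      chrom = cfg$plant_chrom,
      start_bp = panel$map$bp[offs + plant$start_index],
      end_bp = panel$map$bp[offs + plant$end_index],
      n_markers = plant$end_index - plant$start_index + 1L)
    # explanatory variant: a marker in the interval where the carrier
    # founder haplotype holds the 1 allele and the panel frequency is low
    carrier_hap <- panel$haplotypes[[as.character(cfg$plant_chrom)]][
      founder_haps[[as.character(cfg$plant_chrom)]]["F1", 1], ]
    span <- plant$start_index:plant$end_index
    cand <- span[carrier_hap[span] == 1]
    if (length(cand) > 0) {
      ei <- cand[which.min(colMeans(
        panel$haplotypes[[as.character(cfg$plant_chrom)]])[cand])]
      egid <- offs + ei
      row <- which(ann$variant_id == panel$map$id[egid])
      if (length(row) == 0) {
        ann <- rbind(ann, ann[1, , drop = FALSE])
        row <- nrow(ann)
        ann$variant_id[row] <- panel$map$id[egid]
        ann$chrom[row] <- cfg$plant_chrom
        ann$bp[row] <- panel$map$bp[egid]
        hit <- genes$chrom == cfg$plant_chrom &
          genes$start <= ann$bp[row] & genes$end >= ann$bp[row]
        ann$gene[row] <- if (any(hit)) genes$gene[hit][1] else "GENE_PLANT"
      }
      ann$consequence[row] <- "missense"
      ann$sift_call[row] <- "damaging"
      ann$ref_maf[row] <- round(stats::runif(1, 0.01, 0.09), 4)
      manifest$explanatory_variant <- ann$variant_id[row]
    }
  }
  # planted associated variant (counts only; follow-up cohort scale)
  ann <- rbind(ann, ann[1, , drop = FALSE])
  r <- nrow(ann)
  ann$variant_id[r] <- "rs_assoc_planted"
  ann$gene[r] <- ann$gene[1]
  ann$consequence[r] <- "missense"; ann$sift_call[r] <- "damaging"
  ann$polyphen_call[r] <- "damaging"
  ann$ref_maf[r] <- cfg$assoc_ref_freq
  ann$ref_total[r] <- cfg$assoc_ref_total
  ann$ref_minor[r] <- max(1L, stats::rbinom(1, cfg$assoc_ref_total,
                                            cfg$assoc_ref_freq))
  ann$case_total[r] <- cfg$assoc_case_total
  ann$case_minor[r] <- stats::rbinom(1, cfg$assoc_case_total,
                                     cfg$assoc_case_freq)
  manifest$assoc_variant <- "rs_assoc_planted"
  manifest$assoc_truth <- list(case_freq = cfg$assoc_case_freq,
                               ref_freq = cfg$assoc_ref_freq)
  if (is.null(cfg$seed) || !cfg$plant_segment) {
    if (!cfg$plant_segment) {
      manifest$planted_segment <- NULL
      manifest$explanatory_variant <- NULL
    }
  }

  literature <- sample(unique(genes$gene),
                       max(2, round(0.2 * length(unique(genes$gene)))))

  cohort <- NULL
  if (cfg$n_cohort > 0) {
    cohort <- make_cohort_genotypes(panel, cfg$n_cohort,
                                    n_bad_missing = cfg$n_bad_missing_markers,
                                    n_hwe_bad = cfg$n_hwe_bad_markers)
    manifest$cohort_bad_missing <- attr(cohort, "bad_missing")
    manifest$cohort_hwe_bad <- attr(cohort, "hwe_bad")
  }

  bundle <- list(ped = ped, genotypes = geno, map = panel$map,
                 panel = panel, rates = rates, membership = membership,
                 genes = genes, annotations = ann,
                 literature = literature, cohort = cohort,
                 manifest = manifest)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Unrelated cohort genotypes from a panel
#'
#' Draws two panel haplotypes per individual (Hardy-Weinberg proportions at
#' panel frequencies) and optionally plants QC failures: markers with > 5%
#' missing calls and markers with an extreme heterozygote deficit that
#' fails the Hardy-Weinberg exact test.
#'
#' @param panel a [hap_panel()].
#' @param n individuals.
#' @param n_bad_missing,n_hwe_bad planted failure counts.
#' @return genotype matrix with attributes `bad_missing` and `hwe_bad`
#'   (marker ids).
#' @export
make_cohort_genotypes <- function(panel, n, n_bad_missing = 0,
                                  n_hwe_bad = 0) {
  H <- do.call(cbind, panel$haplotypes)
  i1 <- sample.int(nrow(H), n, replace = TRUE)
  i2 <- sample.int(nrow(H), n, replace = TRUE)
  gm <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
  dimnames(gm) <- list(paste0("C", seq_len(n)), panel$map$id)
  bad <- sample.int(ncol(gm), n_bad_missing + n_hwe_bad)
  bad_missing <- utils::head(bad, n_bad_missing)
  hwe_bad <- utils::tail(bad, n_hwe_bad)
  for (j in bad_missing)
    gm[sample.int(n, max(1, ceiling(0.08 * n))), j] <- NA_integer_
  for (j in hwe_bad) {
    # extreme heterozygote deficit at frequency ~0.5
    gm[, j] <- sample(c(0L, 2L), n, replace = TRUE)
  }
  attr(gm, "bad_missing") <- panel$map$id[bad_missing]
  attr(gm, "hwe_bad") <- panel$map$id[hwe_bad]
  gm
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel a [hap_panel()].
#' @param path output path (plain text).
#' @export
write_panel_vcf <- function(panel, path) {
  H <- do.call(cbind, panel$haplotypes)
  n_hap <- nrow(H)
  stopifnot(n_hap %% 2 == 0)
  ns <- n_hap / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       paste0("P", seq_len(ns))), collapse = "\t")), con)
  for (j in seq_len(nrow(panel$map))) {
    gt <- paste0(H[seq(1, n_hap, 2), j], "|", H[seq(2, n_hap, 2), j])
    writeLines(paste(c(panel$map$chrom[j], panel$map$bp[j],
                       panel$map$id[j], panel$map$a1[j], panel$map$a2[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a synthetic bundle to disk
#'
#' Emits every input in the dialect its reader accepts: LINKAGE pedigree,
#' PLINK marker map, phased panel VCF, rates/membership/annotation/gene
#' TSVs, literature gene list, PLINK .ped genotypes and a JSON manifest.
#'
#' @param bundle result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_pedigree(bundle$ped, fp("family.ped"))
  write_plink_map(bundle$map, fp("markers.map"))
  write_panel_vcf(bundle$panel, fp("panel.vcf"))
  write_stratum_rates(bundle$rates, fp("rates.tsv"))
  utils::write.table(bundle$membership, fp("membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$genes, fp("genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$annotations, fp("annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$literature, fp("literature_genes.txt"))
  write_plink_ped(bundle$genotypes, bundle$map, bundle$ped,
                  fp("genotypes.ped"))
  jsonlite::write_json(bundle$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
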