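#' Phased haplotype panel
#'
#' A reference panel of phased haplotypes aligned to a marker map; founder
#' haplotypes for gene-drop simulation are resampled from it
#' whole-chromosome, which preserves the panel's linkage disequilibrium
#' exactly.
#'
#' @param haplotypes integer matrix, haplotypes x markers, alleles 0/1.
#' @param map marker map (see [validate_map()]) matching the columns.
#' @param validate check that the panel has at least two haplotypes and is
#'   polymorphic at every marker (default `TRUE`; disable for deliberately
#'   degenerate panels).
#' @return object of class `hap_panel`: list with per-chromosome haplotype
#'   matrices (`haplotypes`), the `map`, and `chrom_levels`.
#' @export
hap_panel <- function(haplotypes, map, validate = TRUE) {
  stopifnot(ncol(haplotypes) == nrow(map))
  validate_map(map)
  if (validate) {
    if (nrow(haplotypes) < 2) stop("panel needs at least 2 haplotypes")
    freq <- colMeans(haplotypes)
    if (any(freq == 0 | freq == 1))
      stop("panel is monomorphic at ", sum(freq == 0 | freq == 1),
           " markers")
  }
  lev <- unique(map$chrom)
  haps <- lapply(lev, function(ch)
    haplotypes[, map$chrom == ch, drop = FALSE])
  names(haps) <- as.character(lev)
  structure(list(haplotypes = haps, map = map, chrom_levels = lev),
            class = "hap_panel")
}

#' @method print hap_panel
#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d haplotypes, %d markers on %d chromosomes\n",
              nrow(x$haplotypes[[1]]), nrow(x$map),
              length(x$chrom_levels)))
  invisible(x)
}

#' Read a phased haplotype panel
#'
#' Either a VCF with phased GT (two haplotypes per sample) or a plain-text
#' matrix with one row per haplotype and one 0/1 column per marker.
#'
#' @param path file path.
#' @param format `"vcf"` or `"matrix"`.
#' @param map marker map; required for `"matrix"`, and used to align/cM-fill
#'   a VCF panel (VCF markers must match the map positions).
#' @return a [hap_panel()].
#' @export
read_haplotype_panel <- function(path, format = c("vcf", "matrix"),
                                 map = NULL) {
  format <- match.arg(format)
  if (format == "matrix") {
    stopifnot(!is.null(map))
    h <- as.matrix(utils::read.table(path, header = FALSE))
    storage.mode(h) <- "integer"
    return(hap_panel(h, map))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("|", gt, fixed = TRUE)))
    stop(structure(
      class = c("sgsfam_alignment_error", "error", "condition"),
      list(message = "panel VCF must be phased ('|' genotypes)",
           call = sys.call())))
  h1 <- apply(gt, c(1, 2), function(x)
    as.integer(strsplit(x, "|", fixed = TRUE)[[1]][1] != "0"))
  h2 <- apply(gt, c(1, 2), function(x)
    as.integer(strsplit(x, "|", fixed = TRUE)[[1]][2] != "0"))
  haps <- rbind(t(h1), t(h2))
  fix <- vcfR::getFIX(v)
  if (is.null(map)) {
    map <- data.frame(chrom = as.integer(fix[, "CHROM"]),
                      id = fix[, "ID"], bp = as.integer(fix[, "POS"]),
                      cM = 0, a1 = fix[, "REF"], a2 = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  } else {
    if (nrow(map) != nrow(fix) ||
        any(as.integer(fix[, "POS"]) != map$bp) ||
        any(as.integer(fix[, "CHROM"]) != map$chrom))
      stop(structure(
        class = c("sgsfam_alignment_error", "error", "condition"),
        list(message = "panel VCF markers do not align with the marker map",
             call = sys.call())))
  }
  # interleave: sample1 hap1, sample1 hap2, sample2 hap1, ...
  n <- ncol(gt)
  ord <- as.vector(rbind(seq_len(n), seq_len(n) + n))
  hap_panel(haps[ord, , drop = FALSE], map)
}

#' Restrict a panel to a marker subset
#'
#' Keeps the given markers (in map order), e.g. the survivors of
#' [qc_filter()], so genotypes, map and panel stay aligned.
#'
#' @param panel a [hap_panel()].
#' @param marker_ids marker ids to keep.
#' @return a [hap_panel()] on the restricted map.
#' @export
subset_panel <- function(panel, marker_ids) {
  keep <- panel$map$id %in% marker_ids
  H <- do.call(cbind, panel$haplotypes)
  hap_panel(H[, keep, drop = FALSE], panel$map[keep, , drop = FALSE],
            validate = FALSE)
}

#' Single meiosis under the Haldane model
#'
#' Transmits one recombinant gamete from a parent's two haplotypes: the
#' crossover count is Poisson in the chromosome's genetic length (Morgans),
#' crossover positions are uniform on the cM scale, with no interference.
#' The recombination fraction between two loci d Morgans apart is therefore
#' theta = (1 - exp(-2 d)) / 2.
#'
#' @param hapA,hapB the parent's two haplotypes (integer alleles).
#' @param cM marker positions in cM (non-decreasing).
#' @return the transmitted haplotype.
#' @export
meiosis <- function(hapA, hapB, cM) {
  cpp_meiosis(as.integer(hapA), as.integer(hapB), as.numeric(cM))
}

topo_order <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  done <- is.na(ped$father)
  ord <- which(done)
  while (length(ord) < nrow(ped)) {
    newly <- !done & done[idx[ped$father]] & done[idx[ped$mother]]
    newly[is.na(newly)] <- FALSE
    ord <- c(ord, which(newly))
    done <- done | newly
  }
  ord
}

#' Assign founder haplotypes from a panel
#'
#' Each founder receives two whole-chromosome haplotypes drawn uniformly
#' with replacement from the panel, independently per founder and per
#' chromosome, independent of case status.
#'
#' @param ped a `pedigree`.
#' @param panel a [hap_panel()].
#' @return list, one element per chromosome, each an integer matrix
#'   (founders x 2) of panel haplotype row indices; rownames are founder
#'   ids.
#' @export
assign_founder_haplotypes <- function(ped, panel) {
  f <- founders(ped)
  lapply(stats::setNames(panel$haplotypes, names(panel$haplotypes)),
         function(h) {
           n_hap <- nrow(h)
           if (n_hap < 1) stop("empty panel")
           m <- matrix(sample.int(n_hap, 2 * length(f), replace = TRUE),
                       ncol = 2, byrow = TRUE,
                       dimnames = list(f, c("h1", "h2")))
           m
         })
}

#' Drop genes through a pedigree
#'
#' Transmits founder haplotypes through every meiosis under the Haldane
#' model: the crossover count on a chromosome is Poisson(length in
#' Morgans), crossover positions are uniform on the cM scale, no
#' interference.  Optionally a planted segment is forced through a carrier
#' lineage: along each lineage edge the transmitted haplotype is overwritten
#' with the carrier haplotype inside the planted interval, so every carrier
#' is guaranteed to inherit it.
#'
#' @param ped a `pedigree`.
#' @param founder_haps founder assignment from
#'   [assign_founder_haplotypes()].
#' @param panel a [hap_panel()].
#' @param individuals ids whose genotypes to materialize (default: all
#'   genotyped individuals).
#' @param plant optional forcing specification: list with `chrom`,
#'   `start_index`/`end_index` (marker indices within the chromosome),
#'   `founder` (id of the origin founder; its first haplotype copy
#'   carries), and `lineage` (data frame `child`, `parent` of the descent
#'   edges to force).
#' @param return_haplotypes also return per-individual haplotypes.
#' @return integer genotype matrix (individuals x markers, counts of
#'   allele 1) with marker ids as column names; with
#'   `return_haplotypes = TRUE`, a list with `genotypes` and `haplotypes`.
#' @export
drop_genes <- function(ped, founder_haps, panel,
                       individuals = ped$id[ped$is_genotyped],
                       plant = NULL, return_haplotypes = FALSE) {
  ord <- topo_order(ped)
  chroms <- names(panel$haplotypes)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  # haps[[chrom]][[individual]] = list(h1, h2); h1 from father, h2 mother
  haps <- vector("list", length(chroms))
  names(haps) <- chroms
  carrier <- NULL
  if (!is.null(plant)) {
    carrier <- stats::setNames(integer(nrow(ped)), ped$id)  # 0 = no copy
    carrier[plant$founder] <- 1L
  }
  for (ch in chroms) {
    H <- panel$haplotypes[[ch]]
    cm <- panel$map$cM[panel$map$chrom == panel$chrom_levels[
      match(ch, names(panel$haplotypes))]]
    hh <- vector("list", nrow(ped))
    for (i in ord) {
      id <- ped$id[i]
      if (is.na(ped$father[i])) {
        rows <- founder_haps[[ch]][id, ]
        hh[[i]] <- list(H[rows[1], ], H[rows[2], ])
      } else {
        fi <- idx[ped$father[i]]; mi <- idx[ped$mother[i]]
        h1 <- cpp_meiosis(hh[[fi]][[1]], hh[[fi]][[2]], cm)
        h2 <- cpp_meiosis(hh[[mi]][[1]], hh[[mi]][[2]], cm)
        if (!is.null(plant) && ch == as.character(plant$chrom)) {
          hit <- plant$lineage$child == id
          if (any(hit)) {
            par <- plant$lineage$parent[hit][1]
            pi <- idx[par]
            stopifnot(carrier[par] > 0)
            span <- plant$start_index:plant$end_index
            src <- hh[[pi]][[carrier[par]]][span]
            if (par == ped$father[i]) {
              h1[span] <- src; carrier[id] <- 1L
            } else {
              h2[span] <- src; carrier[id] <- 2L
            }
          }
        }
        hh[[i]] <- list(h1, h2)
      }
    }
    haps[[ch]] <- hh
  }
  rows <- match(individuals, ped$id)
  gm <- do.call(cbind, lapply(chroms, function(ch)
    t(vapply(rows, function(i) haps[[ch]][[i]][[1]] + haps[[ch]][[i]][[2]],
             integer(length(haps[[ch]][[rows[1]]][[1]]))))))
  dimnames(gm) <- list(individuals, panel$map$id)
  if (return_haplotypes) list(genotypes = gm, haplotypes = haps) else gm
}

#' Gene-drop null distribution of sharing
#'
#' Builds the empirical null for a family: repeatedly assigns founder
#' haplotypes from the panel, transmits them through the pedigree with
#' recombination, and records every maximal sharing run of every case
#' subset (deduplicated within subset size).  Reproducible bit-for-bit from
#' `seed`; supports checkpoint/resume through `checkpoint_path`.
#'
#' @param ped a `pedigree`.
#' @param panel a [hap_panel()].
#' @param cases genotyped case ids forming the subset universe (default:
#'   genotyped cases of `ped`).
#' @param cfg a [scan_config()]; `min_markers_per_run` bounds which null
#'   runs are recorded, so empirical p-values are supported for observed
#'   segments at or above the same floor.
#' @param n_sims number of gene-drop simulations.
#' @param seed RNG seed.
#' @param checkpoint_path optional RDS path; progress is saved every
#'   `checkpoint_every` simulations and resumed if the file exists.
#' @param checkpoint_every checkpoint interval (default 1000).
#' @return object of class `sgs_null`: list with `runs` (data.table: sim,
#'   size, chrom, start/end marker indices and bp, length), `n_sims`,
#'   `seed`, `map`, `cfg`, `sizes`, `subsets`.
#' @export
simulate_null <- function(ped, panel, cases = genotyped_cases(ped),
                          cfg = scan_config(), n_sims = 10000, seed = 1,
                          checkpoint_path = NULL, checkpoint_every = 1000) {
  stopifnot(n_sims >= 1)
  cases <- sort(unique(as.character(cases)))
  subsets <- enumerate_subsets(length(cases), cfg$min_subset_size,
                               cfg$max_subsets)
  # only case ancestors affect case genotypes; drop everyone else
  ped <- ancestor_closure(ped, cases)
  ord <- topo_order(ped)
  ped_o <- ped[ord, , drop = FALSE]
  father <- match(ped_o$father, ped_o$id) - 1L
  mother <- match(ped_o$mother, ped_o$id) - 1L
  father[is.na(father)] <- -1L; mother[is.na(mother)] <- -1L
  case_rows <- match(cases, ped_o$id)
  sizes <- vapply(subsets, length, integer(1))
  cmlist <- lapply(panel$chrom_levels, function(ch)
    panel$map$cM[panel$map$chrom == ch])

  done <- 0L; parts <- list()
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    st <- readRDS(checkpoint_path)
    if (identical(st$key, list(seed, n_sims, length(subsets),
                               cfg$min_markers_per_run))) {
      done <- st$done; parts <- st$parts
      assign(".Random.seed", st$rng, envir = globalenv())
    }
  }
  if (done == 0L) set.seed(seed)
  while (done < n_sims) {
    todo <- as.integer(min(checkpoint_every, n_sims - done))
    raw <- cpp_simulate_null(todo, father, mother, case_rows, subsets,
                             sizes, unname(panel$haplotypes), cmlist,
                             cfg$min_markers_per_run)
    raw$sim <- raw$sim + as.integer(done)
    parts[[length(parts) + 1L]] <- data.table::as.data.table(raw)
    done <- done + todo
    if (!is.null(checkpoint_path) && done < n_sims) {
      saveRDS(list(key = list(seed, n_sims, length(subsets),
                              cfg$min_markers_per_run),
                   done = done, parts = parts,
                   rng = get(".Random.seed", envir = globalenv())),
              checkpoint_path)
      signalCondition(structure(
        class = c("sgsfam_checkpoint", "condition"),
        list(message = sprintf("checkpoint at %d simulations", done),
             call = NULL)))
    }
  }
  runs <- data.table::rbindlist(parts)
  # chrom index -> map coordinates
  offs <- c(0L, cumsum(vapply(panel$chrom_levels, function(ch)
    sum(panel$map$chrom == ch), integer(1))))
  gidx_start <- runs$start + offs[runs$chrom]
  gidx_end <- runs$end + offs[runs$chrom]
  runs[, `:=`(start_bp = panel$map$bp[gidx_start],
              end_bp = panel$map$bp[gidx_end])]
  runs[, len_bp := end_bp - start_bp]
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path))
    unlink(checkpoint_path)
  structure(list(runs = runs, n_sims = as.integer(n_sims), seed = seed,
                 map = panel$map, chrom_levels = panel$chrom_levels,
                 cfg = cfg, sizes = sort(unique(sizes)), cases = cases),
            class = "sgs_null")
}

#' @method print sgs_null
#' @export
print.sgs_null <- function(x, ...) {
  cat(sprintf(
    "Gene-drop null: %d simulations, %d recorded runs, subset sizes %s\n",
    x$n_sims, nrow(x$runs), paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Persist / restore a gene-drop null distribution
#'
#' The run store is written as a plain columnar TSV next to a metadata
#' JSON (seed, simulation count, subset sizes, scan configuration), so a
#' long null can be archived and reloaded without rerunning.
#'
#' @param null an `sgs_null`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param panel_map the marker map the null was simulated on (needed to
#'   restore coordinates).
#' @return the prefix (write) or the restored `sgs_null` (read).
#' @export
write_null_distribution <- function(null, prefix) {
  utils::write.table(as.data.frame(null$runs), paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = null$seed, n_sims = null$n_sims, sizes = null$sizes,
         cases = null$cases, chrom_levels = null$chrom_levels,
         cfg = unclass(null$cfg)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_null_distribution
#' @export
read_null_distribution <- function(prefix, panel_map) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  runs <- data.table::fread(paste0(prefix, ".tsv"))
  cfg <- do.call(scan_config, meta$cfg[c("min_subset_size",
                                         "min_markers_per_run",
                                         "missing_policy",
                                         "max_subsets")])
  structure(list(runs = runs, n_sims = as.integer(meta$n_sims),
                 seed = meta$seed, map = panel_map,
                 chrom_levels = meta$chrom_levels, cfg = cfg,
                 sizes = meta$sizes, cases = meta$cases),
            class = "sgs_null")
}

#' Empirical segment p-value
#'
#' For each observed segment, the p-value is `(c + 1) / (n_sims + 1)` where
#' `c` counts null simulations containing a sharing run of the same or a
#' larger subset size that covers the observed segment's midpoint with bp
#' length at least the observed length.
#'
#' @param segments segment data frame (from [subset_scan()] /
#'   [maximal_shared_segments()]).
#' @param null an `sgs_null` from [simulate_null()].
#' @return `segments` with the `p_value` column filled.
#' @export
empirical_pvalue <- function(segments, null) {
  if (nrow(segments) == 0) return(segments)
  if (any(segments$n_markers < null$cfg$min_markers_per_run))
    stop("null distribution only records runs of >= ",
         null$cfg$min_markers_per_run,
         " markers; shorter observed segments are unsupported")
  bad <- !(segments$chrom %in% null$chrom_levels)
  if (any(bad))
    stop(structure(
      class = c("sgsfam_coverage_error", "error", "condition"),
      list(message = paste0("segment position outside the simulated map: ",
                            "chromosome ", segments$chrom[bad][1]),
           call = sys.call())))
  runs <- null$runs
  offs <- c(0L, cumsum(vapply(null$chrom_levels, function(ch)
    sum(null$map$chrom == ch), integer(1))))
  p <- numeric(nrow(segments))
  for (ci in seq_along(null$chrom_levels)) {
    ch <- null$chrom_levels[ci]
    g <- which(segments$chrom == ch)
    if (length(g) == 0) next
    sel <- runs$chrom == ci
    m <- sum(null$map$chrom == ch)
    # anchor each query at its central marker, in within-chromosome indices
    qcol <- (segments$start_index[g] + segments$end_index[g]) %/% 2L -
      offs[ci]
    cnt <- cpp_cover_tail_counts(runs$sim[sel], runs$start[sel],
                                 runs$end[sel],
                                 as.numeric(runs$len_bp[sel]),
                                 runs$size[sel], null$n_sims, m,
                                 as.integer(qcol),
                                 as.numeric(segments$length_bp[g]),
                                 as.integer(segments$size[g]))
    p[g] <- (cnt + 1) / (null$n_sims + 1)
  }
  segments$p_value <- p
  segments
}
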