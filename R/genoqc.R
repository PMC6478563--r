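#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, every
#' heterozygote count of the same parity is enumerated, and the p-value is
#' the sum of the conditional probabilities of all configurations no more
#' probable than the observed one.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return exact p-value; 1 for a monomorphic marker (single attainable
#'   configuration).
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  # work with the rarer allele
  n1 <- 2 * n_hom1 + n_het
  n2 <- 2 * n_hom2 + n_het
  nr <- min(n1, n2)
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, nr, by = 2)
  # log P(het = h | n, nr) up to a common constant:
  #   P propto 2^h * n! / (h! * ((nr-h)/2)! * ((2n-nr-h)/2)!)
  logp <- hets * log(2) - lgamma(hets + 1) - lgamma((nr - hets) / 2 + 1) -
    lgamma((2 * n - nr - hets) / 2 + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  if (is.na(obs)) stop("heterozygote count has impossible parity")
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Validate a marker map
#'
#' A marker map has one row per marker with columns `chrom`, `id`, `bp`,
#' `cM`, and allele columns `a1`, `a2`.  Base-pair positions must be
#' strictly increasing and cM positions non-decreasing within chromosome.
#'
#' @param map data frame.
#' @return `map`, invisibly.
#' @export
validate_map <- function(map) {
  stopifnot(all(c("chrom", "id", "bp", "cM") %in% names(map)))
  for (ch in unique(map$chrom)) {
    b <- map$bp[map$chrom == ch]
    g <- map$cM[map$chrom == ch]
    if (any(diff(b) <= 0))
      stop("bp positions not strictly increasing on chromosome ", ch)
    if (any(diff(g) < 0))
      stop("cM positions decreasing on chromosome ", ch)
    if (any(!is.finite(g))) stop("non-finite cM position on chromosome ", ch)
  }
  invisible(map)
}

#' Genotype and sample quality control
#'
#' Reproduces array QC ahead of sharing analysis, in fixed order:
#' markers with missingness above `max_marker_missing` are dropped, then
#' markers failing the Hardy-Weinberg exact test at `hwe_alpha` (computed on
#' all genotyped individuals; statistically conservative under relatedness),
#' then non-polymorphic markers, then markers flagged strand-ambiguous (only
#' when a flag vector is supplied), and finally samples with missingness
#' above `max_sample_missing`.
#'
#' @param gm genotype matrix, individuals x markers, entries 0/1/2/NA
#'   counting copies of allele 2; column names are marker ids.
#' @param map marker map matching the columns of `gm`.
#' @param max_marker_missing maximum tolerated marker missing fraction
#'   (markers strictly above are dropped; default 0.05).
#' @param hwe_alpha Hardy-Weinberg exact-test threshold (default 0.001).
#' @param max_sample_missing maximum tolerated sample missing fraction
#'   (default 0.05).
#' @param ambiguous optional character vector of marker ids whose strand
#'   orientation could not be matched to the reference panel; these are
#'   dropped.
#' @return list with elements `genotypes`, `map` (survivors) and `report`
#'   (data frame of per-filter removal counts in application order).
#' @export
qc_filter <- function(gm, map, max_marker_missing = 0.05, hwe_alpha = 0.001,
                      max_sample_missing = 0.05, ambiguous = NULL) {
  stopifnot(ncol(gm) == nrow(map))
  report <- data.frame(filter = character(0), removed = integer(0))
  note <- function(name, k)
    rbind(report, data.frame(filter = name, removed = as.integer(k)))

  miss <- colMeans(is.na(gm))
  drop <- miss > max_marker_missing
  report <- note("marker_missing", sum(drop))
  gm <- gm[, !drop, drop = FALSE]; map <- map[!drop, , drop = FALSE]

  hwe_p <- apply(gm, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(1)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  drop <- hwe_p < hwe_alpha
  report <- note("hwe", sum(drop))
  gm <- gm[, !drop, drop = FALSE]; map <- map[!drop, , drop = FALSE]

  poly <- apply(gm, 2, function(g) {
    g <- g[!is.na(g)]
    length(g) > 0 && (any(g > 0) && any(g < 2))
  })
  report <- note("non_polymorphic", sum(!poly))
  gm <- gm[, poly, drop = FALSE]; map <- map[poly, , drop = FALSE]

  if (!is.null(ambiguous)) {
    drop <- map$id %in% ambiguous
    report <- note("strand_ambiguous", sum(drop))
    gm <- gm[, !drop, drop = FALSE]; map <- map[!drop, , drop = FALSE]
  }

  if (ncol(gm) == 0)
    stop(degenerate_error("no markers survive QC"))
  smiss <- rowMeans(is.na(gm))
  sdrop <- smiss > max_sample_missing
  report <- note("sample_missing", sum(sdrop))
  gm <- gm[!sdrop, , drop = FALSE]
  if (nrow(gm) == 0)
    stop(degenerate_error("no samples survive QC"))
  list(genotypes = gm, map = map, report = report)
}

degenerate_error <- function(msg) {
  structure(class = c("sgsfam_degenerate_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Write a QC report
#' @param report report data frame from [qc_filter()].
#' @param path output TSV path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- readers / writers ----------------------------------------------------

#' Read a PLINK text marker map
#'
#' `.map` columns: chromosome, marker id, cM, bp.  Allele columns are filled
#' from `alleles` when given, else left `NA` (PLINK maps carry none).
#'
#' @param path file path.
#' @param alleles optional two-column matrix/data frame of alleles.
#' @return marker map data frame (`chrom`, `id`, `cM`, `bp`, `a1`, `a2`).
#' @export
read_plink_map <- function(path, alleles = NULL) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("chrom", "id", "cM", "bp"))
  map <- data.frame(chrom = tab$chrom, id = as.character(tab$id),
                    bp = as.integer(tab$bp), cM = as.numeric(tab$cM),
                    a1 = NA_character_, a2 = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(alleles)) {
    map$a1 <- as.character(alleles[[1]])
    map$a2 <- as.character(alleles[[2]])
  }
  validate_map(map)
  map
}

#' @rdname read_plink_map
#' @param map marker map.
#' @export
write_plink_map <- function(map, path) {
  utils::write.table(map[, c("chrom", "id", "cM", "bp")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read PLINK text genotypes (.ped + .map)
#'
#' Two allele columns per marker; `0` is the missing allele code.  Genotypes
#' are returned as counts of the map's `a2` allele; when the map carries no
#' alleles, `a1`/`a2` are taken as the lexicographically sorted observed
#' alleles per marker.
#'
#' @param ped_path path to the `.ped` file.
#' @param map marker map (from [read_plink_map()]).
#' @return list with `genotypes` (individuals x markers integer matrix,
#'   rownames = individual ids) and `map` (alleles filled in).
#' @export
read_plink_ped <- function(ped_path, map) {
  tab <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  stopifnot(ncol(tab) == 6 + 2 * m)
  ids <- tab[[2]]
  a <- as.matrix(tab[, 7:(6 + 2 * m), drop = FALSE])
  gm <- matrix(NA_integer_, nrow(tab), m,
               dimnames = list(ids, map$id))
  for (j in seq_len(m)) {
    x1 <- a[, 2 * j - 1]; x2 <- a[, 2 * j]
    obs <- setdiff(sort(unique(c(x1, x2))), "0")
    a1 <- if (!is.na(map$a1[j])) map$a1[j] else obs[1]
    a2 <- if (!is.na(map$a2[j])) map$a2[j] else
      if (length(obs) > 1) obs[2] else NA_character_
    miss <- x1 == "0" | x2 == "0"
    g <- (x1 == a2) + (x2 == a2)
    if (is.na(a2)) g <- rep(0L, length(x1))
    g[miss] <- NA_integer_
    gm[, j] <- g
    map$a1[j] <- a1; map$a2[j] <- a2
  }
  list(genotypes = gm, map = map)
}

#' Write PLINK text genotypes
#'
#' @param gm genotype matrix (0/1/2/NA counts of `a2`), rownames are ids.
#' @param map marker map with alleles `a1`, `a2`.
#' @param ped pedigree supplying family/parent/sex/phenotype columns.
#' @param path output `.ped` path.
#' @export
write_plink_ped <- function(gm, map, ped, path) {
  stopifnot(ncol(gm) == nrow(map))
  rows <- match(rownames(gm), ped$id)
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex[rows]]
  lead <- cbind(attr(ped, "family_id"), rownames(gm),
                ifelse(is.na(ped$father[rows]), "0", ped$father[rows]),
                ifelse(is.na(ped$mother[rows]), "0", ped$mother[rows]),
                sexcode, ifelse(ped$is_case[rows], "2", "1"))
  al <- matrix("0", nrow(gm), 2 * ncol(gm))
  for (j in seq_len(ncol(gm))) {
    g <- gm[, j]
    al[, 2 * j - 1] <- ifelse(is.na(g), "0",
                              ifelse(g >= 1, map$a2[j], map$a1[j]))
    al[, 2 * j] <- ifelse(is.na(g), "0",
                          ifelse(g == 2, map$a2[j], map$a1[j]))
  }
  utils::write.table(cbind(lead, al), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transposed PLINK text genotypes (.tped)
#'
#' One row per marker: chromosome, id, cM, bp, then two allele columns per
#' individual.
#'
#' @param tped_path path to the `.tped` file.
#' @param ids individual identifiers in column order.
#' @return list with `genotypes` and `map` as in [read_plink_ped()].
#' @export
read_tped <- function(tped_path, ids) {
  tab <- utils::read.table(tped_path, header = FALSE,
                           colClasses = "character")
  n <- length(ids)
  stopifnot(ncol(tab) == 4 + 2 * n)
  m <- nrow(tab)
  map <- data.frame(chrom = as.integer(tab[[1]]), id = tab[[2]],
                    bp = as.integer(tab[[4]]), cM = as.numeric(tab[[3]]),
                    a1 = NA_character_, a2 = NA_character_,
                    stringsAsFactors = FALSE)
  gm <- matrix(NA_integer_, n, m, dimnames = list(ids, map$id))
  for (j in seq_len(m)) {
    x <- as.character(tab[j, 5:(4 + 2 * n)])
    x1 <- x[seq(1, 2 * n, 2)]; x2 <- x[seq(2, 2 * n, 2)]
    obs <- setdiff(sort(unique(c(x1, x2))), "0")
    a1 <- obs[1]
    a2 <- if (length(obs) > 1) obs[2] else NA_character_
    miss <- x1 == "0" | x2 == "0"
    g <- (x1 == a2) + (x2 == a2)
    if (is.na(a2)) g <- rep(0L, n)
    g[miss] <- NA_integer_
    gm[, j] <- g
    map$a1[j] <- a1; map$a2[j] <- a2
  }
  validate_map(map)
  list(genotypes = gm, map = map)
}

#' Read genotypes from a VCF (GT field)
#'
#' Returns ALT-allele dosages; the marker map is built from the VCF
#' CHROM/POS/ID/REF/ALT columns, with cM filled from `gmap` when supplied
#' (data frame `chrom`, `bp`, `cM`; linear interpolation) else 0.
#'
#' @param path VCF path (plain text or gzip).
#' @param gmap optional genetic map for cM positions.
#' @return list with `genotypes` (individuals x markers) and `map`.
#' @export
read_vcf_genotypes <- function(path, gmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  })
  fix <- vcfR::getFIX(v)
  map <- data.frame(chrom = as.integer(fix[, "CHROM"]),
                    id = ifelse(is.na(fix[, "ID"]),
                                paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                fix[, "ID"]),
                    bp = as.integer(fix[, "POS"]),
                    cM = 0, a1 = fix[, "REF"], a2 = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  if (!is.null(gmap)) {
    for (ch in unique(map$chrom)) {
      sel <- map$chrom == ch
      gsel <- gmap$chrom == ch
      map$cM[sel] <- stats::approx(gmap$bp[gsel], gmap$cM[gsel],
                                   xout = map$bp[sel], rule = 2)$y
    }
  }
  validate_map(map)
  list(genotypes = t(dose), map = map)
}
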