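#' Construct a pedigree
#'
#' A pedigree is a validated data frame of individuals with parent links,
#' sex, affection (case) status and genotyping status.  Founders have both
#' parent ids `NA`; non-founders must have both parents present in the
#' pedigree.  The parent-child graph must be acyclic, and fathers must be
#' male / mothers female wherever sex is known.
#'
#' @param id character vector of individual identifiers (unique).
#' @param father,mother parent identifiers; `NA` (or `"0"`) for founders.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param is_case logical; did the individual die by suicide (affected).
#' @param is_genotyped logical; is a genotype available.
#' @param family_id single identifier for the family.
#' @return An object of class `pedigree` (a data frame with one row per
#'   individual and attribute `family_id`).
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = "unknown",
                     is_case = FALSE, is_genotyped = FALSE,
                     family_id = "F1") {
  n <- length(id)
  ped <- data.frame(
    id = as.character(id),
    father = as.character(rep_len(father, n)),
    mother = as.character(rep_len(mother, n)),
    sex = rep_len(as.character(sex), n),
    is_case = rep_len(as.logical(is_case), n),
    is_genotyped = rep_len(as.logical(is_genotyped), n),
    stringsAsFactors = FALSE
  )
  ped$father[ped$father %in% c("0", "")] <- NA_character_
  ped$mother[ped$mother %in% c("0", "")] <- NA_character_
  attr(ped, "family_id") <- as.character(family_id)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree invariants
#'
#' Checks identifier uniqueness, parent completeness (both or neither parent
#' per individual), presence of referenced parents, acyclicity, existence of
#' at least one founder, and parental sex consistency (skipped when sex is
#' unknown).
#'
#' @param ped a `pedigree`.
#' @return `ped`, invisibly.  Errors (classed `sgsfam_structural_error` or
#'   `sgsfam_reference_error`) describe the offending individual.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id))
    stop_structural("duplicated individual id: ",
                    ped$id[duplicated(ped$id)][1])
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half))
    stop_structural("individual ", ped$id[half][1],
                    " has exactly one parent recorded; founders need none, ",
                    "non-founders need both")
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !(ref %in% ped$id)
    if (any(bad))
      stop_reference("individual ", ped$id[bad][1], " references missing ",
                     col, " '", ref[bad][1], "'")
    self <- !is.na(ref) & ref == ped$id
    if (any(self))
      stop_structural("individual ", ped$id[self][1],
                      " lists itself as ", col)
  }
  if (!any(is.na(ped$father)))
    stop_structural("pedigree has no founder")
  # cycle check: repeatedly peel individuals whose parents are all peeled
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  done <- is.na(ped$father)
  repeat {
    newly <- !done & done[idx[ped$father]] & done[idx[ped$mother]]
    newly[is.na(newly)] <- FALSE
    if (!any(newly)) break
    done <- done | newly
  }
  if (!all(done))
    stop_structural("cycle detected involving individual ",
                    ped$id[!done][1])
  for (col in c("father", "mother")) {
    want <- if (col == "father") "male" else "female"
    ref <- ped[[col]]
    psex <- ped$sex[match(ref, ped$id)]
    bad <- !is.na(ref) & !is.na(psex) & psex != "unknown" & psex != want
    if (any(bad))
      stop_structural(col, " '", ref[bad][1], "' of individual ",
                      ped$id[bad][1], " is not ", want)
  }
  invisible(ped)
}

stop_structural <- function(...) {
  stop(structure(class = c("sgsfam_structural_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_reference <- function(...) {
  stop(structure(class = c("sgsfam_reference_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @method print pedigree
#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf(
    "Pedigree %s: %d individuals (%d founders), %d cases (%d genotyped)\n",
    attr(x, "family_id"), nrow(x), sum(is.na(x$father)), sum(x$is_case),
    sum(x$is_case & x$is_genotyped)))
  invisible(x)
}

#' @method summary pedigree
#' @export
summary.pedigree <- function(object, ...) {
  cat(sprintf("Family %s\n", attr(object, "family_id")))
  cat(sprintf("  individuals : %d\n", nrow(object)))
  cat(sprintf("  founders    : %d\n", sum(is.na(object$father))))
  cat(sprintf("  cases       : %d\n", sum(object$is_case)))
  cat(sprintf("  genotyped   : %d\n", sum(object$is_genotyped)))
  gc <- genotyped_cases(object)
  if (length(gc) >= 2)
    cat(sprintf("  meioses between genotyped cases: %d\n",
                count_meioses(object, gc)))
  invisible(object)
}

#' Ancestor closure of a set of individuals
#'
#' Restricts a pedigree to the given individuals and all their ancestors —
#' the minimal sub-pedigree on which their gene-drop genotypes depend.
#'
#' @param ped a `pedigree`.
#' @param ids individual ids to keep (with ancestors).
#' @return the restricted `pedigree`.
#' @export
ancestor_closure <- function(ped, ids) {
  keep <- unique(as.character(ids))
  repeat {
    rows <- match(keep, ped$id)
    more <- setdiff(stats::na.omit(c(ped$father[rows], ped$mother[rows])),
                    keep)
    if (length(more) == 0) break
    keep <- c(keep, more)
  }
  out <- ped[ped$id %in% keep, , drop = FALSE]
  attr(out, "family_id") <- attr(ped, "family_id")
  class(out) <- c("pedigree", "data.frame")
  validate_pedigree(out)
  out
}

#' Founder identifiers of a pedigree
#' @param ped a `pedigree`.
#' @return character vector of founder ids (both parents missing).
#' @export
founders <- function(ped) ped$id[is.na(ped$father)]

#' Genotyped case identifiers
#' @param ped a `pedigree`.
#' @return character vector of ids with `is_case` and `is_genotyped`.
#' @export
genotyped_cases <- function(ped) ped$id[ped$is_case & ped$is_genotyped]

#' Read a pedigree file
#'
#' Reads whitespace-delimited LINKAGE pre-makeped / PLINK `.fam` text with
#' columns family, individual, father, mother, sex, phenotype.  Parent code
#' `0` means missing; sex 1 = male, 2 = female, other = unknown; phenotype
#' 2 = case, 1 = control, 0/-9 = unknown.
#'
#' @param path file path.
#' @param dialect `"linkage"` or `"plink_fam"` (identical column layout; the
#'   dialect is recorded for provenance).
#' @param genotyped optional character vector of ids with genotypes; by
#'   default all cases are marked genotyped.
#' @return a validated [pedigree].
#' @export
read_pedigree <- function(path, dialect = c("linkage", "plink_fam"),
                          genotyped = NULL) {
  dialect <- match.arg(dialect)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 6)
    stop_structural("pedigree file needs 6 columns (FID IID PAT MAT SEX ",
                    "PHENO); got ", ncol(tab))
  sex <- c("1" = "male", "2" = "female")[tab[[5]]]
  sex[is.na(sex)] <- "unknown"
  is_case <- tab[[6]] == "2"
  geno <- if (is.null(genotyped)) is_case else tab[[2]] %in% genotyped
  pedigree(id = tab[[2]], father = tab[[3]], mother = tab[[4]], sex = sex,
           is_case = is_case, is_genotyped = geno, family_id = tab[[1]][1])
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()]; phenotype 2 for cases, 1 otherwise.
#'
#' @param ped a `pedigree`.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- data.frame(attr(ped, "family_id"), ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    sexcode, ifelse(ped$is_case, "2", "1"))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# --- meiosis counting ------------------------------------------------------

# Build the transmission graph used for meiosis counting: nodes are
# individuals plus parent couples; individual -> couple edges cost 0
# (joining your own couple), couple -> child edges cost 1 (one meiosis per
# transmitted gamete pair, counted once per child as in drawn pedigrees).
meiosis_graph <- function(ped) {
  n <- nrow(ped)
  couple_key <- ifelse(is.na(ped$father), NA,
                       paste(ped$father, ped$mother, sep = "\r"))
  couples <- unique(stats::na.omit(couple_key))
  nC <- length(couples)
  nodes <- c(ped$id, couples)
  adj <- vector("list", n + nC)       # list of c(node, cost) pairs
  for (ci in seq_along(couples)) {
    parts <- strsplit(couples[ci], "\r", fixed = TRUE)[[1]]
    for (p in parts) {
      pi <- match(p, ped$id)
      adj[[pi]] <- rbind(adj[[pi]], c(n + ci, 0L))
    }
    kids <- which(!is.na(couple_key) & couple_key == couples[ci])
    adj[[n + ci]] <- cbind(kids, 1L)
  }
  list(adj = adj, n_nodes = n + nC, ids = nodes)
}

# single-source shortest paths with 0/1 weights (graphs are tiny)
meiosis_dist <- function(g, from) {
  d <- rep(Inf, g$n_nodes)
  d[from] <- 0
  repeat {
    changed <- FALSE
    for (v in order(d)) {
      if (!is.finite(d[v]) || is.null(g$adj[[v]])) next
      e <- g$adj[[v]]
      for (r in seq_len(nrow(e))) {
        w <- d[v] + e[r, 2]
        if (w < d[e[r, 1]]) { d[e[r, 1]] <- w; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d
}

#' Count meioses connecting a set of cases
#'
#' Number of parent-to-child transmissions in the minimal sub-pedigree
#' connecting all the given cases through common ancestry: the union, over
#' the connecting ancestor tree, of the descent paths to each case, counting
#' one meiosis per child included (a sibship of k cases under one founder
#' couple counts k).  In multiply-connected pedigrees the minimum over
#' admissible ancestor trees is returned; the minimal Steiner arborescence is
#' found exactly by Dreyfus-Wagner dynamic programming over case subsets.
#'
#' @param ped a `pedigree`.
#' @param cases character vector (length >= 2) of case ids to connect.
#' @return a non-negative integer meiosis count.
#' @export
count_meioses <- function(ped, cases) {
  cases <- unique(as.character(cases))
  if (length(cases) < 2)
    stop("need at least two cases to count meioses between")
  if (!all(cases %in% ped$id))
    stop_reference("cases not in pedigree: ",
                   paste(setdiff(cases, ped$id), collapse = ", "))
  if (length(cases) > 14)
    stop("exact meiosis counting capped at 14 cases (got ",
         length(cases), ")")
  # the connecting sub-pedigree lives inside the cases ancestor closure
  ped <- ancestor_closure(ped, cases)
  g <- meiosis_graph(ped)
  k <- length(cases)
  term <- match(cases, ped$id)
  nn <- g$n_nodes
  # dist[v, t]: shortest descent cost from node v down to terminal t
  dist <- sapply(seq_len(nn), function(v) meiosis_dist(g, v)[term])
  dist <- matrix(dist, nrow = k)      # k x nn
  nS <- bitwShiftL(1L, k)
  cost <- matrix(Inf, nn, nS - 1L)
  for (t in seq_len(k)) cost[, bitwShiftL(1L, t - 1L)] <- dist[t, ]
  masks <- seq_len(nS - 1L)
  for (S in masks[order(vapply(masks, function(m) sum(bitwAnd(
         bitwShiftR(m, 0:(k - 1)), 1L)), 0))]) {
    if (sum(bitwAnd(bitwShiftR(S, 0:(k - 1)), 1L)) < 2) next
    low <- bitwAnd(S, -S)
    rest <- bitwAnd(S, bitwNot(low))
    # proper submasks of `rest`, each joined with `low`
    sub <- rest
    f <- cost[, S]
    repeat {
      S1 <- bitwOr(sub, low)
      S2 <- bitwAnd(S, bitwNot(S1))
      if (S2 > 0L) f <- pmin(f, cost[, S1] + cost[, S2])
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, rest)
    }
    # relax through edges until stable (0/1 weights, tiny graphs)
    repeat {
      changed <- FALSE
      for (v in seq_len(nn)) {
        if (is.null(g$adj[[v]])) next
        e <- g$adj[[v]]
        w <- min(f[e[, 1]] + e[, 2])
        if (w < f[v]) { f[v] <- w; changed <- TRUE }
      }
      if (!changed) break
    }
    cost[, S] <- f
  }
  best <- min(cost[, nS - 1L])
  if (!is.finite(best))
    stop(structure(
      class = c("sgsfam_disconnection_error", "error", "condition"),
      list(message = paste0("cases are not connected through any common ",
                            "ancestor: ", paste(cases, collapse = ", ")),
           call = sys.call())))
  as.integer(best)
}

#' Family eligibility rule
#'
#' A family enters segment analysis when its familial risk is significantly
#' elevated (FSIR p below `alpha`), it has at least `min_cases_dna`
#' genotyped cases, and the genotyped cases are connected by at least
#' `min_meioses` meioses.
#'
#' @param ped a `pedigree`.
#' @param fsir_p FSIR p-value in `[0, 1]`.
#' @param min_cases_dna minimum genotyped case count (default 3).
#' @param min_meioses minimum meioses between genotyped cases (default 15).
#' @param alpha significance gate for the FSIR p-value (default 0.05).
#' @return `TRUE` or `FALSE`.
#' @export
eligible_family <- function(ped, fsir_p, min_cases_dna = 3,
                            min_meioses = 15, alpha = 0.05) {
  stopifnot(fsir_p >= 0, fsir_p <= 1)
  gc <- genotyped_cases(ped)
  if (fsir_p >= alpha) return(FALSE)
  if (length(gc) < min_cases_dna) return(FALSE)
  count_meioses(ped, gc) >= min_meioses
}
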