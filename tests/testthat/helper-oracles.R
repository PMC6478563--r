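# Independent oracles and tiny fixtures used across the suite.

ped_siblings <- function() {
  pedigree(c("F", "M", "A", "B"), c(NA, NA, "F", "F"),
           c(NA, NA, "M", "M"), c("male", "female", "male", "male"),
           is_case = c(FALSE, FALSE, TRUE, TRUE),
           is_genotyped = c(FALSE, FALSE, TRUE, TRUE))
}

ped_cousins <- function() {
  pedigree(c("GF", "GM", "P1", "P2", "S1", "S2", "X1", "X2"),
           c(NA, NA, "GF", "GF", NA, NA, "P1", "S2"),
           c(NA, NA, "GM", "GM", NA, NA, "S1", "P2"),
           c("male", "female", "male", "female", "female", "male",
             "male", "male"))
}

ped_avuncular <- function() {
  pedigree(c("GF", "GM", "U", "B", "S", "N"),
           c(NA, NA, "GF", "GF", NA, "B"),
           c(NA, NA, "GM", "GM", NA, "S"),
           c("male", "female", "male", "male", "female", "male"))
}

# Brute-force meiosis count: choose the set S of "included children" (one
# transmission each); the connecting structure is valid when all cases lie
# in one component of the graph whose edges are child--parent-couple for
# included children plus free individual--own-couple links.  Minimal |S|
# over all valid subsets is the meiosis count.
oracle_meioses <- function(ped, cases) {
  nonf <- ped$id[!is.na(ped$father)]
  couple_of <- function(id) {
    i <- match(id, ped$id)
    paste(ped$father[i], ped$mother[i], sep = "+")
  }
  own_couples <- function(id)
    unique(stats::na.omit(ifelse(
      ped$father == id | ped$mother == id,
      paste(ped$father, ped$mother, sep = "+"), NA)))
  connected <- function(S) {
    nodes <- unique(c(ped$id, paste(ped$father, ped$mother,
                                    sep = "+")[!is.na(ped$father)]))
    adj <- stats::setNames(vector("list", length(nodes)), nodes)
    add <- function(a, b) {
      adj[[a]] <<- c(adj[[a]], b)
      adj[[b]] <<- c(adj[[b]], a)
    }
    for (s in S) add(s, couple_of(s))
    for (id in ped$id) for (cp in own_couples(id)) add(id, cp)
    seen <- cases[1]
    repeat {
      nxt <- unique(c(seen, unlist(adj[seen])))
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    all(cases %in% seen)
  }
  for (k in 0:length(nonf)) {
    for (S in if (k == 0) list(character(0)) else
         utils::combn(nonf, k, simplify = FALSE)) {
      if (connected(S)) return(k)
    }
  }
  stop("oracle: cases not connectable")
}

# Direct enumeration oracle for the Hardy-Weinberg exact test: absolute
# conditional probabilities of every heterozygote count of the observed
# parity, then the tail sum of configurations no more probable.
oracle_hwe <- function(n1, nh, n2) {
  n <- n1 + nh + n2
  nr <- min(2 * n1 + nh, 2 * n2 + nh)
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, nr, by = 2)
  logp <- hets * log(2) + lgamma(n + 1) - lgamma((nr - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((2 * n - nr - hets) / 2 + 1) +
    lgamma(nr + 1) + lgamma(2 * n - nr + 1) - lgamma(2 * n + 1)
  p <- exp(logp)
  stopifnot(abs(sum(p) - 1) < 1e-9)
  obs <- p[match(nh, hets)]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Two-sided Fisher's exact oracle by full hypergeometric enumeration
# (minimum-likelihood method).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  ks <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(ks, m, n, k)
  sum(pr[pr <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Naive run scanner: per subset, marker by marker, using explicit
# allele-set intersection (the carried-allele sets of dosages 0/1/2).
oracle_segments <- function(gm, map, rows, policy = "compatible",
                            min_markers = 1) {
  carried <- function(g) {
    if (is.na(g)) return(c(1, 2))      # unknown: compatible with both
    if (g == 0) return(1)
    if (g == 2) return(2)
    c(1, 2)
  }
  share <- vapply(seq_len(ncol(gm)), function(j) {
    gs <- gm[rows, j]
    if (policy == "break" && anyNA(gs)) return(FALSE)
    length(Reduce(intersect, lapply(gs, carried))) > 0
  }, logical(1))
  out <- NULL
  j <- 1
  while (j <= ncol(gm)) {
    if (share[j]) {
      k <- j
      while (k < ncol(gm) && share[k + 1] &&
             map$chrom[k + 1] == map$chrom[j]) k <- k + 1
      if (k - j + 1 >= min_markers)
        out <- rbind(out, data.frame(chrom = map$chrom[j],
                                     start_index = j, end_index = k))
      j <- k + 1
    } else j <- j + 1
  }
  out
}

# small deterministic marker map over one or more chromosomes
toy_map <- function(m, n_chrom = 1) {
  per <- m %/% n_chrom
  do.call(rbind, lapply(seq_len(n_chrom), function(ch)
    data.frame(chrom = ch, id = paste0("m", ch, "_", seq_len(per)),
               bp = seq(1e5, by = 1e5, length.out = per),
               cM = seq(0.1, by = 0.1, length.out = per),
               a1 = "A", a2 = "G", stringsAsFactors = FALSE)))
}
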