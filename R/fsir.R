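#' Expected case count under stratified population rates
#'
#' Sums, over family members, the population incidence rate of each member's
#' sex-by-age stratum.  Rates are cross-sectional per-person probabilities.
#'
#' @param members data frame with columns `sex` (`"male"`/`"female"`) and
#'   `age` (age at censoring, years).
#' @param rates stratum rate table: data frame with columns `sex`,
#'   `age_min`, `age_max` (inclusive bounds) and `rate` in `[0, 1]`.
#' @return the expected count E (0 for an empty member list, which is
#'   flagged invalid downstream).
#' @export
expected_count <- function(members, rates) {
  stopifnot(all(c("sex", "age") %in% names(members)),
            all(c("sex", "age_min", "age_max", "rate") %in% names(rates)))
  if (nrow(members) == 0) return(0)
  r <- vapply(seq_len(nrow(members)), function(i) {
    hit <- rates$sex == members$sex[i] &
      rates$age_min <= members$age[i] & members$age[i] <= rates$age_max
    if (sum(hit) != 1)
      stop(structure(
        class = c("sgsfam_stratum_error", "error", "condition"),
        list(message = sprintf(
          "member %d (sex=%s, age=%s) maps to %d strata (need exactly 1)",
          i, members$sex[i], format(members$age[i]), sum(hit)),
          call = sys.call(-1))))
    rates$rate[hit]
  }, numeric(1))
  sum(r)
}

#' Familial standardized incidence ratio
#'
#' Plain observed/expected ratio.  The expected count comes from
#' [expected_count()].
#'
#' @param observed observed case count (non-negative integer).
#' @param expected expected case count (> 0).
#' @return O/E.
#' @export
fsir_statistic <- function(observed, expected) {
  if (any(expected <= 0))
    stop("expected count must be positive; got ", format(expected[1]))
  observed / expected
}

#' FSIR significance
#'
#' One-sided Poisson tail probability P(X >= observed) for X ~
#' Poisson(expected): the chance of seeing at least the observed case count
#' if the family only experienced the population rate.
#'
#' @inheritParams fsir_statistic
#' @return p-value in (0, 1].
#' @export
fsir_pvalue <- function(observed, expected) {
  if (any(expected <= 0))
    stop("expected count must be positive; got ", format(expected[1]))
  stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
}

#' Familial risk table
#'
#' Computes, for each family, observed and expected counts, the FSIR and its
#' Poisson significance — one row per family, mirroring the familial-risk
#' summary of a high-risk family study.
#'
#' @param membership data frame with columns `family_id`, `person_id`,
#'   `sex`, `age`, and logical `is_case`.
#' @param rates stratum rate table (see [expected_count()]).
#' @return data frame with columns `family_id`, `observed`, `expected`,
#'   `fsir`, `p_value`.
#' @export
fsir_table <- function(membership, rates) {
  fams <- unique(membership$family_id)
  rows <- lapply(fams, function(f) {
    mem <- membership[membership$family_id == f, , drop = FALSE]
    E <- expected_count(mem, rates)
    O <- sum(mem$is_case)
    data.frame(family_id = f, observed = O, expected = E,
               fsir = if (E > 0) O / E else NA_real_,
               p_value = if (E > 0) fsir_pvalue(O, E) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Read / write stratum rate tables
#'
#' Tab-separated with columns `sex`, `age_min`, `age_max`, `rate`.
#'
#' @param path file path.
#' @return data frame of rates.
#' @export
read_stratum_rates <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sex", "age_min", "age_max", "rate") %in% names(r)))
  if (any(r$rate < 0 | r$rate > 1)) stop("rates must lie in [0, 1]")
  r
}

#' @rdname read_stratum_rates
#' @param rates data frame of rates.
#' @export
write_stratum_rates <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
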