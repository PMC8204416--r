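# Linkage-quality evaluation: validation sampling, error proportions and
# recall against a gold standard, with binomial confidence intervals.
# Proportions are reported on the percentage scale.

.quality_estimate <- function(k, n, p, lo, hi, method, measure,
                              approach = NA_character_,
                              stratum = NA_character_) {
  data.table::data.table(measure = measure, approach = approach,
                         stratum = stratum, k = as.integer(k),
                         n = as.integer(n), p = p, ci_low = lo, ci_high = hi,
                         method = method)
}

#' Simple random sample of record pairs
#'
#' Samples `n` pairs without replacement, reproducibly for a given seed
#' (the caller's RNG state is left untouched).
#'
#' @param pairs A `data.table` of pairs (any rows).
#' @param n Sample size; must not exceed `nrow(pairs)`.
#' @param seed Integer seed.
#' @return The sampled rows.
#' @export
sample_pairs <- function(pairs, n, seed) {
  pairs <- data.table::as.data.table(pairs)
  if (n > nrow(pairs))
    .stopf("cannot sample %d pairs from %d available", n, nrow(pairs))
  idx <- .with_seed(seed, sample.int(nrow(pairs), n))
  pairs[idx]
}

#' Wald binomial confidence interval for a proportion
#'
#' `p = 100 k/n` with bounds `p +/- z * 100 * sqrt(p(1-p)/n)` (normal
#' approximation), clamped to \[0, 100\].
#'
#' @param k,n Numerator and denominator counts.
#' @param conf Confidence level (default 0.95).
#' @param measure,approach,stratum Optional labels carried in the output.
#' @return One-row `data.table` (a quality estimate): `k`, `n`, `p`,
#'   `ci_low`, `ci_high` in percent, `method = "wald"`.
#' @export
proportion_ci_wald <- function(k, n, conf = 0.95, measure = "other",
                               approach = NA_character_,
                               stratum = NA_character_) {
  if (n < 1) .stopf("n must be >= 1")
  if (k > n || k < 0) .stopf("k must satisfy 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  half <- z * sqrt(ph * (1 - ph) / n)
  .quality_estimate(k, n, 100 * ph,
                    max(0, 100 * (ph - half)), min(100, 100 * (ph + half)),
                    "wald", measure, approach, stratum)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Bounds from beta-distribution quantiles: lower
#' `qbeta(alpha/2, k, n-k+1)` (0 when `k = 0`), upper
#' `qbeta(1-alpha/2, k+1, n-k)` (1 when `k = n`), on the percentage
#' scale.
#'
#' @inheritParams proportion_ci_wald
#' @return One-row quality-estimate `data.table`, `method =
#'   "clopper_pearson"`.
#' @export
proportion_ci_exact <- function(k, n, conf = 0.95, measure = "other",
                                approach = NA_character_,
                                stratum = NA_character_) {
  if (n < 1) .stopf("n must be >= 1")
  if (k > n || k < 0) .stopf("k must satisfy 0 <= k <= n")
  alpha <- 1 - conf
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  .quality_estimate(k, n, 100 * k / n, 100 * lo, 100 * hi,
                    "clopper_pearson", measure, approach, stratum)
}

# shared engine for the two error measures
.error_proportion <- function(sample, contradicting, measure, approach,
                              method) {
  s <- data.table::as.data.table(sample)
  if (!"verdict" %in% names(s)) .stopf("sample must carry a 'verdict' column")
  if (any(is.na(s$verdict) | s$verdict == "pending"))
    .stopf("every sampled pair needs a re-review verdict (none may be pending)")
  bad <- setdiff(unique(s$verdict), c("match", "non-match"))
  if (length(bad)) .stopf("invalid verdict value(s): %s", paste(bad, collapse = ", "))
  k <- sum(s$verdict == contradicting)
  f <- if (method == "clopper_pearson") proportion_ci_exact else proportion_ci_wald
  f(k, nrow(s), measure = measure, approach = approach)
}

#' False match proportion of an approach
#'
#' Among a re-reviewed sample of pairs originally classified as matches,
#' the proportion whose verdict contradicts the classification (i.e. the
#' records belong to different individuals).
#'
#' @param reviewed_sample `data.table` with a `verdict` column
#'   (`"match"`/`"non-match"`; re-review of sampled matches).
#' @param approach Label of the approach being evaluated.
#' @param method `"clopper_pearson"` (default) or `"wald"`.
#' @return One-row quality-estimate `data.table`,
#'   `measure = "false_match"`.
#' @export
false_match_proportion <- function(reviewed_sample, approach = NA_character_,
                                   method = c("clopper_pearson", "wald")) {
  method <- match.arg(method)
  .error_proportion(reviewed_sample, "non-match", "false_match", approach,
                    method)
}

#' Missed match proportion of the clerical review approach
#'
#' Among a re-reviewed sample of pairs originally classified as
#' non-matches, the proportion whose verdict is match (records of the
#' same individual that were not linked).
#'
#' @inheritParams false_match_proportion
#' @param reviewed_nonmatch_sample Sampled non-matches with a `verdict`
#'   column.
#' @return One-row quality-estimate `data.table`,
#'   `measure = "missed_match"`.
#' @export
missed_match_proportion <- function(reviewed_nonmatch_sample,
                                    approach = "clerical",
                                    method = c("clopper_pearson", "wald")) {
  method <- match.arg(method)
  .error_proportion(reviewed_nonmatch_sample, "match", "missed_match",
                    approach, method)
}

#' Recall against an external gold standard
#'
#' Among entities the gold standard marks positive (e.g. individuals a
#' registry records as deceased), the proportion also found by the
#' linkage, overall and per stratum, with Wald confidence intervals.
#'
#' @param gold_ids Identifiers of the gold-positive entities.
#' @param linked_ids Identifiers the linkage found.
#' @param strata Optional vector parallel to `gold_ids` giving each
#'   entity's stratum.
#' @param conf Confidence level.
#' @return Quality-estimate `data.table`, one row overall (stratum
#'   `"all"`) plus one per stratum, `measure = "recall"`.
#' @export
recall_vs_gold <- function(gold_ids, linked_ids, strata = NULL, conf = 0.95) {
  if (!length(gold_ids)) .stopf("empty gold standard set")
  found <- gold_ids %in% linked_ids
  out <- list(proportion_ci_wald(sum(found), length(found), conf,
                                 measure = "recall", stratum = "all"))
  if (!is.null(strata)) {
    if (length(strata) != length(gold_ids))
      .stopf("strata must be parallel to gold_ids")
    for (s in sort(unique(as.character(strata)))) {
      i <- strata == s
      out[[length(out) + 1L]] <-
        proportion_ci_wald(sum(found[i]), sum(i), conf,
                           measure = "recall", stratum = s)
    }
  }
  data.table::rbindlist(out)
}

#' Round-half-up display of a percentage
#'
#' Display helper matching the convention of rounding halves upward at
#' one decimal (base `round()` rounds halves to even).
#'
#' @param p Numeric percentages.
#' @param digits Decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(p, digits = 1) {
  m <- 10^digits
  floor(p * m + 0.5 + 1e-9) / m
}

#' Write an evaluation report CSV
#'
#' @param estimates Quality-estimate rows (rbind of the `*_proportion` /
#'   [recall_vs_gold()] outputs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(estimates, path) {
  data.table::fwrite(data.table::as.data.table(estimates), path)
  invisible(path)
}
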