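# Multi-pass blocked probabilistic linkage (Fellegi-Sunter).
#
# Candidate pairs are generated per pass by exact agreement on an indexing
# key (combinations of phonetic codes, sex, birth year); field comparisons
# are discretised to agree/disagree/missing; per-field m/u probabilities
# are estimated by EM over the comparison vectors; a pair's composite
# score is the sum of log2(m/u) (agreement) or log2((1-m)/(1-u))
# (disagreement) over compared fields, missing contributing 0.

.INDEX_COLS <- c(sx_first = "sx_first", sx_last = "sx_last",
                 sex = "sex", birth_year = "birth_year")
.COMPARE_COLS <- c(full_name = "name", first_name = "name_first",
                   last_name = "name_last", mother_name = "mother_name",
                   birth_date = "birth_date")

#' Specify one probabilistic blocking pass
#'
#' @param pass_number Integer pass id (1..7 in the bundled strategy).
#' @param index_fields Subset of `c("sx_first", "sx_last", "sex",
#'   "birth_year")`; candidates must agree exactly on all of them.
#' @param compare_fields Ordered subset of `c("full_name", "first_name",
#'   "last_name", "mother_name", "birth_date")`.
#' @param threshold Composite-score cutoff: pairs scoring `>= threshold`
#'   receive the pass's output class. Thresholds are data-dependent and
#'   must be supplied (or resolved with `auto_threshold` in
#'   [run_probabilistic()]); see [suggest_threshold()].
#' @param output_class `"match"` (automatic) or `"potential"` (sent to
#'   clerical review).
#' @return An object of class `lw_pass`.
#' @export
blocking_pass <- function(pass_number, index_fields, compare_fields,
                          threshold = NA_real_,
                          output_class = c("match", "potential")) {
  output_class <- match.arg(output_class)
  if (!length(index_fields) || !all(index_fields %in% names(.INDEX_COLS)))
    .stopf("index_fields must be a non-empty subset of {%s}",
           paste(names(.INDEX_COLS), collapse = ", "))
  if (!length(compare_fields) || !all(compare_fields %in% names(.COMPARE_COLS)))
    .stopf("compare_fields must be a non-empty subset of {%s}",
           paste(names(.COMPARE_COLS), collapse = ", "))
  structure(list(pass_number = as.integer(pass_number),
                 index_fields = index_fields,
                 compare_fields = compare_fields,
                 threshold = as.numeric(threshold),
                 output_class = output_class),
            class = "lw_pass")
}

#' The bundled seven-pass blocking strategy
#'
#' Passes 1-5 compare full name, mother's name and birth date under five
#' different indexing keys (all four attributes, then each triple); pass 6
#' re-uses the full key but compares first given name, last family name,
#' mother's name and birth date (robust to truncated/initialed middle
#' names); pass 7 re-uses the full key, compares only name and birth date,
#' and outputs potential matches for clerical review.
#'
#' @param thresholds Numeric vector of length 7 of score cutoffs (may be
#'   `NA` to be resolved at run time via `auto_threshold`).
#' @return List of seven [blocking_pass()] objects.
#' @export
blocking_passes_preset <- function(thresholds = rep(NA_real_, 7)) {
  stopifnot(length(thresholds) == 7)
  full_key <- c("sx_first", "sx_last", "sex", "birth_year")
  cmp_a <- c("full_name", "mother_name", "birth_date")
  list(
    blocking_pass(1L, full_key, cmp_a, thresholds[1], "match"),
    blocking_pass(2L, c("sx_first", "sex", "birth_year"), cmp_a, thresholds[2], "match"),
    blocking_pass(3L, c("sx_last", "sex", "birth_year"), cmp_a, thresholds[3], "match"),
    blocking_pass(4L, c("sx_first", "sx_last", "sex"), cmp_a, thresholds[4], "match"),
    blocking_pass(5L, c("sx_first", "sx_last", "birth_year"), cmp_a, thresholds[5], "match"),
    blocking_pass(6L, full_key,
                  c("first_name", "last_name", "mother_name", "birth_date"),
                  thresholds[6], "match"),
    blocking_pass(7L, full_key, c("full_name", "birth_date"), thresholds[7],
                  "potential")
  )
}

#' Generate candidate pairs for one blocking pass
#'
#' All and only the pairs agreeing exactly on the concatenated index
#' fields; records missing any index field are excluded from the pass.
#'
#' @param left_residual,right_table Preprocessed tables.
#' @param spec A [blocking_pass()].
#' @param exclude_pairs Optional `data.table` of (`left_uid`, `right_uid`)
#'   pairs to omit (e.g. pairs already matched deterministically).
#' @return Pairs `data.table` with `l_*`/`r_*` field projections.
#' @export
build_candidates <- function(left_residual, right_table, spec,
                             exclude_pairs = NULL) {
  stopifnot(inherits(spec, "lw_pass"))
  left <- data.table::as.data.table(left_residual)
  right <- data.table::as.data.table(right_table)
  cols <- .INDEX_COLS[spec$index_fields]
  lkey <- do.call(paste, c(lapply(cols, function(cc) as.character(left[[cc]])), sep = "|"))
  rkey <- do.call(paste, c(lapply(cols, function(cc) as.character(right[[cc]])), sep = "|"))
  lok <- stats::complete.cases(left[, ..cols])
  rok <- stats::complete.cases(right[, ..cols])
  L <- data.table::data.table(.li = which(lok), v = lkey[lok])
  R <- data.table::data.table(.ri = which(rok), v = rkey[rok])
  idx <- merge(L, R, by = "v", allow.cartesian = TRUE)[, .(.li, .ri)]
  pairs <- .project_pairs(left, right, idx)
  if (!is.null(exclude_pairs) && nrow(exclude_pairs) && nrow(pairs)) {
    drop <- paste(pairs$l_record_uid, pairs$r_record_uid, sep = "\r") %in%
      paste(exclude_pairs$left_uid, exclude_pairs$right_uid, sep = "\r")
    pairs <- pairs[!drop]
  }
  pairs
}

#' Compare the fields of candidate pairs
#'
#' Name-type fields agree when their Levenshtein distance is below
#' `name_agree_threshold` (strict `<`); birth dates agree when their ISO
#' serialisations are identical character by character; a field missing on
#' either side yields outcome `missing`. Raw distances are retained for
#' audit.
#'
#' @param pairs Pairs table from [build_candidates()].
#' @param spec The pass ([blocking_pass()]) whose `compare_fields` to use.
#' @param name_agree_threshold Distance bound (default 3).
#' @return The pairs table with, per compared field `f`, columns `cmp_f`
#'   (1 agree / 0 disagree / `NA` missing) and, for name fields, `dist_f`.
#' @export
compare_pairs <- function(pairs, spec, name_agree_threshold = 3L) {
  stopifnot(inherits(spec, "lw_pass"))
  pairs <- data.table::as.data.table(pairs)
  for (f in spec$compare_fields) {
    col <- .COMPARE_COLS[[f]]
    lv <- pairs[[paste0("l_", col)]]
    rv <- pairs[[paste0("r_", col)]]
    if (f == "birth_date") {
      ls <- format(lv, "%Y-%m-%d"); rs <- format(rv, "%Y-%m-%d")
      out <- ifelse(is.na(ls) | is.na(rs), NA_integer_,
                    as.integer(ls == rs))
    } else {
      d <- levenshtein(as.character(lv), as.character(rv))
      pairs[, (paste0("dist_", f)) := d]
      out <- ifelse(is.na(d), NA_integer_, as.integer(d < name_agree_threshold))
    }
    pairs[, (paste0("cmp_", f)) := out]
  }
  pairs
}

# Extract the outcome matrix (n x K of 1/0/NA) from a compared pairs table.
.outcome_matrix <- function(pairs, compare_fields) {
  cols <- paste0("cmp_", compare_fields)
  miss <- setdiff(cols, names(pairs))
  if (length(miss)) .stopf("pairs table lacks comparison column(s): %s",
                           paste(miss, collapse = ", "))
  m <- as.matrix(pairs[, ..cols])
  colnames(m) <- compare_fields
  storage.mode(m) <- "integer"
  m
}

#' Estimate Fellegi-Sunter field weights by EM
#'
#' Fits a two-class latent mixture over independent binary field outcomes:
#' with probability `p` (match prevalence) a pair is a true match and
#' field `k` agrees with probability `m_k`; otherwise it agrees with
#' probability `u_k`. Missing outcomes are excluded from the field's
#' likelihood term. The observed-data log-likelihood is non-decreasing
#' across iterations; the fit stops when its increase falls below `tol`
#' or after `max_iter` iterations. If the converged solution has
#' `m <= u` on average the class labels are swapped (with a warning).
#'
#' @param vectors Integer matrix (or compared pairs table plus `fields`)
#'   of outcomes: 1 agree, 0 disagree, `NA` missing; one column per field.
#' @param fields When `vectors` is a pairs table, the compare fields to
#'   extract.
#' @param init List with starting values `m`, `u` (scalar or per-field)
#'   and `p` (prevalence). Deterministic; no randomness is involved.
#' @param max_iter,tol Stopping rule on the observed-data log-likelihood.
#' @return An object of class `lw_weights`: `$fields` (`data.table` with
#'   `field`, `m`, `u`, `w_agree = log2(m/u)`,
#'   `w_disagree = log2((1-m)/(1-u))`), `$prevalence`, `$loglik` (trace),
#'   `$iterations`, `$converged`, `$swapped`.
#' @export
estimate_weights_em <- function(vectors, fields = NULL,
                                init = list(m = 0.9, u = 0.1, p = 0.01),
                                max_iter = 500L, tol = 1e-6) {
  if (is.data.frame(vectors)) {
    if (is.null(fields)) .stopf("supply 'fields' when passing a pairs table")
    vectors <- .outcome_matrix(data.table::as.data.table(vectors), fields)
  }
  x <- as.matrix(vectors)
  storage.mode(x) <- "double"
  K <- ncol(x); n <- nrow(x)
  if (n < 2L) .stopf("need at least 2 comparison vectors")
  fieldnames <- colnames(x) %||% paste0("field", seq_len(K))

  # collapse identical vectors (NA patterns included) for speed
  pat_key <- apply(x, 1L, paste, collapse = "/")
  tab <- table(pat_key)
  if (length(tab) < 2L)
    .stopf("degenerate input: all comparison vectors are identical; EM cannot separate classes - supply weights manually")
  upat <- x[match(names(tab), pat_key), , drop = FALSE]
  w_n <- as.numeric(tab)
  obs <- !is.na(upat)

  clamp <- function(v, lo = 1e-6, hi = 1 - 1e-6) pmin(pmax(v, lo), hi)
  m <- clamp(rep_len(init$m %||% 0.9, K))
  u <- clamp(rep_len(init$u %||% 0.1, K))
  p <- min(max(init$p %||% 0.01, 1e-8), 1 - 1e-8)

  loglik <- numeric(0)
  x0 <- upat; x0[!obs] <- 0  # zero-filled copy; masked by obs in sums
  for (it in seq_len(max_iter)) {
    # E step: log P(vector | class), missing fields skipped
    la <- sweep(x0, 2, log(m), `*`) + sweep((1 - x0) * obs, 2, log1p(-m), `*`)
    lb <- sweep(x0, 2, log(u), `*`) + sweep((1 - x0) * obs, 2, log1p(-u), `*`)
    lA <- rowSums(la) + log(p)
    lB <- rowSums(lb) + log1p(-p)
    mx <- pmax(lA, lB)
    denom <- mx + log(exp(lA - mx) + exp(lB - mx))
    g <- exp(lA - denom)                 # posterior P(match | vector)
    loglik <- c(loglik, sum(w_n * denom))
    # M step
    wg <- w_n * g; wb <- w_n * (1 - g)
    p <- min(max(sum(wg) / sum(w_n), 1e-8), 1 - 1e-8)
    m <- clamp(colSums(wg * x0) / colSums(wg * obs))
    u <- clamp(colSums(wb * x0) / colSums(wb * obs))
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol) break
  }
  swapped <- FALSE
  if (mean(m) <= mean(u)) {
    tmp <- m; m <- u; u <- tmp
    p <- 1 - p
    swapped <- TRUE
    .warnf("EM converged with m <= u; class labels swapped")
  }
  flt <- data.table::data.table(
    field = fieldnames, m = m, u = u,
    w_agree = log2(m / u), w_disagree = log2((1 - m) / (1 - u))
  )
  structure(list(fields = flt, prevalence = p, loglik = loglik,
                 iterations = length(loglik),
                 converged = length(loglik) < max_iter, swapped = swapped),
            class = "lw_weights")
}

#' @export
print.lw_weights <- function(x, ...) {
  cat("Fellegi-Sunter weights (EM, ", x$iterations, " iterations, prevalence ",
      signif(x$prevalence, 4), "):\n", sep = "")
  print(x$fields)
  invisible(x)
}

#' Manually specified field weights
#'
#' @param fields Character vector of field names.
#' @param m,u Per-field agreement probabilities among matches /
#'   non-matches (`0 < u < m < 1`).
#' @param prevalence Assumed match prevalence (used by
#'   [suggest_threshold()]).
#' @return An `lw_weights` object.
#' @export
manual_weights <- function(fields, m, u, prevalence = 0.01) {
  m <- rep_len(m, length(fields)); u <- rep_len(u, length(fields))
  if (any(u >= m) || any(m >= 1) || any(u <= 0))
    .stopf("weights require 0 < u < m < 1 per field")
  structure(list(
    fields = data.table::data.table(field = fields, m = m, u = u,
                                    w_agree = log2(m / u),
                                    w_disagree = log2((1 - m) / (1 - u))),
    prevalence = prevalence, loglik = numeric(0), iterations = 0L,
    converged = TRUE, swapped = FALSE), class = "lw_weights")
}

#' Composite score of comparison vectors
#'
#' Sum over compared fields of the agreement weight (outcome agree), the
#' disagreement weight (disagree) or 0 (missing).
#'
#' @param vectors Outcome matrix (1/0/`NA`) or compared pairs table.
#' @param weights An `lw_weights` object covering every compared field.
#' @param fields Compare fields to extract when `vectors` is a table
#'   (default: the weight object's fields).
#' @return Numeric vector of scores.
#' @export
score_pairs <- function(vectors, weights, fields = NULL) {
  stopifnot(inherits(weights, "lw_weights"))
  if (is.data.frame(vectors)) {
    fields <- fields %||% weights$fields$field
    vectors <- .outcome_matrix(data.table::as.data.table(vectors), fields)
  }
  x <- as.matrix(vectors)
  fl <- colnames(x) %||% weights$fields$field
  pos <- match(fl, weights$fields$field)
  if (anyNA(pos)) .stopf("no weights for field(s): %s",
                         paste(fl[is.na(pos)], collapse = ", "))
  wa <- weights$fields$w_agree[pos]
  wd <- weights$fields$w_disagree[pos]
  contrib <- sweep(ifelse(is.na(x), 0, x), 2, wa, `*`) +
    sweep(ifelse(is.na(x), 0, 1 - x), 2, wd, `*`)
  rowSums(contrib)
}

#' Score a single comparison vector
#'
#' @param vector Named integer vector of outcomes (1/0/`NA`) per field.
#' @param weights An `lw_weights` object.
#' @return Scalar score.
#' @export
score_pair <- function(vector, weights) {
  m <- matrix(vector, nrow = 1, dimnames = list(NULL, names(vector)))
  score_pairs(m, weights)
}

#' Posterior-odds score threshold
#'
#' The composite score at which the posterior probability of a true match
#' reaches `target_posterior` under the fitted prevalence:
#' `log2(prior odds against) + log2(posterior odds for)`. With the default
#' 0.5 this is the balance point where a pair is more likely a match than
#' not. Thresholds in the source strategy were set empirically per pass;
#' this helper supports that choice, it does not replace it.
#'
#' @param weights `lw_weights` object (its `$prevalence` is used).
#' @param target_posterior Desired posterior match probability at the
#'   cutoff.
#' @return Scalar score threshold.
#' @export
suggest_threshold <- function(weights, target_posterior = 0.5) {
  stopifnot(inherits(weights, "lw_weights"))
  p <- weights$prevalence
  log2((1 - p) / p) + log2(target_posterior / (1 - target_posterior))
}

#' Score histogram helper
#'
#' Binned counts of composite scores, to support manual threshold choice.
#'
#' @param scores Numeric scores.
#' @param breaks Number of bins or break vector (passed to [hist()]).
#' @return `data.table` with `bin_low`, `bin_high`, `count`.
#' @export
score_histogram <- function(scores, breaks = 30) {
  h <- graphics::hist(scores, breaks = breaks, plot = FALSE)
  data.table::data.table(bin_low = h$breaks[-length(h$breaks)],
                         bin_high = h$breaks[-1], count = h$counts)
}

# Attainable score range [sum w_disagree, sum w_agree] for a pass.
.score_range <- function(weights, fields) {
  pos <- match(fields, weights$fields$field)
  c(sum(weights$fields$w_disagree[pos]), sum(weights$fields$w_agree[pos]))
}

#' Run the multi-pass probabilistic linkage stage
#'
#' Executes the blocking passes in order. Per pass: candidate generation
#' by exact agreement on the index key, field comparison, weight
#' estimation (EM) or lookup, composite scoring, and classification: pairs
#' scoring at or above the pass threshold receive the pass's output class
#' (`match` for passes whose `output_class` is match, `potential` for the
#' final review pass). In `one_to_one` mode each left record can match at
#' most one right record (best score, ties to the smaller right uid) and
#' matched records are removed from subsequent passes; in `one_to_many`
#' mode left records persist through all passes while matched right
#' records are removed.
#'
#' @param left_residual,right_table Preprocessed tables (after the
#'   deterministic stage).
#' @param passes List of [blocking_pass()] objects.
#' @param weights `NULL` to fit by EM (shared across passes with identical
#'   compare fields, fitted on the first such pass), a single
#'   `lw_weights`, or a list of `lw_weights` parallel to `passes`.
#' @param mode `"one_to_one"` or `"one_to_many"`.
#' @param exclude_pairs Pairs already matched (e.g. deterministically);
#'   never re-candidated.
#' @param name_agree_threshold Distance bound for name agreement.
#' @param auto_threshold If `TRUE`, passes with `NA` thresholds use
#'   [suggest_threshold()] on the pass's weights.
#' @return List of class `lw_prob_result`: `matches`, `potentials` (both
#'   scored pair tables with per-field outcomes and weight contributions),
#'   `left_residual`, `right_residual`, `weights` (per pass),
#'   `thresholds`, `report`.
#' @export
run_probabilistic <- function(left_residual, right_table, passes,
                              weights = NULL,
                              mode = c("one_to_one", "one_to_many"),
                              exclude_pairs = NULL,
                              name_agree_threshold = 3L,
                              auto_threshold = FALSE) {
  mode <- match.arg(mode)
  if (inherits(passes, "lw_pass")) passes <- list(passes)
  left <- data.table::as.data.table(left_residual)
  right <- data.table::as.data.table(right_table)
  exclude <- if (is.null(exclude_pairs))
    data.table::data.table(left_uid = character(0), right_uid = character(0))
  else data.table::as.data.table(exclude_pairs)[, .(left_uid, right_uid)]

  sig <- vapply(passes, function(p) paste(p$compare_fields, collapse = "+"),
                character(1))
  fitted <- list()     # signature -> lw_weights
  if (is.null(weights)) {
    # Shared weights per compare-field signature, estimated once on the
    # pooled candidates of all passes in the group (the sequential pass
    # loop below still classifies on its own, shrinking candidate sets).
    for (s in unique(sig)) {
      grp <- which(sig == s)
      pool <- data.table::rbindlist(lapply(grp, function(i) {
        sp <- passes[[i]]
        cand <- build_candidates(left, right, sp, exclude_pairs = exclude)
        cand <- compare_pairs(cand, sp, name_agree_threshold)
        cols <- paste0("cmp_", sp$compare_fields)
        if (nrow(cand)) cand[, ..cols] else NULL
      }))
      if (!is.null(pool) && nrow(pool) >= 2L) {
        w <- tryCatch(
          estimate_weights_em(as.matrix(pool)),
          error = function(e) { .warnf("EM failed for signature '%s': %s", s,
                                       conditionMessage(e)); NULL })
        if (!is.null(w)) {
          w$fields$field <- passes[[grp[1]]]$compare_fields
          fitted[[s]] <- w
        }
      }
    }
  }
  pass_weights <- vector("list", length(passes))
  thresholds <- numeric(length(passes))
  matches <- list(); potentials <- list()
  report <- list()
  active_left <- left
  active_right <- right

  for (i in seq_along(passes)) {
    sp <- passes[[i]]
    cand <- build_candidates(active_left, active_right, sp, exclude_pairs = exclude)
    cand <- compare_pairs(cand, sp, name_agree_threshold)
    w <- NULL
    if (!is.null(weights)) {
      w <- if (inherits(weights, "lw_weights")) weights else weights[[i]]
    } else {
      w <- fitted[[sig[i]]]
    }
    pass_weights[[i]] <- w
    thr <- sp$threshold
    if (is.na(thr)) {
      if (!auto_threshold)
        .stopf("pass %d has no threshold; supply one or set auto_threshold = TRUE",
               sp$pass_number)
      if (is.null(w)) thr <- Inf else thr <- suggest_threshold(w)
    }
    thresholds[i] <- thr
    if (nrow(cand) && !is.null(w)) {
      rng <- .score_range(w, sp$compare_fields)
      if (thr < rng[1] || thr > rng[2])
        .warnf("pass %d threshold %.2f outside attainable score range [%.2f, %.2f]",
               sp$pass_number, thr, rng[1], rng[2])
      cand[, score := score_pairs(cand, w, fields = sp$compare_fields)]
      hits <- cand[score >= thr]
    } else {
      cand[, score := numeric(nrow(cand))]
      hits <- cand[0]
    }
    if (nrow(hits)) {
      if (mode == "one_to_one") {
        data.table::setorder(hits, l_record_uid, -score, r_record_uid)
        hits <- hits[!duplicated(l_record_uid)]
      }
      # a right record refers to one person: keep its best-scoring left
      hits <- hits[order(r_record_uid, -score, l_record_uid)]
      hits <- hits[!duplicated(r_record_uid)]
    }
    if (nrow(hits)) {
      hits[, `:=`(pass = sp$pass_number, class = sp$output_class,
                  approach = "probabilistic")]
      if (sp$output_class == "match") matches[[length(matches) + 1L]] <- hits
      else potentials[[length(potentials) + 1L]] <- hits
      if (mode == "one_to_one") {
        active_left <- active_left[!record_uid %in% hits$l_record_uid]
      }
      if (sp$output_class == "match")
        active_right <- active_right[!record_uid %in% hits$r_record_uid]
      exclude <- rbind(exclude,
                       hits[, .(left_uid = l_record_uid, right_uid = r_record_uid)])
    }
    report[[i]] <- data.table::data.table(
      pass = sp$pass_number, n_candidates = nrow(cand), n_hits = nrow(hits),
      threshold = thr, output_class = sp$output_class)
  }
  matches <- data.table::rbindlist(matches, fill = TRUE)
  potentials <- data.table::rbindlist(potentials, fill = TRUE)
  matched_l <- unique(matches$l_record_uid)
  matched_r <- unique(matches$r_record_uid)
  left_res <- if (mode == "one_to_many") data.table::copy(left) else
    left[!record_uid %in% matched_l]
  structure(list(matches = matches, potentials = potentials,
                 left_residual = left_res,
                 right_residual = right[!record_uid %in% matched_r],
                 weights = pass_weights, thresholds = thresholds,
                 report = data.table::rbindlist(report), mode = mode),
            class = "lw_prob_result")
}
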