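# Deterministic rule-based linkage.
#
# Seven pairwise rules over candidate pairs; a linkage process declares its
# match criteria as a disjunction of rule conjunctions ("clauses"). A pair
# is a match when ANY clause has ALL of its rules true. Missing operands
# never agree.

.RULE_LABELS <- c(
  "1" = "linkage key equality",
  "2" = "cpf equality",
  "3" = "nis equality",
  "4" = "birth date equality",
  "5" = "name Levenshtein < 3",
  "6" = "mother name Levenshtein < 3",
  "7" = "name equality"
)

# Rules that are exact-equality joins, in decreasing expected selectivity;
# every clause must contain at least one so that hash joins can reach it.
.EXACT_RULES <- c(1L, 2L, 3L, 7L, 4L)
.EXACT_JOIN_COL <- c("1" = "linkage_key", "2" = "cpf", "3" = "nis",
                     "7" = "name", "4" = "birth_date")

#' Deterministic process criteria
#'
#' Builds (or retrieves a preset of) the clause list a linkage process uses
#' to classify pairs deterministically. A pair is a match if any clause has
#' all its rules true. Rules are identified 1..7:
#' 1 linkage-key equality, 2 CPF equality, 3 NIS equality, 4 birth-date
#' equality, 5 name Levenshtein distance < 3, 6 mother's-name Levenshtein
#' distance < 3, 7 exact name equality.
#'
#' Presets (named after the source-database pairing they were designed
#' for): `"cadu_fhr"` = (1,5,6)|(2,5,6)|(3,5,6)|(2,4)|(3,4);
#' `"cadu_sih"` = (1,5,6); `"cadu_sim"` = (1,5,6);
#' `"fhr_emr"` = (1,5)|(2,5)|(4,7).
#'
#' @param process Preset name, or any label when `clauses` is given.
#' @param clauses List of integer vectors of rule ids (each a conjunction).
#' @return An object of class `lw_criteria`.
#' @export
linkage_criteria <- function(process, clauses = NULL) {
  presets <- list(
    cadu_fhr = list(c(1L, 5L, 6L), c(2L, 5L, 6L), c(3L, 5L, 6L),
                    c(2L, 4L), c(3L, 4L)),
    cadu_sih = list(c(1L, 5L, 6L)),
    cadu_sim = list(c(1L, 5L, 6L)),
    fhr_emr  = list(c(1L, 5L), c(2L, 5L), c(4L, 7L))
  )
  if (is.null(clauses)) {
    if (!process %in% names(presets))
      .stopf("unknown criteria preset '%s' (available: %s)", process,
             paste(names(presets), collapse = ", "))
    clauses <- presets[[process]]
  }
  if (!length(clauses)) .stopf("clause list must be non-empty")
  clauses <- lapply(clauses, function(cl) sort(unique(as.integer(cl))))
  ok <- vapply(clauses, function(cl) length(cl) > 0 && all(cl %in% 1:7), logical(1))
  if (!all(ok)) .stopf("every rule id must be in 1..7")
  structure(list(process = process, clauses = clauses), class = "lw_criteria")
}

#' @export
print.lw_criteria <- function(x, ...) {
  cat("Deterministic criteria for process '", x$process, "':\n", sep = "")
  for (cl in x$clauses)
    cat("  (", paste(cl, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Evaluate one deterministic rule on a record pair
#'
#' @param left,right Single records: one-row `data.table`s (or named lists)
#'   carrying the preprocessed fields.
#' @param rule Integer rule id in 1..7 (see [linkage_criteria()]).
#' @param name_max_dist Distance bound of rules 5 and 6 (strict `<`).
#' @return Logical. A rule whose operand is missing on either side is
#'   `FALSE` (missing never agrees).
#' @export
eval_rule <- function(left, right, rule, name_max_dist = 3L) {
  rule <- as.integer(rule)
  if (length(rule) != 1L || is.na(rule) || rule < 1L || rule > 7L)
    .stopf("invalid rule id: must be a single integer in 1..7")
  l <- as.list(left); r <- as.list(right)
  g <- function(v, f) if (f %in% names(v)) v[[f]][1] else NA
  lev_lt <- function(a, b) {
    if (is.na(a) || is.na(b)) return(FALSE)
    levenshtein(a, b) < name_max_dist
  }
  switch(rule,
    isTRUE(g(l, "key_ok")) && isTRUE(g(r, "key_ok")) &&
      .eq_nonmissing(g(l, "linkage_key"), g(r, "linkage_key")),
    .eq_nonmissing(g(l, "cpf"), g(r, "cpf")),
    .eq_nonmissing(g(l, "nis"), g(r, "nis")),
    !is.na(g(l, "birth_date")) && !is.na(g(r, "birth_date")) &&
      g(l, "birth_date") == g(r, "birth_date"),
    lev_lt(g(l, "name"), g(r, "name")),
    lev_lt(g(l, "mother_name"), g(r, "mother_name")),
    .eq_nonmissing(g(l, "name"), g(r, "name"))
  )
}

# Vectorised rule evaluation over a pairs table with l_* / r_* columns.
# Returns a logical matrix n x 7.
.eval_rules_vec <- function(pairs, name_max_dist = 3L) {
  n <- nrow(pairs)
  m <- matrix(FALSE, n, 7, dimnames = list(NULL, paste0("rule", 1:7)))
  if (!n) return(m)
  m[, 1] <- pairs$l_key_ok & pairs$r_key_ok &
    .eq_nonmissing(pairs$l_linkage_key, pairs$r_linkage_key)
  m[, 2] <- .eq_nonmissing(pairs$l_cpf, pairs$r_cpf)
  m[, 3] <- .eq_nonmissing(pairs$l_nis, pairs$r_nis)
  m[, 4] <- !is.na(pairs$l_birth_date) & !is.na(pairs$r_birth_date) &
    pairs$l_birth_date == pairs$r_birth_date
  dn <- levenshtein(pairs$l_name, pairs$r_name)
  m[, 5] <- !is.na(dn) & dn < name_max_dist
  dm <- levenshtein(pairs$l_mother_name, pairs$r_mother_name)
  m[, 6] <- !is.na(dm) & dm < name_max_dist
  m[, 7] <- .eq_nonmissing(pairs$l_name, pairs$r_name)
  m
}

.clause_label <- function(cl) paste0("(", paste(cl, collapse = ","), ")")

# Given a rule matrix, return the index of the first satisfied clause
# (declaration order), or NA.
.fired_clause <- function(rulemat, criteria) {
  n <- nrow(rulemat)
  fired <- rep(NA_integer_, n)
  for (ci in seq_along(criteria$clauses)) {
    cl <- criteria$clauses[[ci]]
    sat <- rowSums(rulemat[, cl, drop = FALSE]) == length(cl)
    fired[is.na(fired) & sat] <- ci
  }
  fired
}

#' Classify one record pair under a deterministic criteria set
#'
#' @param left,right Single preprocessed records.
#' @param criteria An [linkage_criteria()] object.
#' @param name_max_dist Bound for rules 5/6.
#' @return A list with `class` (`"match"`/`"non-match"`) and
#'   `fired_clause` (label of the first satisfied clause, or `NA`).
#' @export
classify_deterministic <- function(left, right, criteria, name_max_dist = 3L) {
  stopifnot(inherits(criteria, "lw_criteria"))
  rules_needed <- sort(unique(unlist(criteria$clauses)))
  truth <- rep(FALSE, 7)
  for (rl in rules_needed)
    truth[rl] <- isTRUE(eval_rule(left, right, rl, name_max_dist))
  fired <- NA_character_
  cls <- "non-match"
  for (cl in criteria$clauses) {
    if (all(truth[cl])) {
      fired <- .clause_label(cl)
      cls <- "match"
      break
    }
  }
  list(class = cls, fired_clause = fired)
}

# Build candidate pairs for a criteria set via exact-equality hash joins.
# Each clause is joined on its most selective exact rule; the union of the
# per-clause joins is a superset of all pairs any clause can match.
.deterministic_candidates <- function(left, right, criteria) {
  anchors <- integer(0)
  for (cl in criteria$clauses) {
    a <- .EXACT_RULES[.EXACT_RULES %in% cl][1]
    if (is.na(a))
      .stopf("clause %s has no exact-equality rule (1,2,3,4,7); join-reachability violated",
             .clause_label(cl))
    anchors <- c(anchors, a)
  }
  anchors <- unique(anchors)
  li <- data.table::data.table(.li = seq_len(nrow(left)))
  cand <- vector("list", length(anchors))
  for (k in seq_along(anchors)) {
    col <- .EXACT_JOIN_COL[[as.character(anchors[k])]]
    L <- data.table::data.table(.li = seq_len(nrow(left)), v = left[[col]])
    R <- data.table::data.table(.ri = seq_len(nrow(right)), v = right[[col]])
    if (anchors[k] == 1L) {
      L <- L[left$key_ok]; R <- R[right$key_ok]
    }
    L <- L[!is.na(v)]; R <- R[!is.na(v)]
    if (!nrow(L) || !nrow(R)) next
    cand[[k]] <- merge(L, R, by = "v", allow.cartesian = TRUE)[, .(.li, .ri)]
  }
  cand <- data.table::rbindlist(cand[!vapply(cand, is.null, logical(1))])
  if (!nrow(cand)) return(data.table::data.table(.li = integer(0), .ri = integer(0)))
  unique(cand)
}

# Assemble a pairs table with l_* / r_* projections of the fields rules use.
.pair_fields <- c("record_uid", "individual_uid", "name", "mother_name",
                  "birth_date", "cpf", "nis", "address", "linkage_key",
                  "key_ok", "sx_first", "sx_second", "sx_last",
                  "name_first", "name_last", "sex", "birth_year")

.project_pairs <- function(left, right, idx) {
  have_l <- intersect(.pair_fields, names(left))
  have_r <- intersect(.pair_fields, names(right))
  L <- left[idx$.li, ..have_l]
  data.table::setnames(L, have_l, paste0("l_", have_l))
  R <- right[idx$.ri, ..have_r]
  data.table::setnames(R, have_r, paste0("r_", have_r))
  cbind(L, R)
}

#' Run the deterministic linkage stage
#'
#' Generates candidate pairs by exact-equality joins (one per clause, on
#' the clause's most selective exact rule), evaluates all rules on the
#' candidates, and classifies them under `criteria`. The result is
#' identical to classifying the full cross product, because every clause
#' contains at least one exact-equality rule that the join reaches.
#'
#' In `one_to_one` mode, conflicting matches are resolved
#' deterministically (earliest clause, then smallest right then left
#' record uid), matched records leave both residuals, and suppressed
#' alternatives are reported. In `one_to_many` mode the left residual is
#' the full left table (left records persist through the whole process)
#' while matched right records leave the right residual.
#'
#' @param left,right Preprocessed tables ([preprocess_table()]).
#' @param criteria An [linkage_criteria()] object.
#' @param mode `"one_to_one"` or `"one_to_many"`.
#' @param name_max_dist Bound for rules 5/6.
#' @return A list of class `lw_det_result`: `matches` (pair table with
#'   `left_uid`, `right_uid`, `approach`, `fired_clause`, per-rule truth
#'   columns), `left_residual`, `right_residual`, `suppressed`, `n_candidates`.
#' @export
run_deterministic <- function(left, right, criteria,
                              mode = c("one_to_one", "one_to_many"),
                              name_max_dist = 3L) {
  mode <- match.arg(mode)
  stopifnot(inherits(criteria, "lw_criteria"))
  all_pairs <- deterministic_pairs(left, right, criteria, name_max_dist)
  matches <- all_pairs$matches
  if (mode == "one_to_one" && nrow(matches)) {
    ord <- order(matches$clause_index, matches$right_uid, matches$left_uid)
    matches <- matches[ord]
    # greedy: a pair is kept only if both sides are still unclaimed
    keep <- logical(nrow(matches))
    env_l <- new.env(hash = TRUE); env_r <- new.env(hash = TRUE)
    for (i in seq_len(nrow(matches))) {
      lu <- matches$left_uid[i]; ru <- matches$right_uid[i]
      if (is.null(env_l[[lu]]) && is.null(env_r[[ru]])) {
        keep[i] <- TRUE
        env_l[[lu]] <- TRUE; env_r[[ru]] <- TRUE
      }
    }
    suppressed <- matches[!keep]
    matches <- matches[keep]
  } else {
    suppressed <- matches[0]
  }
  left_res <- if (mode == "one_to_many") data.table::copy(left) else
    left[!left$record_uid %in% matches$left_uid]
  right_res <- right[!right$record_uid %in% matches$right_uid]
  structure(list(matches = matches,
                 left_residual = left_res,
                 right_residual = right_res,
                 suppressed = suppressed,
                 n_candidates = all_pairs$n_candidates,
                 mode = mode),
            class = "lw_det_result")
}

#' All deterministically matched pairs (before one-to-one resolution)
#'
#' The raw classified match set: one row per (left, right) pair satisfying
#' at least one clause, with the first satisfied clause recorded for
#' provenance and the seven rule truth values as audit columns.
#'
#' @inheritParams run_deterministic
#' @return List with `matches` (`data.table`) and `n_candidates`.
#' @export
deterministic_pairs <- function(left, right, criteria, name_max_dist = 3L) {
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  idx <- .deterministic_candidates(left, right, criteria)
  pairs <- .project_pairs(left, right, idx)
  rulemat <- .eval_rules_vec(pairs, name_max_dist)
  fired <- .fired_clause(rulemat, criteria)
  is_match <- !is.na(fired)
  matches <- pairs[is_match]
  rm_match <- rulemat[is_match, , drop = FALSE]
  out <- data.table::data.table(
    left_uid = matches$l_record_uid,
    right_uid = matches$r_record_uid,
    approach = "deterministic",
    clause_index = fired[is_match],
    fired_clause = vapply(fired[is_match],
                          function(ci) .clause_label(criteria$clauses[[ci]]),
                          character(1))
  )
  out <- cbind(out, data.table::as.data.table(rm_match))
  data.table::setorder(out, left_uid, right_uid)
  list(matches = out, n_candidates = nrow(pairs))
}
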