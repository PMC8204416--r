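# Post-processing reclassification and clerical-review decision support.
#
# Reclassification only ever moves pairs toward more scrutiny: automatic
# matches can be demoted to potential (review), potentials can be
# discarded to non-match; no pair is promoted to match without an imported
# human decision (or the explicit auto-review mode of the pipeline).

#' Frequency table of tokens or phonetic codes
#'
#' @param x Character vector of observed tokens/codes (counted), or a
#'   `data.frame` with columns `key` and `count`.
#' @param label Reference-population label (for provenance).
#' @return An object of class `lw_freq`; look up counts with
#'   [freq_lookup()] (absent keys count 0).
#' @export
frequency_table <- function(x, label = "unspecified") {
  if (is.data.frame(x)) {
    tab <- data.table::as.data.table(list(key = as.character(x[["key"]]),
                                          count = as.numeric(x[["count"]])))
    tab <- tab[!is.na(key), .(count = sum(count)), by = "key"]
  } else {
    x <- x[!is.na(x)]
    t0 <- table(x)
    tab <- data.table::as.data.table(list(key = names(t0),
                                          count = as.numeric(t0)))
  }
  if (any(tab$count < 1)) .stopf("frequency counts must be >= 1")
  env <- new.env(hash = TRUE, size = max(nrow(tab), 29L))
  for (i in seq_len(nrow(tab))) env[[tab$key[i]]] <- tab$count[i]
  structure(list(table = tab, env = env, label = label), class = "lw_freq")
}

#' Look up a frequency count
#'
#' @param ft An [frequency_table()].
#' @param key Character vector of keys; absent keys return 0.
#' @return Numeric vector of counts.
#' @export
freq_lookup <- function(ft, key) {
  stopifnot(inherits(ft, "lw_freq"))
  vapply(as.character(key), function(k) {
    if (is.na(k)) return(0)
    v <- ft$env[[k]]
    if (is.null(v)) 0 else v
  }, numeric(1), USE.NAMES = FALSE)
}

#' Demote automatic matches to potential matches
#'
#' A pair classified as a match by the automatic (probabilistic) stage is
#' reclassified as a potential match and sent to clerical review if
#' (a) the individual's name length is at most 20 characters, or (b) the
#' Soundex codes of the second segment of the two names disagree. Name
#' length counts the characters of the cleaned full name including its
#' separating spaces and is measured on the left record; a missing
#' second-segment code counts as disagreement (the pair goes to review).
#'
#' @param matches Scored pairs table carrying `l_name`, `l_sx_second`,
#'   `r_sx_second`.
#' @param max_name_length Boundary of condition (a), inclusive
#'   (default 20).
#' @return List with `kept` and `demoted` (the latter with a `reason`
#'   column: `"short_name"`, `"sx_second_disagrees"` or both).
#' @export
demote_matches <- function(matches, max_name_length = 20L) {
  m <- data.table::as.data.table(matches)
  if (!nrow(m)) return(list(kept = m, demoted = cbind(m[0], reason = character(0))))
  len <- nchar(m$l_name)
  a <- !is.na(len) & len <= max_name_length
  b <- !(.eq_nonmissing(m$l_sx_second, m$r_sx_second))
  demote <- a | b
  reason <- ifelse(a & b, "short_name;sx_second_disagrees",
                   ifelse(a, "short_name", "sx_second_disagrees"))
  demoted <- m[demote][, reason := reason[demote]]
  list(kept = m[!demote], demoted = demoted)
}

#' Discard unlikely potential matches as non-matches
#'
#' A potential match is reclassified as a non-match (never sent to
#' review) only when all four hold: (a) the left record's first given
#' name is common (frequency of its Soundex code strictly greater than
#' `freq_threshold`), (b) the left name's length is at most 20, (c) the
#' mother's-name Levenshtein distance is at least 10, and (d) the address
#' Levenshtein distance is at least 12. A missing mother's name or
#' address on either side makes its condition false, keeping the pair for
#' review (conservative).
#'
#' @param potentials Pairs table with `l_sx_first`, `l_name`,
#'   `l_mother_name`, `r_mother_name`, `l_address`, `r_address`.
#' @param first_name_freq [frequency_table()] of first-given-name Soundex
#'   codes in the reference population (by default the pipeline builds it
#'   from the right-hand table).
#' @param freq_threshold,max_name_length,mother_min_dist,address_min_dist
#'   The four boundaries, taken literally as printed: `> 5`, `<= 20`,
#'   `>= 10`, `>= 12`.
#' @return List with `kept` and `discarded`.
#' @export
discard_potentials <- function(potentials, first_name_freq,
                               freq_threshold = 5, max_name_length = 20L,
                               mother_min_dist = 10L, address_min_dist = 12L) {
  p <- data.table::as.data.table(potentials)
  if (!nrow(p)) return(list(kept = p, discarded = p[0]))
  a <- freq_lookup(first_name_freq, p$l_sx_first) > freq_threshold
  len <- nchar(p$l_name)
  b <- !is.na(len) & len <= max_name_length
  dm <- levenshtein(p$l_mother_name, p$r_mother_name)
  cc <- !is.na(dm) & dm >= mother_min_dist
  da <- levenshtein(p$l_address, p$r_address)
  d <- !is.na(da) & da >= address_min_dist
  discard <- a & b & cc & d
  list(kept = p[!discard], discarded = p[discard])
}

#' Classify a name as common, rare or intermediate
#'
#' Under the convention that the first token is the given name and the
#' remaining tokens are surnames: a name is *common* when it has exactly
#' one surname and either the given name or the surname is frequent in
#' the reference population; *rare* when it has two surnames none of
#' which is frequent, or three or more surnames; everything else
#' (including single-token names) is *intermediate*.
#'
#' @param name Cleaned name(s) (character vector), or a [parse_name()]
#'   result.
#' @param given_freq,surname_freq [frequency_table()]s of given names and
#'   surnames.
#' @param frequent_min A name token is "frequent" when its count is at
#'   least this (default 500 against the bundled synthetic lists of
#'   100,000 sampled names; supply real national lists and a matching
#'   cutoff for production use).
#' @return Character vector in `c("common", "rare", "intermediate")`.
#' @export
classify_name_rarity <- function(name, given_freq, surname_freq,
                                 frequent_min = 500) {
  parts <- if (is.data.frame(name)) data.table::as.data.table(name)
           else parse_name(name, on_empty = "na")
  is_freq_given <- freq_lookup(given_freq, parts$first_given) >= frequent_min
  vapply(seq_len(nrow(parts)), function(i) {
    toks <- parts$tokens[[i]]
    nt <- length(toks)
    if (nt >= 4L) return("rare")              # three or more surnames
    if (nt == 3L) {
      sf <- freq_lookup(surname_freq, toks[2:3]) >= frequent_min
      return(if (!any(sf)) "rare" else "intermediate")
    }
    if (nt == 2L) {
      sf <- freq_lookup(surname_freq, toks[2]) >= frequent_min
      return(if (is_freq_given[i] || sf) "common" else "intermediate")
    }
    "intermediate"
  }, character(1))
}

#' Suggested clerical decision for a candidate pair
#'
#' Encodes the general review rules: (a) a rare name is a match even if
#' other attributes disagree; (b) a common name is a match only if the
#' mother's name, the date of birth and the address all agree, otherwise
#' a non-match; (c) an intermediate name is a match if the date of birth
#' agrees and either the mother's name or the address agrees, otherwise
#' the pair is undecided and routed to the supervisor. A missing
#' attribute never counts as agreeing.
#'
#' @param rarity `"common"`, `"rare"` or `"intermediate"` (vectorised).
#' @param mother_agrees,birth_agrees,address_agrees Logical vectors
#'   (`NA` = missing, treated as not agreeing).
#' @return Character vector in `c("match", "non-match", "undecided")`.
#' @export
suggest_review_decision <- function(rarity, mother_agrees, birth_agrees,
                                    address_agrees) {
  n <- length(rarity)
  ma <- isTRUE_vec(mother_agrees, n)
  ba <- isTRUE_vec(birth_agrees, n)
  aa <- isTRUE_vec(address_agrees, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- switch(rarity[i],
      rare = "match",
      common = if (ma[i] && ba[i] && aa[i]) "match" else "non-match",
      intermediate = if (ba[i] && (ma[i] || aa[i])) "match" else "undecided",
      .stopf("unknown rarity class '%s'", rarity[i]))
  }
  out
}

isTRUE_vec <- function(x, n) {
  x <- rep_len(as.logical(x), n)
  !is.na(x) & x
}

#' Score a reviewer's qualification test
#'
#' A trainee reviewer classifies a gold-standard set of pairs and is
#' approved when at least 90% are classified correctly.
#'
#' @param answers,gold Character vectors of classes, aligned by pair; or
#'   `data.frame`s with columns `pair_id` and `decision` (aligned by
#'   `pair_id`).
#' @param pass_mark Minimum accuracy for approval (default 0.90).
#' @return List with `accuracy` (proportion in \[0, 1\]), `n`, `n_correct`,
#'   `approved`.
#' @export
score_reviewer_qualification <- function(answers, gold, pass_mark = 0.90) {
  if (is.data.frame(answers) && is.data.frame(gold)) {
    a <- data.table::as.data.table(answers)
    g <- data.table::as.data.table(gold)
    if (!setequal(a$pair_id, g$pair_id) || anyDuplicated(a$pair_id))
      .stopf("answers and gold must cover the same pair ids exactly once")
    mm <- merge(a, g, by = "pair_id", suffixes = c("_ans", "_gold"))
    answers <- mm$decision_ans; gold <- mm$decision_gold
  }
  if (length(answers) != length(gold))
    .stopf("answers (%d) and gold (%d) differ in length",
           length(answers), length(gold))
  n <- length(gold)
  if (!n) .stopf("empty qualification set")
  k <- sum(answers == gold)
  acc <- k / n
  list(accuracy = acc, n = n, n_correct = k, approved = acc >= pass_mark)
}

#' Build the clerical-review queue
#'
#' Combines the surviving potential matches into review items: pair ids,
#' side-by-side attributes, attribute agreements (same comparators as the
#' probabilistic stage), name rarity and the suggested decision; the
#' decision column starts `"pending"`.
#'
#' @param potentials Pairs table (after [discard_potentials()]).
#' @param given_freq,surname_freq Frequency tables for
#'   [classify_name_rarity()].
#' @param name_agree_threshold Distance bound for name-type agreement.
#' @param frequent_min Passed to [classify_name_rarity()].
#' @return `data.table` of class `lw_review_queue`.
#' @export
build_review_queue <- function(potentials, given_freq, surname_freq,
                               name_agree_threshold = 3L,
                               frequent_min = 500) {
  p <- data.table::as.data.table(potentials)
  q <- data.table::data.table(
    pair_id = if (nrow(p)) sprintf("P%06d", seq_len(nrow(p))) else character(0),
    left_uid = p$l_record_uid %||% character(0),
    right_uid = p$r_record_uid %||% character(0),
    l_name = p$l_name %||% character(0), r_name = p$r_name %||% character(0),
    l_mother_name = p$l_mother_name %||% character(0),
    r_mother_name = p$r_mother_name %||% character(0),
    l_birth_date = p$l_birth_date %||% as.Date(character(0)),
    r_birth_date = p$r_birth_date %||% as.Date(character(0)),
    l_address = p$l_address %||% character(0),
    r_address = p$r_address %||% character(0)
  )
  agree_name <- function(a, b) {
    d <- levenshtein(a, b)
    !is.na(d) & d < name_agree_threshold
  }
  q[, `:=`(
    name_agrees = agree_name(l_name, r_name),
    mother_agrees = agree_name(l_mother_name, r_mother_name),
    birth_agrees = !is.na(l_birth_date) & !is.na(r_birth_date) &
      l_birth_date == r_birth_date,
    address_agrees = agree_name(l_address, r_address)
  )]
  q[, rarity := if (.N) classify_name_rarity(l_name, given_freq, surname_freq,
                                             frequent_min) else character(0)]
  q[, suggested := if (.N) suggest_review_decision(rarity, mother_agrees,
                                                   birth_agrees, address_agrees)
                   else character(0)]
  q[, decision := rep("pending", .N)]
  q[, reviewer := rep(NA_character_, .N)]
  data.table::setattr(q, "class", c("lw_review_queue", class(q)))
  q[]
}

#' Export the review queue to CSV
#'
#' @param items Review queue ([build_review_queue()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_review_queue <- function(items, path) {
  out <- data.table::copy(data.table::as.data.table(items))
  out[, decision := ifelse(decision == "pending", "", decision)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Import clerical decisions back into the queue
#'
#' Reads the exported CSV with the decision column filled. Decisions must
#' be `"match"` or `"non-match"` (empty rows stay pending); unknown pair
#' ids are rejected; malformed rows are reported with their line numbers.
#'
#' @param path CSV produced by [export_review_queue()] with decisions
#'   filled in.
#' @param queue The queue the decisions belong to.
#' @return The queue with `decision` (and `reviewer`) applied.
#' @export
import_review_decisions <- function(path, queue) {
  dec <- data.table::fread(path, colClasses = "character",
                           na.strings = NULL, encoding = "UTF-8")
  required <- c("pair_id", "decision")
  miss <- setdiff(required, names(dec))
  if (length(miss)) .stopf("decision file lacks column(s): %s",
                           paste(miss, collapse = ", "))
  unknown <- setdiff(dec$pair_id, queue$pair_id)
  if (length(unknown))
    .stopf("unknown pair id(s) in decision file: %s",
           paste(head(unknown, 5), collapse = ", "))
  d <- dec$decision
  d[is.na(d)] <- ""
  bad <- !(d %in% c("match", "non-match", ""))
  if (any(bad))
    .stopf("invalid decision value(s) at line(s) %s (allowed: match, non-match, empty)",
           paste(head(which(bad) + 1L, 10), collapse = ", "))
  out <- data.table::copy(data.table::as.data.table(queue))
  idx <- match(dec$pair_id, out$pair_id)
  filled <- d != ""
  out[idx[filled], decision := d[filled]]
  if ("reviewer" %in% names(dec))
    out[idx[filled], reviewer := dec$reviewer[filled]]
  data.table::setattr(out, "class", unique(c("lw_review_queue", class(out))))
  out[]
}
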