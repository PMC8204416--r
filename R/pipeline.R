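# Orchestration of one linkage process: preprocess -> deterministic ->
# probabilistic passes -> post-processing -> clerical review queue ->
# (decision import) -> finalisation and analysis-dataset preparation.

.PERSONAL_IDENTIFIERS <- c("name", "mother_name", "address", "cpf", "nis",
                           "name_first", "name_second", "name_last",
                           "linkage_key", "sx_first", "sx_second", "sx_last")

#' Configure a linkage process
#'
#' @param left,right Input tables: raw `data.frame`s, preprocessed
#'   tables, or CSV paths.
#' @param process Deterministic criteria: a preset name (see
#'   [linkage_criteria()]) or an `lw_criteria` object.
#' @param passes Probabilistic blocking passes: a list of
#'   [blocking_pass()] objects, `"preset"` for the bundled seven-pass
#'   strategy (thresholds resolved automatically unless supplied via
#'   `thresholds`), or `NULL`/empty list for a deterministic-only process.
#' @param thresholds Optional numeric vector of score cutoffs parallel to
#'   the passes.
#' @param mode `"one_to_one"` or `"one_to_many"`. One-to-many keeps every
#'   left record in play through all stages (e.g. linking a person
#'   registry to repeated hospitalisation events) and must be
#'   acknowledged explicitly with `acknowledge_one_to_many = TRUE`.
#' @param acknowledge_one_to_many See `mode`.
#' @param post_processing Apply the demotion/discard reclassification
#'   rules to probabilistic results (default `TRUE`).
#' @param auto_review If `TRUE`, review-queue items are decided by
#'   [suggest_review_decision()] (undecided treated as non-match) instead
#'   of awaiting a human decision file. Intended for simulation studies;
#'   defaults to `FALSE`.
#' @param name_agree_threshold Levenshtein bound for name agreement.
#' @param left_source,right_source Source labels / uid prefixes.
#' @param column_map_left,column_map_right Column maps for raw inputs.
#' @param given_freq,surname_freq,first_name_freq Optional frequency
#'   tables; by default the surname/given tables come from the bundled
#'   pools and the first-given-name Soundex table is computed from the
#'   right-hand table.
#' @param frequent_min Frequency cutoff for [classify_name_rarity()].
#' @param seed Seed for any stochastic step (none in the core pipeline;
#'   kept for reproducibility of downstream sampling).
#' @return An object of class `lw_config`.
#' @export
linkage_config <- function(left, right, process = "cadu_fhr",
                           passes = "preset", thresholds = NULL,
                           mode = c("one_to_one", "one_to_many"),
                           acknowledge_one_to_many = FALSE,
                           post_processing = TRUE, auto_review = FALSE,
                           name_agree_threshold = 3L,
                           left_source = "L", right_source = "R",
                           column_map_left = NULL, column_map_right = NULL,
                           given_freq = NULL, surname_freq = NULL,
                           first_name_freq = NULL, frequent_min = 500,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "one_to_many" && !isTRUE(acknowledge_one_to_many))
    .stopf(paste("one_to_many mode keeps every left record in play across all",
                 "passes; set acknowledge_one_to_many = TRUE to confirm"))
  criteria <- if (inherits(process, "lw_criteria")) process
              else linkage_criteria(process)
  if (identical(passes, "preset")) {
    passes <- blocking_passes_preset(thresholds %||% rep(NA_real_, 7))
  } else if (is.null(passes)) {
    passes <- list()
  } else if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == length(passes))
    for (i in seq_along(passes)) passes[[i]]$threshold <- thresholds[i]
  }
  structure(list(left = left, right = right, criteria = criteria,
                 passes = passes, mode = mode,
                 post_processing = post_processing,
                 auto_review = auto_review,
                 name_agree_threshold = name_agree_threshold,
                 left_source = left_source, right_source = right_source,
                 column_map_left = column_map_left,
                 column_map_right = column_map_right,
                 given_freq = given_freq, surname_freq = surname_freq,
                 first_name_freq = first_name_freq,
                 frequent_min = frequent_min, seed = as.integer(seed)),
            class = "lw_config")
}

.resolve_table <- function(x, source, column_map) {
  if (is.character(x) && length(x) == 1L) {
    read_person_table(x, source = source, column_map = column_map)
  } else if (!is.null(attr(x, "lw_preprocessed")) ||
             all(c("record_uid", "linkage_key", "sx_first") %in% names(x))) {
    data.table::as.data.table(x)
  } else {
    preprocess_table(x, source = source, column_map = column_map)
  }
}

#' Run a full linkage process
#'
#' Executes the sequential strategy: preprocessing, deterministic rules,
#' the probabilistic blocking passes, post-processing reclassification,
#' and construction of the clerical-review queue. Records matched at one
#' stage are not re-offered to later stages (except in one-to-many mode,
#' where left records persist). With `auto_review = TRUE` the queue is
#' decided by the suggestion rules and the result is finalised
#' immediately; otherwise export the queue, collect decisions, and call
#' [finalize_linkage()].
#'
#' @param config An [linkage_config()].
#' @return An object of class `lw_result`: `matches` (final match table
#'   with `left_uid`, `right_uid`, `approach`, provenance and score),
#'   `review_queue`, `left_residual`, `right_residual`, `report`
#'   (per-stage counts), `weights`, plus the preprocessed inputs
#'   (`left_table`, `right_table`).
#' @export
run_linkage <- function(config) {
  stopifnot(inherits(config, "lw_config"))
  left <- .resolve_table(config$left, config$left_source, config$column_map_left)
  right <- .resolve_table(config$right, config$right_source, config$column_map_right)

  det <- run_deterministic(left, right, config$criteria, config$mode,
                           config$name_agree_threshold)
  det_matches <- det$matches[, .(left_uid, right_uid, approach,
                                 provenance = fired_clause,
                                 score = NA_real_)]

  prob_matches <- data.table::data.table()
  potentials <- data.table::data.table()
  demoted <- data.table::data.table()
  discarded <- data.table::data.table()
  weights <- NULL
  prob_report <- NULL
  if (length(config$passes)) {
    prob <- run_probabilistic(det$left_residual, det$right_residual,
                              config$passes, weights = NULL,
                              mode = config$mode,
                              exclude_pairs = det$matches,
                              name_agree_threshold = config$name_agree_threshold,
                              auto_threshold = TRUE)
    weights <- prob$weights
    prob_report <- prob$report
    pm <- prob$matches
    potentials <- prob$potentials
    if (config$post_processing && nrow(pm)) {
      dm <- demote_matches(pm)
      pm <- dm$kept
      demoted <- dm$demoted
      if (nrow(demoted)) {
        demoted[, `:=`(class = "potential")]
        potentials <- rbind(potentials, demoted, fill = TRUE)
      }
    }
    if (config$post_processing && nrow(potentials)) {
      fnf <- config$first_name_freq %||%
        frequency_table(right$sx_first[!is.na(right$sx_first)],
                        label = "right table first-name soundex")
      dp <- discard_potentials(potentials, fnf)
      potentials <- dp$kept
      discarded <- dp$discarded
    }
    prob_matches <- if (nrow(pm))
      pm[, .(left_uid = l_record_uid, right_uid = r_record_uid, approach,
             provenance = paste0("pass", pass), score)]
    else data.table::data.table()
  }

  pools <- NULL
  gf <- config$given_freq
  sf <- config$surname_freq
  if (is.null(gf) || is.null(sf)) {
    pools <- lw_name_pools()
    if (is.null(gf)) gf <- frequency_table(pools$given[, .(key = name, count)],
                                           label = "synthetic given names")
    if (is.null(sf)) sf <- frequency_table(pools$surname[, .(key = name, count)],
                                           label = "synthetic surnames")
  }
  queue <- build_review_queue(potentials, gf, sf,
                              config$name_agree_threshold,
                              config$frequent_min)

  matches <- rbind(det_matches, prob_matches, fill = TRUE)
  res <- structure(list(
    matches = matches, review_queue = queue,
    left_residual = if (config$mode == "one_to_many") data.table::copy(left)
                    else left[!record_uid %in% matches$left_uid],
    right_residual = right[!record_uid %in% matches$right_uid],
    left_table = left, right_table = right,
    weights = weights,
    det = det,
    demoted = demoted, discarded = discarded,
    report = .run_report(left, right, det_matches, prob_matches, queue,
                         demoted, discarded, prob_report),
    config = config, finalized = FALSE), class = "lw_result")
  if (isTRUE(config$auto_review) && nrow(queue)) {
    dec <- data.table::copy(queue)
    dec[, decision := ifelse(suggested == "match", "match", "non-match")]
    res <- finalize_linkage(res, dec)
  } else if (!nrow(queue)) {
    res$finalized <- TRUE
  }
  res
}

.run_report <- function(left, right, det_matches, prob_matches, queue,
                        demoted, discarded, prob_report) {
  counts <- data.table::data.table(
    stage = c("left_records", "right_records", "deterministic_matches",
              "probabilistic_matches", "demoted_to_review",
              "discarded_potentials", "review_queue", "clerical_matches"),
    count = c(nrow(left), nrow(right), nrow(det_matches),
              nrow(prob_matches), nrow(demoted), nrow(discarded),
              nrow(queue), 0L))
  list(counts = counts, probabilistic = prob_report)
}

#' Finalise a linkage after clerical review
#'
#' Applies imported review decisions: queue items decided `"match"` join
#' the final match table with approach `"clerical"`; `"non-match"` items
#' are closed. Items still pending leave the result unfinalised.
#'
#' @param result An [run_linkage()] result.
#' @param decisions A decided review queue (from
#'   [import_review_decisions()], or the queue with `decision` filled).
#' @return The updated `lw_result` (with `$matches` extended and
#'   `$finalized` set when nothing is pending).
#' @export
finalize_linkage <- function(result, decisions) {
  stopifnot(inherits(result, "lw_result"))
  d <- data.table::as.data.table(decisions)
  unknown <- setdiff(d$pair_id, result$review_queue$pair_id)
  if (length(unknown))
    .stopf("decision(s) for unknown pair id(s): %s",
           paste(head(unknown, 5), collapse = ", "))
  q <- data.table::copy(result$review_queue)
  idx <- match(d$pair_id, q$pair_id)
  q[idx, decision := d$decision]
  clerical <- q[decision == "match",
                .(left_uid, right_uid, approach = "clerical",
                  provenance = pair_id, score = NA_real_)]
  already <- paste(result$matches$left_uid, result$matches$right_uid)
  clerical <- clerical[!paste(left_uid, right_uid) %in% already]
  result$matches <- rbind(result$matches, clerical, fill = TRUE)
  result$review_queue <- q
  if (nrow(clerical)) {
    if (result$config$mode == "one_to_one")
      result$left_residual <-
        result$left_residual[!record_uid %in% clerical$left_uid]
    result$right_residual <-
      result$right_residual[!record_uid %in% clerical$right_uid]
  }
  result$finalized <- !any(q$decision == "pending")
  counts <- result$report$counts
  result$report$counts <- rbind(
    counts[stage != "clerical_matches"],
    data.table::data.table(stage = "clerical_matches", count = nrow(clerical)))
  result
}

#' Prepare the analysis dataset from a finalised linkage
#'
#' Merges the matches of all approaches, flags multiplicity conflicts for
#' manual review (one-to-one: any individual with more than one matched
#' right record; one-to-many: individuals with five or more matched right
#' records), and strips every personal identifier, keeping only the
#' created record/individual uids and provenance.
#'
#' @param result A finalised [run_linkage()] result.
#' @param multiplicity_flag One-to-many flag threshold (default 5,
#'   inclusive).
#' @return List with `analysis` (identifier-free match table) and
#'   `conflicts` (flagged pairs).
#' @export
prepare_analysis_dataset <- function(result, multiplicity_flag = 5L) {
  stopifnot(inherits(result, "lw_result"))
  if (!isTRUE(result$finalized))
    .stopf("linkage result has pending review items; finalise it first")
  m <- data.table::copy(result$matches)
  lmap <- result$left_table[, .(left_uid = record_uid,
                                left_individual_uid = individual_uid)]
  rmap <- result$right_table[, .(right_uid = record_uid,
                                 right_individual_uid = individual_uid)]
  m <- merge(m, lmap, by = "left_uid", all.x = TRUE, sort = FALSE)
  m <- merge(m, rmap, by = "right_uid", all.x = TRUE, sort = FALSE)
  per_ind <- m[, .(n_right = data.table::uniqueN(right_uid)),
               by = left_individual_uid]
  flagged_ids <- if (result$config$mode == "one_to_one")
    per_ind[n_right > 1L, left_individual_uid]
  else per_ind[n_right >= multiplicity_flag, left_individual_uid]
  conflicts <- m[left_individual_uid %in% flagged_ids]
  keep <- c("left_uid", "left_individual_uid", "right_uid",
            "right_individual_uid", "approach", "provenance", "score")
  analysis <- m[, intersect(keep, names(m)), with = FALSE]
  leak <- intersect(.PERSONAL_IDENTIFIERS, names(analysis))
  if (length(leak)) .stopf("identifier column(s) leaked: %s",
                           paste(leak, collapse = ", "))
  list(analysis = analysis, conflicts = conflicts)
}

#' Run a linkage against a partitioned right table
#'
#' Links each chunk of the right table separately under the same
#' configuration and unions the results, mirroring the handling of very
#' large right-hand databases stored in several files. For
#' deterministic-only processes the union equals the unsplit run, since
#' candidate generation is key-based and chunk-local.
#'
#' @param config An [linkage_config()] (its `right` entry is ignored).
#' @param right_chunks List of raw right tables (chunks must not share
#'   `record_uid`s).
#' @return List of per-chunk `lw_result`s plus a combined `matches`
#'   table.
#' @export
run_chunked <- function(config, right_chunks) {
  stopifnot(inherits(config, "lw_config"))
  pre <- lapply(seq_along(right_chunks), function(i)
    .resolve_table(right_chunks[[i]],
                   paste0(config$right_source, i), config$column_map_right))
  uids <- unlist(lapply(pre, function(x) x$record_uid))
  if (anyDuplicated(uids)) .stopf("right chunks share record_uid(s); chunks must partition the table")
  results <- lapply(pre, function(chunk) {
    cfg <- config
    cfg$right <- chunk
    run_linkage(cfg)
  })
  list(results = results,
       matches = data.table::rbindlist(lapply(results, `[[`, "matches"),
                                       fill = TRUE))
}

#' @export
print.lw_result <- function(x, ...) {
  cat("Linkage result (", if (x$finalized) "finalised" else "pending review",
      "):\n", sep = "")
  print(x$report$counts)
  invisible(x)
}
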