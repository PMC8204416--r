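make_match_row <- function(name_len, sx2_agree) {
  data.table::data.table(
    l_record_uid = "L-1", r_record_uid = "R-1",
    l_name = paste0(strrep("A", name_len - 2), " B"),
    l_sx_second = "S410",
    r_sx_second = if (sx2_agree) "S410" else "T000")
}

test_that("match demotion applies the two reclassification rules", {
  # boundary grid: length {20, 21} x second-segment soundex {agree, disagree}
  for (len in c(16L, 20L, 21L, 25L)) {
    for (agree in c(TRUE, FALSE)) {
      row <- make_match_row(len, agree)
      expect_identical(nchar(row$l_name), len)
      out <- demote_matches(row)
      should_demote <- (len <= 20L) || !agree
      expect_identical(nrow(out$demoted), as.integer(should_demote),
                       info = sprintf("len=%d agree=%s", len, agree))
      expect_identical(nrow(out$kept), as.integer(!should_demote))
    }
  }
  # left name "JOSE CARLOS LIMA" has 16 characters: demoted via (a)
  r <- data.table::data.table(l_record_uid = "L-1", r_record_uid = "R-1",
                              l_name = "JOSE CARLOS LIMA",
                              l_sx_second = "C642", r_sx_second = "C642")
  expect_identical(demote_matches(r)$demoted$reason, "short_name")
  # missing second-segment code cannot agree: goes to review
  r2 <- make_match_row(25L, TRUE)[, r_sx_second := NA_character_]
  expect_identical(nrow(demote_matches(r2)$demoted), 1L)
})

make_potential_row <- function(freq_common, len, mdist, adist) {
  data.table::data.table(
    l_record_uid = "L-1", r_record_uid = "R-1",
    l_sx_first = if (freq_common) "M600" else "Z999",
    l_name = paste0(strrep("A", len - 2), " B"),
    l_mother_name = "M", r_mother_name = paste0("M", strrep("X", mdist)),
    l_address = "A", r_address = paste0("A", strrep("Y", adist)))
}

test_that("potential discarding needs all four conditions at their printed boundaries", {
  ft <- frequency_table(data.frame(key = c("M600", "J200"), count = c(6, 5)))
  grid <- expand.grid(f = c(5, 6), len = c(20L, 21L), md = c(9L, 10L),
                      ad = c(11L, 12L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    row <- make_potential_row(TRUE, g$len, g$md, g$ad)
    row$l_sx_first <- if (g$f == 6) "M600" else "J200"   # freq 6 vs 5
    out <- discard_potentials(row, ft)
    should <- (g$f > 5) && (g$len <= 20) && (g$md >= 10) && (g$ad >= 12)
    expect_identical(nrow(out$discarded), as.integer(should),
                     info = paste(g, collapse = "/"))
  }
  # unknown soundex code counts 0: kept
  row <- make_potential_row(FALSE, 20L, 10L, 12L)
  expect_identical(nrow(discard_potentials(row, ft)$discarded), 0L)
  # missing mother's name: conservative, kept for review
  row2 <- make_potential_row(TRUE, 20L, 10L, 12L)[, r_mother_name := NA_character_]
  expect_identical(nrow(discard_potentials(row2, ft)$discarded), 0L)
})

test_that("name rarity follows the surname-count and frequency rules", {
  gf <- frequency_table(data.frame(key = c("MARIA", "ZULMIRA"),
                                   count = c(5000, 10)))
  sf <- frequency_table(data.frame(key = c("SILVA", "XIMENES", "KRAUSS"),
                                   count = c(8000, 20, 10)))
  rar <- function(nm) classify_name_rarity(nm, gf, sf)
  expect_identical(rar("MARIA SILVA"), "common")       # frequent either part
  expect_identical(rar("ZULMIRA SILVA"), "common")     # surname frequent
  expect_identical(rar("ZULMIRA KRAUSS"), "intermediate")
  expect_identical(rar("MARIA XIMENES KRAUSS"), "rare")    # 2 rare surnames
  expect_identical(rar("MARIA SILVA KRAUSS"), "intermediate")
  expect_identical(rar("MARIA SILVA SANTOS COSTA"), "rare") # >= 3 surnames
  expect_identical(rar("MADONNA"), "intermediate")
})

test_that("suggested decisions reproduce the review rule truth table", {
  oracle <- function(rarity, m, b, a) {
    # transcribed independently from the three review rules
    if (rarity == "rare") return("match")
    if (rarity == "common") {
      return(if (m && b && a) "match" else "non-match")
    }
    if (b && (m || a)) "match" else "undecided"
  }
  for (rarity in c("common", "rare", "intermediate")) {
    for (nm in c(TRUE, FALSE)) for (m in c(TRUE, FALSE)) {
      for (b in c(TRUE, FALSE)) for (a in c(TRUE, FALSE)) {
        got <- suggest_review_decision(rarity, m, b, a)
        expect_identical(got, oracle(rarity, m, b, a),
                         info = paste(rarity, nm, m, b, a))
      }
    }
  }
  # missing attribute never counts as agreement
  expect_identical(suggest_review_decision("intermediate", NA, TRUE, TRUE),
                   "match")
  expect_identical(suggest_review_decision("common", NA, TRUE, TRUE),
                   "non-match")
})

test_that("reviewer qualification uses the 90% pass mark", {
  gold <- rep(c("match", "non-match"), 100)
  mk <- function(n_wrong) {
    a <- gold
    a[seq_len(n_wrong)] <- ifelse(gold[seq_len(n_wrong)] == "match",
                                  "non-match", "match")
    a
  }
  expect_true(score_reviewer_qualification(mk(20), gold)$approved)   # 180/200
  expect_false(score_reviewer_qualification(mk(21), gold)$approved)  # 179/200
  perfect <- score_reviewer_qualification(gold, gold)
  expect_true(perfect$approved)
  expect_identical(perfect$accuracy, 1)
  expect_error(score_reviewer_qualification(gold[-1], gold), "length")
})

test_that("review queue round-trips through CSV with decisions applied", {
  sim <- get_sim(62, n = 400)
  res <- suppressWarnings(run_linkage(
    linkage_config(sim$left, sim$right, auto_review = FALSE)))
  q <- res$review_queue
  expect_gt(nrow(q), 0)
  f <- tempfile(fileext = ".csv")
  export_review_queue(q, f)
  # fill every decision as the suggestion (undecided -> non-match)
  filled <- data.table::fread(f, colClasses = "character", na.strings = NULL)
  filled[, decision := ifelse(suggested == "match", "match", "non-match")]
  data.table::fwrite(filled, f)
  q2 <- import_review_decisions(f, q)
  expect_identical(q2$pair_id, q$pair_id)
  expect_true(all(q2$decision %in% c("match", "non-match")))

  # invalid decision values are rejected with their line numbers
  bad <- data.table::copy(filled)[1, decision := "maybe"]
  data.table::fwrite(bad, f)
  expect_error(import_review_decisions(f, q), "line")
  # unknown pair ids are rejected
  ghost <- data.table::copy(filled)[1, pair_id := "P999999"]
  data.table::fwrite(ghost, f)
  expect_error(import_review_decisions(f, q), "unknown pair id")
})

test_that("an empty queue exports as a header-only CSV", {
  pools <- lw_name_pools()
  gf <- frequency_table(pools$given[, .(key = name, count)])
  sf <- frequency_table(pools$surname[, .(key = name, count)])
  q <- build_review_queue(data.table::data.table(), gf, sf)
  expect_identical(nrow(q), 0L)
  f <- tempfile(fileext = ".csv")
  export_review_queue(q, f)
  lines <- readLines(f)
  expect_identical(length(lines), 1L)
  expect_match(lines, "pair_id")
})

test_that("reclassification moves pairs only toward scrutiny", {
  # structural: demotion outputs potentials, never non-matches; discarding
  # outputs non-matches, never matches; neither invents pairs
  row <- make_match_row(18L, FALSE)
  d <- demote_matches(row)
  expect_identical(nrow(d$kept) + nrow(d$demoted), nrow(row))
  ft <- frequency_table(data.frame(key = "M600", count = 10))
  p <- make_potential_row(TRUE, 18L, 11L, 13L)
  dd <- discard_potentials(p, ft)
  expect_identical(nrow(dd$kept) + nrow(dd$discarded), nrow(p))
})
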