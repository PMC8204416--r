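test_that("clean_text applies the standardisation rules in order", {
  expect_identical(clean_text("  maria-josé   da silva "), "MARIA JOSE SILVA")
  expect_identical(clean_text("JOÃO"), "JOAO")
  expect_identical(clean_text(""), "")
  expect_identical(clean_text(NA_character_), NA_character_)
  # invalid placeholder terms vanish in both kinds; stop words only in names
  expect_identical(clean_text("NAO INFORMADO"), "")
  expect_identical(clean_text("RUA DA PAZ, 10", kind = "address"),
                   "RUA DA PAZ 10")
  expect_identical(clean_text("ANA DA SILVA IGNORADO"), "ANA SILVA")
})

test_that("clean_text is idempotent and produces uppercase ASCII", {
  set.seed(101)
  pieces <- c("josé", "  ", "-", "ção", "DA", "silva", "N.", "ignorado",
              "Érica", "d'ávila", "123", "\tx")
  for (i in 1:50) {
    raw <- paste(sample(pieces, sample(2:6, 1), replace = TRUE), collapse = " ")
    once <- clean_text(raw)
    expect_identical(clean_text(once), once)
    expect_match(once, "^[A-Z0-9 ]*$")
    expect_false(grepl("^ | $|  ", once))
  }
})

test_that("parse_name extracts the three key segments", {
  p <- parse_name("MARIA JOSE SANTOS SILVA")
  expect_identical(p$first_given, "MARIA")
  expect_identical(p$second_segment, "JOSE")
  expect_identical(p$last_family, "SILVA")
  expect_false(p$degenerate)

  two <- parse_name("ANA SILVA")
  expect_identical(two$second_segment, "SILVA")
  expect_identical(two$last_family, "SILVA")

  one <- parse_name("MADONNA")
  expect_true(one$degenerate)
  expect_identical(one$first_given, "MADONNA")

  expect_error(parse_name(""), "unparseable")
  flagged <- parse_name(c("ANA SILVA", ""), on_empty = "na")
  expect_true(flagged$unparseable[2])
})

test_that("soundex implements the classic coding rules", {
  expect_identical(soundex(c("SILVA", "ROBERT", "RUPERT", "MARIA", "JOSE")),
                   c("S410", "R163", "R163", "M600", "J200"))
  expect_identical(soundex("A"), "A000")
  # H/W transparency and duplicate collapse across them
  expect_identical(soundex("ASHCRAFT"), "A261")
  expect_identical(soundex("TYMCZAK"), "T522")
  expect_identical(soundex("PFISTER"), "P236")
  expect_error(soundex(""), "uppercase")
  expect_error(soundex("JOSÉ"), "uppercase")
  set.seed(7)
  for (i in 1:100) {
    tok <- paste(sample(LETTERS, sample(1:12, 1), replace = TRUE), collapse = "")
    expect_match(soundex(tok), "^[A-Z][0-9]{3}$")
  }
})

test_that("the linkage key concatenates soundex codes, sex and ISO date", {
  k <- build_linkage_key("MARIA JOSE SILVA", "F", as.Date("1980-05-01"))
  expect_identical(k$linkage_key, "M600|J200|S410|F|1980-05-01")
  expect_true(k$key_ok)

  # invariant to punctuation, case, diacritics and extra whitespace
  messy <- clean_text("  Maria   josé-SILVA ")
  k2 <- build_linkage_key(messy, "F", as.Date("1980-05-01"))
  expect_identical(k2$linkage_key, k$linkage_key)

  expect_false(build_linkage_key("MARIA JOSE SILVA", "F", as.Date(NA))$key_ok)
  expect_false(build_linkage_key("MADONNA", "F", as.Date("1980-05-01"))$key_ok)
})

test_that("levenshtein distance matches independent oracles", {
  expect_identical(levenshtein("MARIA", "MARIANA"), 2L)
  expect_identical(levenshtein("", "ABC"), 3L)
  expect_identical(levenshtein("X", "X"), 0L)
  expect_true(is.na(levenshtein(NA, "A")))

  set.seed(11)
  rs <- function() paste(sample(c("A", "B", "C", "D"), sample(0:8, 1),
                                replace = TRUE), collapse = "")
  for (i in 1:200) {
    a <- rs(); b <- rs(); c <- rs()
    d_ab <- levenshtein(a, b)
    expect_identical(d_ab, as.integer(utils::adist(a, b)))   # DP oracle
    expect_identical(d_ab, levenshtein(b, a))                # symmetry
    expect_identical(levenshtein(a, a), 0L)                  # identity
    expect_lte(d_ab, levenshtein(a, c) + levenshtein(c, b))  # triangle
  }
})

test_that("invalid calendar dates are nulled, never coerced", {
  dt <- preprocess_table(
    data.frame(name = c("ANA SILVA", "RUI COSTA"),
               birth_date = c("1985-02-30", "1985-02-28"), sex = "F"))
  expect_true(is.na(dt$birth_date[1]))
  expect_identical(dt$birth_date[2], as.Date("1985-02-28"))
  expect_identical(attr(dt, "n_invalid_dates"), 1L)
})

test_that("assign_uids groups records of the same individual", {
  tb <- toy_table(list(
    toy_rec("MARIA JOSE SILVA", cpf = "123", birth = "1980-05-01"),
    toy_rec("MARIA JOSE SILVE", cpf = "123", birth = "1980-05-01"),
    toy_rec("OUTRA PESSOA COSTA", cpf = "999", birth = "1990-01-01")))
  expect_identical(tb$individual_uid[1], tb$individual_uid[2])
  expect_false(tb$individual_uid[3] == tb$individual_uid[1])
  rep_multi <- attr(tb, "multi_record_individuals")
  expect_identical(rep_multi$n_recs, 2L)

  # same cpf but different birth date: not the same individual
  tb2 <- toy_table(list(
    toy_rec("MARIA JOSE SILVA", cpf = "123", birth = "1980-05-01"),
    toy_rec("MARIA JOSE SILVA", cpf = "123", birth = "1981-05-01")))
  expect_false(tb2$individual_uid[1] == tb2$individual_uid[2])

  # all-distinct records: individual uids bijective with record uids
  tb3 <- toy_table(list(toy_rec("ANA DIAS LIMA"), toy_rec("RUI REIS MOTA")))
  expect_identical(tb3$individual_uid, tb3$record_uid)

  empty <- assign_uids(data.table::data.table(name = character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("preprocessing reports exceptions with reason codes", {
  tb <- toy_table(list(
    toy_rec("MADONNA"),
    toy_rec("ANA SILVA", sex = NA),
    toy_rec("RITA COSTA DIAS")))
  exc <- exceptions_report(tb)
  expect_setequal(exc$reason, c("DEGENERATE_NAME", "KEY_MISSING_SEX_OR_DOB"))
  expect_identical(nrow(exc), 2L)
  # exceptional records stay in the table but never satisfy key rules
  expect_identical(nrow(tb), 3L)
  expect_identical(sum(tb$key_ok), 1L)
})
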