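test_that("single rules honour the missing-never-agrees contract", {
  a <- toy_table(list(toy_rec("MARIA SILVA", mother = "RITA DIAS")))[1]
  b <- toy_table(list(toy_rec("MARIA SILVA COSTA", mother = "RITA DIAS")))[1]
  # distance("MARIA SILVA", "MARIA SILVA COSTA") = 6 >= 3
  expect_false(eval_rule(a, b, 5))
  expect_true(eval_rule(a, b, 6))
  # strict boundary: distance exactly 3 is not an agreement
  x <- toy_table(list(toy_rec("ABCDEF GH")))[1]
  y <- toy_table(list(toy_rec("ABCDEF GHXYZ")))[1]
  expect_identical(levenshtein(x$name, y$name), 3L)
  expect_false(eval_rule(x, y, 5))
  # missing cpf on one side never agrees
  p <- toy_table(list(toy_rec("ANA LIMA", cpf = "11122233344")))[1]
  q <- toy_table(list(toy_rec("ANA LIMA")))[1]
  expect_false(eval_rule(p, q, 2))
  expect_true(eval_rule(p, q, 7))
  expect_error(eval_rule(p, q, 8), "invalid rule")
  expect_error(eval_rule(p, q, 0), "invalid rule")
})

test_that("process criteria classify pairs through their clauses", {
  # same cpf and birth date but names far apart: the benefits-registry /
  # family-health criteria match through clause (2, 4)
  l <- toy_table(list(toy_rec("MARIA JOSE SILVA", cpf = "111",
                              birth = "1980-05-01")))[1]
  r <- toy_table(list(toy_rec("MARTA PEREIRA DUARTE SOUZA", cpf = "111",
                              birth = "1980-05-01")))[1]
  out <- classify_deterministic(l, r, linkage_criteria("cadu_fhr"))
  expect_identical(out$class, "match")
  expect_identical(out$fired_clause, "(2,4)")

  # the mortality-registry criteria have only clause (1, 5, 6): cpf and
  # birth date agreement is not enough when the key disagrees
  out2 <- classify_deterministic(l, r, linkage_criteria("cadu_sim"))
  expect_identical(out2$class, "non-match")

  # health-registry / medical-record criteria: equal birth date and
  # identical name fire clause (4, 7)
  m1 <- toy_table(list(toy_rec("ANA COSTA", birth = "1970-01-02")))[1]
  m2 <- toy_table(list(toy_rec("ANA COSTA", birth = "1970-01-02", sex = "M")))[1]
  out3 <- classify_deterministic(m1, m2, linkage_criteria("fhr_emr"))
  expect_identical(out3$class, "match")
  expect_identical(out3$fired_clause, "(4,7)")
})

test_that("criteria presets and clause validation behave", {
  expect_error(linkage_criteria("nope"), "unknown criteria preset")
  expect_error(linkage_criteria("x", clauses = list(c(5, 8))), "1..7")
  expect_error(linkage_criteria("x", clauses = list()), "non-empty")
  cr <- linkage_criteria("x", clauses = list(c(5, 6)))
  sim <- get_sim(21, n = 100)
  l <- preprocess_table(sim$left, source = "L")
  r <- preprocess_table(sim$right, source = "R")
  expect_error(run_deterministic(l, r, cr), "join-reachability")
})

test_that("indexed-join classification equals the cross-product oracle", {
  for (seed in c(301, 302, 303)) {
    sim <- get_sim(seed, n = 150)
    l <- preprocess_table(sim$left, source = "L")
    r <- preprocess_table(sim$right, source = "R")
    for (preset in c("cadu_fhr", "cadu_sim", "fhr_emr")) {
      cr <- linkage_criteria(preset)
      got <- deterministic_pairs(l, r, cr)$matches
      want <- brute_force_deterministic(l, r, cr)
      expect_identical(pair_keys(got), pair_keys(want))
    }
  }
})

test_that("one-to-one mode yields disjoint matches and clean residuals", {
  sim <- get_sim(77, n = 300)
  l <- preprocess_table(sim$left, source = "L")
  r <- preprocess_table(sim$right, source = "R")
  res <- run_deterministic(l, r, linkage_criteria("cadu_fhr"), "one_to_one")
  expect_false(anyDuplicated(res$matches$left_uid) > 0)
  expect_false(anyDuplicated(res$matches$right_uid) > 0)
  expect_identical(nrow(res$matches) + nrow(res$left_residual), nrow(l))
  expect_identical(nrow(res$matches) + nrow(res$right_residual), nrow(r))
  expect_false(any(res$matches$left_uid %in% res$left_residual$record_uid))
})

test_that("one-to-many mode keeps the left table in play", {
  left <- toy_table(list(
    toy_rec("MARIA JOSE SILVA", mother = "RITA LIMA", birth = "1980-05-01")),
    source = "L")
  right <- toy_table(list(
    toy_rec("MARIA JOSE SILVA", mother = "RITA LIMA", birth = "1980-05-01"),
    toy_rec("MARIA JOSE SILVA", mother = "RITA LIMA", birth = "1980-05-01"),
    toy_rec("MARIA JOSE SILVA", mother = "RITA LIMA", birth = "1980-05-01")),
    source = "R")
  res <- run_deterministic(left, right, linkage_criteria("cadu_sih"),
                           "one_to_many")
  expect_identical(nrow(res$matches), 3L)
  expect_identical(res$left_residual$record_uid, left$record_uid)
  expect_identical(nrow(res$right_residual), 0L)
})

test_that("adding a record that satisfies no rule changes nothing else", {
  sim <- get_sim(88, n = 120)
  l <- preprocess_table(sim$left, source = "L")
  r <- preprocess_table(sim$right, source = "R")
  cr <- linkage_criteria("cadu_fhr")
  base <- deterministic_pairs(l, r, cr)$matches
  intruder <- data.table::as.data.table(
    toy_rec("ZZYZX QWRTP VKLMB", sex = "M", birth = "1900-01-01",
            mother = "QQQQQ WWWWW", cpf = "00000000000"))
  intruder[, birth_date := as.Date(birth_date)]
  l2 <- preprocess_table(rbind(sim$left[, !"record_uid"], intruder,
                               fill = TRUE), source = "L")
  with_intruder <- deterministic_pairs(l2, r, cr)$matches
  expect_identical(pair_keys(base), pair_keys(with_intruder))
})
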