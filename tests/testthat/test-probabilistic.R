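test_that("blocking generates all and only pairs agreeing on the index key", {
  sim <- get_sim(41, n = 150)
  l <- preprocess_table(sim$left, source = "L")
  r <- preprocess_table(sim$right, source = "R")
  for (sp in blocking_passes_preset()[c(1, 2, 4)]) {
    cand <- build_candidates(l, r, sp)
    cols <- c(sx_first = "sx_first", sx_last = "sx_last", sex = "sex",
              birth_year = "birth_year")[sp$index_fields]
    # oracle: cross-product with exact key agreement, complete keys only
    lk <- do.call(paste, lapply(cols, function(cc) as.character(l[[cc]])))
    rk <- do.call(paste, lapply(cols, function(cc) as.character(r[[cc]])))
    lok <- stats::complete.cases(l[, cols, with = FALSE])
    rok <- stats::complete.cases(r[, cols, with = FALSE])
    hits <- which(outer(ifelse(lok, lk, NA), ifelse(rok, rk, NA), `==`),
                  arr.ind = TRUE)
    want <- sort(paste(l$record_uid[hits[, 1]], r$record_uid[hits[, 2]]))
    got <- sort(paste(cand$l_record_uid, cand$r_record_uid))
    expect_identical(got, want)
    expect_false(anyDuplicated(got) > 0)
  }
})

test_that("records missing an index field are excluded from that pass", {
  l <- toy_table(list(toy_rec("ANA MARIA SILVA", birth = NA)), source = "L")
  r <- toy_table(list(toy_rec("ANA MARIA SILVA", birth = "1980-05-01")),
                 source = "R")
  sp_year <- blocking_passes_preset()[[1]]       # key includes birth year
  expect_identical(nrow(build_candidates(l, r, sp_year)), 0L)
  sp_noyear <- blocking_passes_preset()[[4]]     # sx_first + sx_last + sex
  expect_identical(nrow(build_candidates(l, r, sp_noyear)), 1L)
})

test_that("field comparison discretises distances and dates correctly", {
  l <- toy_table(list(toy_rec("MARIA JOSE SILVA", mother = NA,
                              birth = "1980-05-01")), source = "L")
  r <- toy_table(list(toy_rec("MARIA JOSE SILVE", mother = "RITA LIMA",
                              birth = "1980-05-10")), source = "R")
  sp <- blocking_passes_preset()[[1]]
  cand <- compare_pairs(build_candidates(l, r, sp), sp)
  expect_identical(cand$cmp_full_name, 1L)     # distance 1 < 3
  expect_identical(cand$dist_full_name, 1L)
  expect_identical(cand$cmp_birth_date, 0L)    # 01 vs 10: character mismatch
  expect_true(is.na(cand$cmp_mother_name))     # missing on the left
})

test_that("EM matches the single-field closed-form posterior at its fixed point", {
  # a one-field mixture is identifiable only up to a ridge, so the check
  # is that the generative values are (numerically) an EM fixed point and
  # yield the closed-form Bayes posterior .5*.9/(.5*.9 + .5*.1) = 0.9
  set.seed(5150)
  n <- 20000
  truth <- rbinom(n, 1, 0.5)
  x <- matrix(rbinom(n, 1, ifelse(truth == 1, 0.9, 0.1)), ncol = 1,
              dimnames = list(NULL, "f"))
  w <- estimate_weights_em(x, init = list(m = 0.9, u = 0.1, p = 0.5))
  p <- w$prevalence; m <- w$fields$m; u <- w$fields$u
  posterior_agree <- p * m / (p * m + (1 - p) * u)
  expect_lt(abs(posterior_agree - 0.9), 0.02)
  expect_lt(abs(m - 0.9), 0.05)
  expect_lt(abs(u - 0.1), 0.05)
  expect_true(all(diff(w$loglik) >= -1e-8))
})

test_that("EM rejects degenerate input and repairs swapped labels", {
  same <- matrix(1L, nrow = 50, ncol = 2)
  expect_error(estimate_weights_em(same), "identical")

  set.seed(99)
  truth <- rbinom(5000, 1, 0.2)
  x <- cbind(a = rbinom(5000, 1, ifelse(truth == 1, 0.95, 0.1)),
             b = rbinom(5000, 1, ifelse(truth == 1, 0.9, 0.05)))
  expect_warning(
    w <- estimate_weights_em(x, init = list(m = 0.1, u = 0.9, p = 0.8)),
    "swapped")
  expect_true(all(w$fields$m > w$fields$u))
})

test_that("composite scores sum per-field weight contributions", {
  w <- manual_weights(c("a", "b", "c"), m = c(0.95, 0.9, 0.9),
                      u = c(0.05, 0.05, 0.05))
  # overwrite with round weights to check pure summation
  w$fields$w_agree <- c(10, 12, 13)
  w$fields$w_disagree <- c(-8, -9, -10)
  expect_equal(score_pair(c(a = 1L, b = 1L, c = 1L), w), 35)
  expect_equal(score_pair(c(a = 0L, b = 0L, c = 0L), w), -27)
  expect_equal(score_pair(c(a = 1L, b = NA, c = 0L), w), 0)  # 10 + 0 - 10

  set.seed(3)
  x <- matrix(sample(c(0L, 1L, NA), 300, replace = TRUE), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  s <- score_pairs(x, w)
  manual <- apply(x, 1, function(v) {
    sum(ifelse(is.na(v), 0,
               ifelse(v == 1, w$fields$w_agree, w$fields$w_disagree)))
  })
  expect_equal(s, manual)
  # attainable extremes
  expect_true(all(s >= sum(w$fields$w_disagree) - 1e-12 &
                    s <= sum(w$fields$w_agree) + 1e-12))
})

test_that("a pair scoring exactly the threshold is classified", {
  l <- toy_table(list(toy_rec("MARIA JOSE SILVA", mother = "RITA LIMA",
                              birth = "1980-05-01")), source = "L")
  r <- toy_table(list(toy_rec("MARIA JOSE SILVA", mother = "ZULMIRA PAES",
                              birth = "1980-05-01")), source = "R")
  w <- manual_weights(c("full_name", "mother_name", "birth_date"),
                      m = 0.9, u = 0.1)
  sc <- w$fields$w_agree[1] + w$fields$w_disagree[2] + w$fields$w_agree[3]
  sp <- blocking_pass(1L, c("sx_first", "sx_last", "sex", "birth_year"),
                      c("full_name", "mother_name", "birth_date"),
                      threshold = sc)
  out <- run_probabilistic(l, r, list(sp), weights = w)
  expect_identical(nrow(out$matches), 1L)
  expect_equal(out$matches$score, sc)
  # a hair above the score: no match
  sp2 <- sp; sp2$threshold <- sc + 1e-9
  out2 <- run_probabilistic(l, r, list(sp2), weights = w)
  expect_identical(nrow(out2$matches), 0L)
})

test_that("uncorrupted pairs all match in pass 1; later passes receive none", {
  sim <- get_sim(61, n = 300,
                 corruption = list(char_edit_rate = 0, surname_drop_rate = 0,
                                   initialing_rate = 0, date_typo_rate = 0,
                                   sex_flip_rate = 0),
                 completeness = list(left = completeness_profile("full"),
                                     right = completeness_profile("full")))
  l <- preprocess_table(sim$left, source = "L")
  r <- preprocess_table(sim$right, source = "R")
  w <- manual_weights(c("full_name", "mother_name", "birth_date"),
                      m = 0.95, u = 0.05)
  passes <- blocking_passes_preset(rep(5, 7))[1:5]
  out <- run_probabilistic(l, r, passes, weights = w)
  expect_identical(out$report$n_hits[1], nrow(sim$truth))
  expect_identical(sum(out$report$n_hits[-1]), 0L)
  expect_identical(sort(pair_keys(out$matches, "l_record_uid", "r_record_uid")),
                   sort(pair_keys(sim$truth)))
})

test_that("one-to-one matches are disjoint across passes; one-to-many may repeat lefts", {
  sim <- get_sim(62, n = 400)
  l <- preprocess_table(sim$left, source = "L")
  r <- preprocess_table(sim$right, source = "R")
  out <- suppressWarnings(
    run_probabilistic(l, r, blocking_passes_preset(), mode = "one_to_one",
                      auto_threshold = TRUE))
  expect_false(anyDuplicated(out$matches$l_record_uid) > 0)
  expect_false(anyDuplicated(out$matches$r_record_uid) > 0)

  left1 <- toy_table(list(toy_rec("MARIA JOSE SILVA", mother = "RITA LIMA",
                                  birth = "1980-05-01")), source = "L")
  right3 <- toy_table(list(
    toy_rec("MARIA JOSE SILVA", mother = "RITA LIMA", birth = "1980-05-01"),
    toy_rec("MARIA JOSE SILVA", mother = "RITA LIMA", birth = "1980-05-01")),
    source = "R")
  w <- manual_weights(c("full_name", "mother_name", "birth_date"),
                      m = 0.9, u = 0.1)
  res <- run_probabilistic(left1, right3, blocking_passes_preset(rep(0, 7))[1:2],
                           weights = w, mode = "one_to_many")
  expect_identical(nrow(res$matches), 2L)
  expect_identical(unique(res$matches$l_record_uid), left1$record_uid)
})
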