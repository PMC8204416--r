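# Synthetic paired person tables with known ground truth.
#
# The generator emulates the data-quality conditions the toolkit is built
# for: Brazilian-style names (double given names, one to three surnames,
# heavy-tailed name frequencies so homonyms occur), typographic
# corruption, surname truncation/initialing, and per-field completeness
# profiles matching the source registries, with a replayable
# ground-truth link table.

#' Bundled synthetic name pools
#'
#' Loads the packaged synthetic given-name and surname lists (stand-ins
#' for real national frequency lists, which users can supply instead).
#' Pool weights are Zipf-like in list rank, making a few names very
#' frequent and the rest rare, so exact full-name homonyms occur at
#' realistic rates.
#'
#' @param given_path,surname_path Optional paths to user-supplied lists
#'   (CSV with a `name` column, ordered by decreasing frequency, or with
#'   an explicit `weight` column).
#' @param zipf_exponent Rank-weight exponent (weight ~ 1/rank^s).
#' @return List with `given` and `surname` `data.table`s (`name`,
#'   `weight`, `count` scaled to a population of 100,000).
#' @export
lw_name_pools <- function(given_path = NULL, surname_path = NULL,
                          zipf_exponent = 0.85) {
  load1 <- function(path, default_file) {
    if (is.null(path))
      path <- system.file("extdata", default_file, package = "linkwise",
                          mustWork = TRUE)
    dt <- data.table::fread(path, colClasses = "character")
    if (!"name" %in% names(dt)) .stopf("name pool %s lacks a 'name' column", path)
    w <- if ("weight" %in% names(dt)) as.numeric(dt$weight)
         else 1 / seq_len(nrow(dt))^zipf_exponent
    data.table::data.table(name = dt$name, weight = w / sum(w),
                           count = pmax(1, round(1e5 * w / sum(w))))
  }
  list(given = load1(given_path, "synthetic_given_names.csv"),
       surname = load1(surname_path, "synthetic_surnames.csv"))
}

#' Per-field completeness profiles of the source registries
#'
#' The fraction of records with each personal identifier filled, per
#' database, as observed in the linked registries (social-benefits
#' registry `"cadu"`, family-health registry `"fhr"`, electronic medical
#' record `"emr"`, hospital-admission system `"sih"`, mortality system
#' `"sim"`); a 0 marks an attribute the database does not carry.
#'
#' @param db One of `"cadu"`, `"fhr"`, `"emr"`, `"sih"`, `"sim"`, or
#'   `"full"` (everything complete).
#' @return Named numeric vector over `name`, `mother_name`, `birth_date`,
#'   `sex`, `address`, `cpf`, `nis` with values in \[0, 1\].
#' @export
completeness_profile <- function(db = c("cadu", "fhr", "emr", "sih", "sim",
                                        "full")) {
  db <- match.arg(db)
  f <- function(name, mother, birth, sex, addr, cpf, nis)
    c(name = name, mother_name = mother, birth_date = birth, sex = sex,
      address = addr, cpf = cpf, nis = nis)
  switch(db,
    cadu = f(1.000, 0.996, 1.000, 1, 0.823, 0.565, 0.996),
    fhr  = f(1.000, 1.000, 1.000, 1, 0.988, 0.827, 0.073),
    emr  = f(0.992, 0.000, 1.000, 1, 0.800, 0.840, 0.073),
    sih  = f(0.966, 0.902, 1.000, 1, 0.986, 0.000, 0.000),
    sim  = f(0.998, 0.966, 0.972, 1, 0.886, 0.000, 0.000),
    full = f(1, 1, 1, 1, 1, 1, 1))
}

#' Synthetic-data generator configuration
#'
#' @param n_individuals Number of distinct individuals in the population.
#' @param overlap_fraction Fraction present in both tables (the ground
#'   truth); the remainder is split evenly into left-only and right-only.
#' @param pools Name pools ([lw_name_pools()]).
#' @param double_given_rate Probability of a double given name.
#' @param surname_count_probs Probabilities of 1, 2 or 3 surnames.
#' @param mother_co_surname_rate Probability the mother's name shares the
#'   individual's last family surname.
#' @param corruption Named list of rates in \[0, 1\] applied to the
#'   right-side copy of each record: `char_edit_rate` (one random
#'   insert/delete/substitute per affected name/address field),
#'   `surname_drop_rate` (a middle surname dropped),
#'   `initialing_rate` (middle name tokens reduced to initials),
#'   `date_typo_rate` (day/month swap or day slip),
#'   `sex_flip_rate`.
#' @param completeness List with elements `left` and `right`: per-field
#'   present-fractions ([completeness_profile()]); defaults emulate the
#'   social-benefits registry on the left and the family-health registry
#'   on the right.
#' @param seed Mandatory integer seed; identical seeds give byte-identical
#'   output.
#' @return An object of class `lw_genconfig`.
#' @export
generator_config <- function(n_individuals = 5000L,
                             overlap_fraction = 0.6,
                             pools = lw_name_pools(),
                             double_given_rate = 0.5,
                             surname_count_probs = c(0.30, 0.55, 0.15),
                             mother_co_surname_rate = 0.9,
                             corruption = list(char_edit_rate = 0.05,
                                               surname_drop_rate = 0.10,
                                               initialing_rate = 0.12,
                                               date_typo_rate = 0.02,
                                               sex_flip_rate = 0.01),
                             completeness = list(
                               left = completeness_profile("cadu"),
                               right = completeness_profile("fhr")),
                             seed) {
  if (missing(seed) || is.null(seed)) .stopf("generator_config requires a seed")
  rates <- c(overlap_fraction, double_given_rate, mother_co_surname_rate,
             unlist(corruption), unlist(completeness))
  if (any(rates < 0 | rates > 1)) .stopf("all rates/fractions must lie in [0, 1]")
  if (!nrow(pools$given) || !nrow(pools$surname)) .stopf("empty name pools")
  stopifnot(abs(sum(surname_count_probs) - 1) < 1e-8)
  structure(list(n_individuals = as.integer(n_individuals),
                 overlap_fraction = overlap_fraction, pools = pools,
                 double_given_rate = double_given_rate,
                 surname_count_probs = surname_count_probs,
                 mother_co_surname_rate = mother_co_surname_rate,
                 corruption = corruption, completeness = completeness,
                 seed = as.integer(seed)),
            class = "lw_genconfig")
}

.STREETS <- c("RUA DAS FLORES", "AVENIDA BRASIL", "RUA SAO JORGE",
              "TRAVESSA DA PAZ", "RUA QUINZE DE NOVEMBRO", "AVENIDA ATLANTICA",
              "RUA DAS LARANJEIRAS", "ESTRADA VELHA", "RUA DO SOL",
              "AVENIDA CENTRAL", "RUA SANTA LUZIA", "RUA PROJETADA",
              "RUA DOM PEDRO", "AVENIDA DAS AMERICAS", "RUA DA MATRIZ")

.sample_w <- function(pool, n) {
  pool$name[sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight)]
}

.digits <- function(n, width) {
  vapply(seq_len(n), function(i)
    paste(sample(0:9, width, replace = TRUE), collapse = ""), character(1))
}

#' Generate the synthetic population of individuals
#'
#' Individuals with one or two given names and one to three surnames
#' sampled from the weighted pools, a mother's name sharing the family
#' surname, plausible birth dates, sex, address, and structurally valid
#' digit-string identifiers.
#'
#' @param config A [generator_config()].
#' @return `data.table` with `person_id`, `name`, `mother_name`,
#'   `birth_date`, `sex`, `address`, `cpf`, `nis`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "lw_genconfig"))
  .with_seed(config$seed, .generate_population_impl(config))
}

.generate_population_impl <- function(config) {
  n <- config$n_individuals
  pg <- config$pools$given; ps <- config$pools$surname
  given1 <- .sample_w(pg, n)
  has2 <- runif(n) < config$double_given_rate
  given2 <- ifelse(has2, .sample_w(pg, n), NA_character_)
  nsur <- sample.int(3L, n, replace = TRUE, prob = config$surname_count_probs)
  surs <- lapply(seq_len(n), function(i) unique(.sample_w(ps, nsur[i])))
  name <- vapply(seq_len(n), function(i) {
    paste(c(given1[i], if (!is.na(given2[i]) && given2[i] != given1[i]) given2[i],
            surs[[i]]), collapse = " ")
  }, character(1))
  m_given <- .sample_w(pg, n)
  m_sur <- .sample_w(ps, n)
  shares <- runif(n) < config$mother_co_surname_rate
  mother <- vapply(seq_len(n), function(i) {
    last <- surs[[i]][length(surs[[i]])]
    own <- if (m_sur[i] != last) m_sur[i]
    fam <- if (shares[i]) last
    paste(c(m_given[i], own, fam), collapse = " ")
  }, character(1))
  data.table::data.table(
    person_id = sprintf("I%06d", seq_len(n)),
    name = name,
    mother_name = mother,
    birth_date = as.Date("1930-01-01") + sample.int(31411L, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    address = paste0(sample(.STREETS, n, replace = TRUE), " ",
                     sample.int(999L, n, replace = TRUE)),
    cpf = .digits(n, 11),
    nis = .digits(n, 11)
  )
}

# --- corruption operators -------------------------------------------------

.char_edit1 <- function(s) {
  if (is.na(s) || nchar(s) == 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  op <- sample(c("sub", "ins", "del"), 1)
  pos <- sample.int(length(ch), 1)
  letter <- sample(setdiff(LETTERS, ch[pos]), 1)
  out <- switch(op,
    sub = { ch[pos] <- letter; ch },
    ins = append(ch, letter, after = pos),
    del = if (length(ch) > 1) ch[-pos] else ch)
  paste(out, collapse = "")
}

.initialing1 <- function(s) {
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  k <- length(toks)
  if (k < 3L) return(s)
  toks[2:(k - 1)] <- substr(toks[2:(k - 1)], 1, 1)
  paste(toks, collapse = " ")
}

.surname_drop1 <- function(s) {
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  k <- length(toks)
  if (k < 3L) return(s)
  drop <- sample(2:(k - 1), 1)
  paste(toks[-drop], collapse = " ")
}

.date_typo1 <- function(d) {
  if (is.na(d)) return(d)
  day <- as.integer(format(d, "%d")); mon <- as.integer(format(d, "%m"))
  yr <- format(d, "%Y")
  if (day <= 12L && day != mon) {
    as.Date(sprintf("%s-%02d-%02d", yr, day, mon))
  } else {
    nd <- day + sample(c(-1L, 1L), 1)
    nd <- min(max(nd, 1L), 28L)
    as.Date(sprintf("%s-%02d-%02d", yr, mon, nd))
  }
}

#' Apply the configured corruption operators to one record
#'
#' Uses the current RNG state (seed upstream with `set.seed()` or let
#' [derive_linked_tables()] drive it). Operators applied per configured
#' rate: initialing of middle name tokens, dropping a middle surname,
#' single character edits on name/mother's name/address, a date typo
#' (day/month swap or day slip), and a sex flip. Applied operators are
#' recorded in the returned record's `corruption_ops` element.
#'
#' @param rec Named list or one-row `data.frame` with fields `name`,
#'   `mother_name`, `birth_date`, `sex`, `address`.
#' @param config A [generator_config()] (its `$corruption` rates are
#'   used).
#' @return The corrupted record as a named list, with `corruption_ops`
#'   (character, `;`-separated).
#' @export
corrupt_record <- function(rec, config) {
  r <- as.list(rec)
  cr <- config$corruption
  ops <- character(0)
  if (!is.na(r$name) && runif(1) < cr$initialing_rate) {
    r$name <- .initialing1(r$name); ops <- c(ops, "initialing:name")
  }
  if (!is.na(r$name) && runif(1) < cr$surname_drop_rate) {
    r$name <- .surname_drop1(r$name); ops <- c(ops, "surname_drop:name")
  }
  for (f in c("name", "mother_name", "address")) {
    if (!is.na(r[[f]]) && runif(1) < cr$char_edit_rate) {
      r[[f]] <- .char_edit1(r[[f]]); ops <- c(ops, paste0("char_edit:", f))
    }
  }
  if (!is.na(r$birth_date) && runif(1) < cr$date_typo_rate) {
    r$birth_date <- .date_typo1(r$birth_date); ops <- c(ops, "date_typo:birth_date")
  }
  if (!is.na(r$sex) && runif(1) < cr$sex_flip_rate) {
    r$sex <- ifelse(r$sex == "F", "M", "F"); ops <- c(ops, "sex_flip:sex")
  }
  r$corruption_ops <- paste(ops, collapse = ";")
  r
}

.corrupt_table <- function(dt, config) {
  rows <- lapply(seq_len(nrow(dt)), function(i)
    corrupt_record(dt[i], config))
  out <- data.table::rbindlist(lapply(rows, function(r) {
    r$birth_date <- as.Date(r$birth_date)
    data.table::as.data.table(r[c("person_id", "name", "mother_name",
                                  "birth_date", "sex", "address", "cpf",
                                  "nis", "corruption_ops")])
  }))
  out
}

.mask_completeness <- function(dt, profile) {
  for (f in names(profile)) {
    if (!f %in% names(dt)) next
    keep <- runif(nrow(dt)) < profile[[f]]
    if (f == "birth_date") {
      dt[!keep, birth_date := as.Date(NA)]
    } else {
      dt[!keep, (f) := NA_character_]
    }
  }
  dt
}

#' Derive the linked left/right tables and the ground truth
#'
#' Splits the population into both-sides, left-only and right-only
#' individuals; the right-side copies of all right records pass through
#' [corrupt_record()]; both sides are then masked to their per-field
#' completeness profiles. The truth table lists the (left_uid,
#' right_uid) pairs of individuals present on both sides, and the
#' applied-corruption log is attached as attribute `"corruption_log"`.
#'
#' @param individuals Population from [generate_population()].
#' @param config The same [generator_config()].
#' @return List with `left`, `right` (raw tables with `record_uid`,
#'   ready for [preprocess_table()]) and `truth` (`data.table` of
#'   `left_uid`, `right_uid`, `person_id`).
#' @export
derive_linked_tables <- function(individuals, config) {
  stopifnot(inherits(config, "lw_genconfig"))
  .with_seed(config$seed + 1L, .derive_linked_tables_impl(individuals, config))
}

.derive_linked_tables_impl <- function(individuals, config) {
  pop <- data.table::as.data.table(individuals)
  n <- nrow(pop)
  idx <- sample.int(n)
  n_both <- round(config$overlap_fraction * n)
  n_lonly <- floor((n - n_both) / 2)
  both <- idx[seq_len(n_both)]
  lonly <- idx[n_both + seq_len(n_lonly)]
  ronly <- idx[-seq_len(n_both + n_lonly)]

  left <- pop[sort(c(both, lonly))]
  left[, record_uid := sprintf("L-%06d", seq_len(.N))]
  right_src <- pop[sort(c(both, ronly))]
  right <- .corrupt_table(right_src, config)
  right[, record_uid := sprintf("R-%06d", seq_len(.N))]

  corruption_log <- right[, .(record_uid, person_id, ops = corruption_ops)]
  right[, corruption_ops := NULL]

  left <- .mask_completeness(left, config$completeness$left)
  right <- .mask_completeness(right, config$completeness$right)

  truth <- merge(left[person_id %in% pop$person_id[both],
                      .(person_id, left_uid = record_uid)],
                 right[person_id %in% pop$person_id[both],
                       .(person_id, right_uid = record_uid)],
                 by = "person_id")[, .(left_uid, right_uid, person_id)]
  data.table::setorder(truth, left_uid)
  data.table::setattr(truth, "corruption_log", corruption_log)
  list(left = left[, !"person_id"], right = right[, !"person_id"],
       truth = truth)
}

#' Generate a complete synthetic linkage study
#'
#' Convenience wrapper: population, linked tables and truth in one call.
#'
#' @param config A [generator_config()].
#' @return List with `left`, `right`, `truth`, `config`.
#' @export
simulate_linkage_data <- function(config) {
  pop <- generate_population(config)
  out <- derive_linked_tables(pop, config)
  out$config <- config
  out
}
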