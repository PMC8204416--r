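# Independent oracles and small fixtures used across the suite.
library(data.table)

pair_keys <- function(dt, l = "left_uid", r = "right_uid") {
  if (!nrow(dt)) return(character(0))
  paste(dt[[l]], dt[[r]], sep = "\r")
}

# Naive recursive Levenshtein (textbook definition), independent of the
# package's dynamic-programming kernel. Only for very short strings.
lev_recursive <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- if (substr(a, 1, 1) == substr(b, 1, 1)) 0L else 1L
  ta <- substr(a, 2, nchar(a)); tb <- substr(b, 2, nchar(b))
  min(lev_recursive(ta, b) + 1L,
      lev_recursive(a, tb) + 1L,
      lev_recursive(ta, tb) + cost)
}

# Cross-product deterministic-classification oracle built from full
# distance/equality matrices (utils::adist), independent of the package's
# join-based path. Returns the sorted set of matching (left_uid, right_uid).
brute_force_deterministic <- function(left, right, criteria,
                                      name_max_dist = 3) {
  eqm <- function(a, b) {
    m <- outer(a, b, `==`)
    m[is.na(m)] <- FALSE
    m & outer(!is.na(a), !is.na(b), `&`)
  }
  levm <- function(a, b) {
    m <- utils::adist(ifelse(is.na(a), "", a),
                      ifelse(is.na(b), "", b))
    m < name_max_dist & outer(!is.na(a), !is.na(b), `&`)
  }
  rules <- list(
    eqm(ifelse(left$key_ok, left$linkage_key, NA),
        ifelse(right$key_ok, right$linkage_key, NA)),
    eqm(left$cpf, right$cpf),
    eqm(left$nis, right$nis),
    eqm(as.character(left$birth_date), as.character(right$birth_date)),
    levm(left$name, right$name),
    levm(left$mother_name, right$mother_name),
    eqm(left$name, right$name)
  )
  match_m <- matrix(FALSE, nrow(left), nrow(right))
  for (cl in criteria$clauses) {
    clm <- Reduce(`&`, rules[cl])
    match_m <- match_m | clm
  }
  idx <- which(match_m, arr.ind = TRUE)
  out <- data.table(left_uid = left$record_uid[idx[, 1]],
                    right_uid = right$record_uid[idx[, 2]])
  setorder(out, left_uid, right_uid)
  out
}

# Small synthetic fixture cache (per seed/size), so several tests can share
# one generated dataset without regenerating it.
.sim_cache <- new.env(parent = emptyenv())
get_sim <- function(seed, n = 400, ...) {
  key <- paste(seed, n, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.sim_cache[[key]])) {
    cfg <- generator_config(n_individuals = n, seed = seed, ...)
    .sim_cache[[key]] <- simulate_linkage_data(cfg)
  }
  .sim_cache[[key]]
}

# Uncorrupted, fully complete generator settings.
clean_generator <- function(n, seed) {
  generator_config(
    n_individuals = n, seed = seed,
    corruption = list(char_edit_rate = 0, surname_drop_rate = 0,
                      initialing_rate = 0, date_typo_rate = 0,
                      sex_flip_rate = 0),
    completeness = list(left = completeness_profile("full"),
                        right = completeness_profile("full")))
}

# A tiny hand-built person table for rule-level tests.
toy_table <- function(rows, source = "T") {
  dt <- rbindlist(lapply(rows, as.data.table), fill = TRUE)
  preprocess_table(dt, source = source)
}

toy_rec <- function(name, sex = "F", birth = "1980-05-01", mother = NA,
                    cpf = NA, nis = NA, address = NA) {
  list(name = name, sex = sex, birth_date = birth, mother_name = mother,
       cpf = cpf, nis = nis, address = address)
}
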