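#' Default stop words removed from cleaned names
#'
#' Portuguese name particles that carry no discriminating power and are
#' removed from name strings during cleaning. Override via the `stop_words`
#' argument of [clean_text()] or [preprocess_table()].
#'
#' @return Character vector of uppercase tokens.
#' @export
default_stop_words <- function() {
  c("DA", "DE", "DO", "DAS", "DOS", "E")
}

#' Default invalid placeholder terms
#'
#' Placeholder phrases that some source systems store instead of a real
#' value (e.g. "IGNORADO"). They are deleted wherever they occur, for both
#' name and address fields.
#'
#' @return Character vector of uppercase phrases.
#' @export
default_invalid_terms <- function() {
  c("IGNORADO", "IGNORADA", "NAO INFORMADO", "NAO INFORMADA",
    "SEM INFORMACAO", "NAO DECLARADO", "XXX")
}

#' Standardise a raw text field
#'
#' Applies, in order: Unicode to ASCII transliteration, upper-casing,
#' replacement of punctuation and special characters by spaces, deletion of
#' invalid placeholder terms, deletion of stop words (name fields only),
#' and whitespace normalisation. The function is idempotent:
#' `clean_text(clean_text(x)) == clean_text(x)`.
#'
#' @param raw Character vector (may contain `NA` or empty strings).
#' @param kind `"name"` or `"address"`; stop words are removed only for
#'   names.
#' @param stop_words Tokens removed from name fields
#'   (default [default_stop_words()]).
#' @param invalid_terms Placeholder phrases deleted from any field
#'   (default [default_invalid_terms()]).
#' @return Character vector of cleaned uppercase ASCII text; `NA` in, `NA`
#'   out; empty in, empty out.
#' @examples
#' clean_text("  maria-josé   da silva ")  # "MARIA JOSE SILVA"
#' @export
clean_text <- function(raw, kind = c("name", "address"),
                       stop_words = default_stop_words(),
                       invalid_terms = default_invalid_terms()) {
  kind <- match.arg(kind)
  if (!length(raw)) return(character(0))
  x <- as.character(raw)
  na <- is.na(x)
  x[na] <- ""
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- toupper(x)
  x <- gsub("[^A-Z0-9 ]", " ", x)
  x <- .squish(x)
  for (term in invalid_terms) {
    x <- gsub(paste0("(^| )", term, "(?= |$)"), " ", x, perl = TRUE)
  }
  x <- .squish(x)
  if (kind == "name" && length(stop_words)) {
    pat <- paste0("(^| )(", paste(stop_words, collapse = "|"), ")(?= |$)")
    x <- gsub(pat, " ", x, perl = TRUE)
    x <- .squish(x)
  }
  x[na] <- NA_character_
  x
}

#' Split a cleaned name into its segments
#'
#' Tokenises a cleaned name and extracts the three segments used by the
#' phonetic linkage key: the first given name, the second segment (second
#' given name of a double given name, or the first family name), and the
#' last family name. For a two-token name the second segment and the last
#' family name are both the second token; a single-token name is flagged
#' degenerate (its segments all equal the token, but key-based rules never
#' accept it).
#'
#' @param clean_name Character vector already passed through [clean_text()].
#' @param on_empty `"error"` (default) to fail on empty/`NA` names, or
#'   `"na"` to return `NA` segments with `unparseable = TRUE` (used when
#'   routing records to an exceptions report).
#' @return A `data.table` with columns `tokens` (list), `first_given`,
#'   `second_segment`, `last_family`, `n_tokens`, `degenerate`,
#'   `unparseable`.
#' @examples
#' parse_name("MARIA JOSE SANTOS SILVA")
#' @export
parse_name <- function(clean_name, on_empty = c("error", "na")) {
  on_empty <- match.arg(on_empty)
  x <- as.character(clean_name)
  empty <- .is_blank(x)
  if (any(empty) && on_empty == "error") {
    .stopf("unparseable (empty) name at position(s): %s",
           paste(head(which(empty), 10), collapse = ", "))
  }
  toks <- strsplit(x, " ", fixed = TRUE)
  toks[empty] <- list(character(0))
  n <- lengths(toks)
  first <- vapply(toks, function(t) if (length(t)) t[1] else NA_character_,
                  character(1))
  second <- vapply(toks, function(t) {
    if (length(t) >= 2) t[2] else if (length(t) == 1) t[1] else NA_character_
  }, character(1))
  last <- vapply(toks, function(t) {
    if (length(t)) t[length(t)] else NA_character_
  }, character(1))
  data.table::data.table(
    tokens = toks,
    first_given = first,
    second_segment = second,
    last_family = last,
    n_tokens = as.integer(n),
    degenerate = n == 1L,
    unparseable = empty
  )
}

#' American Soundex phonetic code
#'
#' Classic four-character Soundex: the initial letter followed by three
#' digits coding the remaining consonants (B/F/P/V=1, C/G/J/K/Q/S/X/Z=2,
#' D/T=3, L=4, M/N=5, R=6), with H and W transparent for adjacency,
#' vowels separating duplicates, adjacent duplicate codes collapsed, and
#' zero-padding to three digits. Inputs must be uppercase ASCII letters
#' (apply [clean_text()] first).
#'
#' @param token Character vector of non-empty uppercase alphabetic tokens.
#' @return Character vector of codes matching `^[A-Z][0-9]{3}$`.
#' @examples
#' soundex(c("SILVA", "ROBERT"))  # "S410" "R163"
#' @export
soundex <- function(token) {
  x <- as.character(token)
  bad <- is.na(x) | !grepl("^[A-Z]+$", x)
  if (any(bad)) {
    .stopf("soundex requires non-empty uppercase alphabetic tokens; offending value(s): %s",
           paste(head(unique(x[bad]), 5), collapse = ", "))
  }
  vapply(x, .soundex1, character(1), USE.NAMES = FALSE)
}

.soundex_code <- c(
  B = "1", F = "1", P = "1", V = "1",
  C = "2", G = "2", J = "2", K = "2", Q = "2", S = "2", X = "2", Z = "2",
  D = "3", T = "3",
  L = "4",
  M = "5", N = "5",
  R = "6",
  A = "0", E = "0", I = "0", O = "0", U = "0", Y = "0",
  H = "-", W = "-"
)

.soundex1 <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  codes <- .soundex_code[ch]
  out <- character(0)
  last <- codes[1]  # the initial letter's code takes part in duplicate collapse
  if (length(ch) > 1) {
    for (i in 2:length(ch)) {
      ci <- codes[i]
      if (ci == "-") next         # H/W: transparent, previous code persists
      if (ci == "0") { last <- "0"; next }  # vowel: emits nothing, breaks runs
      if (ci != last) out <- c(out, ci)
      last <- ci
      if (length(out) >= 3) break
    }
  }
  paste0(ch[1], paste(c(out, "0", "0", "0")[1:3], collapse = ""))
}

# Tolerant variant used when building tables: invalid/missing tokens -> NA.
.soundex_or_na <- function(token) {
  x <- as.character(token)
  ok <- !is.na(x) & grepl("^[A-Z]+$", x)
  out <- rep(NA_character_, length(x))
  if (any(ok)) out[ok] <- vapply(x[ok], .soundex1, character(1), USE.NAMES = FALSE)
  out
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions, or
#' substitutions converting one string into the other, at unit cost.
#' Vectorised elementwise with recycling of a length-1 argument.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances; `NA` where either input is `NA`.
#' @examples
#' levenshtein("MARIA", "MARIANA")  # 2
#' @export
levenshtein <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  .lev_pairwise(a, b)
}

#' Build the deterministic linkage key
#'
#' The key concatenates the Soundex codes of the first given name, the
#' second name segment and the last family name with the sex and the ISO
#' date of birth, joined by `"|"`:
#' `"SX1|SX2|SX3|SEX|YYYY-MM-DD"`. The key is flagged incomputable when the
#' name is degenerate (a single token) or unparseable, or when sex or date
#' of birth is missing; such records are excluded from key-equality joins
#' only.
#'
#' @param name Cleaned name (character vector).
#' @param sex Character vector with values `"F"`/`"M"` (`NA` = unknown).
#' @param birth_date `Date` vector (or ISO `YYYY-MM-DD` strings).
#' @return A `data.table` with columns `linkage_key` (serialised key or
#'   `NA`) and `key_ok` (logical).
#' @examples
#' build_linkage_key("MARIA JOSE SILVA", "F", as.Date("1980-05-01"))
#' @export
build_linkage_key <- function(name, sex, birth_date) {
  parts <- parse_name(name, on_empty = "na")
  sx1 <- .soundex_or_na(parts$first_given)
  sx2 <- .soundex_or_na(parts$second_segment)
  sx3 <- .soundex_or_na(parts$last_family)
  bd <- as.Date(birth_date)
  sex <- as.character(sex)
  ok <- !parts$unparseable & !parts$degenerate &
    !is.na(sx1) & !is.na(sx2) & !is.na(sx3) &
    !is.na(sex) & !is.na(bd)
  key <- rep(NA_character_, length(ok))
  if (any(ok)) {
    key[ok] <- paste(sx1[ok], sx2[ok], sx3[ok], sex[ok],
                     format(bd[ok], "%Y-%m-%d"), sep = "|")
  }
  data.table::data.table(linkage_key = key, key_ok = ok)
}

# Parse dates tolerantly: invalid calendar dates (e.g. Feb 30) become NA and
# are reported, never coerced to a neighbouring valid date.
.parse_dates <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  # round-trip check: as.Date silently rolls some invalid dates on some
  # platforms; require the formatted value to match the input.
  bad <- !is.na(x) & x != "" & (is.na(d) | format(d, "%Y-%m-%d") != x)
  d[bad] <- NA
  attr(d, "n_invalid") <- sum(bad)
  d
}

#' Prepare a person table for linkage
#'
#' Cleans text fields, normalises identifiers and dates, parses names,
#' computes Soundex codes and the deterministic linkage key, and assigns
#' record and individual unique identifiers. Records with degenerate names
#' or incomputable keys are collected into an exceptions report (attribute
#' `"exceptions"`, also retrievable with [exceptions_report()]); they stay
#' in the table and simply never satisfy key-based rules.
#'
#' @param dt A `data.frame`/`data.table` with (a subset of) columns `name`,
#'   `mother_name`, `birth_date`, `sex`, `address`, `cpf`, `nis`,
#'   `vital_status`, `death_date`. Use `column_map` to rename source
#'   headers.
#' @param source Label recorded in the `source` column and used as the
#'   record-uid prefix.
#' @param column_map Named character vector mapping standard field names to
#'   source column names, e.g. `c(name = "NOME", birth_date = "DT_NASC")`.
#' @param stop_words,invalid_terms Passed to [clean_text()].
#' @param dedup Passed to [assign_uids()]; `FALSE` disables same-individual
#'   grouping (each record is its own individual).
#' @return A `data.table` with standardised fields plus `record_uid`,
#'   `individual_uid`, `name_first`, `name_second`, `name_last`,
#'   `degenerate`, `sx_first`, `sx_second`, `sx_last`, `linkage_key`,
#'   `key_ok`, `birth_year`.
#' @export
preprocess_table <- function(dt, source = "T", column_map = NULL,
                             stop_words = default_stop_words(),
                             invalid_terms = default_invalid_terms(),
                             dedup = TRUE) {
  dt <- data.table::as.data.table(dt)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(dt)) .stopf("column_map refers to absent column '%s'", src)
      data.table::setnames(dt, src, std)
    }
  }
  if (!"name" %in% names(dt)) .stopf("input table has no 'name' column (after column_map)")
  out <- data.table::copy(dt)
  n <- nrow(out)
  ensure <- function(col) if (!col %in% names(out)) out[, (col) := NA_character_]
  for (col in c("mother_name", "sex", "address", "cpf", "nis")) ensure(col)
  if (!"birth_date" %in% names(out)) out[, birth_date := as.Date(NA)]

  out[, name := clean_text(name, "name", stop_words, invalid_terms)]
  out[, mother_name := clean_text(mother_name, "name", stop_words, invalid_terms)]
  out[, address := clean_text(address, "address", stop_words, invalid_terms)]
  out[name == "", name := NA_character_]
  out[mother_name == "", mother_name := NA_character_]
  out[address == "", address := NA_character_]

  for (col in c("cpf", "nis")) {
    v <- gsub("[^0-9]", "", as.character(out[[col]]))
    v[v == ""] <- NA_character_
    out[, (col) := v]
  }
  sx <- toupper(substr(as.character(out$sex), 1, 1))
  sx[!sx %in% c("F", "M")] <- NA_character_
  out[, sex := sx]
  bd <- .parse_dates(out$birth_date)
  n_bad_dates <- attr(bd, "n_invalid") %||% 0L
  out[, birth_date := bd]
  if ("death_date" %in% names(out)) out[, death_date := .parse_dates(death_date)]

  if (!"record_uid" %in% names(out))
    out[, record_uid := sprintf("%s-%06d", source, seq_len(n))]
  if (anyDuplicated(out$record_uid)) .stopf("record_uid must be unique within a table")
  out[, source := source]

  parts <- parse_name(out$name, on_empty = "na")
  out[, `:=`(name_first = parts$first_given,
             name_second = parts$second_segment,
             name_last = parts$last_family,
             n_tokens = parts$n_tokens,
             degenerate = parts$degenerate)]
  out[, `:=`(sx_first = .soundex_or_na(name_first),
             sx_second = .soundex_or_na(name_second),
             sx_last = .soundex_or_na(name_last))]
  keyinfo <- build_linkage_key(out$name, out$sex, out$birth_date)
  out[, `:=`(linkage_key = keyinfo$linkage_key, key_ok = keyinfo$key_ok)]
  out[, birth_year := as.integer(format(birth_date, "%Y"))]

  out <- assign_uids(out, dedup = dedup)

  reasons <- character(0)
  idx <- which(parts$unparseable | parts$degenerate | !out$key_ok)
  if (length(idx)) {
    reasons <- vapply(idx, function(i) {
      if (parts$unparseable[i]) "EMPTY_NAME"
      else if (parts$degenerate[i]) "DEGENERATE_NAME"
      else if (is.na(out$sex[i]) || is.na(out$birth_date[i])) "KEY_MISSING_SEX_OR_DOB"
      else "KEY_INCOMPUTABLE"
    }, character(1))
  }
  exc <- data.table::data.table(record_uid = out$record_uid[idx],
                                name = out$name[idx], reason = reasons)
  data.table::setattr(out, "exceptions", exc)
  data.table::setattr(out, "n_invalid_dates", n_bad_dates)
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exceptions report of a preprocessed table
#'
#' Records whose names are degenerate/empty or whose linkage key is
#' incomputable, with reason codes (`EMPTY_NAME`, `DEGENERATE_NAME`,
#' `KEY_MISSING_SEX_OR_DOB`).
#'
#' @param dt A table returned by [preprocess_table()].
#' @return A `data.table` with columns `record_uid`, `name`, `reason`.
#' @export
exceptions_report <- function(dt) {
  attr(dt, "exceptions") %||%
    data.table::data.table(record_uid = character(0), name = character(0),
                           reason = character(0))
}

#' Read a person table from CSV and prepare it for linkage
#'
#' @param path CSV file (RFC-4180, UTF-8, header row).
#' @param ... Passed to [preprocess_table()] (`source`, `column_map`, ...).
#' @return A preprocessed `data.table`; see [preprocess_table()].
#' @export
read_person_table <- function(path, ...) {
  dt <- data.table::fread(path, colClasses = "character",
                          na.strings = c("", "NA"), encoding = "UTF-8")
  preprocess_table(dt, ...)
}

#' Assign record and individual unique identifiers
#'
#' Every record receives a fresh `record_uid` (if absent). Records judged
#' to belong to the same individual share an `individual_uid`: by default,
#' two records are the same individual when they agree exactly on a
#' non-missing `cpf` or `nis` *and* their cleaned names are at Levenshtein
#' distance < 3 *and* their birth dates are equal. A report of
#' multi-record individuals is attached as attribute
#' `"multi_record_individuals"`.
#'
#' @param dt Preprocessed `data.table` (needs `name`, `birth_date`, `cpf`,
#'   `nis`; `record_uid` is created when absent).
#' @param dedup `TRUE` for the default rule, `FALSE` to make every record
#'   its own individual, or a function `(dt) -> integer matrix` of record
#'   index pairs to connect.
#' @param name_max_dist Name-distance bound of the default rule (strict
#'   `<`, default 3).
#' @return The table with `individual_uid` set (keyed to the first
#'   `record_uid` of each group).
#' @export
assign_uids <- function(dt, dedup = TRUE, name_max_dist = 3L) {
  dt <- data.table::as.data.table(dt)
  n <- nrow(dt)
  if (!"record_uid" %in% names(dt))
    dt[, record_uid := sprintf("R-%06d", seq_len(n))]
  if (n == 0L) {
    dt[, individual_uid := character(0)]
    return(dt[])
  }
  edges <- NULL
  if (is.function(dedup)) {
    edges <- dedup(dt)
  } else if (isTRUE(dedup)) {
    edges <- .default_dedup_edges(dt, name_max_dist)
  }
  comp <- .union_find(n, edges)
  dt[, individual_uid := dt$record_uid[comp]]
  multi <- dt[, .(n_recs = .N), by = individual_uid][n_recs > 1L]
  data.table::setattr(dt, "multi_record_individuals", multi)
  dt[]
}

# Candidate same-individual record pairs under the default rule.
.default_dedup_edges <- function(dt, name_max_dist) {
  pairs <- list()
  for (idcol in c("cpf", "nis")) {
    if (!idcol %in% names(dt)) next
    idx <- data.table::data.table(i = seq_len(nrow(dt)), v = dt[[idcol]])
    idx <- idx[!is.na(v)]
    grp <- idx[, if (.N > 1L) .(a = rep(i, each = .N), b = rep(i, times = .N)), by = v]
    if (nrow(grp)) pairs[[idcol]] <- grp[a < b, .(a, b)]
  }
  if (!length(pairs)) return(NULL)
  ed <- unique(data.table::rbindlist(pairs))
  if (!nrow(ed)) return(NULL)
  keep <- !is.na(dt$birth_date[ed$a]) & !is.na(dt$birth_date[ed$b]) &
    dt$birth_date[ed$a] == dt$birth_date[ed$b] &
    !is.na(dt$name[ed$a]) & !is.na(dt$name[ed$b])
  ed <- ed[keep]
  if (!nrow(ed)) return(NULL)
  d <- levenshtein(dt$name[ed$a], dt$name[ed$b])
  ed <- ed[!is.na(d) & d < name_max_dist]
  if (!nrow(ed)) return(NULL)
  as.matrix(ed)
}
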