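# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Collapse runs of whitespace and trim ends.
.squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  gsub("^ | $", "", x)
}

.is_blank <- function(x) is.na(x) | x == ""

# NA-safe equality used by every "exact agreement" rule: missing never agrees.
.eq_nonmissing <- function(a, b) {
  !is.na(a) & !is.na(b) & a != "" & b != "" & a == b
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Minimal union-find over 1..n used for same-individual grouping.
.union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1L]); rb <- find(edges[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  vapply(seq_len(n), find, integer(1))
}
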