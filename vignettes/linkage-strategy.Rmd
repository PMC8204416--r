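---
title: "A multi-approach record linkage strategy for suboptimal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-approach record linkage strategy for suboptimal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Linking large person-level administrative databases — a social-benefits
registry against primary-care, hospitalisation or mortality data — is
hard when no single identifier is complete and reliable. A national
identity number may be present in only half of one database and under a
tenth of another; names are long, repetitive and prone to transcription
variants (double given names, two or three family names, middle names
recorded as initials, particles like "DA"/"DOS" used inconsistently); and
homonyms are common enough that exact name agreement is weak evidence on
its own. `linkwise` implements a sequential, auditable strategy for this
setting: aggressive standardisation, conservative deterministic rules,
multi-pass probabilistic scoring on the residual, rule-based
post-processing, and a structured clerical-review loop, with an
evaluation module that quantifies the errors the automatic stages make.

## Pre-processing and the linkage key

All text comparisons operate on a canonical form: Unicode transliterated
to ASCII, uppercase, punctuation replaced by spaces, placeholder terms
(e.g. "IGNORADO", "NAO INFORMADO") deleted everywhere, stop-word
particles (`DA, DE, DO, DAS, DOS, E` by default) deleted from names
only, and whitespace collapsed. `clean_text()` is idempotent, so storing
cleaned values and re-cleaning them is safe. Both lists are arguments —
they are conventions, not constants.

A name is segmented into tokens; the *first given name*, the *second
segment* (the second token: either the second half of a double given
name or the first family name — with only the string there is no way to
tell, and the ambiguity is deliberate), and the *last family name*. The
deterministic linkage key concatenates the Soundex codes of those three
segments with sex and the ISO birth date:

```
M600|J200|S410|F|1980-05-01
```

Two conventions matter and are configurable choices rather than facts
about the data:

* **Two-token names** ("ANA SILVA") set second segment = last family
  name, so the key remains computable for the very common
  "given + single surname" pattern. Single-token names are flagged
  degenerate, reported in the exceptions report, and never satisfy
  key-based rules.
* **Soundex variant**: classic four-character American Soundex (initial
  letter + three digits, H/W transparent, vowels separating duplicate
  codes), applied after ASCII transliteration. Other phonetic encoders
  can be substituted upstream by supplying precomputed code columns.

Dates that do not exist (e.g. February 30th) are set to missing and
counted, never silently rolled to a neighbouring date; a record missing
sex or birth date keeps an incomputable key and is excluded from
key-equality joins only.

Each table receives fresh record uids, and an *individual* uid groups
records judged to be the same person. The default same-individual rule —
identical CPF or NIS, plus cleaned-name Levenshtein distance < 3 and
equal birth date — mirrors the style of the deterministic rules and is
replaceable by any function returning record-index pairs.

## Deterministic rules

Seven pair-level rules are combined into per-process criteria
(disjunctions of conjunctions): key equality, CPF equality, NIS
equality, birth-date equality, name distance < 3, mother's-name distance
< 3, exact name equality. Four presets ship, named for the
database pairings they were designed around (`cadu_fhr`, `cadu_sih`,
`cadu_sim`, `fhr_emr`); criteria are data, so any clause list over rules
1–7 can be declared.

Missing operands never agree — an absent CPF cannot create a match. Every
clause must contain at least one exact-equality rule so candidate pairs
can be generated by hash joins; the classified match set is then provably
identical to evaluating the full cross product (the test suite checks
this against a cross-product oracle). When two matches collide in
one-to-one mode, the pair with the earliest-declared clause wins, ties
broken by smallest right then left record uid — deterministic and
auditable, with suppressed alternatives retained.

## Probabilistic model

The probabilistic stage is a Fellegi–Sunter linkage. For a candidate
pair, each compared field yields agree / disagree / missing: name-type
fields agree when their Levenshtein distance is below 3 (the same
convention as the deterministic rules; configurable per run), and birth
dates agree only on exact character equality of their ISO form. With
`m_k = P(field k agrees | true match)` and
`u_k = P(field k agrees | non-match)`, a pair's composite score is

```
score = sum over compared fields of:
  log2(m_k / u_k)             if field k agrees
  log2((1-m_k) / (1-u_k))     if field k disagrees
  0                           if field k is missing
```

Missing contributing zero is the standard choice when `m`/`u` are
estimated from observed outcomes only: an absent field is neither
evidence for nor against.

`m_k`, `u_k` and the match prevalence are estimated by EM on a two-class
latent mixture with conditionally independent binary outcomes, missing
entries dropped from the affected field's likelihood term. The
implementation collapses identical comparison vectors, guarantees a
non-decreasing observed-data log-likelihood (asserted in the tests on
every run), starts from `m = 0.9, u = 0.1, prevalence = 0.01`
deterministically, stops at `1e-6` log-likelihood change or 500
iterations, clamps probabilities to `[1e-6, 1 - 1e-6]`, and swaps class
labels with a warning if the converged solution has the classes
reversed. Degenerate inputs (a single distinct vector) are rejected with
advice to supply `manual_weights()`.

Two estimation caveats are worth knowing. A *single-field* mixture is
identifiable only up to a ridge — many `(prevalence, m, u)` triples give
the same likelihood — so one-field fits are meaningful only near a known
starting point; the bundled passes always compare at least two fields.
And on very small candidate pools the conditional-independence model can
invert a field (estimated `m < u`), which the run surfaces through the
attainable-score-range warning rather than hiding.

### Blocking passes and weight sharing

The bundled strategy uses seven passes. Passes 1–5 compare full name,
mother's name and birth date under five indexing keys (Soundex of first
and last name + sex + birth year, then each triple); pass 6 re-uses the
full key but compares first given name, last family name, mother's name
and birth date, which is exactly the comparison that survives
initialed/truncated middle names; pass 7 re-uses the full key, compares
only name and birth date, and its survivors become the clerical-review
queue. Records missing an index field sit a pass out. Matched records do
not re-enter later passes (one-to-one), or re-enter on the left only
(one-to-many, for event data such as repeated hospitalisations, which
must be acknowledged explicitly in the configuration).

Weights are shared across passes with identical compare fields and
fitted once per group on the *pooled* candidates of the group's passes.
The pooled fit sees both the tight pass-1 blocks and the looser
single-triple blocks, which stabilises `u` estimation; and since passes
1–5 compare the same fields under the same discretisation, their weights
estimate the same quantities and share a single attainable score range.
Per-pass or manual weights remain available.

### Thresholds

Score cutoffs are genuinely data-dependent — in production use they are
set empirically per pass after inspecting the score distribution — so
they are configuration inputs, not defaults. Two helpers support the choice: `score_histogram()` for manual
inspection, and `suggest_threshold()`, which returns the score where the
posterior match probability reaches a target (0.5 by default) under the
fitted prevalence: `log2((1-p)/p) + log2(t/(1-t))`. `run_linkage()` uses
the posterior-odds rule when no threshold is supplied
(`auto_threshold`); a threshold outside the attainable range
`[Σ w_disagree, Σ w_agree]` triggers a warning. For the review pass a
too-low automatic threshold errs toward sending more pairs to humans,
never toward silent matches.

## Post-processing

Both reclassification rules move pairs only toward more scrutiny, never
toward automatic matches:

* an automatic match is **demoted** to the review queue when the cleaned
  left name has 20 characters or fewer (spaces included — the length
  definition is a stated convention, measured on the left record) or the
  second-segment Soundex codes disagree (a missing code counts as
  disagreement, i.e. demotion);
* a potential match is **discarded** only when four conditions hold
  simultaneously: first-given-name Soundex frequency > 5 in the
  reference population (the right-hand table by default), name length
  ≤ 20, mother's-name distance ≥ 10, and address distance ≥ 12 — with a
  missing mother's name or address keeping the pair for review. The
  boundary operators are taken literally (`>`, `≤`, `≥`).

## Clerical review

Queue items carry side-by-side attributes, the same agreement outcomes
the probabilistic stage used plus the address, a name-rarity class, and
a suggested decision. Rarity follows surname counting (first token =
given name, the rest surnames): three or more surnames → rare; two
surnames none of which is frequent → rare; exactly one surname with
either part frequent → common; everything else intermediate. "Frequent"
is membership above a count cutoff in a reference list; the bundled
lists are synthetic stand-ins (see below) and real national lists should
be supplied for production use.

The suggestion rules: rare names match even with disagreements elsewhere;
common names match only when mother's name, birth date and address all
agree; intermediate names match when the birth date and either the
mother's name or the address agree, and are otherwise routed to a
supervisor as undecided. The suggestion is decision support: imported
human decisions (`match`/`non-match` only, validated row by row) are what
finalise a linkage. `auto_review = TRUE` short-circuits this with the
suggestions themselves (undecided → non-match) and exists for simulation
studies. Reviewer qualification is a plain accuracy gate: at least 90%
correct on a 200-pair gold set.

## Evaluation

Error measures are proportions with 95% confidence intervals, reported
on the percentage scale:

* **False-match proportion** of an approach: contradicting verdicts in a
  re-reviewed random sample of its matches. **Missed-match proportion**:
  match verdicts in a re-reviewed sample of clerical non-matches. Both
  default to exact Clopper–Pearson intervals (via beta quantiles), the
  right choice for the small numerators these audits produce; the lower
  bound is exactly 0 at `k = 0` and the upper exactly 100 at `k = n`.
* **Recall** against an external gold standard (e.g. deaths recorded in
  another registry), overall and per stratum, with Wald intervals —
  appropriate for the large `k` recall audits involve.

Sampling is simple random without replacement, seeded, and restores the
caller's RNG state. Display rounding is half-up at one decimal
(`round_half_up()`), because banker's rounding produces occasional
off-by-one last digits against conventionally rounded reports; tests
compare unrounded values wherever a printed figure is ambiguous between
rounding and truncation.

## The synthetic generator

`generator_config()` describes a population and two overlapping extracts
of it. What it emulates, and the defaults:

* **Names**: given names and surnames drawn from weighted pools with
  Zipf-like rank weights (exponent 0.85), so a handful of names dominate
  and exact full-name homonyms occur at realistic rates; 50% double
  given names; 1–3 surnames with probabilities (0.30, 0.55, 0.15); the
  mother shares the family surname 90% of the time. The bundled pools
  (`synthetic_given_names.csv`, `synthetic_surnames.csv`) are
  constructed lists in Brazilian naming style, *not* real frequency
  tables — flagged synthetic in their filenames — and can be replaced by
  user-supplied lists.
* **Completeness**: per-field present-fractions per side,
  defaulting to the profiles observed in the source registries
  (`completeness_profile("cadu")` on the left — e.g. CPF 56.5%,
  NIS 99.6%, address 82.3% — and `"fhr"` on the right, e.g. NIS 7.3%).
  Realised completeness lands within ±2 percentage points at the sample
  sizes the tests use.
* **Corruption** of right-side copies: a single random character edit
  per affected field (rate 0.05 on name, mother's name, address),
  dropping a middle surname (0.10), reducing middle tokens to initials
  (0.12) — the operator that defeats full-name comparison but not pass
  6 —, day/month swaps or day slips (0.02), and sex flips (0.01). Every
  applied operator is logged per record, and identical seeds reproduce
  the tables byte for byte.

The corruption rates are the package's chosen study conditions: strong
enough that deterministic rules alone lose roughly a tenth of the true
pairs, mild enough that the combined strategy recovers nearly all of
them — the regime the strategy was designed for.

What the generator does **not** emulate: real name-frequency
distributions (the pools are synthetic), address structure beyond a
cleaned free-text line, households and siblings (homonyms arise only
from pool collisions), duplicate records within one table, or
longitudinal drift. Passing the end-to-end tests therefore demonstrates
the machinery is correct under these conditions, not that any particular
real-world linkage will reach the same precision and recall.

## Numerical and design choices

* Levenshtein distance is a unit-cost two-row dynamic programme in C++
  (`src/distance.cpp`); the test suite proves it against base R's
  `adist()` on the full grid of strings up to length 6 over a 3-letter
  alphabet, against a naive recursion on short strings, and for the
  metric axioms on random pairs.
* One-to-one resolution is greedy in a fully specified order (clause
  index, then right uid, then left uid deterministically; score
  descending for probabilistic passes), so reruns are byte-identical.
* The first-given-name frequency table for the discard rule is computed
  from the right-hand (population-wide) table by default; which
  population to count is a genuine open choice and is configurable.
* Analysis preparation strips every personal identifier column and
  verifies by schema scan; one-to-one duplicates (an individual with
  more than one matched record) and one-to-many multiplicities (five or
  more events) are flagged for manual review rather than silently
  resolved.
* Chunked execution (`run_chunked()`) links each right-table chunk
  independently; for deterministic-only processes the union provably
  equals the unsplit run because candidate generation is key-local.

## Problem sizes

The test suite and acceptance script run at sizes chosen to exercise
every stage while keeping the whole suite in the minutes range:
populations of 150–800 individuals for unit-level checks, 2,000 for the
clean-data exactness benchmark, 4,000 for the corrupted benchmark, 50
replicates of 200×200 tables for the cross-product oracle, 50,000
simulated comparison vectors for EM parameter recovery, and 100 seeded
validation samples for interval coverage. All scale linearly with the
generator's `n_individuals` for users who want larger rehearsals.

## Known limitations

* Conditional independence of field agreements given match status is
  assumed by the EM; correlated fields (mother's surname shares the
  individual's surname) bias weights somewhat, which is one reason the
  strategy keeps a clerical stage.
* Frequency-scaled per-value weights and string comparators other than
  Levenshtein/exact (e.g. Jaro–Winkler) are out of scope.
* The rarity classifier depends entirely on the quality of the supplied
  name-frequency lists.
* Thresholds remain a human decision; the posterior-odds default is a
  reasonable starting point, not a calibration.
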