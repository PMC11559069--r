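---
title: "Profiling ontology categories: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling ontology categories: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure

The pipeline profiles a subclass ontology — the Human Phenotype Ontology
(HPO) being the motivating instance — in two stages.

**Stage 1: category leaf extraction.** The ontology is a rooted DAG of
terms connected child-to-parent by `is_a` (subclass) edges. The
*categories* are the non-obsolete direct children of a chosen root
(default `HP:0000118`, Phenotypic abnormality). For each category we
compute its descendant closure (`ont_descendants()`) and its *leaf set*:
the members with no non-obsolete subclass child anywhere in the graph.
Leaf extraction is what per-category downloads of HPO contain, and the
leaf counts per category form the first report (`count_table()`,
`summarize_counts()`).

**Stage 2: attribute composition.** Clinicians curate each leaf term
with up to four attributes — Disease Name, Condition, Test Data,
Symptoms and Findings — in a spreadsheet with `+`/`−` cells, optionally
refining Test Data into five subtypes. `read_curation()` loads such a
table, `merge_curation()` aligns it with a category's leaf set, and
`attribute_profile()` reports, per category, the leaf total, the count
flagged with the chosen attribute, and the percentage.

### Assumptions

- Category membership is **subclass-based**: only `is_a` edges are
  traversed. `part_of` and other relationships, if present in the input,
  are parsed, counted, and ignored (the count is logged so dropped
  structure is visible). Whether any leaf-extraction service consults
  other relations is not documented anywhere we know of; subclass
  closure is the defensible reading.
- **Leaf** means "no non-obsolete subclass child anywhere in the
  graph". Because subclass closures are downward closed, this coincides
  with leaf-within-closure; the test suite asserts
  `leaves(c) = members(c) ∩ global_leaves(graph)` on every generated
  graph rather than relying on the argument alone.
- A **multi-parent term counts in every category** it descends from.
  This is deliberate: the DAG semantics of HPO treat multiple parent
  concepts as separate, so per-category counts may double-count across
  rows. `overlap_matrix()` makes the double counting inspectable; its
  diagonal sum always equals the `count_table()` total.
- **Obsolete terms** are retained in the graph for diagnostics but
  excluded from traversal, leaf sets, and every count: curated lists
  should not contain deprecated ids.

## Numerical and procedural choices

- **Rounding is half-up (away from zero) to one decimal**, computed in
  exact integer arithmetic: `tenths = (2000k + n) %/% (2n)`. Every
  percentage cell of the published reference table is reproduced under
  this rule; none of those cells sits on a tie, so half-even would
  reproduce them too — the rule is fixed explicitly (and exercised on a
  genuine tie, 1/16 → 6.3) to make outputs bit-stable. Integer
  arithmetic avoids the floating-point hazard that `100*k/n` lands a
  hair under a tie.
- **Empty categories report `NA` percent, rendered `"NA"`, never 0.0** —
  0.0 is a real observed value (a category can have every leaf
  unflagged) and must not be conflated with no-data.
- **Uncurated leaves stay in the denominator** as all-false. The
  published percentages divide flagged counts by the *full* leaf count
  (895/961 = 93.1%), so coverage gaps must not shrink denominators; they
  are surfaced separately as `uncurated` diagnostics. Curated ids that
  are not in the leaf set (`stale`, e.g. from an older release) are
  reported and excluded.
- **All orderings are byte-wise (radix) sorts** of labels or ids, never
  locale collation, so outputs are identical across platforms; every
  writer is deterministic (no timestamps), which is what makes the
  end-to-end byte-identity test possible.
- **Dangling parent references are an error by default** (corrupted
  exports should fail loudly), with `prune_dangling = TRUE` as the
  explicit escape hatch. Cycles, self-loops and duplicate ids are
  reported as typed data by `validate_ontology()` so callers can decide
  severity; the pipeline entry points escalate all of them.
- **Category selection is exact matching** (case-insensitive, after
  whitespace normalization) on labels or ids; no fuzzy matching. A near
  miss fails, listing the available labels — a silently wrong category
  is far more dangerous in a curation workflow than a failed run.
- The curation dialect accepts the Unicode minus `−`, the ASCII hyphen,
  the en dash, and the empty cell as "absent", and matches headers
  case-insensitively against singular/plural aliases, because real
  spreadsheets mix all of these. An unrecognized marker is an error with
  its row number, not a silent false.

## The synthetic generator

Real per-category counts depend on which HPO release is profiled, so
absolute counts are not reproducible desk-side. The package therefore
ships a seeded generator (`synthetic_spec()`, `generate_ontology()`,
`generate_curation()`) whose artifacts have *recorded ground truth*,
and the pipeline is validated against that.

What it emulates: a rooted DAG with a category layer directly under the
root; layered trees below the categories with Poisson branching; extra
child-to-parent cross-links that create multi-parent terms and hence
multi-category leaves; per-leaf attribute flags drawn independently per
attribute at per-category probabilities.

Defaults (chosen once, to mirror the profiled study's shape): 23
categories; depth 4; `branching_mean` 2.5 (giving graphs on the order of
1,500 terms — large enough for category counts in the tens to low
hundreds, small enough that the whole suite runs in seconds);
`multi_parent_prob` 0.1 (multi-parentage is common in HPO but a
minority of terms); Symptoms-and-Findings proportions spread evenly over
[0, 0.93] across categories, emulating the published spread of 0 to
93.1%, with the other attributes at fixed moderate probabilities (0.2,
0.3, 0.25).

Three design points matter for trustworthiness:

- **Cross-links only point from deeper layers to strictly shallower
  ones**, so acyclicity is structural. The alternative — generate
  arbitrary links and reject cycles — would condition the random stream
  on the traversal code and bias seeded graphs.
- **Ground truth is recorded by the generator's own reachability loop
  over its own edge list**, never by calling the traversal code under
  test. The central oracle property — extracted leaf sets equal recorded
  leaf sets exactly — would be circular otherwise.
- **One named RNG substream per concern** (topology, labels, tags),
  derived from the single seed, so changing tag proportions never
  perturbs topology at a fixed seed. Generation is a pure function of
  the spec; identical specs yield byte-identical OBO files.

What it does *not* emulate: realistic phenotype label text, semantic
plausibility of the hierarchy, the real depth heterogeneity of HPO
branches (real categories range from 4 to thousands of leaves; the
generator's categories are statistically exchangeable), obsolete terms
(exercised by hand-built fixtures instead), and inter-curator
disagreement. Passing tests therefore demonstrate that the *mechanics*
— traversal, counting, merging, rounding — are correct on DAGs of the
right shape, not that any particular HPO release yields any particular
count.

## What is checked, at what sizes

- Leaf extraction equals recorded ground truth and an independent
  depth-first-search oracle on 51 seeded ontologies (tree-shaped through
  `multi_parent_prob` 0.3, up to a few thousand terms).
- Proportion recovery: tagging a 961-leaf and a 24-leaf category at the
  published head-and-neck and breast proportions, the mean recovered
  percentage over 200 seeds lies within the 3-sigma binomial band
  `3·sqrt(p(1−p)/n)·100` of the target.
- Every reader inverts every writer (OBO, two-table dialect, curation
  tables, templates) on the retained fields, and
  simulate → extract → profile is byte-identical across reruns.
- The published report arithmetic is reproduced exactly: all 16
  percentage cells, and the count summary (mean 676.8, range 4–2743).

## Limitations

- XLSX is read but not written; templates and reports are CSV/TSV.
- The two-table dialect has no column for obsolescence, so obsolete
  terms do not survive a round trip through it (the OBO writer retains
  them).
- Whether curators required at least one attribute per term is unknown;
  all-false is permitted here, which is also how uncurated terms enter
  denominators.
- Only 16 of the 23 categories have published curation tallies; the
  remaining 7 have counts but no attribute profile, and the package
  makes no assumption about them.
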