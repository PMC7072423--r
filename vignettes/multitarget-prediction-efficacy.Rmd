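---
title: "Prediction efficacy for multi-target docking screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction efficacy for multi-target docking screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtscreen)
```

## The problem and the statistic

A virtual screen of a multi-compound preparation against a panel of protein
targets yields an L x T matrix of docking scores: for each of L ligands and
T targets, an estimated binding free energy in kcal/mol, negative when
binding is favorable. Single-target ranking discards what makes a
polypharmacological preparation interesting — that its activity is spread
over many targets. mtscreen implements a simple aggregate for that setting,
the *prediction efficacy* (PE).

For a compound \(c\) with docking score \(s_{ct}\) against target \(t\),

\[ \mathrm{PE}_c \;=\; \sum_{t \,:\, s_{ct} \le \theta} s_{ct}, \]

the sum of its scores over all targets passing a threshold \(\theta\)
(default \(-6.0\) kcal/mol). A compound that binds nothing passing the
filter has PE exactly 0 (the empty sum). More negative PE means stronger
predicted engagement of the panel, through some mix of breadth (many
passing targets) and depth (very favorable scores).

At the formulation level the default statistic credits the mixture with its
best binder at each target:

\[ \mathrm{PE}_F \;=\; \sum_{t} \min_{c \,:\, s_{ct} \le \theta} s_{ct}, \]

skipping targets where no compound passes. This is the
`"best-per-target"` mode of `formulation_pe()`. An alternative reading —
the sum of all compound PEs, counting each target once per passing compound
— is available as `"sum-of-compound-pe"`; it is not the default because it
double-counts targets and breaks the dominance bound below. Both readings
circulate in the literature, so the mode is an explicit argument rather
than a hidden choice.

Two structural facts make these statistics easy to sanity-check, and the
test suite asserts both on hundreds of random matrices:

* **Dominance.** In best-per-target mode, \(\mathrm{PE}_F \le
  \mathrm{PE}_c\) for every compound \(c\): the formulation is at least as
  good as its best component, since at each target it inherits the best
  passing score.
* **Monotonicity in the cutoff.** Loosening \(\theta\) toward 0 can only
  add non-positive terms, so every PE weakly decreases.

Neither statistic is a free-energy model. Docking scores are crude, targets
are treated as independent and equally weighted, and summing kcal/mol
across unrelated binding sites has no thermodynamic meaning. PE is a
screening *prioritisation* device — a way to rank compounds and
formulations for follow-up — and nothing in this package should be read as
a claim that PE predicts biological efficacy.

## The pass filter

`threshold_policy()` holds the cutoff and its boundary rule. The default
is \(-6.0\) kcal/mol, *inclusive*: a score of exactly \(-6.0\) passes.
Published PE tables are not always consistent about the boundary — the
packaged inflammation table only reproduces under the inclusive rule
(shikimic and quinic acid each have a cell at exactly \(-6.0\)), while two
rows of the angiogenesis table are instead consistent with an exclusive
filter. Inclusivity is therefore a flag, and `threshold_sweep()` makes the
sensitivity of every compound's PE to the cutoff explicit. Cutoffs above
zero are rejected outright: a positive score is an unfavorable pose, and
letting one "pass" would silently break the monotonicity contract.

Missing cells (pairs never docked) fail the filter by definition and
contribute nothing. The packaged matrices are dense, so this rule only
matters for user data from sparse screens.

## Per-target champions, ties, and the network

`per_target_best()` assigns each target its *champion* — the passing
ligand with the most negative score. Ties are resolved by ligand order in
the matrix; ranking ties in `all_compound_pe()` are resolved
lexicographically by ligand id. Both rules are deterministic and
documented rather than clever: on the packaged angiogenesis panel an exact
\(-18.4\) tie on GSK 3beta resolves to punicalagin because its column
precedes isoterchebulin's, which is also how the published champion lists
read.

`build_dtn()` turns the passing cells into a bipartite drug–target
network: one edge per passing pair, weighted by the signed affinity, with
the champion edge per target flagged. Its edge count always equals the
number of passing cells, and a compound's degree equals its
`n_contributing` — two invariants the tests enforce. Export is SIF
(`ligand binds target`) or GraphML with node-kind, affinity and champion
attributes; viewers that need positive weights can request absolute values
at export while the signed affinity attribute is preserved.

## Input dialects and Vina outputs

Affinity tables arrive in two sign conventions: signed kcal/mol, and
unsigned *magnitudes* of negative affinities (common in publication
tables). `read_affinity_matrix()` takes an explicit `matrix_dialect()` —
sign convention plus orientation — and normalises everything to the
canonical form: ligands as rows, signed values, magnitudes negated at
ingest. Nothing is sniffed from file contents; deterministic parsing beats
convenience here, because a mis-guessed sign convention flips every
conclusion. Ids are whitespace-trimmed only, never case-folded or fuzzily
matched.

Raw AutoDock Vina outputs are supported one level down:
`parse_docked_pdbqt()` and `parse_vina_log()` extract per-mode affinities,
`best_affinity()` reduces them to the best (most negative) pose, and
`collect_vina_batch()` walks a directory whose *filenames* carry pair
identity (Vina output embeds no receptor name), feeding
`affinity_from_records()`. Duplicate records for a pair collapse to the
most negative value, mirroring best-pose selection; the best pose is taken
as the minimum rather than "mode 1" so reordered files cannot change a
result. Whether published per-pair affinities are best-pose or averaged is
rarely stated; best-pose is standard practice and is what this package
computes.

## The packaged Triphala screens and their errata

Two published screens of the 15 principal phytochemicals of Triphala
churna (a polyherbal preparation of *Terminalia bellirica*, *Terminalia
chebula* and *Emblica officinalis*) ship as fixtures: `angiogenesis`
(27 targets of the VEGF/VEGFR2 signaling cascade, signed) and
`inflammation` (COX-2 and 5-LOX, magnitudes). Each comes in two variants:

* `*_as_printed` reproduces every published cell verbatim — including two
  angiogenesis cells printed without a minus sign (shikimic acid vs PI3K
  and Hsp27) and one inflammation cell (ellagic acid vs COX-2, magnitude
  23.8) that contradicts ellagic acid's own published PE of \(-17\).
* `*_errata` applies exactly the corrections listed by
  `triphala_errata()`: the two sign cells negated, and the ellagic/COX-2
  cell replaced by \(-8.0\), the unique value consistent with the
  published PE given the \(-9.0\) 5-LOX affinity.

Errata are never applied silently — reproducing the tables *as printed*
is itself a supported use — and the manifest is machine-readable so the
corrections are auditable. The two negated sign cells are corroborated by
an independent published number: with them, shikimic acid's angiogenesis
PE recomputes to exactly its published \(-59.4\). Other small
inconsistencies (several large-PE angiogenesis rows differ from
recomputation by 0.2–2.3 kcal/mol, under 1%) cannot be attributed to a
specific cell from the published record, so no correction is invented for
them; the package computes from the matrix and documents the residual
discrepancy rather than reconciling it. The published per-target champion
counts likewise disagree with the printed matrix in two places (MAPKAPK
and SRC); `per_target_best()` reports what the matrix implies.

```{r}
m <- triphala_matrix("inflammation_as_printed")
all_compound_pe(m)
formulation_pe(triphala_matrix("inflammation_errata"))$pe
```

## The synthetic generator

`simulate_affinity_matrix()` emulates the statistical shape of a screening
matrix, for property tests and for users who want calibrated negative
controls:

* cells are drawn uniformly from `favorable_range`, default
  `c(-20.4, -6)` kcal/mol — the spread observed across the packaged
  screens. Uniform is the simplest distribution matching that spread;
  nothing downstream depends on the shape, only on which side of the
  cutoff a cell falls;
* a `nonbinder_fraction` (default 0.1) of cells is drawn from
  `nonbinder_range`, default `c(-5.9, -3)`, strictly above the
  conventional \(-6\) filter, so the expected fraction of non-passing
  cells is directly controlled;
* selected targets can carry a *planted champion*: a chosen ligand forced
  strictly at least 0.5 kcal/mol below every other cell in its column, so
  recovery by `per_target_best()` is a sharp pass/fail test. To make the
  plant always feasible, the other favorable cells of a planted column are
  drawn from `[low + 1, high]`, reserving the bottom margin; a favorable
  range of width \(\le 1\) errors rather than degrading.

One integer seed fully determines the matrix, and the caller's RNG state
is restored afterwards. The generator mimics only score-matrix structure —
no pose geometry, no correlated targets, no per-ligand score offsets. A
passing planted-champion or dominance test therefore validates the
arithmetic and the selection logic, not the realism of docking scores;
conclusions about real screens still rest on the real matrices.

## Numerical and reporting choices

PE is computed and compared in full double precision; only reports round,
to one decimal, *half away from zero* (`round_half_away()`), matching how
published tables print \(-32.05\)-type values. The delimited matrix format
is UTF-8 with a mandatory header, comma or tab chosen by flag, and a
configurable missing marker (default: empty cell). Degenerate inputs have
defined behavior throughout: empty pose lists, matrices where nothing
passes, targets with no passing ligand, and truncated Vina logs (parsed up
to the truncation, with a warning) are all exercised in the tests.

Test problem sizes were chosen to make the suite a few seconds long while
still exhausting the small-matrix space against a brute-force oracle:
random matrices up to 8x8, 100–200 replicates per property, and the two
packaged 15-ligand panels end-to-end.

## Command line

The same operations are scriptable via the thin wrapper installed at
`system.file("cli", "mtscreen.R", package = "mtscreen")`, with subcommands
`pe`/`rank`, `formulation`, `network`, `sweep`, `parse-vina` and
`simulate`, YAML config files (flags win over the file), and exit codes
0/2/3 for success / input error / validation error.
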