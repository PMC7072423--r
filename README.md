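# mtscreen

Post-processing for multi-target molecular-docking screens: from a
ligand × target binding-affinity matrix to ranked compounds, a
formulation-level score, and the drug–target network.

Virtual screens of multi-compound preparations (polyherbal formulations,
fragment cocktails, natural-product extracts) produce an L × T matrix of
docking scores in kcal/mol, negative when binding is favorable. mtscreen
implements the *prediction efficacy* (PE) statistic for that setting. With
a pass filter at threshold θ (default −6.0 kcal/mol, inclusive):

- **compound PE** — the sum of a compound's scores over all targets
  passing the filter: `PE_c = Σ_{t : s_ct ≤ θ} s_ct`. More negative =
  predicted stronger engagement of the panel; a compound with no passing
  target scores exactly 0.
- **formulation PE** — the sum over targets of the best (most negative)
  passing score among all compounds: `PE_F = Σ_t min_c s_ct`, crediting
  the mixture with its champion binder at each target. `PE_F` is always ≤
  every compound's PE.

Around the statistic the package provides: delimited matrix I/O in two
sign dialects (signed kcal/mol, or unsigned magnitudes of negative
affinities as publication tables often print), AutoDock Vina docked-PDBQT
and console-log parsing down to best-pose affinities, per-target champion
assignment, threshold sweeps, a bipartite drug–target network with SIF and
GraphML export, and a seeded synthetic matrix generator with planted
champions for validation. The Triphala churna screens — 15 phytochemicals
against 27 VEGF/VEGFR2-pathway angiogenesis targets and against
COX-2/5-LOX — ship as fixtures, each both verbatim as published and with a
machine-readable errata variant.

## Worked example

```r
library(mtscreen)

m <- triphala_matrix("inflammation_as_printed")  # 15 ligands x {COX-2, 5-LOX}
head(all_compound_pe(m), 4)
#>   rank       ligand_id    pe n_contributing
#> 1    1     punicalagin -33.8              2
#> 2    2    ellagic acid -32.8              2
#> 3    3  isoterchebulin -32.0              2
#> 4    4 chebulagic acid -30.7              2
```

Punicalagin leads with PE −33.8 kcal/mol: both its affinities (−17.1 on
COX-2, −16.7 on 5-LOX) pass the −6.0 filter and sum. The ellagic acid row
is the one known defect of the published matrix — its COX-2 cell as
printed (−23.8) contradicts its published PE of −17; the
`"inflammation_errata"` variant applies the documented correction (−8.0,
see `triphala_errata()`), under which its PE recomputes to exactly −17.

```r
a <- triphala_matrix("angiogenesis_as_printed")  # 15 ligands x 27 targets
formulation_pe(a)$pe
#> [1] -439

build_dtn(m)
#> drug_target_network: 15 compounds, 2 targets, 29 edges (2 champion)
```

The angiogenesis formulation PE of −439.0 kcal/mol sums the best passing
binder at each of the 27 targets (published total: −436.7, a 0.5%
discrepancy traceable to small internal inconsistencies of the published
matrix). The inflammation network has 29 edges: 30 cells, of which
triacontanoic acid on COX-2 (−4.2) fails the filter; punicalagin holds
both champion edges. `export_dtn(net, "net.graphml", "graphml")` writes a
Cytoscape-readable graph.

A command-line wrapper with subcommands `pe`, `formulation`, `network`,
`sweep`, `parse-vina` and `simulate` is installed at
`system.file("cli", "mtscreen.R", package = "mtscreen")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mtscreen.R", package="mtscreen"))')" \
  pe --fixture inflammation_as_printed --output pe.tsv
```

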