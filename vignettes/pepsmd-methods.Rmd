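---
title: "Models and methods in pepsmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pepsmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepsmd)
```

`pepsmd` packages a two-stage design strategy for anchor-substituted
peptide libraries against class II MHC proteins — structure-based culling
followed by ligand-based statistical molecular design (SMD) — together
with the multivariate machinery needed to read SAR out of the resulting
assay panels. This vignette records the models, the defaults and their
units, the numerical choices, and what the synthetic-data tests do and do
not establish.

## The design pipeline

A library member is a fixed octapeptide template
(`Ac-p260-Ala-Gly-p263-Lys-Gly-Glu-Gln-NH2`, the minimal T-cell epitope
with an unmodified Lys at 264) with free residue choices at the two MHC
anchor positions p260 and p263. `enumerate_library()` builds the full
factorial in deterministic p260-major order; with the 105 commercially
available non-charged building blocks at each position this is 11 025
candidates, and with the 7 + 7 finally chosen residues it is 49.

### Geometric filtering

Docked poses are compared with a reference pose by backbone RMSD. Because
all candidates share the template C-terminus — which dominates the
conformational scatter — poses are first truncated to the varied 260–263
fragment (`truncate_fragment()`). "Backbone" is read as the {N, CA, C}
atom set per residue; the role set is an argument of `backbone_rmsd()`,
so {N, C} or {N, CA, C, O} variants are one keyword away. No superposition
is applied by default: all poses live in a single fixed receptor frame, so
a rigid offset is a real geometric difference. Optional Kabsch
superposition (`superpose = TRUE`) is available for frame-free
comparisons; atom pairing is by (residue index, role) with lexicographic
tie-breaking, and a rigidly transformed copy scores 0 within 1e-9.

The two-stage cull (`two_stage_filter()`) keeps peptides with
RMSD < 3.0 Å for the docked pose and RMSD < 1.5 Å for the externally
energy-minimized pose. Both inequalities are strict: a pose at exactly the
threshold is culled. Energy minimization itself is out of scope — the
filter consumes minimized coordinates produced elsewhere, and errors when
a stage-1 survivor lacks them unless `reuse_docked = TRUE` is set
explicitly.

### Consensus scoring of individual residues

Surviving peptides are rescored by several scoring functions (seven in the
intended workflow). Functions whose raw values increase with predicted
affinity are negated first (`orient_scores()`, by default Goldscore), so
that across all columns lower is better and "best" is uniformly the
minimum. The peptide-level table is then collapsed **per varied position**
(`summarize_position()`): for each residue observed at the position, its
frequency in the culled set plus best, mean, and sample SD of the scores
under each function — 1 + 3 × 7 = 22 parameters. A residue seen once gets
SD 0 rather than a missing value so the matrix stays complete for PCA.

Selection (`consensus_select()`) replaces the visual score-plot judgement
with an explicit rule: PCA on the preprocessed 22-parameter matrix, PC1
sign-oriented from its loadings so that the positive direction means high
frequency, good (low) scores, and low SDs, then `PC1 > threshold`
(default 0, i.e. more favourable than the cohort average). The number of
inspected components and the cutoff were never stated for the original
visual selection, so both are arguments; the default reproduces the
stated qualities of the selected residues (highly ranked, frequent, low
SD) without any manual step.

### Principal properties and D-optimal selection

Each candidate residue set is characterized by physicochemical
descriptors; PCA compresses them into principal properties
(`build_pp_space()`), and each peptide candidate is represented in the
design model matrix by `[1, PP(p260) (k values), PP(p263) (k values)]`
with k = 4 score vectors per position by default — main effects only,
since nothing beyond the property space itself is specified for the
selection model. `fedorov_select()` maximizes det(XᵀX) over N-row subsets
by classic single-point Fedorov exchange: best improving (remove, add)
swap until none improves, ties broken by candidate index, best of 20
random starts (seeded; every run is bit-reproducible, and the log-det
trace is monotone by construction). A ridge of 1e-8 on XᵀX guards the
determinant numerically; selecting fewer rows than model columns requires
an explicit larger ridge.

`coverage_check()` verifies the level balance that makes per-residue
effects estimable downstream (every residue in ≥ 2 of the selected
peptides, the balance the 20-peptide design achieved). A repair pass
(`coverage_repair()`, off by default) greedily swaps candidates to fill
deficient levels, choosing at each step the deficiency-reducing swap that
loses the least log-determinant. The repair is an extension beyond the
original workflow, whose balance may have been curated manually.

## The chemometrics engine

All models preprocess columns by mean-centering and unit-variance scaling
(`mv_preprocess()`); constant columns cannot be scaled and are dropped
with a warning. Indicator columns are scaled like any variable (the
SIMCA-like convention); `scale_x = FALSE` turns this off.

**PCA** (`fit_pca()`) is computed by SVD. R²X(cum) is the cumulative
explained sum of squares. Q²(cum) is estimated by element-wise
cross-validation in the Eastment–Krzanowski style: for each component the
cells of the current (deflated) matrix are deleted in 7 diagonal groups,
the component is re-estimated from the remaining cells by NIPALS with
missing-value handling, the deleted cells are predicted, and
Q²(cum) = 1 − Π PRESSₐ/SSₐ. The commercial packages this emulates do not
document their exact algorithm, so agreement is expected to be
qualitative, not digit-for-digit. **DModX** is the per-observation
residual SD off the model plane divided by the pooled training residual
SD (degrees of freedom corrected for the components and, when centering
is used, the mean): 0 for an observation in the plane, ≈ 1 on average,
large for outliers.

**PLS** (`fit_pls()`) is NIPALS PLS1. The response is centered and
uv-scaled by default, consistent with the treatment of every other
variable, and coefficients are reported on the preprocessed (unitless)
scale as in standard coefficient bar plots. R²Y = 1 − SS_res/SS_tot on
the training data; Q²(cum) comes from leave-one-out cross-validation with
the preprocessing re-estimated inside every fold (so the held-out row
never leaks into the column means). When `n_lv` is omitted it is chosen
to maximize Q²(cum) — the latent-variable count behind a reported model
is rarely stated, and Q²-maximization is the conventional recipe. At full
rank the PLS fit reproduces least squares, which the tests exploit as an
independent oracle (as well as cross-checking scores and predictions
against `mixOmics::pls`).

**Permutation validation** (`permutation_test()`) refits the model under
`n_perm = 100` seeded response permutations and regresses R²Y and Q²
against the absolute correlation between permuted and original response.
The reported intercepts estimate the fit level attainable by chance; the
`valid` verdict uses the conventional limits R²-intercept < 0.3 and
Q²-intercept < 0.05, which are defaults, not dogma — with 14 indicator
variables and n = 20 the R² intercept is naturally high (0.55 on the
shipped A^q data) while the Q² intercept (−1.5 there) is the decisive
diagnostic. Both are exposed, and the full permutation table is returned
for plotting (`autoplot()`).

### Identifiability of indicator coefficients

Every peptide row of the indicator matrix contains exactly one 1 in the
p260 block and one in the p263 block, so the block sums are constant
columns of ones: adding any constant to all coefficients of one block and
subtracting it from the intercept leaves every fitted value unchanged.
Only **within-position contrasts** of the coefficients are identifiable —
which is also exactly what a SAR reading needs ("is Ile better than Gln at
p260?"). The parameter-recovery tests therefore compare estimated
coefficients with the planted vector *centered within each position
block*; comparing against the raw planted vector would penalize the model
for a quantity no estimator could recover.

## The response panel and its encoding

The shipped fixture (`response_panel()`) transcribes the competitive
inhibition and T-cell activation panels for the reference glycopeptide
(peptide 1) and the 20 designed analogues: % inhibition of a biotinylated
marker peptide at 100 and 500 µM against both proteins, and ordinal
response categories for six A^q-restricted and two DR4-restricted
hybridomas. Categories encode the antigen concentration reaching 10 % of
the maximal IL-2 response; `encode_tcell()` maps them to
−log10(concentration/µM), which is strictly monotone in response
strength. "No response" is floored at 1500 µM — ten times the highest
tested concentration, one log-unit below the weakest category — and the
floor is an argument.

Two kinds of missingness occur and are handled differently by default.
Designed peptides classified inactive against A^q (< 30 % inhibition in a
preliminary assay) have no dose-dependent A^q measurements and were never
tested against the A^q hybridomas. These cells are *structurally* missing:
the peptides were skipped because they do not bind. The default encoding
(`missing = "floor"`) therefore enters 0 % inhibition and the no-response
floor — the informative value. Mean imputation after scaling
(`missing = "mean"`) is available for genuinely-missing-at-random cells,
but as a default it would pull known non-binders into the middle of the
response space and erase precisely the binder/non-binder contrast the
combined-response PCA is built to display.

`response_pca()` runs the PCA on the encoded peptide × response matrix
and groups peptides by complete-linkage clustering of the leading score
vectors (3 components, 4 groups by default; both arguments). On the
shipped panel the weak-binder quartet (peptides 10, 13, 16, 17) falls in
one group away from the strong binders, the qualitative pattern the
original analysis reported. The per-concentration hybridoma dose–response
values behind the original combined PCA were never published, so the
ordinal category strengths stand in for them; the function accepts any
extra numeric response columns if such data exist.

The 14-variable PLS on these tables reproduces the qualitative SAR —
Ile dominant at p260, Gln and the indane derivative strongly negative,
several Phe variants tolerated at p263 — with R²Y 0.90 / Q² 0.47 (A^q,
100 µM, inactives at 0 %; all 20 peptides included by default, a config
choice since the original variable set is not fully specified) and R²Y
0.90 / Q² 0.46 (DR4, 500 µM). The anchor assignment of several peptides
is only partly documented; `inst/extdata/glycopeptides.tsv` flags each
(position, residue) pair as confirmed or provisional, so these numbers
are indicative rather than exact reproductions.

## What the synthetic data does and does not show

The generators (`gen_score_table()`, `gen_descriptor_table()`,
`gen_poses()`, `gen_binding_responses()`) produce data with exactly the
structure each stage assumes: additive per-residue latent affinities with
equicorrelated multi-function Gaussian scoring noise; low-rank descriptor
factor models; per-atom Gaussian pose perturbations (expected RMSD
≈ √3 · sd) or exact rigid translations; and linear indicator responses
with Gaussian noise clipped to [0, 100] (the clipping is a deliberate
bounded-assay deviation from pure linearity). All generators require a
seed and are bit-reproducible.

Property tests run at deliberately chosen sizes: 8 + 8 residues for
consensus recovery (latent SD 0.25, scoring-noise SD 0.5, planted
advantage 1.0 = 2 noise SDs, 50 replicates), the 49-candidate /
20-selection / 8-dimensional property space for design checks, 20 × 14
indicator data with response-noise SD 5 (roughly the assay replicate SD
in the transcribed tables) for PLS recovery, and exhaustive-search
comparisons on all instances up to 12 candidates. Passing them shows the
algorithms are correct and well-behaved under their own assumptions; it
does **not** show that real docking scores are additive per residue, that
real descriptor spaces are low-rank, or that binding is linear in residue
presence. Conversely, the quantities that depend on unpublished docking
and descriptor outputs (the 1540-survivor count, the 46/52 selected
residues, the exact multivariate fit statistics of the original models)
are not recomputable from first principles and are covered only by the
property suites and the qualitative fixture checks above.

## Known limitations

- Single-response PLS1 only; multi-block and orthogonalized PLS variants
  are out of scope.
- PCA cross-validation approximates, but will not numerically match,
  closed commercial implementations.
- The Fedorov exchange is the classic single-point variant; for the
  library sizes involved (≤ a few hundred candidates) this is fast and,
  on all tested small instances, exact.
- The pose reader expects one pose per PDB MODEL with standard atom
  naming; exotic records are not parsed.
- Peptides are treated as (p260, p263) pairs on a fixed template; no 3D
  structure or glycan modelling is attempted.
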