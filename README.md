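# pepsmd

Statistical molecular design and SAR analysis for anchor-modified peptide
libraries binding class II MHC proteins.

## The problem

Glycopeptide fragments of type II collagen (CII259–273) bind the murine
A<sup>q</sup> and human DR4 class II MHC proteins through two anchor
residues — position 260 (the A<sup>q</sup> P1 pocket) and position 263 (the
A<sup>q</sup> P4 / DR4 P1 pocket) — and the resulting peptide–MHC complexes
activate the T cells implicated in collagen-induced arthritis and
rheumatoid arthritis. Probing how anchor substitutions change MHC binding
and T-cell recognition requires choosing a small, synthesizable set of
analogues from a combinatorial space of thousands, then extracting reliable
per-residue structure–activity relationships (SAR) from the assay results.

`pepsmd` implements that workflow as composable, tested R functions:

1. **Library enumeration** — the full factorial of candidate residues at
   the two anchors (`enumerate_library()`; 105 × 105 candidates → 11 025
   peptides) and 0/1 indicator design matrices (`encode_indicators()`).
2. **Geometric pose filtering** — backbone RMSD of docked poses against a
   reference pose over {N, CA, C} atoms, with fragment truncation and the
   strict two-stage cull RMSD < 3.0 Å (docked), then < 1.5 Å (after
   external energy minimization) (`truncate_fragment()`,
   `backbone_rmsd()`, `two_stage_filter()`).
3. **Consensus scoring per position** — surviving peptides' scores from
   seven scoring functions (Goldscore sign-flipped so lower is always
   better) collapsed per residue into 22 parameters: frequency plus
   {best, mean, SD} × 7 functions; candidate residues picked from a PCA of
   that matrix (`orient_scores()`, `summarize_position()`,
   `consensus_select()`).
4. **Statistical molecular design** — principal properties (PCA score
   vectors) of each residue set's physicochemical descriptors, a candidate
   model matrix `[1, PP(p260), PP(p263)]` over all combinations, and
   D-optimal subset selection maximizing det(XᵀX) by multi-start Fedorov
   exchange, with per-level coverage checks
   (`build_pp_space()`, `build_candidate_matrix()`, `fedorov_select()`,
   `coverage_check()`, `coverage_repair()`).
5. **Indicator-variable PLS SAR** — NIPALS PLS1 relating residue presence
   to % inhibition, with R²Y, leave-one-out Q², coefficient bar plots, and
   validation by 100 response permutations (`fit_pls()`,
   `pls_coefficients()`, `permutation_test()`).
6. **Response-pattern PCA** — all binding and T-cell hybridoma responses
   combined into one activity fingerprint per peptide, grouped in PCA
   score space (`response_pca()`), with DModX outlier diagnostics.

The chemometrics core (PCA with element-wise cross-validated Q²(cum) and
DModX; PLS1 with LOO Q²(cum)) is self-contained and oracle-tested against
SVD, least squares, and mixOmics. A synthetic-data module
(`gen_score_table()`, `gen_descriptor_table()`, `gen_poses()`,
`gen_binding_responses()`) generates inputs with known ground truth so the
whole pipeline is testable without docking software, and the transcribed
competitive-inhibition / T-cell response panels for the 20 designed
glycopeptides ship as fixtures (`response_panel()`).

## Worked example

Indicator-variable SAR of A<sup>q</sup> binding for the 20 designed
glycopeptides (inactive peptides entered as 0 % inhibition):

```r
library(pepsmd)
library(dplyr)

panel <- response_panel()
table_aggregates(panel)$n_aq_active
#> [1] 11

des <- filter(panel, designed)
x <- encode_indicators(tibble(id = des$peptide, p260 = des$p260,
                              p263 = des$p263))
y <- ifelse(is.na(des$aq_inhib_100), 0, des$aq_inhib_100)

m <- fit_pls(x, y, n_lv = 2)
m
#> PLS model: 2 latent variable(s), 14 predictors
#>   R2Y: 0.9  Q2(cum): 0.475

pls_coefficients(m) |> arrange(desc(coefficient)) |> head(3)
#> # A tibble: 3 x 4
#>   variable position residue coefficient
#>   <chr>    <chr>    <chr>         <dbl>
#> 1 p260.Ile p260     Ile           0.558
#> 2 p263.Mfe p263     Mfe           0.293
#> 3 p263.Thz p263     Thz           0.138
```

The model explains 90 % of the binding variation (R²Y = 0.90) with a
cross-validated Q² of 0.48. Isoleucine carries the largest positive
coefficient at p260 — the P1 pocket strongly prefers the native residue —
while at p263 several phenylalanine variants (m-methyl, 4-thiazolyl,
4-fluoro) are tolerated or beneficial. Permutation validation
(`permutation_test(x, y, n_lv = 2, n_perm = 100, seed = 1)`) gives a Q²
intercept of −1.5: the predictive ability collapses as soon as the
response is shuffled, so the SAR is not a chance correlation.
`autoplot(m)` draws the coefficient bar chart; `response_pca(panel)`
groups the peptides by their combined activity fingerprint.

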