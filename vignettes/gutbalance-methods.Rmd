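---
title: "Models and design choices in gutbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in gutbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gutbalance analyses paired (pre/post surgery) stool-metagenome
relative-abundance profiles together with clinical covariates, outcomes
and cardiopulmonary exercise testing (CPET) parameters. This vignette
explains the statistical machinery, the assumptions behind it, the
parameters worth knowing about, and the design decisions we made where the
methodology left genuine choices open.

## The data model

Every abundance table is held as an `AbundanceTable`: a samples x features
matrix of non-negative fractions, each row closed to sum 1 (percent input
is rescaled at construction; anything else is flagged non-closed and
renormalized explicitly, and renormalization is idempotent). Closure is
central: relative abundances carry only relative information, so all
downstream log-ratio machinery (SparCC, balances, phylum ratios) is
constructed to be invariant to the closure constant. Feature identifiers
may be pipe-separated lineages (MetaPhlAn style); species-level filtering
keeps rows with a species rank and no strain rank, and pathway tables drop
stratified (taxon-attributed) rows, keeping community totals.

Clinical records live in a `ClinicalTable` (one row per patient and
timepoint; binary covariates strictly 0/1; missing numeric values stay
`NA` and are handled complete-case per analysis, never imputed — no
imputation rule would be defensible at this cohort size). The
`PairedDesign` maps each patient to exactly one pre and one post sample;
patients with an incomplete pair are dropped with a warning naming them.

## Diversity and community-level testing

Shannon (`-sum p log p`, natural log) and Simpson in the Gini–Simpson form
(`1 - sum p^2`, bounded in [0, 1], matching how such values are usually
plotted) are computed directly on fractions. Chao1 is a count-based
richness estimator; profiler output is relative, so we multiply by a
configurable library-size constant (default 10,000) and round to
pseudo-counts, with a logged caveat — richness from relative data is
inherently approximate. We use the classic estimator
`S_obs + F1^2 / (2 F2)` (with the `F2 = 0` fallback
`S_obs + F1(F1 - 1)/2`) rather than the bias-corrected variant, because it
is the form whose closed-form values our tests pin down.

Beta diversity is Bray-Curtis,
`d(x, y) = 1 - 2 sum min(x_i, y_i) / sum (x_i + y_i)`, embedded by
classical PCoA (negative eigenvalues are reported, never silently
dropped — Bray-Curtis is semi-metric). The pre/post comparison uses a
one-factor PERMANOVA: `SS_total = sum d_ij^2 / n` partitioned into within-
and between-group components, pseudo-F with `a - 1` and `n - a` degrees of
freedom, and `p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)` over
seeded label permutations (999 by default). For semi-metric distances the
between-group share can be marginally negative under the null; we report
it as computed rather than clamping. The paired design arguably calls for
permutations restricted within patient; the original analysis used the
adonis default of free permutation, so free permutation is our default too
and `strata` restricts swaps to within-patient blocks when wanted.

## Paired differential abundance

Features are first prevalence-filtered: kept if non-zero in at least 10%
of all samples (pre and post pooled), boundary inclusive — a feature seen
in exactly 10% of samples survives. Each surviving feature gets a
two-sided Wilcoxon signed-rank test on the per-patient post - pre
differences: the exact distribution for up to 25 non-zero differences
without ties, otherwise the normal approximation with continuity and tie
correction. Differences below 1e-12 are treated as zero (they are closure
round-off, not biology); a feature with no non-zero differences is flagged
untestable with p = 1 and excluded from multiplicity correction.
Benjamini-Hochberg q-values are computed across all testable features of a
table, and *significance for downstream modules means q < 0.05*. Figure
conventions in this literature often gate on raw p < 0.05 instead; the
`use_fdr = FALSE` switch (and the `network_restrict_no_fdr` pipeline
option) reproduces that reading where a user wants it.

Fold changes are `log2((mean post + eps) / (mean pre + eps))` with `eps`
half the smallest non-zero value of the table — one shared pseudo-fraction
per table, reused by balances and change tables so all log-ratio
quantities are comparable.

The aggregate oxygen-class comparison sums the relative abundance of all
aerobes (or anaerobes) per sample and tests the sums as one paired
variable; the matched-pairs effect size is `r = |Z| / sqrt(n_pairs)` with
Z the tie- and continuity-corrected normal-approximation statistic — the
standard definition compatible with effect sizes reported as percentages.
No authoritative aerobe/anaerobe source exists in the profiler output, so
the annotation map is a user input, matched to table features by the exact
terminal species token (deterministic; unmatched features are `unknown`
and excluded from every class sum).

## SparCC networks and sign-flip edges

SparCC estimates correlations of unobserved absolute ("basis") abundances
from the variation matrix `t_ij = Var(log(x_i / x_j))`. Under sparsity the
basis variances solve a linear system; we solve it densely (the same
solution as the textbook per-component formula, which our tests verify on
small systems) and exclude the most strongly correlated pair
(|rho| > 0.1) from the system iteratively, up to 10 exclusions — the
canonical settings of the method. Each of the 20 inference iterations
resamples the composition by a Dirichlet-posterior draw from pseudo-counts
(relative abundance x depth 10,000, +1 prior); this is simultaneously the
zero-replacement scheme and what makes averaging over iterations
meaningful. Negative solved variances (possible at very small n) are
clipped to a small positive value with a warning. The inner loop is
compiled (RcppArmadillo) and uses R's RNG, so results are reproducible
from a single seed.

Pseudo p-values shuffle every feature's values across samples
*independently* — the permutation scheme is not spelled out in common
usage, and per-feature shuffling is the variant that destroys all
inter-feature dependence while keeping marginals — recompute the full
SparCC estimate per permutation, and apply the add-one rule
`(1 + exceedances) / (1 + permutations)`, so a pseudo p-value is never 0
and 100 permutations bound it below at 1/101.

Pre and post networks are estimated independently on their own sample
subsets. A *sign-flip edge* is a feature pair significant (pseudo-p <
0.05) in both networks with opposite correlation signs, restricted to
differentially abundant features; edge significance is per-condition — we
compare significance masks, not a formal test of the correlation
difference, which is out of scope.

## Partial Spearman screens

Associations between features (abundances, or per-patient log2 changes)
and lung-function/CPET parameters are partial Spearman correlations
adjusted for COPD and cancer type. Cancer type enters as one-hot dummies
(first level dropped) — the only encoding that makes sense inside a
correlation matrix; binary and dummy columns pass through the rank
transform unchanged, continuous columns get average ranks. The partial
correlation is read off the inverse of the rank-correlation matrix,
`rho_xy.Z = -P_xy / sqrt(P_xx P_yy)`, with p-values from
`t = rho sqrt((n - 2 - q)/(1 - rho^2))` on `n - 2 - q` degrees of freedom.
Perfectly rank-correlated pairs short-circuit to rho = +/-1 (the precision
matrix is singular there); collinear covariates raise an error naming the
columns. Cells are computed on pairwise-complete cases with `n_used`
reported per cell. *This screen is deliberately uncorrected for multiple
testing* — it mirrors the raw p < 0.05 reporting convention of such
correlation heatmaps (unlike the differential module) — and the fungal
reporting convention adds a magnitude filter |rho| > 0.65.

## Balance selection

A balance is the difference of log geometric means of two disjoint feature
sets (`proportional` mode is the bare formula; `normalized` multiplies by
`sqrt(k+ k- / (k+ + k-))`, the isometric log-ratio scaling). Forward
selection initialises with the best pair (orientation fixed so the plus
set associates positively with the response), then adds the single feature
to either side that most improves the fit: squared Pearson correlation for
continuous responses, AUC (exact Mann-Whitney rank form) for dichotomous
ones. Equal improvements are broken lexicographically by feature id, plus
side first — determinism over elegance.

Cross-validation geometry is 5 folds x 10 repeats (the referenced
method's convention; configurable), stratified by class for dichotomous
responses. `C_opt` is the smallest number of components whose mean
held-out fit is within one standard error of the best — the 1-SE rule,
favouring parsimony, which matches the very small balances such studies
report. The global balance is refit on all samples at `C_opt`, and the CV
balances at `C_opt` are tallied into component and whole-balance selection
frequencies. Both the in-sample fit of the global balance and the
cross-validated fit are reported side by side, since reported fits in this
literature are ambiguous between the two.

Two small-n estimator choices deserve a note. For dichotomous responses
the cross-validated AUC pools held-out scores within each repeat before
computing AUC (then averages over repeats): with 15 patients a 5-fold test
set holds ~3 samples, and a per-fold AUC over 2-3 pairwise comparisons is
too quantized to be meaningful. For continuous responses the held-out
squared correlation has a positive noise floor of roughly
`1/(n_test - 1)` under a null response; our null-calibration tests check
against that floor, not against literal zero. Overall survival is treated
as a continuous response (optionally log-transformed); censoring
indicators, if present, are ignored with a warning — the balance-vs-OS
association is a correlation, not a survival model.

Phylum-level ratios (`phylumRatio()`) are log-ratios of summed phylum
abundances with the shared pseudo-fraction; the Firmicutes/Bacteroidetes
ratio is the same operation with those two phyla.

## The synthetic generator

`generateDataset()` draws per-feature log-basis abundances multivariate
normally — log-normal basis is exactly SparCC's own generative assumption,
which makes network recovery tests fair — with per-timepoint correlation
matrices, adds planted log2 shifts to the post means, and closes to
compositions. Planted correlations (including sign flips: `+rho` pre,
`-rho` post) are installed into the correlation matrices and repaired to
the nearest PSD correlation matrix by eigenvalue clipping at 1e-8 and
rescaling to unit diagonal — deterministic and standard. Outcomes come
from a planted balance B on the post composition: a VO2-like continuous
response `beta B + gamma covariates + N(0, sigma^2)` (defaults beta = 3,
sigma = 1.5 on a ml/kg/min-like scale, intercept 16), recurrence from a
Bernoulli-logistic model on the centred linear predictor with slope 4
(chosen so the planted classes are strongly separable, as in the cohorts
this emulates), and survival `24 exp(0.3 eta + noise)` months (the
damping keeps survival times in a clinically plausible 6-90 month range).
COPD prevalence 0.4 and a three-category cancer type act as confounders
with modest negative effects on the outcomes. CPET parameters other than
VO2 are independent noise on plausible clinical scales and exist only at
follow-up. One integer seed drives every draw.

The default demo scenario mirrors the target study design: 15 patients,
200 species-level features, 32 planted shifts (17 up, 15 down, 4-fold),
a 2-vs-3 species balance driving all three outcomes, and six planted sign
flips of |rho| ~ 0.8. Planted signal features are placed at *typical*
abundance (log-mean spread halved relative to background): correlations of
features near the sampling-depth floor are attenuated by SparCC's
resampling noise, and planting the truth there would test abundance
extremes rather than method behaviour. The generator intentionally does
*not* model sequencing count noise (negative binomial, zero inflation),
within-patient correlation of pre and post draws, or fungal ITS
specifics — so passing recovery tests demonstrate correctness of the
estimators under their own assumptions, not robustness to profiler
artefacts.

## Reproducibility and problem sizes

`runPipeline()` executes all stages from one config; a single top-level
seed deterministically derives per-stage sub-seeds from the stage name, so
stages are independently rerunnable and the analysis TSVs are
byte-identical across reruns (the manifest additionally records wall
times, which of course differ). The test suite exercises the stack at
sizes chosen to make planted truths identifiable while keeping the suite
quick: correlation recovery at 50 features x 200 samples over 50 seeds,
sign-flip recovery at 40 features x 200 samples per condition, PERMANOVA
null calibration over 500 replicates at n = 20, balance recovery and null
calibration at 50 patients x 12 features over 50 seeds each, and the
oracle-equivalence checks (dense basis solve, rank-residual partial
correlations, exhaustive best-pair search) at small dimensions where brute
force is exact.

## Known limitations

- PERMANOVA is one-factor only; multi-factor designs need adonis-style
  modelling outside this package.
- Pseudo p-values are uncorrected for the number of edges; at 100
  permutations the resolution is 1/101, and network comparisons inherit
  both properties.
- The correlation screen is exploratory by design (no FDR), matching its
  reporting convention.
- Survival is correlated, not modelled; censoring is ignored.
- At n = 15 the cross-validated fits of selected balances are noisy and
  often far below the in-sample fit; the robustness frequencies are the
  more trustworthy output at that scale.
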