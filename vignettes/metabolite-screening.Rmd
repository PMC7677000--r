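---
title: "Screening protective bacterial metabolites: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening protective bacterial metabolites: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbioscreen)
```

# The problem

Onion maggot (*Delia antiqua*) larvae carry a bacterial community on their
cuticle that protects them against the entomopathogenic fungus *Beauveria
bassiana* — an instance of colonization resistance. Six culturable strains
(labelled B108, B253, B263, B424, B505, B585) inhibit the fungus; a seventh,
*Klebsiella oxytoca* B313, does not. The screening question is: which
bacterium-derived metabolites carry the protection? `symbioscreen`
implements the computational side of that screen, from untargeted LC-MS
feature tables through candidate annotation, in-situ quantification,
cocktail formulation, bioassay summarization, and survival analysis. The
numbered scripts under `analysis/` run the stages in order on synthetic
data; every computation they perform lives in the package and is unit
tested.

# Feature-table hygiene

The pipeline starts at the feature table (one intensity per feature and
sample; a feature is an m/z–retention-time pair, identified as
`M<mz>T<rt>` with both values rounded half-up to integers). Three hygiene
steps precede any statistics:

* **QC filtering** (`qc_filter`). "High-quality" features are defined here
  as: relative standard deviation across the pooled-QC injections at most
  30% (sample SD over mean, linear scale), and presence in at least 50% of
  the biological samples. Both thresholds are configurable
  (`qc_filter_config`); the combination is standard untargeted-metabolomics
  practice. RSD uses the n−1 standard deviation so tests are exact.
* **Imputation** (`impute_missing`). Absent values become half the
  feature's minimum present intensity — a simple, monotone surrogate for
  below-detection-limit censoring. Features absent everywhere are dropped
  with a warning.
* **Normalization** (`normalize_intensities`). Each sample is scaled so
  its total (or median) intensity equals the across-sample mean of that
  statistic. The drivers use **median** normalization: at the panel sizes a
  synthetic demonstration can afford (hundreds to a few thousand features),
  a handful of strongly differential features measurably inflates a
  sample's total intensity, and total-intensity scaling would then bias the
  very fold changes the screen thresholds on. With tens of thousands of
  features the two are nearly equivalent.

# Multivariate models

PCA (`pca`) is the overview/outlier tool: log10, column centering,
optional unit-variance scaling, then an SVD with a deterministic sign
convention (largest-magnitude loading positive per component), so score
plots are reproducible run to run.

PLS-DA (`plsda_fit`) is the supervised workhorse, implemented from scratch
as NIPALS PLS1 on a centered 0/1 class code: per component the unit-norm
weight vector $w_a \propto X^\top y$, score $t_a = X w_a$, loadings
$p_a = X^\top t_a / t_a^\top t_a$ and $q_a = y^\top t_a / t_a^\top t_a$,
then deflation of both $X$ and $y$. The per-component explained response
sum of squares $SS_a = q_a^2\, t_a^\top t_a$ feeds the VIP score

$$\mathrm{VIP}_j = \sqrt{\,p \cdot \frac{\sum_a SS_a\, w_{ja}^2}{\sum_a SS_a}\,},$$

whose squared values average to exactly 1 over the $p$ features — an
identity the test suite asserts on every fitted model. Two components are
the default for screening models; at the limit of full rank the fit
reproduces least-squares predictions, which the tests check against `lm`.

The permutation diagnostic (`permutation_test`) guards against overfitting:
labels are permuted (at least 20 times), each permuted model's $R^2$ and
K-fold cross-validated $Q^2$ (stratified folds, default $K = 7$, fold
assignment deterministic in the seed) are recorded, and the permuted $Q^2$
values plus the original model (at label correlation 1) are regressed on
the absolute correlation between permuted and original labels. The model
passes when every permuted $Q^2$ sits below the original and the
regression line crosses the vertical axis below zero.

# The screening cascade

Candidates emerge from a two-step cascade per strain and ion mode:

1. **Step I — versus the medium blank.** A feature is differential for a
   strain when its fold change versus LB is at least 2, its Welch-test
   p-value (on log10 intensities) is below 0.05, and its VIP in the
   strain-versus-LB PLS-DA is at least 2. Fold changes are ratios of
   arithmetic group means on normalized *linear* intensities — that is the
   scale on which the published candidate ratios (12.3 to 1,834.9) live —
   while p-values are computed on the log scale for variance
   stabilization. B313's own differential set is computed with the same
   rule.
2. **Union.** The strain's passing set is merged with B313's (stable
   order: strain features first).
3. **Step II — versus the non-protective control.** Within the union, a
   feature is retained when its strain/B313 fold change is at least 10,
   again with p < 0.05 and VIP ≥ 2 from the strain-versus-B313 model.

No multiple-testing correction is applied by default (the published
candidate table reports raw p-values); `screen_config(p_adjust = "BH")`
enables Benjamini–Hochberg. Candidate rows are keyed by feature id within
ion mode; cross-mode identity is never assumed.

A property worth knowing when designing experiments with this screen: VIP
scales with the size of the feature panel. With $p$ features and a handful
of informative ones, an informative feature's VIP is roughly
$\sqrt{p \cdot \text{(its share of explained response)}}$, and on very
small panels (tens of features) even a feature with a 20-fold effect can
sit below the VIP = 2 cutoff simply because the panel is small. The test
suite therefore exercises recovery on panels of several hundred features,
the smallest size that behaves like a realistically sized untargeted run;
the `analysis/` drivers use 1,000. Even there the screen is conservative:
with a dense background of shared bacterial metabolites an occasional true
candidate lands just under the VIP cutoff, which mirrors how the published
candidates themselves span VIP 2.18–6.40, close to the threshold.

# Annotation

Candidates are matched against a compound library by accurate mass within
10 ppm, modeling only protonation adducts: expected m/z is the
monoisotopic mass plus 1.007276 Da in positive mode ([M+H]+) or minus it
in negative mode ([M−H]−). Library masses are computed from molecular
formulas, not the nominal table m/z. Fragment-spectrum confirmation is out
of scope; the packaged library carries the ten candidate compounds plus
the four nutrient compounds (l-tyrosine, l-sorbose, l-leucine, l-valine)
that are excluded before bioassays. Isobaric pairs — glutaric and
ethylmalonic acid share C5H8O4 — produce deliberately ambiguous
annotations: both are kept and flagged rather than silently choosing one.
`finalize_candidates` de-duplicates by CAS across strains and modes.

# In-situ quantification

Pooled washes (20 larvae in 1.5 ml) give extract concentrations; per larva
that is `extract_conc × 0.0015 / 20` mg, and dividing by the body-surface
water film — 0.0920 mg per second-instar larva, taken at density 1 g/ml,
i.e. 9.2e−8 liters — gives the in-situ concentration in mg/liter. Both
conversions are linear and exactly invertible, which the synthetic
generator exploits: `simulate_quant_dataset` runs the model in reverse
with mean-one log-normal noise of a chosen coefficient of variation, so at
`cv = 0` quantification returns the input concentrations to machine
precision.

Axenic/nonaxenic comparisons use a test-selection tree: Lilliefors-form
Kolmogorov-Smirnov normality checks per group at α = 0.05 (the named KS
test applied the way statistics packages apply it when the normal's
parameters are estimated), then Levene's test to choose between the pooled
and Welch t statistics; any normality failure falls back to the
Mann-Whitney U test with normal approximation and tie correction. Values
below the detection limit are carried as 0 with a `detected` flag.

# Cocktail, doses, bioassays

`build_recipe` includes every metabolite whose mean nonaxenic
concentration reaches 0.1 mg/liter (undetected metabolites excluded).
Applied to the published means this reproduces the seven-organic-acid
formulation exactly — kynurenic acid at 0.1 mg/liter sits precisely on the
cut, hypoxanthine (0.001) and ethylmalonic acid (0.0) fall out, thymine
was never detected. Whether the original formulation used such a threshold
or judgment is not stated anywhere; the 0.1 mg/liter rule is a
reconstruction that reproduces the printed recipe and is configurable.

`dose_series` scales the recipe by $2^1, 2^0, \dots, 2^{-6}$ plus a zero
control. Bioassay responses are summarized relative to the control mean:
germination as fractions, growth as **net** colony diameter (observed
diameter minus the 3-mm agar plug — the source protocol never states
whether the plug is subtracted; subtracting it is the dimensionally
sensible choice and is documented here). The omnibus comparison reuses the
normality/homogeneity tree: ANOVA + Tukey HSD, Welch ANOVA + Dunnett T3,
or Kruskal-Wallis + Bonferroni-corrected pairwise Mann-Whitney. Dunnett's
T3 is hand-implemented (no installed package provides it): pairwise Welch
statistics judged against the studentized-maximum-modulus bound in its
Sidak product form, slightly conservative for correlated comparisons.
Groups get a compact letter display (insert-and-absorb algorithm), ordered
by decreasing mean.

One behavior of the tree deserves a note. With $k$ dose groups each
checked for normality at α = 0.05, truly normal data passes all checks
only $0.95^k$ of the time, so a fraction of well-behaved datasets
legitimately routes to Kruskal-Wallis; and Bonferroni-corrected pairwise
Mann-Whitney tests at $n = 6$ replicates across nine dose groups cannot
reach significance at all (the smallest attainable corrected p exceeds
0.05), so that branch can return an emphatic omnibus rejection with an
entirely tied letter display. Both are properties of the published
decision rule, not defects; the tests assert branch selection rates
consistent with them.

# Survival

Kaplan-Meier estimation and the two-group log-rank test are delegated to
the `survival` package behind `km_estimate`/`logrank_test`, with the
standard tie convention (all deaths at a time count against that time's
risk set; censoring at an event time is processed after the event).
Subjects alive at the last observation are censored there — the drivers
censor at day 20, the pupation horizon, since the original censoring
convention at pupation is not recoverable from the text. A zero-variance
comparison returns χ² = 0, p = 1 with a warning rather than an error. The
tests verify the estimator against hand-computed product limits and the
test statistic against a brute-force O−E/variance tabulation.

# What the generators emulate, and what they do not

`simulate_feature_table` draws log10-normal intensities: a per-feature
baseline (mean 5, SD 0.5 on the log10 scale — the source reports no
dispersion, so these are free parameters of the generator), within-group
replicate noise of 0.08 log10 units, QC injections as the grand mean of
the biological samples perturbed by 0.02 log10 units (QC samples are
pooled aliquots of all extracts, so the grand mean is their natural
center), and uniform completely-at-random missingness. Planted candidates
raise their target strains by `fc_vs_lb` over LB and set B313 so the
strain/B313 ratio is `fc_vs_b313`; six replicates per group throughout.
Event times are exponential, discretized upward to the 2-day observation
grid. Germination counts are binomial; colony diameters normal.

Not emulated: chromatographic peak shapes, retention-time drift, batch
effects, isotope patterns, intensity-dependent missingness, or correlated
features. Passing tests on these generators therefore demonstrate the
correctness of the screening arithmetic and the statistical machinery
under the stated model — not robustness to the full messiness of real
LC-MS data.

# Problem sizes and numerical conventions

The test suite runs the recovery property on 300-feature panels over 50
seeds, type-I error checks on 500 simulations each (log-rank and the
omnibus tree), the permutation diagnostic's null behavior on 100 datasets,
and oracle equivalences (PCA eigendecomposition, an independent NIPALS
implementation, least-squares limits) on instances of at most 8×8 at
tolerances of 1e−6 to 1e−8; the whole suite completes in well under a
minute of compute per property group. Other conventions: round-half-up in
feature ids (matching the published integer ids); ratios on linear,
p-values on log10 intensities; deterministic SVD signs; stratified,
seed-deterministic CV folds with K reduced (never below 2) when a class is
small; all randomness behind explicit integer seeds with no hidden global
state.
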