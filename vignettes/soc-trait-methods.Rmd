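---
title: "Methods: from heterogeneous soil profiles to trait-driven SOC inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from heterogeneous soil profiles to trait-driven SOC inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soctraits)
```

## The scientific problem

How much organic carbon a forest soil stores depends far more on *where*
the forest grows (climate, soil, land-use history) than on *which* trees
grow there. Yet for management the tree-species lever is the one we
control. The analysis implemented here isolates that lever: in
common-garden-like sites where several mono-specific stands share the
same soil and climate, the between-stand differences in soil organic
carbon (SOC) can be attributed to the species — summarised through their
functional traits — and to stand biomass, with site conditions entering
only as modifiers of those effects.

The package implements the full chain: soil-profile harmonisation,
study weighting, site-relative normalisation, trait-index construction,
phylogenetic distances, mixture overyielding, and the inference layer.
A synthetic multi-site generator with known ground truth makes every
stage testable end-to-end.

## Equivalent-soil-mass harmonisation

Comparing SOC pools over fixed *depths* is biased: SOC lowers bulk
density (BD), so a carbon-rich 0–10 cm layer holds less mineral soil
than a carbon-poor one. All pools are therefore expressed on an
equivalent-soil-mass (ESM) grid of 1000 Mg~soil~ ha^-1^ increments
(ESM.0000-1000, ESM.1000-2000, ...; roughly 10 cm each at typical
forest-soil BD of 0.8–1.5 kg L^-1^). `to_esm()`:

* computes each measured layer's dry mass (100 x BD x thickness, in
  Mg ha^-1^) and SOC pool (mass x concentration / 1000, Mg C ha^-1^);
* interpolates cumulative SOC against cumulative mineral mass at the
  1000-increment breakpoints — piecewise-linear by default, because a
  chord through measured totals is the only interpolant fully
  determined by the data (a monotone Hyman cubic is available via
  `interpolation = "monotone"`);
* never extrapolates below the deepest measured mass; partial
  increments are reported missing;
* keeps the forest floor outside the mineral-mass ledger.

`pool_topsoil()` sums the first three increments into the topsoil pool
(ESM.0000-3000) and adds the forest floor for the combined pool — the
response used throughout the analysis. Deeper increments are carried
but not analysed: species effects develop over decades and concentrate
in the top ~30 cm.

Missing BD is filled by `estimate_bd()`: a fixed 0.1346 kg L^-1^ for
forest floors; a texture+SOC rule for mineral layers at SOC
<= 20 mg g^-1^; an SOC-only rule above; and a log-log regression of BD
on the layer's SOC pool (`fit_pool_fallback()`) when only pools are
reported. The two rule forms ship as replaceable configuration — their
coefficients are site-compilation-specific, and tests inject known
couplings instead of trusting defaults. SOM-only records convert via
the fixed SOC = SOM / 2. Layers at or above 200 mg C g^-1^ are
rejected as organic soils (Histosols) outside the model's domain.

A stand reporting a single thick layer cannot be interpolated; it is
split by the mean relative SOC distribution with mass — 45%, 30%, 25%
over the first three increments. For masses beyond 3000 Mg ha^-1^ the
three fractions are extended by their fitted geometric decay and
renormalised, flagged as low-confidence provenance; only the 3000 case
is anchored in compiled data, so the extension is a documented
modelling choice. Note one deliberate asymmetry: a *multi-layer*
uniform profile reproduces the constant concentration exactly in every
full increment, while a *single* thick uniform layer is split 45/30/25
— the device encodes the typical downward decline when within-layer
information is absent.

Degenerate inputs error loudly: overlapping layers, gaps above 0.5 cm
(configurable), profiles not starting at the surface, unrecoverable BD.

## Study weights

Each study's reliability enters as a case weight `W_data`: the mean of
a design-class weight (common garden 1.00, comparative plantation
0.66, spontaneous 0.33, heterogeneous 0.00), `log10(blocks)` and
`log10(profiles)/2`, each clamped to [0, 1], with the mean floored at
0.05 so no study is silently discarded. Clamping before averaging is
the only reading consistent with all criteria remaining in [0, 1] for
arbitrarily replicated designs. Missing block or profile counts are
treated as 1 (weight 0) and flagged.

## Site-relative response ratios

Between-site variability dwarfs the within-site species signal, so all
responses and predictors are normalised per site:
`rr = ln(value / site mean)`, the site mean being the unweighted
arithmetic mean over the site's non-missing stands (weights are
constant within a site, so weighting could not change it). Natural
logarithms are used, following the lnRR convention of meta-analysis;
every downstream statistic is base-invariant. The identity
`mean(exp(rr)) = 1` holds exactly per site and is tested. Sites with
fewer than two measured stands for a variable contribute nothing;
recomputation per variable pair maximises usable records.

Two-class contrasts (angiosperm vs gymnosperm, and similar) first
average stands within class per site — otherwise a site with four
conifers and one broadleaf would pseudo-replicate the conifer signal —
then form `ln(mean_A / mean_B)`, one value per site.

## Trait table and the PES index

Trait observations are collapsed to species means after removing
duplicated sources; interconnected traits close through the
C:N = C/N identity (computed values carry `closed` provenance,
inconsistent complete triplets are flagged but measured values kept);
remaining gaps fill by cross-trait regression (`gap_fill_regression()`,
OLS on species with both traits, >= 8 required) and, for leaf C, by
hierarchical clade means (genus, then family, then class).

The Plant Economics Spectrum (PES) index is the score on the first
axis of a PCA over the standardised species-by-trait matrix. Because
the matrix is gappy, missing cells are first completed by iterative
low-rank SVD imputation (`impute_pca()`): standardise on observed
cells, initialise gaps at column means, and alternate rank-k
reconstruction with gap replacement. The rank is chosen by
cell-holdout cross-validation (5% of observed cells, 10 repeats, fixed
seed, rank capped at 5). Convergence is declared when imputed cells
stabilise (1e-7 max change) *or* when the observed-cell reconstruction
error plateaus — the latter matters because near-degenerate principal
subspaces can rotate indefinitely without changing the fit. Observed
cells are never altered, and with no missing cells the path reduces
exactly to plain PCA.

PCA axes have arbitrary sign, so the axis is oriented to load
positively on A~max~ (leaf maximum photosynthetic capacity): positive
scores mean acquisitive species (high A~max~, SLA, leaf N), negative
scores conservative ones (high LDMC, lignin). Under this convention
the expected SOC–PES slope is negative — conservative species
accumulate SOC. Categorical traits stay out of the PCA. The Biomass
index uses the same machinery anchored on standing biomass.

## Phylogenetic distances

Distances between species are *MRCA crown ages* in Myr, not path
lengths: the angiosperm–gymnosperm "distance" of 350 Myr is the split
age, and doubling it (the cophenetic convention) would not match that
anchor. This choice is prominent in the API because the factor-2
alternative is the default in most tree software; the newick export is
cross-checked against `ape` cophenetic distances divided by two.

The tree is defined by a lineage map (species, genus, family, order,
class) plus a crown-age table. Only two ages are fixed reference
values — 350 Myr (angiosperms vs gymnosperms) and 273 Myr (Cupressales
vs Pinales); the shipped CSV marks all other ages as editable
placeholders, and tests rely only on the two anchors and on synthetic
trees. When a pair's MRCA clade lacks an age, the fallback is half the
crown age of the smallest containing clade with a resolved age,
flagged `half_crown_fallback`. Unranked intermediate levels (an `NA`
order, say) are skipped, not treated as splits.

## Mixtures

For a 50–50 mixture AB of mono-specific stands A and B at the same
site, overyielding is `ln(AB / mean(A, B))` and transgressive
overyielding `ln(AB / max(A, B))` (always the smaller of the two);
absolute combined pools are used, not ESM grids, since mixture studies
rarely report full profiles. Tests against zero run on one record per
site — sites with several mixtures contribute their mean, the same
anti-pseudo-replication rule as the categorical contrasts. Zero
variance yields a flagged degenerate report, not an exception. The
link from biomass overyielding to SOC overyielding is a
`W_data`-weighted least-squares slope.

## Inference layer

Driver ranking uses random-forest permutation importance (%IncMSE, 500
trees, `mtry = ceiling(p/3)`, fixed seed) with the direction of each
effect taken from a univariate weighted slope; the forest itself is
unweighted because the ensemble implementation accepts no case
weights, which is documented rather than worked around.

The interaction model is
`SOC ~ (Trait x Biomass) + {(Trait + Biomass):(f_climate + Sand + pH [+ PLU])}`,
fitted by weighted least squares with greedy forward selection by AIC
over that explicit candidate list. Site conditions never appear as
main effects: site-normalised responses average to ~zero within each
site, so site-constant covariates carry no main-effect information.
This marginality violation is intentional, which is why selection is a
small purpose-built loop rather than `stats::step()` (which enforces
hierarchy). The climate covariate `f_climate` (favourability,
increasing with concomitant warmth and moisture) is treated as a
supplied site property — its defining formula lives in external
references and is not re-derived here. A PLU-free variant exists
because past land-use is confounded with favourable site conditions.
Collinear covariate blocks are reduced beforehand
(`collinearity_screen()`): components of the |r| >= 0.7 graph, with
the conventional representative (sand for texture, f_climate for
climate) or, failing a name match, the member loading highest on the
block's first principal component.

Two-class contrasts gate on Shapiro–Wilk normality at alpha 0.05 — t
test if normal, Wilcoxon otherwise, both two-sided — with Bonferroni
correction within each reported family. Validation stands measured
only to ESM.0000-1000 or ESM.0000-2000 (plus forest floor) are
rescaled to the calibration scale by the fixed factors 1.115 and
1.064.

## The synthetic generator: what it emulates, and what it does not

`simulate_dataset()` draws the study conditions the analysis assumes:
136 sites bearing 2–5 mono-specific stands (~480 stands), mixtures at
14% of sites (~19 mixture sites), matching the scale of the global
compilations this kind of analysis is run on. Species traits follow a
one-factor latent PES model (`trait = baseline + loading x factor +
noise`); log SOC is a site baseline plus `beta_trait x (1 +
harshness_interaction x harshness) x PES + beta_biomass x biomass`
(defaults -0.15, 1.0, +0.10), so the trait effect doubles from the
most favourable to the harshest site. The SOC depth profile is a
continuous exponential in cumulative mass (surface mean 25 mg g^-1^,
decay 4e-4 per Mg ha^-1^) with a monotone BD(SOC) coupling that keeps
mineral BD inside 0.8–1.5 kg L^-1^; measured layers are *exact
aggregates* of that continuous truth, so harmonisation can be scored
against closed-form integrals. Bulk-density missingness is
site-homogeneous (studies either report BD or don't), trait
missingness is per-cell MCAR, and all randomness flows from one seed
through deterministic per-table substreams.

Deliberately absent: spatial autocorrelation between sites, intraspecific
trait variation, non-exponential (e.g. bimodal podzol) carbon profiles,
measurement bias correlated with site conditions, and TRY-scale trait
breadth (10 traits suffice to exercise the index machinery). Passing
recovery tests therefore demonstrates the *pipeline's* correctness
under its stated assumptions, not robustness of the science to
violations of them.

## Numerical choices and problem sizes

* ESM interpolation error is bounded by layer coarseness; with <= 5 cm
  layers full increments land within ~2% of the analytic truth, and
  the generator samples field-realistic schemes (5–15 cm layers).
* Disaggregation conserves mass to 1e-9 relative; cumulative curves
  are monotone by construction.
* EM imputation: tol 1e-7 on imputed cells, objective plateau 1e-10,
  3000 iterations max; CV uses lighter settings (300/1e-6).
* Forward AIC stops when no candidate improves AIC by more than 1e-8;
  aliased terms are dropped with a warning.
* Recovery suites: the generating trait effect is estimated on the
  unit latent scale as the PES main effect plus the PES-by-climate
  interaction at `f_climate = 1` (i.e. harshness 0), over 50 generator
  seeds; interaction-sign recovery uses 20 seeds at 120 sites; the
  mixture-test size check uses 10,000 replicates at n = 19. These
  sizes give Monte-Carlo noise well inside the asserted margins while
  keeping the full validation run to a few minutes.

## Interfaces

All computation lives in the package functions; the numbered scripts
under `analysis/` are thin narrative drivers that run the chain on a
generated dataset and write their tables under `results/`, and
`scripts/acceptance.R` recomputes the headline validation quantities
from scratch. No separate command-line binary is provided — the
functions, the analysis scripts and this vignette are the interface.

## Known limitations

* Pedo-transfer defaults are generic shapes; serious use requires
  coefficients calibrated to the compilation at hand.
* Clade ages other than the two fixed anchors are placeholders.
* The random-forest stage ignores case weights (implementation limit,
  documented above).
* Single-thick-layer disaggregation assumes the mean relative SOC
  distribution applies to the stand at hand; provenance flags make the
  assumption auditable downstream.
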