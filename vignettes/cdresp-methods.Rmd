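---
title: "Identifying cadmium-responsive soil bacteria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cadmium-responsive soil bacteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdresp)
```

Soil cadmium reshapes bacterial communities in two observable ways: it
shifts which taxa are present (composition) and which taxa are metabolically
stimulated when Cd is added (activity). `cdresp` implements both lines of
evidence and the set logic that combines them, for the setting of cacao
rhizosphere soils sampled across farms spanning a natural Cd gradient of
0–4.3 mg kg⁻¹, with paired control/Cd-spiked isothermal microcalorimetry
(IMC) assays run for 80 h at three sampling timepoints (start S, activity
peak P, end E).

## 1. Heat-curve kinetics

An IMC thermogram records heat flow (mW) from one sealed ampoule.
Integrating flow over time (trapezoid rule; 1 mW sustained for 1 h releases
3.6 J) gives cumulative heat $Q(t)$ in joules, which we model with the
modified Gompertz growth curve in its directly interpretable
parameterization:

$$Q(t) \;=\; Q_{\max} \exp\!\left\{-\exp\!\left[\frac{\mu_{\max} e}{Q_{\max}}(\lambda - t) + 1\right]\right\}$$

* $Q_{\max}$ (J): asymptotic total heat — the community's total metabolic
  output;
* $\mu_{\max}$ (J h⁻¹): maximal heat-production rate, equal to the peak of
  the flow curve;
* $\lambda$ (h): adaptation (lag) phase.

Two quantities are derived, never fitted: the time to peak activity
$\mathrm{TTP} = \lambda + Q_{\max}/(e\,\mu_{\max})$ (where the model's
derivative is maximal — an exact identity of this parameterization, checked
to 10⁻⁶ relative on every fit), and the mean log-phase rate
$\mu = [Q(\mathrm{TTP}) - Q(\lambda)]/(\mathrm{TTP} - \lambda)$. The
distinction matters because "growth rate" and "maximal growth rate" are
separate kinetic summaries in calorimetry practice; we define $\mu$ as the
average rate between the end of the lag and the activity peak, and the
formula is recorded here because the literature often leaves it implicit.

**Fitting.** Nonlinear least squares (Levenberg–Marquardt via minpack.lm)
on the *cumulative* heat curve, not raw flow: integration damps instrument
noise, while flow-domain residuals remain available through
`summary()`. Multi-start initialization guards against the lag/rate
trade-off: $Q_{\max}$ starts at the final observed heat, $\mu_{\max}$ at
the maximal finite-difference flow, and $\lambda$ at 0 h, at the time the
curve reaches 10% of final heat, and at the 37 h fallback sampling hour;
the best-RSS start wins, ties broken toward the smaller lag. Curves whose
final heat is not positive are reported unfit rather than forced — negative
recorded flows (baseline dips, endothermic soil chemistry) are retained in
integration because negative paired deltas are scientifically meaningful.

On 50 synthetic curves with $Q_{\max} \in [0.5, 5]$ J,
$\mu_{\max} \in [0.01, 0.2]$ J h⁻¹, $\lambda \in [5, 30]$ h, white noise at
1% of $Q_{\max}$ on the heat curve, and 0.5 h sampling over 80 h (the
assay's own resolution and duration), median parameter recovery error is
well under 1% per parameter (see `scripts/acceptance.R`).

**Paired deltas.** Each control ampoule is the activity baseline for its
spiked partner. On the common time support (finer grid, linear
interpolation of the coarser member) we compute $\Delta$AUC (J),
$\Delta Q_{\max}$, $\Delta\mu_{\max}$, and call a sample
*activity-responsive* when $\Delta\mathrm{AUC} > 0$. The Cd immobilization
ratio is implemented as the spiked/control final-heat ratio; this is a
stated proxy — the original index is defined in prior calorimetry work and
its exact formula is not reproducible from the sources available here, so
the proxy is labelled as such everywhere it appears.

**Peak detection** smooths flow with a centred 2 h moving average and takes
the global maximum, requiring it to be interior to the record and at least
0.1 mW (configurable) above the smoothed minimum; otherwise the sampling
rule falls back to hour 37.

## 2. Compositional differential abundance

Sequencing counts are compositional: each sample observes its community
through an unknown sampling fraction. The estimator here follows the
bias-corrected (ANCOM-BC-style) approach in a deliberately simplified,
fully self-contained form:

1. **Structural zeros.** A taxon entirely absent from one group is flagged
   and excluded from modelling (its fold change is not estimable) but kept
   in the report.
2. **Sampling-fraction offsets.** With $y_{ij} = \log(c_{ij} + 0.5)$, we
   alternate per-taxon group means of offset-corrected logs with per-sample
   offsets set to the median residual, damping the update by half because
   the raw alternating-median iteration can two-cycle, and re-centring
   offsets within each group every pass (a per-group offset constant is not
   identified — it trades off against the group means — and drifts without
   this pinning). Convergence: max offset change < 10⁻⁶, at most 100
   iterations.
3. **Residual bias.** Because offsets are identified only within group,
   the *between*-group compositional bias survives step 2 as a common
   shift of every taxon's raw contrast coefficient. It is estimated
   robustly as the median coefficient across tested taxa and subtracted —
   valid while fewer than half the taxa truly change, which is the regime
   this design targets (≈28% planted responders).
4. **Per-taxon tests.** OLS of the corrected logs on the contrast plus any
   fixed-effect covariates (farm, by default, in the field analysis);
   $W = \widehat{\mathrm{lfc}}/\mathrm{se}$ referred to the $t$
   distribution with the residual degrees of freedom. The $t$ reference
   rather than the normal is a deliberate choice: at the assay's 6–10
   replicates per arm and timepoint the normal is anti-conservative enough
   to flood the null timepoint analysis with false enrichments, while at
   the field survey's ~90 samples per Cd category the two are
   indistinguishable.
5. **Multiplicity.** Benjamini–Hochberg across taxa; direction assigned at
   $q \le \alpha$ (default 0.05).

This is not a port of any published estimator, and no numerical equality
with reference implementations is claimed; its acceptance is statistical —
under the global null (200 taxa, 20+20 samples, 25 replicates) the mean
number of discoveries at $q \le 0.05$ stays below 1, and with 10% of taxa
planted at $|\mathrm{lfc}| = \ln 4$ (30+30 samples) recall exceeds 0.8 with
empirical FDR below 0.1. Counts can be aggregated to any lineage rank
(phylum, genus, …) before testing; aggregation is a pre-step, the model is
unchanged.

## 3. Community statistics

Implemented from first principles (vegan serves only as an independent
cross-check in the test suite):

* **Alpha diversity**: observed richness; bias-corrected Chao1
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (defined even without doubletons —
  the variant is stated because "Chao1" alone is ambiguous); Shannon
  entropy in natural log.
* **Kruskal–Wallis + Dunn letters**: omnibus H with tie correction, Dunn z
  on pooled ranks, BH over all pairs, and a compact-letter display built
  from maximal cliques of the non-significance graph. Letters are
  *protected* by the omnibus test — they split only when the
  Kruskal–Wallis p value is itself below α — which keeps the null rate of
  spurious letter splits well under 5%; the pairwise table is always
  reported.
* **Bray–Curtis** on relative abundances by default: library sizes in this
  design span 2788–25083 reads (ninefold), so raw-count dissimilarities
  would be dominated by depth. A config switch restores raw counts.
  Depth-evening by rarefaction is exposed as an option and off by default —
  whether the original ASV tables were rarefied is not stated in the
  sources this pipeline mirrors, so the default makes the weaker
  assumption.
* **PERMANOVA**: pseudo-F from the Gower-centred distance matrix,
  $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$, 999 permutations
  by default, optional strata restricting permutations to within blocks
  (plots within farms). Ties count: with two 5+5 point clusters a random
  relabelling preserves the cluster partition with probability
  $2\cdot 5!\,5!/10! = 1/126$ and reproduces $F_{obs}$ exactly, so the
  attainable minimum p is ≈0.009, not 1/1000 — vegan's `adonis2` behaves
  identically. With 10+10 clusters the tie probability is ~10⁻⁵ and
  $p = 0.001$ is attained.
* **PCoA / CAP**: classical principal coordinates by
  eigen-decomposition; negative eigenvalues are dropped with their summed
  magnitude recorded (no Lingoes/Cailliez correction — documented, not
  hidden). The constrained ordination is the distance-based RDA flavour of
  CAP: retained PCoA axes are least-squares-projected onto the constraint
  space and the constrained axes are the singular vectors of the fitted
  values. The original CAP's discriminant variant with cross-validated
  axis choice is out of scope.

## 4. Cd-response classification

Soil Cd maps to categories low [0, 1), medium [1, 2), high [2, ∞) mg kg⁻¹ —
half-open on the left so every concentration lands in exactly one category
(the printed ranges "0–1 / 1–2 / 2–4.3" leave boundary membership
ambiguous; left-closed is our resolution, and the bounds are configurable).

* **Composition evidence**: differential abundance of high vs low natural
  Cd (low is the reference; medium samples are excluded from this
  contrast, mirroring the reference-group design); responsive ⇔
  $q \le \alpha$, direction from the sign of the fold change.
* **Activity evidence**: within each arm (control, spiked) the start
  timepoint S is the reference against P and E; a taxon is *enriched* in
  an arm when significantly increased in either contrast (union rule;
  intersection available — the union is the default because both the peak
  and the end of the assay carry evidence). The Cd-responsive set is then
  `enriched(spiked) \ enriched(control)`: taxa enriched in both arms grew
  on the culture medium, not on Cd, and are explicitly non-response. The
  direction of a call comes from the spiked arm; the control arm
  contributes membership only.
* **Core taxa**: a taxon occurs in a group when its relative abundance
  reaches the detection threshold (default 1/100) in at least the
  prevalence fraction (default 0.001) of the group's samples; occurring
  taxa are partitioned into the Venn regions over farms or Cd categories.
  Both thresholds are exposed because the compact "0.001/100" notation in
  field reports is readable either way; the default follows the
  convention of the microbiome core-taxa functions.
* **Summaries** report responsive/positive/negative/stable fractions. When
  phylum-level results are summarized, both natural denominators (tested
  phyla, and all taxa) can be computed, since published percentages are
  quoted against either.

## 5. The synthetic-data generator

The generator exists so that every stage is testable end to end without
any sequencing download; it emulates the statistical structure of the
field study, not its biology:

* **Design**: 5 farms, 16 plots (3/3/3/3/4), 14–20 samples per plot
  (~225–270 samples), 300 taxa by default.
* **Soil Cd**: farm means evenly spaced over 0–4.3 mg kg⁻¹ with
  within-farm SD 0.9, clamped to the range. The within-farm spread is
  deliberately wide enough that Cd categories cut across farms; this keeps
  farm estimable as a fixed-effect covariate next to the Cd-category
  contrast. (If each farm fell entirely into one category the two would be
  collinear and farm adjustment impossible — a real design constraint
  worth knowing about before sampling.)
* **Responders**: 13% of taxa increase and 15% decrease with the Cd
  category ordinal (0/1/2), by ±1.0 natural-log units per step by default.
  Effects ride on the category ordinal rather than raw Cd so the generator
  and the detector speak the same contrast. Published field studies report
  responder *fractions* but not effect sizes, so the default magnitude is
  chosen for detectability and documented as such, not claimed as
  realistic.
* **Counts**: baseline taxon log-abundances $\sim N(0, 1.2^2)$, per-taxon
  farm effects $\sim N(0, 0.25^2)$, log-normal overdispersion (SD 0.4),
  then a multinomial draw at a depth uniform on 2788–25083 reads — so
  per-sample sampling fractions genuinely vary and the bias correction has
  something real to correct. Log-normal-plus-multinomial was chosen over
  Dirichlet-multinomial for transparent per-taxon effect injection.
* **Timepoints**: S→P→E trajectories are log-linear (no functional form is
  given in the sources; log-linearity is the minimal monotone choice),
  reaching the full planted fold change at E, with a configurable
  non-response set that rises identically in both arms.
* **Thermograms**: exact Gompertz flow plus Gaussian noise and optional
  linear drift; the spiked member gets a longer lag (default +5 h,
  reflecting the delayed adaptation consistently seen in Cd-spiked soils)
  and a $Q_{\max}$ multiplier (default 1.3).

What passing tests on this generator do **not** show: robustness to real
16S artefacts (chimeras, variable copy number, taxonomy errors), to
zero-inflation beyond the multinomial, to phylogenetically structured
effects, or to calorimetric multi-peak curves from succession of
sub-populations. The generator draws each sample's noise independently, so
plot-level autocorrelation is weaker than in real soils.

## 6. Numerical and design choices, in one place

* Gompertz fit tolerances: minpack.lm defaults, 200 iterations max; ties
  between equal-RSS starts go to the smaller lag.
* Offset iteration: half-step damping; within-group re-centring; 10⁻⁶
  stopping threshold; non-convergence is a warning plus the last iterate,
  never a silent failure.
* All randomized stages take a seed; identical seed and inputs give
  identical outputs (the CLI writes the seed and a config hash into every
  output's provenance header).
* Problem sizes used by the acceptance script: 50 kinetics curves, 25
  null + 10 planted differential-abundance replicates, 200 PERMANOVA null
  replicates at 199 permutations, 10 end-to-end field replicates — sizes
  at which each property is measured with comfortable Monte-Carlo margin
  while the whole script runs in seconds.
* Known limitations: `cd_imm` is a proxy; the differential-abundance
  estimator is simplified (no mixture model for the bias term, no
  zero-inflation); CAP is the db-RDA flavour; NMDS is intentionally not
  provided (PCoA/CAP cover ordination); no BIOM/HDF5 or FASTQ handling —
  the pipeline starts at the ASV count table.
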