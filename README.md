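# cdresp

Identifying **cadmium-responsive soil bacteria** from two complementary
lines of evidence:

* **Activity** — paired control vs Cd-spiked isothermal microcalorimetry
  (IMC): each ampoule's heat-flow record is integrated to cumulative heat
  and fitted with the modified Gompertz growth model, and a sample is
  activity-responsive when the spiked member releases more total heat than
  its unamended control.
* **Composition** — 16S ASV count tables analysed with a bias-corrected
  compositional differential-abundance model across soil-Cd categories
  (low [0,1), medium [1,2), high [2,∞) mg kg⁻¹) and across the assay
  timepoints (start S, peak P, end E), with the set-logic rule that a
  Cd-responsive taxon is one enriched in the spiked arm **and not** in its
  control arm.

The package targets microbial ecologists working on heavy-metal stress in
agricultural soils (the motivating system is cacao rhizosphere soil across
farms spanning a natural Cd gradient), but every component is generic:
thermogram kinetics, Chao1/Shannon diversity, Kruskal–Wallis + Dunn
letters, Bray–Curtis, PERMANOVA, PCoA/CAP ordination, structural-zero
screening, sampling-fraction correction, BH-adjusted per-taxon contrasts,
and core-taxa Venn partitions. A synthetic-data generator reproduces the
study design (five farms, 16 plots, depths 2788–25083 reads, 13% positive
and 15% negative planted responders, paired Gompertz heat curves with
longer lag under spiking) so the entire pipeline is testable without any
sequence download.

## The model at the core

Cumulative heat follows the modified Gompertz curve

$$Q(t) = Q_{\max}\,\exp\!\left\{-\exp\!\left[\tfrac{\mu_{\max}e}{Q_{\max}}(\lambda-t)+1\right]\right\},$$

with total heat $Q_{\max}$ (J), maximal heat-production rate $\mu_{\max}$
(J h⁻¹, the flow-curve peak) and lag phase $\lambda$ (h); time to peak is
the exact identity $\mathrm{TTP}=\lambda+Q_{\max}/(e\,\mu_{\max})$.
`fit_gompertz()` returns a classed model object with `print`, `summary`,
`coef`, `predict`, `fitted`, `residuals`, `plot` and `simulate` methods.

Differential abundance follows the ANCOM-BC idea in a self-contained form:
structural zeros are screened out, per-sample sampling-fraction offsets are
estimated by a damped alternating-median iteration, the residual
between-group compositional bias is removed as the median contrast
coefficient across taxa, and each taxon's corrected log counts are tested
by OLS with a t reference and Benjamini–Hochberg correction.

## Worked example

```r
library(cdresp)

## --- activity evidence: one paired thermogram ---------------------------
pair <- simulate_thermogram_pair(thermo_sim_params(
  q_max = 2, mu_max = 0.1, lag = 10, spike_lag_extension = 5,
  spike_qmax_multiplier = 1.3, noise_sd = 0.01, seed = 42,
  sample_id = "farm3_S07"))
fit_c <- fit_gompertz(integrate_heat(pair$control))
fit_s <- fit_gompertz(integrate_heat(pair$spiked))
fit_s
#> Gompertz heat-curve fit
#>   Q_max  = 2.626 J
#>   mu_max = 0.09692 J/h
#>   lag    = 14.71 h
#>   TTP    = 24.67 h
#>   mu     = 0.07954 J/h
#>   RSS    = 0.0967 J^2 (3 starts)

paired_delta(pair$spiked, pair$control, fit_s, fit_c)
#> paired_delta 'farm3_S07': dAUC = 0.7093 J, dQmax = 0.6275 J,
#>   dMumax = 0.001629 J/h, Cd_imm = 1.38 -> activity-responsive
```

The spiked ampoule released 0.71 J more than its control (ΔAUC > 0), its
lag is ~5 h longer (delayed adaptation under Cd stress), and the
spiked/control heat ratio (the Cd-immobilization proxy) is 1.38: this
sample's community is called activity-responsive.

```r
## --- composition evidence: full synthetic field survey ------------------
sim <- simulate_field_experiment(community_sim_params(seed = 1))
meta <- sim$metadata
meta$cd_category <- assign_cd_category(meta$cd_soil)
da <- differential_abundance(sim$table, meta,
  da_contrast("cd_category", "low", "high", covariates = "farm"))
classify_composition_responders(da)$summary
#> response summary (asv level): 86/300 responsive
#>   (28.7%: 13.3% up, 15.3% down), 71.3% stable
```

The generator planted 13% positive + 15% negative responders (28% of 300
taxa); the pipeline recovers 28.7% — 13.3% increasing and 15.3% decreasing
with soil Cd — with the farm effect adjusted as a covariate.

A command-line wrapper (`inst/scripts/cdresp`) exposes the stages as
subcommands (`simulate`, `imc-fit`, `diversity`, `diffabund`, `respond`,
`report`); every output carries a provenance header with the config hash
and seed.

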