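# lactotran

Translational PKPD modeling of prolactin response to dopamine D2 receptor
antagonists.

Antipsychotics block pituitary D2 receptors and release prolactin — in rats
as in humans — which makes plasma prolactin a biomarker for scaling
pharmacodynamics across species. `lactotran` implements the two
semimechanistic prolactin turnover models used for this translation, couples
them to analytic pharmacokinetic drivers, and predicts human D2 receptor
occupancy (RO) and prolactin time courses for clinical dose regimens of
paliperidone (PA, OROS controlled-release oral) and remoxipride (REM, IV).

**Precursor pool (PP):** prolactin is synthesized into a lactotroph pool
(rate `R_form`) and released into plasma at a drug-stimulated first-order
rate; tolerance on repeated dosing is pool depletion.

```
dC_pool/dt = R_form·(1+PF) − K_base·(1+DE)·C_pool
dC_prl/dt  = K_base·(1+DE)·C_pool − K_out·C_prl
DE         = Emax·Cu^γ/(ECu50^γ + Cu^γ)        (or the equivalent RO form)
```

**Agonist–antagonist interaction (AAI):** a hypothetical scaled dopamine
concentration `DAs` competes with the drug at the receptor and inhibits
prolactin release; prolactin feeds back on dopamine production.

```
dC_prl/dt = K_in0·(1+DAs0)·(1 − DAs/(DAs + Cu/KI + 1)) − K_out·C_prl
dDAs/dt   = K_DA·[DAs0·(C_prl/C_prl0)^γ − DAs]
```

Shared competitive occupancy algebra: `RO_drug = 100·(Cu/KI)/(DAs+Cu/KI+1)`,
`RO_dopamine = 100·DAs/(DAs+Cu/KI+1)`; rat-to-human translation scales
turnover rates by `(70/0.28)^−0.25` and leaves potency/dimensionless
parameters unscaled. The package also ships a synthetic rat-study generator
(single/two-dose IV arms with lognormal residual error) and lognormal
maximum-likelihood recovery of the PD parameters, plus a small CLI
(`inst/cli/lactotran`: simulate / translate / generate / fit / summarize /
benchmark).

Because the supplementary PK/rat tables of the source publication are not
redistributable here, rat PD sets are back-derived from the published
translated values and all PK sets are clearly-labelled synthetic stand-ins
calibrated to the descriptors stated in the main text (see the methods
vignette, `vignettes/translational-prolactin-pkpd.Rmd`).

## Worked example

Eight days of remoxipride 200 mg every 12 h under the translational pool
model:

```r
library(lactotran)

pp  <- load_parameter_set("pp_translational")   # R_form 12.4, K_base 0.060, K_out 1.67
rem <- default_compounds("remoxipride")

pool_baseline(pp)
#>    c_pool0     c_prl0
#> 206.666667   7.425150     # printed in the source as 207 and 7.42 ng/mL

sim <- run_scenario("pp", rem, human_regimen("remoxipride", 200, 12, 16),
                    pp, load_human_pk("remoxipride"))
max(sim$ro_drug)
#> [1] 94.97032              # peak receptor occupancy, reported as 95%
tolerance_ratio(sim, 1, 8)
#> [1] 0.07069394            # day-8 prolactin peak ≈ 10% of day 1 (tolerance)
max(sim$c_prl[sim$time <= 24])
#> [1] 112.9564              # first-day prolactin peak, ng/mL

derive_ec50_cross_compound(22, 2.08, 165.75)
#> [1] 0.2760784             # putative human PA EC50, µmol/L (printed: 0.276)
occupancy_dopamine(0, 165.75, 10.9)
#> [1] 91.59664              # baseline dopamine RO at DAs0 = 10.9 (printed: 91.6%)
```

The first number says the lactotroph pool holds ~207 ng/mL-equivalents of
prolactin at baseline; the occupancy peak near 95% explains why motor side
effects (which appear above ~80% RO) are predicted at this regimen; the
tolerance ratio shows the pool-depletion mechanism: after a week of dosing,
prolactin peaks are a tenth of the first day's.

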