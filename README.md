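# odtcea

An R implementation of a one-year decision-analytic cost-effectiveness
model comparing orally disintegrating tablet (ODT) and standard oral
tablet (SOT) formulations of olanzapine, risperidone and aripiprazole for
the treatment of schizophrenia from the Moroccan payer perspective (2022
MAD). It is aimed at health-economics analysts who want a tested,
reusable version of the adherence-stratified relapse model behind the
published Moroccan base case: the input tables ship as fixtures, every
stage of the pipeline is a plain R function, and the whole analysis — base
case, calibration, one-way and probabilistic sensitivity analysis — can be
re-run, perturbed or re-parameterised.

## The model in brief

Patients on arm *s* fall into adherence strata (compliant / partially
compliant / non-compliant by medication possession ratio, MPR) with
probabilities `a_c`. Each stratum has per-cycle probabilities `ph`, `po`
of a relapse with / without hospitalisation; over a one-year horizon with
a calibrated continuous-hazard exponent `K`,

    P(stable)      = (1 − ph − po)^K
    P(hospitalised): P(outpatient) split the remainder in ratio ph : po

and marginal outcomes are adherence-weighted. `K` is fitted once by least
squares against the published annual outcome table (fitted value 3.4729).
QALYs value state-occupancy time (11.7-day hospitalised episodes, 30-day
outpatient episodes) at stratum-specific utilities; costs accrue
MPR-prorated drug acquisition, per-event relapse and adverse-event
resource baskets, and scaled stable-time routine care. Strategies are
compared by incremental cost-effectiveness ratio ICER = ΔC/ΔE, net
monetary benefit NMB = Q·λ − C at the Moroccan threshold λ = MAD
250,832.40/QALY, dominance analysis on the efficiency frontier, tornado
one-way sensitivity analysis with sequential-bifurcation screening, and a
second-order Monte Carlo PSA (beta/gamma/Dirichlet parameter
distributions) summarised by cost-effectiveness acceptability curves.
See `vignettes/cost-effectiveness-model.Rmd` for the full account,
including where the published tables cannot be reconciled with the
published totals.

## Worked example

```r
library(odtcea)

params <- morocco_parameters()          # published input tables + config
res    <- evaluate_all(params)          # six arms + three ODT+SOT groups

print(res$olanzapine_odt)
#> <cohort_result> olanzapine_odt: cost 8741.91 MAD, QALY 0.7959,
#>   outcomes 78.2%/10.4%/11.3% (stable/outpatient/hospitalised)
```

The arm remains relapse-free in 78.2% of patient-years (published: 79%),
with 11.3% hospitalised relapses (published: 11%) and 0.7959 QALYs
(published: 0.7916). Model costs are internally consistent but sit above
the published totals, which are not derivable from the published input
tables (see the vignette); relative comparisons are the meaningful
output:

```r
icer(3034, 0.7916, 3106, 0.7733, "olanzapine_odt", "olanzapine_sot")
#> <cea_comparison> olanzapine_odt vs olanzapine_sot: dCost -72.0,
#>   dQALY 0.0183 -> dominant (ICER magnitude 3934.4 MAD/QALY)
```

i.e. on the published base-case totals, olanzapine ODT is cheaper and
more effective than olanzapine SOT (published ICER magnitude: 3921; the
difference is rounding of the printed inputs). Reports, calibration,
tornado and PSA files are written by `write_base_case()`,
`write_calibration()`, `write_owsa()` and `write_psa()`, or from a shell
via `inst/cli/odtcea.R` (subcommands `run`, `calibrate`, `owsa`, `psa`,
`validate`, `generate`).

## Parameter files

`load_parameters()` / `save_parameters()` read and write either a CSV
bundle — a directory with `params.yaml` (engine configuration, arm and
group definitions, file pointers) plus `adherence.csv`, `relapse.csv`,
`adverse_events.csv` (percentages as published), `utilities.csv`
(decimals) and `resources.csv` (usage quantities and MAD unit costs) — or
a single self-contained YAML document with fractions. The packaged
Moroccan bundle lives in `inst/extdata/morocco2022/` together with the
published annual outcome targets (`targets.csv`) and the published
base-case totals (`reference_base_case.csv`).

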