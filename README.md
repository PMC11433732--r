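# nalpbpk

Mechanistic pharmacokinetics of oral extended-release **nalbuphine (NAL)**
and its four major circulating metabolites (**M1, M3, M4, M5**) in healthy
subjects and in moderate/severe hepatic impairment, with **enterohepatic
recirculation (EHR)** of the parent and its glucuronides.

The package is for pharmacometricians and DMPK scientists who want a fully
mechanistic, mass-balanced alternative to empirical compartment fits for a
drug whose kinetics are dominated by first-pass metabolism and biliary
recycling: ER tablet release feeds a **continuous intestinal absorption
model** (a 1-D convection–dispersion–reaction tube with lumen, apical
membrane, enterocyte and lipid layers), coupled to a **well-stirred
liver** that partitions the parent intrinsic clearance into metabolite
formation, a **gallbladder** that stores biliary NAL/M5/M4-G and empties
at meals into the duodenum (where distal β-glucuronidase regenerates the
aglycones), and linear **compartmental systemic disposition** per analyte.

At its core sit two pieces of standard clinical-pharmacology arithmetic:

- the well-stirred liver model in blood terms,
  `CL_H = BP·Q_h·CL_int,H / (Q_h + CL_int,H)` with `Q_h = 1.45 L/min`,
  used forward and inverted to move between plasma clearances and
  intrinsic clearances across impairment groups, and
- the impairment initializer `a = sqrt((CL/F)_healthy / (CL/F)_impaired)`
  under the assumption of reciprocal changes in clearance and oral
  bioavailability.

Everything in the coupled system is first-order, so the model is a sparse
piecewise-constant linear ODE system integrated by a compiled
Dormand–Prince 5(4) stepper with meal windows as exact breakpoints; a
molar mass-balance ledger closes to ~1e-15 relative.

Also included: PK metrics matching the source analysis (trapezoidal and
model-integrated AUC, interval half-lives, dose normalization, naive
pooling, average absolute percent error), stepwise parameter estimation
on pooled concentration–time data, a synthetic-cohort generator
(lognormal inter-subject variability, proportional residual error, LLOQ
censoring), delimited-text I/O, and a CLI.

## Worked example

```r
library(nalpbpk)

p <- load_parameter_set("healthy")
p
#> <nal_params> group: healthy
#>   CL_int,H 322 L/h -> CL_H 78.8 L/h (Q_h 87 L/h, BP 1.15)
#>   fractions M3/M4/M5: 0.5/0.1/0.4; CL_gi 80.5 L/h

mod <- assemble(p, regimen = dose_regimen("oral-ER", 162))
sim <- simulate_model(mod, t_end = 120)
sim
#> <nal_sim> healthy 162 mg oral-ER over 120 h
#>   NAL Cmax 43.9 ug/L at 3.9 h; |mass imbalance|/dose 4.3e-15

pk_summary(sim_ct_series(sim, "NAL"))
#>     group analyte dose_mg   auc  cmax tmax thalf_12_24 thalf_24_36
#> 1 healthy     NAL     162 483.7 43.88  3.9       3.926       26.28

# moderate hepatic impairment raises dose-normalized NAL exposure ~3.4-fold
simm <- simulate_model(assemble(load_parameter_set("moderate")))
fold_change(auc_model(simm, "NAL"), auc_model(sim, "NAL"))
#> [1] 3.37
```

Reading the output: Cmax 43.9 µg/L at T_max 3.9 h sits in the reported
3–6 h window for the ER tablet; the 24–36 h interval half-life (26 h) is
far longer than the 12–24 h one (3.9 h) because meal-triggered biliary
recycling keeps returning drug to the gut — switch it off
(`cl_gi_mult = 0`) and the late half-life collapses to ~5 h. The
3.37-fold AUC increase under moderate impairment emerges purely from the
reduced hepatic intrinsic clearance (322 → 92 L/h) acting on both
clearance and first-pass extraction.

## Command line

```sh
exec/nalpbpk simulate --group healthy --dose 162 --t-end 120 --out-dir out/
exec/nalpbpk make-synthetic --group moderate --n 8 --seed 7 --out cohort.csv
exec/nalpbpk metrics --input cohort.csv --out-dir out/
exec/nalpbpk fit --input cohort.csv --group moderate --free cl_int_h,k_rel --out-dir out/
exec/nalpbpk recover --seed 42 --out-dir out/
```

Every run writes a JSON manifest with the package version and the full
configuration; equal manifests produce equal outputs.

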