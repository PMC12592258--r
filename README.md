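# lazdose

Population pharmacokinetic simulation of GSTM1 genotype-guided lazertinib
dosing.

Lazertinib (a third-generation EGFR tyrosine kinase inhibitor) is cleared
mainly by glutathione conjugation. Patients homozygous for the *GSTM1*
deletion ("null" genotype) clear the drug more slowly: at the approved
240 mg once-daily (QD) dose their steady-state exposure is roughly 1.8-fold
that of non-null patients. This package asks whether a genotype-guided
regimen in null patients — 160 mg QD or 240 mg every other day (QOD) —
brings exposure back to the non-null reference range while keeping trough
concentrations above the 0.0568 mg/L efficacy threshold, and quantifies the
cost consequence (at $728 per dosing day, QOD dosing halves the annual drug
cost from $265,720 to $132,860).

No individual-level data are available. The package ships only published
steady-state exposure summaries (geometric mean and %CV of trough and
average concentration per genotype/regimen cell,
`inst/extdata/table1_targets.csv`) and recovers everything else:

1. **PK engine** — closed-form two-compartment oral model with *exact*
   periodic steady state by geometric superposition (no ODE integration, no
   run-in); verified in the tests against an independent `deSolve` oracle.
2. **Calibration** (`calibrate_model()`) — genotype clearances and
   clearance variability in closed form from the average-concentration
   summaries; disposition by multi-start least squares on the trough
   geometric means; absorption/volume variability by a
   common-random-numbers Monte Carlo fit to the trough %CVs; a
   geometric-mean recentering loop ties the population GM to the targets.
   The null 160 mg QD cell is held out of calibration and predicted.
3. **Simulation study** (`run_paper_scenarios()`) — 10,000 virtual patients
   per scenario (log-normal weight 70 kg GM / 20% CV, allometric scaling,
   1:1 sex), geometric mean ratios with bioequivalence-style verdicts,
   threshold attainment, and annual cost.

See `vignettes/genotype-guided-dosing.Rmd` for the full methods, modelling
assumptions and numerical choices.

## Worked example

```r
library(lazdose)

# a single patient: steady-state exposure under two regimens
p <- structural_params(CL = 32.3, V1 = 60, Q = 43, V2 = 1660, ka = 0.10)
exposure_metrics(p, regimen_preset("240QD"))
exposure_metrics(p, regimen_preset("240QOD"))

# full study: calibrate to the shipped exposure summaries, then simulate
cal <- calibrate_model(seed = 2025)
report <- run_paper_scenarios(cal, n = 10000, seed = 2025)
report
```

Output (calibration takes a minute or two; exposure metrics in mg/L):

```
$ctrough
[1] 0.2050344

$caverage
[1] 0.3095975

$ctrough
[1] 0.07911114

$caverage
[1] 0.1547988

Steady-state dosing simulation report (n = 10000 per scenario, seed 2025)

Exposure summaries:
      scenario   metric gm_mg_per_L cv_pct     n
 nonnull_240QD  Ctrough      0.0959   62.3 10000
 nonnull_240QD Caverage      0.1740   42.2 10000
    null_240QD  Ctrough      0.2050   54.8 10000
    null_240QD Caverage      0.3080   41.6 10000
    null_160QD  Ctrough      0.1380   54.8 10000
    null_160QD Caverage      0.2080   41.8 10000
   null_240QOD  Ctrough      0.0872   60.6 10000
   null_240QOD Caverage      0.1560   42.5 10000

Geometric mean ratios vs GSTM1 non-null 240 mg QD:
    scenario   metric  gmr equivalence_pass not_lower_pass
  null_240QD  Ctrough 2.14            FALSE           TRUE
  null_240QD Caverage 1.77            FALSE           TRUE
  null_160QD  Ctrough 1.44            FALSE           TRUE
  null_160QD Caverage 1.19             TRUE           TRUE
 null_240QOD  Ctrough 0.91             TRUE           TRUE
 null_240QOD Caverage 0.89             TRUE           TRUE

Fraction of patients with Ctrough > 0.0568 mg/L:
      scenario fraction_above_pct
 nonnull_240QD               79.7
    null_240QD               98.4
    null_160QD               93.7
   null_240QOD               76.6

Annual drug cost:
      scenario                regimen dosing_days_per_year annual_cost_usd
 nonnull_240QD              240 mg QD                365.0          265720
    null_240QD              240 mg QD                365.0          265720
    null_160QD              160 mg QD                365.0          265720
   null_240QOD 240 mg every other day                182.5          132860
 savings_vs_reference_usd
                        0
                        0
                        0
                   132860
```

Reading the report: GSTM1-null patients on the approved dose sit 2.1-fold
above the reference trough; 240 mg QOD restores both metrics to the
0.80–1.25 equivalence range at half the cost, while 160 mg QD keeps average
exposure near-equivalent (GMR 1.19) with troughs still above the reference.
Both alternatives keep threshold attainment close to the reference arm.

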