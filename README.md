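# rubicap

Carbon and redox accounting for Rubisco-based CO2 capture in engineered
*Escherichia coli*.

Strains that co-express phosphoribulokinase (PRK) and Rubisco can route part
of their xylose catabolism through a Calvin-cycle bypass: ribulose-5-phosphate
is phosphorylated to RuBP, Rubisco fixes one CO2 per RuBP, and the resulting
3-phosphoglycerate is deposited as d-lactate. When the medium supplies
13C-bicarbonate, the fixed carbon labels the lactate carboxyl position, so the
labeled-lactate fraction measures the bypass flux. `rubicap` is for the
metabolic engineers running such capture fermentations: it turns time-course
and rate measurements into CO2-uptake fluxes, closed carbon and NADH balances,
and Rubisco kinetic/expression parameters, with uncertainties.

## The model

With `Xyl` and `Gly` the specific xylose and glycerol consumption fluxes
(mmol gDCW⁻¹ h⁻¹), xylose splits between the pentose phosphate pathway (`x1`)
and the bypass (`x2`, equal to the CO2-uptake flux):

    Xyl = x1 + x2
    x3  = (5/3) x1 + Gly                    (G3P flux)
    r   = x2 / (x3 + 2 x2)                  (labeled lactate fraction)

Each carboxylation yields two 3PGA, exactly one labeled. Given a measured,
background-corrected `r`, the closed-form inversion

    x2 = r ((5/3) Xyl + Gly) / (1 - r/3)

recovers the bypass flux. Around this core the package provides:

* `specific_rate()`, `label_fraction_from_timecourse()` — rates from
  resting-cell time courses (OD600 → dry cell weight at 0.3 gDCW/L per OD).
* `infer_flux_partition()`, `forward_label_fraction()`, `bypass_fraction()` —
  the flux partition, forward and inverse.
* `carbon_ledger()`, `redox_ledger()`, `monte_carlo_propagate()` —
  carbon-atom recovery (released CO2 estimated as one per acetate plus one
  per ethanol), NADH consumption/production ratio, and SD propagation.
* `fit_michaelis_menten()`, `catalytic_efficiency()`, `turnover_number()`,
  `csp_fraction()`, `specific_activity()` — carboxylation kinetics and
  CABP-titration-based expression quantitation.
* `simulate_fermentation()`, `simulate_kinetic_assay()` — synthetic data
  with known ground truth for validation.

## Worked example

```r
library(rubicap)
tabs <- read_rate_table_csv(reference_rates_path())
run_capture_analysis(tabs)
```

```
Rubisco CO2-capture accounting (rubicap 0.1.0, DCW/OD = 0.3)
                 quantity 197-2021 7002   RPE
                   xylose     0.41 0.67  0.50
                 glycerol     0.18 0.28  0.46
               co2_uptake     0.00 0.05  0.18
                  lactate     0.57 0.89  1.01
                  acetate     0.11 0.11  0.18
                  ethanol     0.01 0.06  0.06
             released_co2     0.12 0.17  0.24
 total_carbon_consumption     2.59 4.24  4.06
  total_carbon_production     2.07 3.18  3.75
           carbon_balance     0.80 0.75  0.92
               nadh_ratio     0.56 0.60  0.74
           bypass_percent     0.00 7.46 36.00

CO2-uptake fold comparisons:
 strain_a strain_b co2_uptake_fold
      RPE     7002             3.6
```

Reading the output: strain RPE routes 36% of its xylose through the
PRK/Rubisco bypass (0.18 mmol gDCW⁻¹ h⁻¹ of CO2 uptake) versus 7.5% for the
strain carrying the poorly expressing cyanobacterial enzyme — a 3.6-fold
difference in captured CO2 — while recovering 92% of consumed carbon atoms in
detected products, and staying inside the NADH feasibility premise
(consumption/production = 0.74 ≤ 1). The control strain (`197-2021`, inactive
PRK and Rubisco) defines the zero-uptake background.

Kinetics side:

```r
catalytic_efficiency(16.4, 172.4)   # 95.13 s^-1 mM^-1
catalytic_efficiency(12.3, 194.6)   # 63.21 s^-1 mM^-1
relative_change(95.13, 63.21)       # +50.5 %
```

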