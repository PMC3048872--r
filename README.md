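# dscfit

Equilibrium two-state analysis of protein thermal denaturation in R:
DSC thermogram processing and fitting, CD melt fitting, ligand-linked
thermal-shift analysis, and structure-based prediction of unfolding
energetics from accessible-surface-area changes.

## Who it is for

Biophysicists analysing protein stability data: a DSC scan yields a
transition temperature T<sub>m</sub>, a calorimetric enthalpy ΔH (peak
area) and a van't Hoff enthalpy ΔH<sup>VH</sup> (transition
sharpness); the ratio ΔH/ΔH<sup>VH</sup> ≈ 1 (0.8–1.2) diagnoses a
two-state monomer transition. A parallel structure-based route
predicts the enthalpy of *complete* unfolding from the apolar/polar
surface-area change between the folded structure and an extended
unfolded reference — when the measured ΔH falls far below it, the
thermally denatured state retains substantial residual structure.

## The model

Excess molar heat capacity of a two-state transition:

    Cp_ex(T) = ΔH · ΔH_vH · K / (R · T² · (1 + K)²),
    K(T)     = exp[(ΔH_vH / R) · (1/Tm − 1/T)]

with R = 1.9872 cal mol⁻¹ K⁻¹ and T in kelvin (public interfaces use
°C and kcal/mol). The curve integrates to ΔH exactly and peaks at
ΔH·ΔH_vH/(4RTm²). Processing: buffer-reference subtraction → molar
normalization → progress-baseline removal → bounded least-squares fit
with Gauss–Newton standard errors. Structure energetics:

    ΔCp     = (0.45·ΔASA_ap − 0.26·ΔASA_pol) / 1000   kcal K⁻¹ mol⁻¹
    ΔH(60)  = (31.4·ΔASA_pol − 8.44·ΔASA_ap) / 1000   kcal/mol
    ΔH(Tm)  = ΔH(60) + ΔCp · (Tm − 60)

with ΔASA from a deterministic Shrake–Rupley engine or supplied
directly. Single-site linkage models the T<sub>m</sub> shift with
ligand concentration: 1/Tm0 − 1/Tm = (R/ΔH0)·ln(1 + L/Kd).

## Worked example

```r
library(dscfit)

apo <- two_state_params(tm = 62.5, dh_cal = 111.6, dh_vh = 96.3)
tg  <- simulate_thermogram(apo, noise_sd = 0.1, seed = 42,
                           baseline = list(pre = c(2, 0.012),
                                           post = c(3.2, 0.006)))
bl  <- remove_chemical_baseline(tg)
fit <- fit_two_state(bl$excess)
summary(fit)
#> Two-state DSC fit
#> Two-state parameters: Tm = 62.50 degC, dH_cal = 112.4 kcal/mol, dH_vH = 95.7 kcal/mol
#>   rss = 7.611 on 801 points
#>
#> Parameters (temperatures degC, enthalpies kcal/mol):
#>        Estimate Std. Error
#> tm       62.501     0.0054
#> dh_cal  112.377     0.1469
#> dh_vh    95.737     0.1543
#>
#> dH_cal/dH_vH = 1.17 (two-state band: 0.8-1.2)

predict_energetics(dasa_ap = 18746, dasa_pol = 10598, tm = 71,
                   dh_exp = 120.4)
#> Structure-energetics prediction
#>   dASA apolar / polar :    18746 /    10598 A^2
#>   dCp_calc            :      5.7 kcal/K/mol
#>   dH_calc(60 degC)    :    174.6 kcal/mol
#>   dH_calc(Tm = 71.0)  :    237.0 kcal/mol
#>   dH_exp / dH_calc    :     0.51
```

The fit recovers the injected parameters through the full processing
chain (baseline recovery is validated to 1% of peak height), the
enthalpy ratio 1.17 sits inside the two-state band, and the
structure-based prediction of ~237 kcal/mol against a measured
~120 kcal/mol flags a highly structured denatured state
(ΔH_exp/ΔH_calc ≈ 0.51).

`run_pipeline()` drives the same chain from a YAML config (input
files, windows, energetics blocks) to a JSON report with provenance;
`fit_cd_melt()` and `fit_titration()` handle optical melts and
Kd estimation from Tm-shift series.

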