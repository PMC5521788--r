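# cellrad

In vitro dosimetry and radiobiology for targeted radionuclide therapy
experiments: absorbed dose to cells in 6-well plates from alpha- and
beta-emitting radioligands, clonogenic survival-curve fitting, and
relative biological effectiveness (RBE) at fixed survival levels.

## Who this is for

Radiopharmaceutical and radiobiology groups comparing an alpha emitter
(e.g. a Bi-213-labelled somatostatin analogue) against a beta emitter
(Lu-177) or external photon irradiation need the comparison on an
absorbed-dose axis, not an applied-activity axis. That requires
(i) time-integrated activities of a branched decay chain, (ii) S-value
dosimetry for both the radioactive incubation medium and the
specifically bound fraction, and (iii) survival-curve fits whose D₁₀
values feed RBE ratios. `cellrad` implements the full chain of
computation with packaged nuclear-data and S-value fixtures, plus seeded
synthetic-assay generators so the entire pipeline is testable without
laboratory data.

## The core computations

**Cumulated activity.** For each member of the Bi-213 chain
(Bi-213 → Po-213 (97.84%) / Tl-209 (2.16%) → Pb-209) the Bateman
activities are integrated in closed form over any window,
Ã = ∫ A(t) dt (MBq·s), with the 4.2 µs Po-213 handled in the secular
equilibrium limit Ã_Po = BR·Ã_Bi. Validated against a stiff-ODE oracle
to 10⁻⁶ relative.

**Medium (non-specific) dose.** D̄(25 µm ← fluid) = Σᵢ Ãᵢ ·
Sᵢ(25 µm ← fluid) × 10⁻³ Gy over chain members and radiation classes,
using the packaged bottom-layer S-value table for a 2 mL well.

**Cellular (specific) dose.** MIRD schema for a 6 µm cell:
D̄_cell = Σᵢ Ãᵢ [f_int·Sᵢ(C←C) + f_mem·Sᵢ(C←CS)] × 10⁻³ Gy, integrated
from the end of incubation (T₀ = 1 h) to the end of colony formation
(T = 12 d), no clearance assumed.

**Survival and RBE.** Linear-quadratic survival
SF(D) = exp(−αD − βD²) (β = 0 for the one-phase high-LET case), fitted
either by constrained least squares on −ln SF or — for colony-count
data — by a constrained Poisson GLM that estimates the plating
efficiency jointly from control wells. D at survival S solves
αD + βD² = −ln S; RBE = D_reference / D_test at the common endpoint.

## Worked example

Dose to the bottom cell layer from 1 MBq Bi-213 in the medium for 1 h:

```r
library(cellrad)
medium_dose(1, bi213_chain(), c(0, 3600), layer_s_values_bi213())
#> <dose_breakdown>
#>   nuclide radiation_class   dose_Gy
#> 1  Bi-213           alpha 1.936e-02
#> 2  Bi-213            beta 3.755e-02
#> 3  Bi-213        auger_ic 1.889e-03
#> 4  Bi-213           gamma 2.361e-04
#> 5  Po-213           alpha 1.056e+00
#> 6  Tl-209            beta 1.075e-03
#> 7  Tl-209        auger_ic 7.396e-05
#> 8  Tl-209           gamma 4.930e-05
#> 9  Pb-209            beta 2.251e-03
#> total: 1.118 Gy (alpha fraction 0.961)
```

So one MBq delivers ≈1.12 Gy to the cells during the incubation, 96% of
it from the 8.4 MeV Po-213 alpha — the practical reason Bi-213 ligands
kill cells even without receptor binding.

Fit a simulated photon clonogenic assay (8 doses × 3 replicates,
Poisson colony noise) and read out D₁₀:

```r
dat <- simulate_clonogenic(sim_config(seed = 42))       # true α=0.21, β=0.05
fit <- fit_survival_counts(dat$dose_Gy, dat$colonies, dat$seeded, "LQ")
fit
#> <survival_fit> LQ model, n = 27
#>   alpha = 0.2015 Gy^-1 (SE 0.0404)
#>   beta  = 0.04836 Gy^-2 (SE 0.00751)
#>   R^2 = 0.986
dose_at_survival(fit, 0.1)
#> [1] 5.125086
```

The fitted curve recovers the generating parameters within one standard
error and puts D₁₀ near 5 Gy. An RBE then needs only the test
condition's D₁₀: e.g. `rbe(5.1, 2.6)` → 1.96, i.e. the alpha ligand
needs half the photon dose for the same 90% kill.

`run_pipeline()` composes all of this for a multi-condition experiment
from a YAML/CSV configuration and writes JSON + TSV reports; see
`?run_pipeline` and the methods vignette
(`vignettes/cellular-dosimetry.Rmd`).

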