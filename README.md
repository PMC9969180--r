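# muellerpol

Mueller-matrix polarimetry of optically active solutions: forward modeling
and global inversion of broadband transmission Mueller spectra of chiral
liquids, with first-order mutarotation kinetics of reducing sugars.

## The problem

A transparent chiral solution rotates the plane of linearly polarized light
because its left- and right-circular eigenmodes propagate with different
refractive indices n_L and n_R. A broadband Mueller-matrix ellipsometer
measures, at every wavelength, the normalized 4×4 Mueller matrix of the
solution, whose central block is a Stokes-space rotation:

    m22 = m33 = cos 2Γ,   m23 = −m32 = sin 2Γ,
    Γ(λ) = (π d / λ) (n_L − n_R)

with d the optical path. Because the matrix elements are periodic, a single
wavelength pins Γ only modulo π. `muellerpol` resolves the absolute
(branch-unwrapped) rotation by fitting a physically constrained dispersion
model across the whole spectrum:

* water refractive index n(λ) from a Sellmeier parameterization,
* gyration tensor element g11(λ) = Σᵢ aᵢ/(λ² − λᵢ²) (Drude form, resonances
  fixed below the electronic CD region of sugars),
* eigenmode indices n_{L,R} = √(n² ± g11).

For a reducing sugar such as d-glucose, the freshly dissolved α-anomer
interconverts to the β-anomer (mutarotation) with first-order kinetics

    C_α(t) = C_α,eq + (C − C_α,eq) e^(−τt),   C_α,eq = C/(1+K),

and the solution's gyration is the concentration-weighted sum of the anomer
dispersions. A single global least-squares fit over all wavelengths and
times (the spectral–temporal coupled model) recovers the total rate
constant τ, its α→β / β→α split, and the per-anomer gyration spectra —
including the specific rotation of each pure anomer, which cannot be
measured directly. Specific rotatory power is reported in the conventional
units [Γ] = Γ_deg / (ρ·d) with ρ in g/mL and d in dm.

Because no raw ellipsometer data are publicly deposited for this kind of
experiment, the package ships a synthetic-data generator that emulates the
instrument: 300–1000 nm in 1 nm steps, i.i.d. Gaussian noise of 0.001 on
each normalized Mueller element, 100 time points from 300 s to 12 h, and
optional cuvette-stress linear-birefringence artifacts.

## Worked example

Simulate a full mutarotation experiment of 0.25 M α-d-glucose and invert
it:

```r
library(muellerpol)
scen   <- glucose_mutarotation_scenario(seed = 7)
series <- simulate_mutarotation(scen)
series
#> mueller_series: 701 wavelengths (300-1000 nm) x 100 time points
#>   species: alpha-d-glucose

fit   <- fit_mutarotation(series)
rates <- split_rates(fit$kinetics)
fit$kinetics$tau                     # 0.0002331 1/s
rates                                # k(a->b) = 1.492e-4, k(b->a) = 8.393e-5 1/s
fit$alpha_specific_rotation_589      # 104.66 deg mL/(g dm)
fit$beta_specific_rotation_589       # 20.74  deg mL/(g dm)
```

The recovered total rate constant matches the generator truth
(2.332 × 10⁻⁴ s⁻¹) to a fraction of a percent, and the two anomer specific
rotations are separated from a single forward reaction. A static
equilibrium spectrum works the same way:

```r
sfit <- fit_static(simulate_static(static_scenario("fructose", seed = 7)))
sfit$specific_rotation_spectrum[sfit$wavelengths == 589]
#> -92.54      # deg mL/(g dm); residual rms 0.001 = the noise floor
```

Other entry points: `extract_state()` (principal-value retardation from one
matrix), `unwrap_absolute()` (branch-resolved absolute rotation),
`differential_decompose()` (matrix-logarithm decomposition into LD/LD′/CD/
LB/LB′/CB measures), `detection_limit()`, `inject_cuvette_stress()`, and a
command-line interface `cli_dispatch()` (wrapper script in
`inst/scripts/muellerpol`) with `simulate-static`, `simulate-kinetics`,
`fit-static`, `fit-kinetics`, `decompose` and `unwrap` subcommands reading
and writing a documented TSV + JSON series format.

## Vignette

`vignettes/mueller-polarimetry.Rmd` documents the model, its assumptions,
the numerical choices of the fitters, and what the synthetic-data tests do
and do not demonstrate about real instrument data.
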