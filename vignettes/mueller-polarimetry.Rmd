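---
title: "Spectral–temporal Mueller-matrix analysis of chiral solutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral–temporal Mueller-matrix analysis of chiral solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellerpol)
```

## The physical model

An isotropic chiral liquid in transmission is a non-depolarizing
polarimetric element with two parameters per wavelength: the circular
retardation $\Gamma$ (the rotation angle of the plane of linear
polarization, half the accumulated phase difference between the left- and
right-circular eigenmodes) and the circular dichroism angle $\Gamma'$. Its
normalized Mueller matrix is

$$
\mathbf{M} = \begin{pmatrix}
1 & 0 & 0 & \tanh\Gamma' \\
0 & \cos 2\Gamma/\cosh\Gamma' & \sin 2\Gamma/\cosh\Gamma' & 0 \\
0 & -\sin 2\Gamma/\cosh\Gamma' & \cos 2\Gamma/\cosh\Gamma' & 0 \\
\tanh\Gamma' & 0 & 0 & 1
\end{pmatrix},
$$

which `mueller_chiral()` evaluates exactly and which reduces to the Stokes
rotator for $\Gamma' = 0$. Monosaccharides have their electronic CD bands
below 190 nm, far outside the 300–1000 nm window accessible between the
cuvette-glass and water absorption edges, so the package default is
$\Gamma'(\lambda) = 0$ throughout the window; the CD path (elements
$m_{14}, m_{41}$) is implemented and can be switched on in the fits
(`fit_config(use_cd = TRUE)`).

**Sign conventions** (fixed package-wide and verified by the oracle tests):
circular basis $\hat e_L = (1, i)/\sqrt2$, $\hat e_R = (1,-i)/\sqrt2$;
positive $\Gamma$ is dextrorotatory and gives $m_{23} = +\sin 2\Gamma$; the
circular-basis Jones rotator is $\mathrm{diag}(e^{+i\Gamma},
e^{-i\Gamma})$, whose Cartesian form is the plane rotation by $\Gamma$.
Note the factor of two: a circular retarder with L/R phase difference
$2\Gamma$ rotates the polarization plane by $\Gamma$ and the $(S_1, S_2)$
Stokes pair by $2\Gamma$. All three layers (Jones, Mueller, differential)
are kept consistent with this choice, and
`jones_to_mueller(jones_rotator(g))` equals `mueller_rotator(g)` to
machine precision.

## Dispersion model

The measured element spectra mix the solvent refraction and the chiral
response. The package separates them:

* **Water index.** A Sellmeier form $n^2(\lambda) = 1 + \sum_i A_i
  \lambda^2/(\lambda^2 - B_i)$ with the Daimon–Masumura coefficients for
  pure water at 20 °C, stored in `inst/extdata/water_sellmeier.json`
  rather than hard-coded. Pure-water $n$ stands in for the solution index:
  at the few-percent mass fractions considered, the index dispersion
  changes by well under 1 %. The test suite cross-checks this model
  against an independently implemented IAPWS formulation (agreement
  $\sim 5\times10^{-5}$ over the window).
* **Gyration.** A Drude-type oscillator form $g_{11}(\lambda) = \sum_i
  a_i/(\lambda^2 - \lambda_i^2)$. The default is a single term with
  $\lambda_1 = 150$ nm held fixed — below the electronic CD region, so the
  dispersion is smooth and monotone over the window — leaving the
  amplitude $a_1$ as the only free dispersion parameter per species.
  Amplitudes are stored per unit molar concentration and scaled linearly
  by the solution concentration, which makes the concentration-weighted
  anomer mixing rule well-posed.
* **Eigenmodes and retardation.** $n_{L,R} = \sqrt{n^2 \pm g_{11}}$ (the
  rigorous wave-equation form; it agrees with the first-order
  $g_{11}/n$ split to $O(g_{11}^2)$), and $\Gamma = (\pi d/\lambda)(n_L -
  n_R)$.

`calibrate_gyration()` inverts this chain in closed form, so a dispersion
can be pinned to a conventional specific rotation at 589 nm: from
$\Delta = \Gamma\lambda/(\pi d)$ follows $g_{11} = \tfrac{\Delta}{2}
\sqrt{4n^2 - \Delta^2}$ exactly.

**Units.** Wavelengths are nm everywhere; the path length is stored in mm
and converted to dm only inside the specific-rotation definition
$[\Gamma] = \Gamma_{\deg}/(\rho\, d_{\mathrm{dm}})$ ($\rho$ in g/mL) and
to nm inside the retardation formula. $\Gamma$ is radians internally and
degrees in all output tables.

## Mutarotation kinetics

The reversible first-order interconversion of the glucose anomers is
parameterized by the observed total rate constant $\tau = k_{\alpha\to\beta}
+ k_{\beta\to\alpha}$ and the equilibrium constant $K =
C_{\beta,\mathrm{eq}}/C_{\alpha,\mathrm{eq}}$, with
$C_\alpha(t) = C_{\alpha,\mathrm{eq}} + (C - C_{\alpha,\mathrm{eq}})
e^{-\tau t}$ for a pure-$\alpha$ start. Because arrow-direction labels for
the split constants are a recurring source of confusion in the literature,
`split_rates()` returns species-named components (`rate_alpha_to_beta`,
`rate_beta_to_alpha`); with $K \approx 1.78$ at 20 °C the $\alpha\to\beta$
rate is the larger one. Furanose forms and powder impurities are
deliberately not modeled. The reacting solution's gyration is the mixing
rule $g_{11}(\lambda, t) = [C_\alpha(t)\, g_{11,\alpha}(\lambda) +
C_\beta(t)\, g_{11,\beta}(\lambda)]/C$.

## Inversion

`fit_static()` minimizes the unweighted sum of squared residuals of the
elements $\{m_{22}, m_{23}, m_{32}, m_{33}\}$ (homoscedastic instrument
noise justifies equal weights) over all wavelengths simultaneously, with
the single Drude amplitude free. Working in element space makes wrapped
spectra ($|2\Gamma| > \pi$ at high concentration) unproblematic: the model
elements are periodic too, and the dispersion shape selects the branch.
Starting values come from a deterministic coarse grid of candidate
specific rotations (±200 deg mL g⁻¹ dm⁻¹ in steps of 1 by default, wide
enough for multi-molar solutions of strongly active sugars), refined by
Levenberg–Marquardt (`minpack.lm::nls.lm`, max 200 iterations, parameter
tolerance $10^{-10}$). The fit is deterministic given the data.

`unwrap_absolute()` then assigns each principal-value retardation
$\hat\Gamma \in (-\pi/2, \pi/2]$ (from `extract_state()`, which averages
all four rotation elements via $\tfrac12\,\mathrm{atan2}(\bar s, \bar c)$)
the branch $k \in [-K_{\max}, K_{\max}]$ minimizing $|\hat\Gamma + k\pi -
\Gamma_{\mathrm{model}}|$. $K_{\max} = 8$ covers several full turns at
multi-molar concentrations. If the best and second-best branches are
closer than `ambiguity_tol` ($10^{-3}$ rad), the function raises an error
instead of guessing.

`fit_mutarotation()` fits the coupled model globally over all
(wavelength, time) pairs with three free parameters: the two anomer Drude
amplitudes and $\tau$. The equilibrium ratio is **fixed** (default 36:64
$\alpha$:$\beta$ for glucose at 20 °C) because late-time data dominate the
$\beta$ information and $g_{11,\beta}$ correlates with
$C_{\alpha,\mathrm{eq}}$; the ratio is an explicit argument so the
correlation risk stays visible. Starting values are derived
deterministically: a per-time-slice static fit yields an effective
amplitude trajectory, a grid-plus-linear-regression exponential fit seeds
$\tau$ and the asymptotes, and the mixing rule converts those to anomer
amplitudes. The global refinement then typically moves parameters by a few
percent at most.

`detection_limit()` implements the package's own small-angle chain: a
per-element noise floor $\sigma$ bounds the smallest detectable rotation
via $m_{23} \approx 2\Gamma$, so $\Gamma_{\min} = \sigma/2$ rad and
$C_{\min} = \Gamma_{\min,\deg}/([\Gamma]\, d_{\mathrm{dm}})$. Only
concentration *ratios* between solutes are instrument-independent; the
absolute values depend on how the noise floor is defined.

## The synthetic-data generator

`simulate_static()` and `simulate_mutarotation()` emulate a broadband
dual-rotating-compensator transmission ellipsometer measuring a cuvette of
solution:

* wavelength grid 300–1000 nm in 1 nm steps (701 points), bounded by the
  cuvette-glass and water transparency edges;
* 0.25 M solution in a 50.04 mm cell at 20 °C by default; kinetic default
  $\tau = 2.332\times10^{-4}$ s⁻¹ with the 36:64 equilibrium, anomer
  589 nm rotations 104.66 and 20.74, equilibrium glucose 52.68 and
  fructose −92.53 deg mL g⁻¹ dm⁻¹ (all stored in
  `inst/extdata/saccharide_defaults.json`);
* time grid of 100 points from the first reading at 300 s (dead time of
  dissolution and instrument start) to 12 h;
* i.i.d. Gaussian noise of $\sigma = 0.001$ (the nominal noise floor of
  this instrument class) added independently to each of the 15 normalized
  elements at each grid point — the standard detector-noise assumption;
  real per-element correlations of such instruments are unknown and not
  modeled;
* optional cuvette-stress linear birefringence as a commuting half-sandwich
  of linear retarders (`inject_cuvette_stress()`), which places signals in
  $m_{24}, m_{34}, m_{42}, m_{43}$ exactly as residual window stress does.

What passing tests on this generator demonstrate: that the inversion is
unbiased and precise *under the model's own assumptions* (single-term
Drude truth, white element noise, exact first-order kinetics, stable
temperature). What they do not demonstrate: robustness to systematic
instrument errors, wavelength-correlated noise, temperature drift,
furanose side reactions, or dispersions outside the Drude family. The
fitted-model residual RMS equaling the configured noise floor (≈0.001) is
the internal consistency check.

## Numerical choices

* $n_L - n_R$ is evaluated as $2g_{11}/(n_L + n_R)$ — algebraically
  identical to the square-root difference but free of the catastrophic
  cancellation that otherwise costs ~7 significant digits at
  $g_{11} \sim 10^{-7}$.
* The differential decomposition uses a principal-branch matrix logarithm
  by eigendecomposition, written in-package so that eigenvalues on (or
  numerically at) the negative real axis raise a classed branch-ambiguity
  error instead of silently wrapping; complex residuals above $10^{-10}$
  are likewise fatal. Its 2×2 rotation-block closed form serves as the
  independent oracle in the tests.
* Forward constructors are checked against the Gil–Bernabeu
  non-depolarization equality to $10^{-6}$; fit *inputs* are only warned
  about, since measured matrices always carry noise.
* All Monte-Carlo studies take explicit seeds; the generator records its
  seed in the series manifest, so every artifact on disk is reproducible
  from its manifest alone.
* Problem sizes: the unit tests run on a decimated 71-point wavelength
  grid with 20 time points, which keeps each fit in the tens of
  milliseconds; the full-scale study conditions (701 × 100, 20 and 100
  replicates) are exercised in the acceptance test and in
  `scripts/acceptance.R`.

## Design decisions that were genuinely open

* **Drude resonance at 150 nm, fixed.** Any value comfortably below the
  window edge yields near-identical fits over 300–1000 nm (the resonance
  position trades off almost perfectly against the amplitude); fixing it
  removes a poorly identified parameter, and 150 nm sits below the 190 nm
  electronic CD region.
* **Equilibrium ratio as an input, not a parameter.** See the correlation
  argument above; the 36:64 glucose value at 20 °C is the accepted
  literature number. The generator derives its kinetic $K$ from the same
  fixed fraction, so generator and fitter share one self-consistent truth.
* **YAML configuration and a TSV/JSON series format.** No standard
  bio-format covers Mueller spectra and vendor formats are proprietary;
  the dialect is documented in `read_series()`/`write_series()` and
  round-trips to 12 significant digits. Vendor-file import is out of
  scope.
* **Noise model at the floor, not calibrated per element.** Only a single
  floor figure is available for this instrument class; a wavelength- or
  element-resolved noise map would change the weighting of the fits but
  not their structure.

## Known limitations

Depolarization is not modeled (no Lu–Chipman/Cloude decompositions), and
the decomposition applies to transmission matrices only. Absorptive
gyration ($\Gamma' \neq 0$ with Kramers–Kronig-consistent CD bands),
temperature dependence of the rate constants and of the dispersions, and
multi-species mixtures at unknown concentrations are out of scope — the
latter is fundamentally ill-posed without prior knowledge of the
individual gyration responses.
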