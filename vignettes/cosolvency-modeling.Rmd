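---
title: "Cosolvency solubility modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosolvency solubility modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosolvr)
```

## The problem

Poorly water-soluble bioactive compounds are routinely solubilized by
blending water with a miscible cosolvent.  A solubility study of this kind
measures the equilibrium mole-fraction solubility $x_e$ of the solute over
a grid of cosolvent mass fractions $m$ (0 = pure water, 1 = pure cosolvent)
and temperatures $T$, and then asks three questions: how far from ideal is
each solution (activity coefficients, mixing thermodynamics), does a simple
cohesion-parameter argument explain the solvent ranking (Hansen solubility
parameters), and which compact empirical model best correlates — and can
therefore interpolate — the whole grid.

`cosolvr` implements that complete analysis.  The packaged dataset is the
solubility grid of piperine, the pungent alkaloid of black pepper, in
Transcutol-HP (diethylene glycol monoethyl ether) + water: 11 mass
fractions ($m = 0, 0.1, \dots, 1$) by 5 temperatures (298.2–318.2 K in 5 K
steps), spanning nearly four orders of magnitude in solubility.

## From raw measurements to mole fractions

Shake-flask measurements give mg of solute per g of solute-free solvent
blend.  Per gram of blend there are $m$ g cosolvent and $1-m$ g water, so

$$x_e = \frac{m_1/M_1}{m_1/M_1 + m/M_2 + (1-m)/M_3},$$

with $m_1$ the solute mass in grams and $M_1, M_2, M_3$ the molar masses of
solute, cosolvent and water.  `to_mole_fraction()` implements this with its
exact inverse `from_mole_fraction()`; "mg per g" is interpreted per gram of
*solvent*, not of solution, which is the reading that reproduces the
packaged system's worked conversions (185.29 mg/g in pure cosolvent
$\rightarrow 8.01\times 10^{-2}$).  The packaged constants use the water
molar mass exactly as tabulated in the source material (18.07 g/mol); the
constructor accepts any value, and the worked conversions agree at three
significant figures under 18.02 as well.

## Ideal solubility, activity coefficients, mixing thermodynamics

The ideal solubility follows from the solute's fusion properties alone:

$$\ln x^{idl} = -\frac{\Delta H_{fus}(T_{fus}-T)}{R\,T_{fus}\,T} +
\frac{\Delta C_p}{R}\left[\frac{T_{fus}-T}{T} +
\ln\frac{T}{T_{fus}}\right],$$

with $T_{fus}$ = 404.88 K, $\Delta H_{fus}$ = 32.69 kJ/mol and
$\Delta C_p$ = 80.74 J/(mol K) for piperine.  Both terms vanish at the
melting point, where $x^{idl} = 1$.  The activity coefficient is the ratio
$\gamma_i = x^{idl}/x_e$, and the saturated ternary composition
$(x_1, x_2, x_3)$ is obtained by splitting $1 - x_1$ in the mole ratio of
the solute-free blend.

Ideal mixing functions come from composition alone:
$\Delta_{mix}G^{id} = RT\sum x_i \ln x_i$,
$\Delta_{mix}S^{id} = -R\sum x_i \ln x_i$, $\Delta_{mix}H^{id} = 0$, with
the $0\ln 0 := 0$ limit convention.  Three design choices in the
non-ideal part were genuinely open and are worth recording:

* **Excess Gibbs energy.**  Solubility data identify only the *solute's*
  activity coefficient; no solvent–solvent interaction parameters (e.g.
  Wilson $\Lambda$) are estimable from a saturation grid.  `cosolvr`
  therefore treats the solvent species as ideal and computes
  $G^E = RT\,x_1\ln\gamma_i$.  Multiplying all three mole fractions by the
  same solute $\gamma_i$ — the literal reading of some formulations —
  has no thermodynamic interpretation, and with $x_2 + x_3 \approx 1$ it
  would simply rescale $G^E$ without changing any sign conclusion.
* **Excess enthalpy.**  $H^E = -T^2\,\partial(G^E/T)/\partial T$ is
  evaluated by regressing $G^E/T$ linearly on $1/T$ over each
  composition's five temperatures and differentiating the fitted form
  analytically ($H^E$ = slope, constant over the window).  This is far
  more noise-robust than pointwise finite differences on a 5-point
  series; `gibbs_helmholtz_fd()` exposes the finite-difference evaluation
  as an independent cross-check, and the two agree to $10^{-6}$ relative
  on the fitted smooth form.
* **Entropy closure.**  Rather than carrying a separate entropy formula,
  the net entropy is recovered from the exact identity
  $\Delta_{mix}S = (\Delta_{mix}H - \Delta_{mix}G)/T$, which holds under
  any consistent convention; every record in the output table satisfies
  $G = H - TS$ to numerical precision by construction, and the tests
  assert it.

## Hansen solubility parameters

Totals obey $\delta^2 = \delta_d^2 + \delta_p^2 + \delta_h^2$; blend
parameters use the linear rule
$\delta_{mix} = \alpha\delta_1 + (1-\alpha)\delta_2$.  Although $\alpha$
is formally a volume fraction, `cosolvr` defaults to $\alpha = m$ (mass
fraction): for this system the tabulated blend endpoints (45.16 MPa$^{1/2}$
at $m=0.1$, 24.04 at $m=0.9$) are reproduced bit-for-bit only under that
choice, and without component densities the volume fractions are not
derivable from the data anyway.  Callers with densities can pass true
volume fractions.  Component-level values of the packaged system are not
available — only totals — so component arithmetic is exercised with
synthetic values in the tests.

## The five cosolvency models

For each composition $m$ (temperature direction):

* **van't Hoff**: $\ln x = a + b/T$, ordinary least squares of $\ln x$ on
  $1/T$ (2 coefficients per composition).
* **Apelblat**: $\ln x = A + B/T + C\ln T$ — linear in its coefficients,
  so it is fit by exact least squares on the regressors
  $\{1, 1/T, \ln T\}$ despite the "nonlinear regression" label this model
  often carries.  Over a 20 K window that design is severely collinear
  (condition numbers around $10^9$): predictions are excellent and
  reproducible, individual coefficients are not.  The fit therefore
  reports the design's condition number, and coefficient values are not a
  meaningful comparison surface; predictions and %RMSD are.

Across the mixture direction:

* **Yalkowsky–Roseman** (log-linear): $\log_{10} x = m_1\log_{10}x_1 +
  m_2\log_{10}x_2$ — parameter-free blending of the measured pure-solvent
  solubilities.
* **Jouyban–Acree**: adds temperature-scaled interaction terms,
  $\ln x_{m,T} = m_1\ln x_{1,T} + m_2\ln x_{2,T} +
  \frac{m_1 m_2}{T}\sum_{i=0}^{2}J_i(m_1-m_2)^i$, fit by no-intercept
  least squares of the interaction residual on the three regressors;
  terms with $p > 0.05$ are dropped in one pass and the model refit (on
  the packaged grid a single $J_0$ survives).
* **Jouyban–Acree–van't Hoff**: replaces the measured pure-solvent
  anchors with fitted van't Hoff lines, giving a closed-form surface in
  $(m, T)$.  It is fit in two stages — pure-solvent lines first, then the
  $J$ terms on the residuals — because that matches how its published
  trained forms reuse the pure-solvent coefficients verbatim.

Fit quality is reported two ways, matching where each statistic plausibly
comes from: $R^2$ on the $\ln x$ regression scale, and the deviation
metric on the solubility scale as

$$\%RMSD = 100\sqrt{\tfrac{1}{N}\sum_i\big((x^{obs}_i -
x^{pred}_i)/x^{obs}_i\big)^2}.$$

This relative form reproduces the packaged study's printed pure-water
van't Hoff deviation (1.11%) from its printed coefficients, which pins the
formula down among the several RMSD variants in circulation.
`rank_models()` orders models by average %RMSD with ties broken toward
fewer coefficients — the parsimony argument that favors the single-$J$
Jouyban–Acree model in this literature.

Numerical edge cases: when a no-intercept selection step meets a
numerically perfect fit (residual standard error below $10^{-10}$ of the
$\ln x$ scale), t-based p-values are meaningless; terms are then retained
iff their coefficient exceeds $10^{-6}$ K in magnitude, far below any
physically meaningful interaction coefficient.  This makes noiseless
closure tests exact: refitting a noise-free surface recovers the
generating coefficients to $10^{-8}$.

## The synthetic-data generator

`generate_solubility_grid()` draws grids from the Jouyban–Acree–van't Hoff
surface with additive Gaussian noise on $\ln x$ — i.e. multiplicative
lognormal noise on $x$, matching the relative-error structure implied by
the %RMSD metric and by solubility assays generally.  The defaults *are*
the packaged study's conditions: the 11 × 5 grid, the fitted pure-solvent
lines ($A_1 = -0.21$, $B_1 = -696.21$; $A_2 = -4.45$, $B_2 = -2093.60$),
the trained interaction coefficient $J_0 = -16.42$ K, and
$\sigma = 0.01$ on $\ln x$ (about 1% relative error, the scale of the
per-model %RMSDs the models achieve on real grids of this kind).
Generation is seed-deterministic down to the written CSV, and the seed is
applied locally so the caller's RNG stream is untouched.

What the generator emulates — and does not.  It reproduces the smooth
$(m, T)$ structure and the relative-error magnitude of a real grid.  It
does not emulate assay-specific error structure (inter-day variability,
heteroscedasticity across the four decades of solubility, rounding of
reported values) or any deviation of real systems from the
Jouyban–Acree–van't Hoff surface itself.  Passing recovery tests on
generated grids therefore demonstrates the fitters are correct and
unbiased under the model's own assumptions, not that the model is true of
any particular solvent system.

## Verification strategy and problem sizes

Every fitter is checked against an independent oracle on small instances:
the covariance closed form and a decorrelated grid search for van't Hoff,
iteratively refined normal equations for Apelblat, and the projection
formula $\hat J_0 = \sum w y / \sum w^2$ for single-term no-intercept
fits.  Property tests cover nested-model ordering (Apelblat never fits
worse than van't Hoff on the same series), the exact collapse of
Jouyban–Acree onto the log-linear rule when all $J = 0$, thermodynamic
closure $G = H - TS$ on every record, and Gibbs–Helmholtz consistency.
Monte-Carlo checks use 100–200 seeded replicates at $\sigma = 0.005$–$0.01$
on the 55-cell study grid — large enough for 2–3 standard-error bias
bounds, small enough that the whole suite runs in well under a minute.

## Known limitations

* The mixing-thermodynamics stage reports solute-only excess quantities;
  full Wilson/NRTL/UNIQUAC parameter estimation is out of scope.
* Jouyban–Acree predictions (unlike the van't Hoff-anchored variant)
  require temperatures present in the fitted grid, since the model
  anchors on measured pure-solvent solubilities.
* Intercepts of van't Hoff fits are extrapolations to $1/T = 0$ and are
  highly sensitive to rounding of the input solubilities; refits from a
  3-significant-figure grid can differ from coefficients computed on
  unrounded data by a few percent even when slopes, predictions and
  deviations agree closely.
* No molarity or density-based unit conversions; no uncertainty
  propagation from measurement replicates.
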