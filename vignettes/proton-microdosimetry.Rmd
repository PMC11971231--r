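---
title: "Analytic microdosimetry of protons: model and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic microdosimetry of protons: model and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microlineal)
```

## The quantity being computed

The lineal energy of a single event in a site is $y = \varepsilon/\bar l$,
the energy imparted divided by the site's mean chord length; its
dose-weighted average
$$y_D = \frac{\int y^2 f(y)\,dy}{\int y f(y)\,dy}$$
is the radiation-quality indicator this package computes for protons of
1 MeV--1 GeV crossing liquid-water spheres of 10--1000 nm diameter.  In the
site model of the theory of dual radiation action the low-dose limit of the
relative biological effectiveness is the ratio of dose-mean lineal
energies, which is identified with the quality factor
$Q(T) = y_D(T)/y_D(T_\mathrm{ref})$; the reference proton energy defaults
to 100 MeV.

Events split into *crossers* (the proton traverses the site; "direct") and
*touchers* (the proton passes outside but its delta electrons reach the
site; "indirect").  The two contributions combine as
$$y_D = f_\mathrm{ion}\, y_{D,\mathrm{dir}} +
        (1 - f_\mathrm{ion})\, y_{D,\mathrm{ind}},$$
where $f_\mathrm{ion}$ is the fraction of the proton's energy loss retained
inside the site, computed from the ratio of restricted to unrestricted LET
with delta-ray in/out-flux corrections:
$$f_\mathrm{ion} =
  \frac{\ln\!\big[E_\mathrm{max}(\Delta + \Delta_1 + \Delta_2)/I^2\big]}
       {2\ln\!\big[E_\mathrm{max}/I\big]},\qquad
  \Delta_1 + \Delta_2 = \Big(1 - \frac{\Delta}{E_\mathrm{max}}\Big)(I + \Delta).$$
Here $I = 0.078$ keV is the mean excitation energy of water,
$E_\mathrm{max}$ the exact two-body maximum delta-electron energy, and
$\Delta$ the cut-off energy of electrons whose range equals the mean chord
$\bar l = 2d/3$.  The bundled cut-offs are $\Delta = 0.180$, $1.37$ and
$5.56$ keV for $d = 10$, $100$ and $1000$ nm; other diameters interpolate
log-log between these, which is flagged as an approximation whenever used
(inverting an electron range--energy relation is outside this package's
scope).

## Direct events

The energy imparted by a crosser is modelled by a parametric straggling
distribution with mean
$\bar\varepsilon = f_\mathrm{ion} \cdot \mathrm{LET} \cdot \bar l$ and
relative variance $V = V_s + V_\delta$, where $V_s = 1/8$ is the chord
relative variance of a sphere under $\mu$-randomness (exact for
$c(l) = 2l/d^2$), LET fluctuations are neglected (the proton loses a
negligible fraction of its energy in a sub-micron site), and
$V_\delta = \delta_2/\bar\varepsilon$ is the straggling term.  Three
families are supported and matched to $(\bar\varepsilon, V)$:

* **log-normal**, $\sigma^2 = \ln(1+V)$, $\mu = \ln\bar\varepsilon - \sigma^2/2$;
* **gamma-Erlang**, rate $\lambda = 1/(V\bar\varepsilon)$, shape $\kappa = 1/V$
  --- $\kappa$ is non-integer for every realistic $V$ (at least $1/8$), so the
  Erlang factorial is generalized to $\Gamma(\kappa)$;
* **logistic**, location $\bar\varepsilon$, scale
  $s = (\sqrt3/\pi)\bar\varepsilon\sqrt V$.  Its support includes negative
  deposits; the density is truncated at zero and renormalized before any
  moment or spectrum is formed.  This truncation is what makes the logistic
  results differ from the other two families, which are already
  positive-support and give practically identical $y_D$.

Two spectrum constructions are provided.  The default (`single`) builds one
distribution carrying the full variance budget $V$.  The alternative
(`chord_convolved`) mixes per-chord distributions --- mean proportional to
the chord $l$, variance from straggling only --- over the chord pdf.  For
untruncated families both reduce to the same closed form
$$y_{D,\mathrm{dir}} = f_\mathrm{ion}\,\mathrm{LET}\,(1 + V_s) +
  \delta_2/\bar l,$$
which the test suite verifies to 0.5%; the choice is therefore exposed as a
flag rather than silently fixed, and matters only for the truncated
logistic.

## The straggling factor from first principles

$\delta_2$ is the dose-weighted energy deposited per single collision,
restricted to deposits that stay local:
$$\delta_2 = \frac{\sum_n \int (E+B_n)^2\, \frac{d\sigma_n}{dE}\, dE}
                  {\sum_n \int (E+B_n)\, \frac{d\sigma_n}{dE}\, dE},$$
with sums over the ionization shells and the integrals restricted by the
cut-off $\Delta$.  Two readings of that restriction are possible: on the
ejected-electron energy ($E \le \Delta$) or on the deposit
($W = E + B_n \le \Delta$).  They differ only once the oxygen K shell opens
(deposits of 0.54 keV and above at $\Delta = 0.180$ keV).  This package
restricts the deposit: that reading reproduces the classical Kellerer
comparator's construction (a $1/E^2$ spectrum restricted at $\Delta$, giving
$\delta_2 = \Delta/(2\ln(\Delta/I))$) like-for-like, and it preserves the
expected ordering --- the first-principles $\delta_2$ stays below Kellerer's
at every canonical cut-off, as the $1/E^2$ approximation overweights small
transfers' complement.  Comparator forms (`kellerer`, `xapsos`, and a
`fitted` power-law summary $0.0074 + 0.174\Delta^{0.651}$ keV) are exposed
alongside the first-principles `rpwba` method.

A caveat the acceptance machinery makes explicit: fitting
$a + b\Delta^c$ through the three canonical cut-offs puts all of the
exponent's information into the curvature between three points.  With the
dielectric parameterization bundled here the energy-averaged values are
$\{0.054, 0.221, 0.604\}$ keV, whose exponent is $c \approx 0.73$ ---
close to, but measurably steeper than, the $0.651$ of the power-law
summary quoted above.  The end-point curvature is sensitive to
parameterization and dispersion details (and to exchange and low-energy
Born corrections, which are deliberately out of scope); the mid-point
value is robust.

## Proton inelastic cross sections

All first-principles inputs (stopping power, $\delta_2$, the indirect-term
weights) come from differential ionization cross sections in the dielectric
formulation of the relativistic plane-wave Born approximation.  The DICS is
a longitudinal plus a transverse term: the longitudinal term integrates the
energy-loss function over recoil energy,
$$\frac{d\sigma_L^{(n)}}{dE} = \frac{2}{\pi a_0 N mc^2 \beta^2}
  \int_{q_-}^{q_+} \mathrm{ELF}^{(n)}(W,q)\,
  \frac{q + mc^2}{q(q + 2mc^2)}\, dq,$$
between the exact relativistic recoil limits; the transverse term uses the
optical ($q = 0$) ELF with the velocity factor
$\ln\!\big(1/(1-\beta^2)\big) - \beta^2$ (small-angle approximation, no
density-effect correction).  The stopping power is the
energy-transfer-weighted integral of the DICS plus the
transition-energy-weighted excitation cross sections.

### The dielectric model

The ELF of liquid water is a sum of Drude oscillator channels: five
ionization shells (1b1, 3a1, 1b2, 2a1, 1a1) and five discrete excitations
(A$^1$B$_1$, B$^1$A$_1$, Rydberg A+B, Rydberg C+D, diffuse band).  Each
channel contributes
$f_j\,\Omega_p^2\,\gamma_j W / [(E_j(q)^2 - W^2)^2 + (\gamma_j W)^2]$ above
its threshold, where $\Omega_p$ is the one-electron-per-molecule plasma
energy (6.79 eV at unit density), so amplitudes count electrons.
Ionization resonances disperse as $E_j(q) = E_j + q$ (free-particle
quadratic dispersion in the recoil energy, producing the Bethe ridge);
excitations are carried undispersed up to a configurable recoil cut
(100 eV by default) and dropped beyond it, consistent with the transverse
term's near-zero-momentum restriction.

The published coefficient set behind the reference electron model is not
printed anywhere accessible, so the bundled coefficients
(`inst/extdata/water_drude.yaml`) are this package's own calibration of the
same Drude family against three integral constraints of liquid water:

* the optical f-sum rule --- the model carries 9.95 effective electrons per
  molecule (target 10);
* the dipole mean excitation energy --- the model implies $I = 78.0$ eV
  (the ICRU recommendation for water);
* the collective optical resonance --- peak at 21.2 eV with height 1.42.

Every coefficient lives in the YAML config, so an alternative
parameterization is a config swap.  Construction of a model validates the
sum rule and non-negativity; downstream code can assume a sane model.

## Indirect events

The indirect term is a frequency-weighted average of electron dose-mean
lineal energies over the secondary-electron spectrum:
$$y_{D,\mathrm{ind}} = \frac{\sum_n \int_\Delta^{E_\mathrm{up}}
  y_D^{e}(E, d)\, \frac{d\sigma_n}{dE}\, dE}
  {\sum_n \int_\Delta^{E_\mathrm{up}} \frac{d\sigma_n}{dE}\, dE},$$
with the lower limit at the geometric cut-off (Spencer--Attix reasoning).
The upper limit is taken as the proton-kinematics maximum $E_\mathrm{max}$:
the $(E+B_n)/2$ form sometimes quoted for this integral is an
electron-projectile (indistinguishability) convention that is circular for
proton impact, so it is not used.  The electron values $y_D^e(E, d)$ must
come from electron track-structure transport, which this package does not
do: the table is an explicit plug-in (`electron_yd_table`, CSV-backed).
The bundled table is *synthetic* --- an electron-LET-like magnitude scaled
by the idealized continuous-slowing-down conversion $y_D = (9/8) y_F$, a
mild small-site enhancement, and seeded log-normal jitter --- labelled
non-authoritative in its metadata.  Every test that needs the indirect
term uses synthetic tables, so no quantitative claim rests on the
placeholder; users with real electron tables supply them as CSV.

At proton energies where $E_\mathrm{max} \le \Delta$ (e.g. 2 MeV protons
and the 1000 nm sphere), every delta electron stays local: the curve
builder sets $f_\mathrm{ion} = 1$, caps the cut-off at $E_\mathrm{max}$,
and reports no indirect component rather than extrapolating.

## The Monte Carlo oracle

`simulate_direct()` is a seeded stochastic twin of the direct-event
machinery: draw a chord by inverse CDF ($l = d\sqrt u$), draw a deposit
from the per-chord straggling law (the logistic by rejection of negatives,
which samples the truncated law exactly --- clipping would bias the
moments), record $y = x/\bar l$.  Runs are bit-for-bit reproducible for a
fixed seed and do not disturb the caller's RNG stream.  Empirical
$y_F, y_D$ carry delta-method standard errors for the moment ratio; the
suite checks 3-SE agreement with the analytic spectra for all three
families, including the truncated logistic, and the $1/\sqrt n$ error
decay over $n = 10^3$--$10^5$.

## Comparison statistics

`rd_mpd()` implements the per-energy relative difference against the
arithmetic mean of externally supplied track-structure datasets and its
absolute mean (the mean percentage deviation).  Each dataset carries a
stated maximum valid energy; the baseline at each energy averages only the
sources whose validity covers it, so baseline membership switches exactly
at those limits (emulating codes valid to 300 MeV alongside codes valid to
1 GeV).  Mismatched grids are interpolated log-log, never extrapolated.
The synthetic fixture generator produces six sources (four valid to
300 MeV, two to 1000 MeV) as smooth decreasing curves with per-source
multiplicative perturbations; real comparisons require real datasets,
which are not bundled.

## Numerical choices

* **Recoil-energy quadrature.**  The longitudinal integrand has three
  regimes: a $1/q$ soft-collision stretch spanning up to twelve decades, a
  Lorentzian Bethe ridge at $q^* = W - E_j$ whose relative width
  $\gamma/W$ can reach $10^{-3}$, and dispersion structure at recoil
  energies of the order of the oscillator parameters.  The node set is the
  union of a global log grid, a tan-spaced core with geometric wings around
  the ridge (also engaged when the ridge sits just *below* $q_{\min}$,
  which is exactly the geometry as $W \to E_\mathrm{max}$), and a denser
  patch over 0.8--1500 eV.  Integration is trapezoidal in $\ln q$, which
  is exact on the $1/q$ stretches; all quadratures accept a `density`
  factor, and doubling it moves the stopping power by under 0.1%.
* **Outer integrals.**  Secondary-energy integrals use log-grid trapezoids
  (about 48 nodes per decade); an adaptive Gauss--Kronrod path is provided
  and agrees within 0.5%.
* **Spectra.**  $f(y)$ lives on a 2048-point log grid spanning the
  $10^{-8}$ to $1 - 10^{-7}$ quantile range of the straggling family;
  moments are trapezoidal in $\ln y$.  Near-degenerate mixture components
  (tiny chords under the gamma family) place a sub-percent probability
  mass at vanishing deposits below the grid; that mass carries no lineal
  energy, so the density is renormalized, with a 2% deficit treated as
  quadrature breakdown.
* **Caching.**  First-principles $\delta_2$ values are cached per
  (model, energy, cut-off) within a session.
* **Problem sizes.**  The test suite and the acceptance script use
  10-point energy grids, $10^5$-history oracle runs, and the
  $10 \times 3$ energy--cut-off grid for the straggling-factor fit;
  together they complete in a few minutes on one core.

## Known limitations

* First-order Born throughout: no Barkas or Bloch terms, no shell or
  exchange corrections, no low-energy corrections, no nuclear stopping.
  Below a few MeV the stopping power is therefore a few percent low; at
  1 GeV the absence of a density-effect correction leaves the relativistic
  rise slightly too strong.
* The indirect term is only as good as the electron table plugged in; the
  bundled placeholder is a smooth heuristic, not transport.
* Protons are assumed to be crossers with constant LET across the site
  (no stoppers/starters, $V_\mathrm{LET} = 0$); valid for the stated
  energy and size ranges, not below them.
* Cut-offs for non-canonical diameters are log-log interpolations, not
  range inversions.
* The synthetic data generators emulate curve shapes, validity windows and
  seeded scatter of track-structure results --- not their physics.  Tests
  passing on synthetic fixtures validate the statistical machinery
  (baseline membership, RD/MPD arithmetic, determinism), not agreement
  with any real code.
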