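---
title: "Methods: fusion-pore energetics and single-pore current analysis"
author: "snarepore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion-pore energetics and single-pore current analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snarepore)
```

# Overview

`snarepore` studies how crowding of SNARE proteins dilates exocytotic
fusion pores, in the geometry of the nanodisc-cell single-pore assay: a
discoidal bilayer particle of diameter $D \approx 24$ nm, bounded by ApoE
scaffold proteins and carrying $N$ v-SNAREs per face, fuses with a
t-SNARE-presenting plasma membrane, opening a nanometre-scale pore whose
conductance can be recorded in the cell-attached patch configuration.

The package has two halves that meet in the middle:

* an **equilibrium free-energy model** $U(r_{po}, N)$ of the pore, whose
  Boltzmann statistics predict the preferred pore radius, the net inward
  force resisting dilation, and how both change with SNARE availability;
* an **electrophysiology pipeline** that turns raw current traces into
  idealized bursts, flickers, per-pore conductances and radii, and, via
  Boltzmann inversion of the radius distribution, an *apparent* free
  energy directly comparable with the model.

A synthetic-recording generator with exact ground truth closes the loop:
every pipeline stage is validated end to end without any external data.

# The equilibrium pore model

## Geometry

The pore is a toroid connecting the disc to an effectively infinite
planar membrane.  Its midplane is the surface of revolution of a
semicircle of radius $H = h/2 + \delta/2$ whose waist sits at
$R = r_{po} + \delta/2$ from the symmetry axis, where $r_{po}$ is the
pore (lumen) radius, $h$ the membrane separation at the rim and
$\delta = 5$ nm the bilayer thickness.  Small pores are fully toroidal.
When $r_{po} + h/2 + \delta \ge D/2$ the toroid no longer fits inside the
disc: the shape is truncated at the disc rim and the scaffold proteins
there must rotate by a twist angle

$$\phi = \arcsin\!\left(\frac{r_{po} + h/2 + \delta - D/2}{h/2}\right).$$

Beyond $r_{po} = D/2 - \delta$ no truncated toroid exists at any $h$,
which caps the radius grid at 7 nm for the default geometry.

## Energy terms

For one microstate $(r_{po}, h, N_z)$ the total energy (in $kT$) is the
sum of:

* **Bending.** The Helfrich curvature energy
  $U_{bend} = \kappa \oint C^2\, dA$ with $C = (c_1 + c_2)/2$ the mean
  curvature and $\kappa = 20\,kT$, evaluated in closed form over the
  (possibly truncated) toroid midplane.  Note the convention: the package
  uses $\kappa\!\oint\!C^2$, one of the two common normalisations of the
  Helfrich energy (the other, $\tfrac{\kappa}{2}\oint (c_1+c_2)^2$, is
  exactly twice as large; the value of $\kappa$ is tied to the
  convention).  The closed form is verified against direct numerical
  surface quadrature of the same integrand to $10^{-6}$ relative accuracy
  in the test suite.
* **Tension.** $U_{tens} = \gamma \, \Delta A$ with
  $\Delta A = A_{wall} - A_{rims}$: the toroid wall area minus the two
  flat discs of radius $R + H$ it replaces (in the truncated regime, the
  disc-side rim is the whole disc face).  At fixed $h$, $\Delta A$ can
  *decrease* with $r_{po}$, which looks like tension assisting dilation;
  along the conditionally optimal separation $h^\*(r_{po})$, however, the
  separation grows with the pore and the tension term robustly resists
  expansion (about $+3\,kT$ per nm at the default parameters).  This
  path-dependence is why the decomposition below is always evaluated at
  $h^\*$.
* **Steric hydration.** Short-ranged repulsion between apposed bilayers,
  $P(d) = P_0 e^{-d/\lambda}$ with $\lambda = 0.10$ nm, integrated over
  the flat disc-membrane gap and over the pore lumen (an effective
  cylinder of height $l = 2\sqrt{\lambda(h/2+\delta)}$).  It builds the
  repulsive wall that sets the preferred radius near 0.5 nm, and is
  evaluated for fully toroidal shapes only — its range is negligible once
  the shape reaches the disc rim.
* **Scaffold twisting.** $U_{ApoE} = \tau \pi D \phi$: the ApoE belt
  resists rotation with constant torque per unit length
  $\tau = 8.43$ pN, producing a steep wall against very large pores.
* **SNAREs.** Of the $N$ v-SNAREs on the disc face, $N_z$ are fully
  zippered and form a ring of rods (footprint $b = 2$ nm) at the pore
  waist; the remaining $N - N_z$ are partially zippered and roam the
  disc.  The zippered ring contributes one-dimensional positional entropy
  on the free circumference $2\pi r_{po} - N_z b$, the zippering energy
  $-\varepsilon_{zip}$ per pin, and an orientational confinement penalty
  $-kT \ln \Omega_z$ **per transmembrane anchor** — a fully zippered pin
  bridges both membranes through two stiff TMD anchors, so the default
  counts the confinement twice (`tmd_anchors = 2`).  Roaming pins
  contribute positional entropy on the disc boundary and a hemispheric
  orientational freedom.  States with $N_z b \ge 2\pi r_{po}$ are
  excluded (zero weight).

## The state sum

$$e^{-U(r_{po}, N)/kT} \;=\; \sum_{N_z = 0}^{N} \binom{N}{N_z}
  \int_{b}^{h_{max}} e^{-U_{tot}(r_{po}, h, N_z)/kT}\, dh .$$

The binomial factor counts which subset of the $N$ identical SNAREs is
zippered (`state_multiplicity = TRUE`); together with the per-anchor
orientational penalty it fixes the zippering equilibrium so that, at the
default $\varepsilon_{zip} = 9.6\,kT$, the mean number of zippered pins
grows smoothly with pore size rather than saturating the ring.  With
these defaults the model reproduces its reference phenomenology: the
minimum near 0.5 nm that barely shifts with $N$, a net inward force of
$\sim$22 pN without SNAREs falling to $\sim$5 pN at $N = 15$, and a
$\sim$3.0/2.4 $kT$ tension/bending decomposition of the first nanometre
of expansion.  Both counting choices are exposed as parameters, so the
single-factor, unweighted-sum variant is one switch away; that variant
cannot reproduce the reference phenomenology (its minimum migrates to
$\sim$3.7 nm at $N = 15$).

## Numerical choices

* **Separation integral.** Deterministic composite Simpson quadrature on
  $[b, h_{max}]$ with $h_{max} = 20$ nm and 400 nodes.  The integrand has
  a derivative kink at the toroidal/partial boundary and decays on a
  $\sim$0.03 nm scale just above it (the torque wall), so the nodes are
  placed in graded panels around that point; doubling the node count
  changes $U$ by less than $10^{-6}\,kT$ anywhere on the grid.  A
  diagnostic warning fires if the integrand has not decayed at
  $h_{max}$.
* **Radius grid.** 0.25–7 nm in 0.025 nm steps (7 nm is the geometric
  maximum for the default disc).  Minima are refined below the grid step
  by parabolic interpolation.
* **Force window.** The net inward force is the mean of $dU/dr_{po}$
  over $[1.5\,\text{nm}, r_{max}]$ converted to pN, where $r_{max}$ is
  the largest radius whose conditionally optimal SNARE-free shape is an
  *interior* toroid, i.e. not pressed against the partial-regime boundary
  (3.275 nm at the defaults).  Beyond $r_{max}$ the disc edge dominates
  the landscape and the "inherent bilayer resistance" reading of the
  slope no longer applies.
* **Work decomposition.** Tension and bending works over an expansion
  are differences of the respective terms evaluated at the conditionally
  optimal separation $h^\*$ of each endpoint, with the expansion taken
  from the free-energy minimum over 1 nm.
* **Temperature.** $kT \leftrightarrow$ pN nm conversions use
  $T = 298$ K ($kT = 4.11$ pN nm), configurable through
  `model_params(T = )`.
* **Lipid-anchor variant.** `lipid_anchor_delta()` halves the zippered
  rod's footprint in the excluded-volume term only (the entropy length
  unit is a fixed reference) and finds, by bisection to $0.01\,kT$, the
  decrease in $\varepsilon_{zip}$ that keeps the Boltzmann-mean pore
  radius at $N = 15$ unchanged; the default parameters give
  $\approx 0.58\,kT$.

## Staged parameter fitting

`fit_hydration_and_tension()`, `fit_zippering()` and `fit_torque()`
implement a deliberately sequential recipe against reference curves:

1. $\lambda$ moves the hydration wall until the SNARE-free minimum
   matches the reference minimum (parabolically refined argmin).
2. $\gamma$ matches the mean slope on 0.5–1.0 nm, where tension
   dominates.  The search is restricted to $\gamma \le 1.5$ pN/nm: at
   unphysiologically high tensions the separation is clamped to its
   minimum and the slope becomes non-monotone in $\gamma$, creating a
   second, spurious solution branch.
3. $\varepsilon_{zip}$ matches the slope of an $N = 15$ curve on
   0.5–2.5 nm, where crowding controls the flattening.
4. $\tau$ matches the slope of an $N = 4$ curve on 4.0–4.5 nm, inside
   the partially toroidal regime (an error is raised if the window is
   fully toroidal, where $\tau$ has no effect).

All slope matching is least squares on finite-difference slopes at the
reference's own abscissae, optimised by golden-section search with
$10^{-3}$ tolerance in parameter units.  On model-generated references
the full recipe recovers $(\lambda, \gamma, \varepsilon_{zip}, \tau)$ to
about 1%, and the fits are exactly invariant to constant offsets of the
reference curve.

# The current-trace pipeline

## Conditioning and idealization

Raw currents (20 kHz sampling, 16 mV driving force) are low-pass
filtered at 280 Hz with a zero-phase Butterworth filter (a half-order
section run forward-backward realises the nominal 8th-order magnitude
response without phase distortion), optionally notch-filtered at line
frequencies, and decimated by non-overlapping 80-point block means to
250 samples/s (125 Hz bandwidth), bringing baseline rms noise to
$\lesssim 0.2$ pA.

Idealization rules, in order:

* **Bursts** (`detect_bursts`): clusters of $|I| > 2$ pA excursions.
  Excursions separated by sub-threshold gaps shorter than `max_gap`
  (default 1 s — between the flicker and burst-separation timescales)
  are merged, and a cluster is accepted once its cumulative
  above-threshold time reaches 250 ms.  The burst lifetime $T_0$ is
  threshold-to-threshold and includes intra-burst closures.
* **Flickers** (`detect_flickers`): within a burst, open periods are
  maximal runs with $I < -0.25$ pA lasting at least 15 samples (60 ms);
  the flicker count is the number of open periods.
* **Records** (`pore_record`): point-by-point open-state conductances
  $G = |I|/V$, their mean $G_{po}$, the open probability
  $P_o$ = open time / $T_0$, and open-pore radii from the cylinder
  approximation $r_{po} = \sqrt{\rho \lambda_c G / \pi}$ with
  $\rho = 0.60$ Ω·m and channel length $\lambda_c = 15$ nm (two bilayers
  plus the gap); 1 nS corresponds to 1.7 nm.

## Distributions, inversion, dwell statistics

Per-pore open-state distributions use a fixed bin width (50 pS / 0.1 nm
by default) on a shared binning and are averaged *across pores with
equal weight*, so long-lived pores do not dominate.  The apparent free
energy is $U/kT = -\ln P + A$ with $P$ the per-bin mass and $A$ set so
$\min U = 0$; unobserved bins are reported as `NA` rather than
$+\infty$.  Flicker counts are fitted by a geometric law on
$n = 0, 1, 2, \dots$ (MLE $\hat p = 1/(1 + \bar n)$, delta-method CI),
burst lifetimes by an exponential (MLE mean, SE $= \bar T_0/\sqrt n$),
and nucleation rates are per-recording bursts/minute with user-supplied
exclusion windows removed from both numerator and denominator, averaged
unweighted across recordings.

## Conductance states and the dilation sigmoid

Per-pore mean conductances separate into a small ($\sim$300 pS) and a
large (several nS) population.  `fit_conductance_mixture()` fits a
two-component Gaussian mixture (EM with deterministic hierarchical
initialisation, optionally on the log scale) and reports the
responsibility-crossing boundary; `classify_pores()` applies the fixed
1 nS cut by default (strictly greater; a pore at exactly 1 nS is small).
The dilation probability per condition is the fraction of large pores
with a Wilson interval, and `fit_dilation_sigmoid()` fits
$P(N) = e^{(N - N_0)/b} / (1 + e^{(N - N_0)/b})$ — the two-state
Boltzmann form in the copy number — by unweighted least squares with
logit-linearised starting values, which makes noise-free recovery exact.

# The synthetic generator

`synth_trace()` emulates what the analysis assumes about cell-attached
recordings: a flat baseline; bursts placed by a renewal process
($\sim$0.2/min by default); per burst, $\max(1, n)$ open periods with
$n$ geometric ($p = 0.0573$); exponential open and closed dwells whose
geometric-sum structure makes burst lifetimes approximately exponential
with the target 10.3 s mean; open currents $-G \times V$ with $G$ fixed,
mixture-drawn per burst, or sampled point-by-point from the Boltzmann
weights of a supplied free-energy profile; and white Gaussian noise at
the raw rate.  Two deliberate idealisations serve testability: event
boundaries are quantised to the decimated grid, and the first open
period is at least 250 ms, so every generated burst is detectable and
the noise-free round trip through the pipeline is *exact* (with the
280 Hz filter enabled, edge transients of one or two samples per
transition perturb $G_{po}$ and $P_o$ at the percent level, which the
tests bound explicitly).

What the generator does **not** emulate — coloured/1-f noise, baseline
drift and seal instabilities, overlapping pores, finite filter rise
times in the recording chain, within-open-state correlated conductance
fluctuations for the fixed and mixture sources — bounds what green tests
mean for real data: they validate the algorithmic chain, not robustness
to every experimental artefact.

## Validation problem sizes

The test suite runs the detection sensitivity/specificity check on 12
noisy synthetic recordings of 2 minutes each (raw-noise sd 1.6 pA,
$\sim$0.18 pA post-processing rms; $\ge 95$% of true bursts recovered,
zero false bursts), the flicker/lifetime marginals on 200 bursts, the
geometric-CI coverage on 200 replicates of 64 bursts, the Boltzmann
inversion round trip on $10^4$ open samples, and mixture recovery at
$n = 99$ pores.  These sizes were chosen as the smallest that make the
statistical assertions sharp.

# Known limitations

* The model is equilibrium-only: flicker kinetics, dwell-time dynamics
  and nucleation rates are outside its scope.
* Partially toroidal shapes are a single-parameter truncation ansatz; no
  shape relaxation is attempted, and hydration is ignored in that
  regime.
* The bending/orientational conventions noted above are part of the
  model definition; comparisons with differently normalised bending
  moduli must rescale $\kappa$ accordingly.
* The lipid-anchor calculation treats the footprint reduction as the
  only effect of replacing a TMD by a lipid anchor.
* Exclusion of unstable-baseline periods is user-supplied; no automatic
  seal-quality diagnostics are attempted.
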