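---
title: "Gene circuit models of the gap gene network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene circuit models of the gap gene network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapCircuits)
```

# The model

gapCircuits implements the *gene circuit* formalism for the *Drosophila*
trunk gap gene system: a hybrid dynamical model of a one-dimensional row of
syncytial blastoderm nuclei, each running identical regulatory dynamics.
During interphase the concentration $v_i^a$ of gap gene product $a$ in
nucleus $i$ obeys

$$\frac{dv_i^a}{dt} = R^a\, g(u_i^a)
  + D^a(n)\left[(v_{i-1}^a - v_i^a) + (v_{i+1}^a - v_i^a)\right]
  - \lambda^a v_i^a,$$

with the sigmoid regulation-expression function
$g(u) = \tfrac12\!\left(u/\sqrt{u^2+1} + 1\right)$ and total regulatory
input

$$u_i^a = \sum_b w^{ba} v_i^b + \sum_m e^{ma} v_i^m + h^a.$$

$W = (w^{ba})$ and $E = (e^{ma})$ are the interconnectivity matrices of
gap–gap and external-input weights (sign encodes activation / repression /
no interaction), $R^a$ the maximum synthesis rate, $D^a$ the diffusion
rate, $\lambda^a$ the decay rate and $h^a$ a threshold representing
uniformly distributed maternal factors.  The external inputs — the
maternal gradients Bcd and Cad and the terminal gap genes Tll and Hkb —
are time-dependent forcing profiles, not state variables.

The hybrid part is the cleavage cycle: simulation starts at the beginning
of cycle 13 ($t = 0$), mitosis runs from 16.0 to 21.0 min (gene product
*synthesis* is set to zero; decay and diffusion remain active, and the
external inputs are still evaluated — they only enter through $g$, which
is off), and at 21.0 min an instantaneous division copies every mother
concentration to both daughter nuclei and doubles the lattice.  Diffusion
acts between nearest neighbours with no-flux boundaries (the missing
neighbour term is simply omitted at the edges).  Because the
inter-nucleus distance halves at division, the effective diffusion rate is
rescaled Fickian-style, $D_\mathrm{eff}(n) = D\cdot 4^n$ with $n$ the
number of prior divisions ($D/l^2$ with $l \to l/2$).

The modelled region is the trunk, 35–87 % A–P position (0 % = anterior
pole).  The axis holds 50 nuclei at C13 and 100 at C14A; nucleus $j$
(0-based) spans $[100j/n, 100(j+1)/n)$ % A–P and is included iff its span
intersects the closed trunk interval.  This convention yields 27 trunk
nuclei at C13 and 53 at C14A (58 for the extended 35–92 % region), i.e.
circuits of 108 and 212 ODEs for four gap genes.  After division the 27
mothers produce 54 daughters of which the daughter whose span falls
outside the trunk — the most anterior one under this index convention —
is dropped, leaving the 53-nucleus C14A lattice.

Integration uses a stiff-capable adaptive method (`deSolve::lsoda`,
defaults `rtol = 1e-6`, `atol = 1e-8`) with the right-hand side in
compiled C; mitosis entry/exit and the division are integration
breakpoints (stop/restart), never stepped over.  External inputs are
sampled onto a 1-minute grid per segment and linearly interpolated inside
the compiled code.  A fixed-step RK4 integrator written independently in
plain R serves as a brute-force oracle in the test suite (agreement within
$10^{-4}$ relative on a two-gene toy circuit).

## Fixed parameters

Following standard practice for gap gene circuits, the thresholds are
fixed at $h^a = -2.5$ for all gap genes, and all Hkb weights except
Hkb→*hb* are fixed at zero.  The mask system
(`defaultMask()`, the `mask` slot of `CircuitParameters`) stores a
free/fixed flag per entry, so any other fixing variant can be configured
without code change; fixed entries are guaranteed never to move through
the fitting interface.

# From boundary annotations to fitting data

The quantification strategy represents each expression domain edge as a
three-point *boundary spline*: anchors $(x_0, 0)$ where staining reaches
background and $(x_2, 1)$ where it reaches maximum, midpoint at the mean
$x$.  The interpolant is a monotone two-piece cubic with zero first
derivative at both end knots.  Edges are "rising" (anterior edge of a
domain, $x_0 < x_2$) or "falling" (posterior edge, $x_0 > x_2$).  Median
boundaries are computed per (gene, time class, boundary id) group as
coordinate-wise medians of start and end anchors (even group sizes: mean
of the two central values).

`assembleProfile()` integrates a gene's median boundaries at one time
class into a normalised profile: spline values across each edge span,
plateau 1 between a rising edge and the next falling one, 0 outside,
sampled at the nucleus bin centres (50 bins at C13, 100 at C14A).
Overlapping spans of the same gene are an error; the profile is invariant
under re-ordering of the input boundaries.

Four post-processing steps make the normalised profiles comparable to
quantitative protein data, applied in this order by `postprocess()`:

1. **binning** to the 50/100-bin axis (done by the sampling above);
2. **spatial intensity scaling**, linear from ×1.0 at 50 % A–P to ×0.5 at
   both poles ($1 - |x-50|/100$), reflecting brighter central domains;
3. **temporal scaling** by the unique quadratic through 0.1 at expression
   onset ($t=0$), 1.0 around T5 ($t=48$ min) and 0.7 at gastrulation
   ($t=71.1$ min), emulating gradual mRNA accumulation and late decay
   ("second-degree spline": the quadratic is the simplest curve through
   the three printed anchors with an interior peak, which falls at 45 min);
4. **×200**, putting mRNA data on the concentration scale of
   protein-based circuits.

Steps 2 and 3 commute (independent multipliers); binning does not, which
is why it comes first.

**WLS weights.**  Variances are not measured by this pipeline, so weights
are approximated from expression level: $v = 1/(\varepsilon + \hat y)^2$
with $\hat y$ the normalised (pre-×200) intensity and $\varepsilon = 0.1$.
Any strictly-decreasing-in-$\hat y$ formula satisfies the design contract
(variation grows with expression level); this one is bounded at
$v(0) = 100$ and penalises ectopic expression in non-expressing regions
most, which is its practical purpose.  Both the formula's
$\varepsilon$ and the boundary width are configurable.

**Packaged boundary table.**  The published median mRNA boundary
positions of the six trunk domains over the nine time classes (C13,
T1–T8) ship as a plain-text table; `loadTable2Fixture()` turns each
printed position into a spline start anchor with a default width of 5 %
A–P into the domain.  Domains too narrow for two full-width edges (late
posterior *gt*, for instance) have both spans shrunk symmetrically to
meet at the domain midpoint.  The result is the standard 1804-point
dataset: 4 genes × (27 C13 + 8 × 53 C14A nuclei).

**Posterior Kr.**  The posterior *Kr* domain appearing in late C14A is
under terminal-gap/Forkhead control outside the modelled network;
`dropPosteriorKr()` removes it, either as annotation rows or by zeroing
the posterior contiguous Kr run at late time classes of an assembled
dataset (idempotent; warns when nothing is found).

**Initial conditions** at $t = 0$ interpolate linearly in time between a
cycle-12 anchor ($t = -6.2$ min, zeros by default: mRNA levels are low at
the start of C13, and the quantified tables contain no C12 data) and the
dataset's C13 time class ($t = 10.55$ min).

# External inputs

All input profiles share one evaluation contract, $f(x, t)$, and the
fitting machinery never branches on whether a profile is measured or
artificial.  The artificial generators are:

* **Bcd** — a time-constant anterior exponential $A e^{-x/L}$, fit by
  least squares in linear space to all available samples pooled across
  time (`fitBcdExponential()`; a log-space fit is available).
* **Cad** — a smooth surface satisfying three qualitative features: (1)
  complementary to the Bcd gradient, (2) abdominal (50–80 % A–P)
  expression decaying over time, (3) a posterior stripe near 80 % A–P
  appearing from T6 onwards.  The original construction used thin-plate
  splines over unpublished control points; this package instead builds a
  closed-form surface (mirrored exponential × smooth decay window +
  ramped Gaussian stripe) and validates it against the three feature
  predicates, which is the testable part of the contract.
* **Tll / Hkb** — time-invariant profiles obtained by averaging each
  boundary's anchors over all time classes and assembling the mean
  boundaries.

Amplitudes of artificial inputs are not published; the default is 200,
matching the ×200 gap-gene concentration scale, and is configurable
(`artificialInputs(config = ...)`).

# Fitting

The cost is weighted least squares over every gene, nucleus and data time
class, $S(\theta) = \sum v\,(\text{model} - \text{data})^2$; with all
weights 1 it reduces to ordinary least squares, and both modes are
provided.  Goodness of fit is reported as the *unweighted*
$\mathrm{RMS} = \sqrt{\sum(\text{model}-\text{data})^2 / N_d}$, which is
comparable across weighting schemes and datasets.

Global optimisation uses simulated annealing with the Lam–Delosme
adaptive schedule (`lamAnneal()`): single-coordinate Gaussian moves
reflected into box bounds, per-coordinate move scales adapted towards a
target acceptance ratio of 0.44, an accept-all warm-up that estimates the
energy scale, and the inverse-temperature update
$dS \propto 4\rho(1-\rho)^2 / \left[(2-\rho)^2 S^2 \sigma^3\right]$
driven by smoothed acceptance-ratio and energy-variance statistics.  As
the temperature falls the dynamics reduce to greedy descent; a small
Nelder–Mead polish refines the best point.  Runs are deterministic given
the seed.  The original published fits used a 50-core parallel annealer
for ~7 h per run; that scale is explicitly not reproduced here — the
optimiser contract is validated by property (parameter recovery, below),
not by trace identity.  The optimizer is pluggable: any function with the
`lamAnneal()` signature can be passed to `fitCircuit(optimizer = ...)`.

Parameter bounds are scale-free defaults on the ×200 concentration
scale: $|w|, |e| \le 0.3$, $R \in [0.5, 30]$, $\lambda \in [0.005, 0.3]$,
$D \in [0, 0.3]$ (all per minute, all configurable).  A failed
integration during annealing yields a large finite penalty cost
($10^6 \times N_d$) so the move is rejected rather than aborting the run.

**Quality control** (`qcScreen()`) replaces the visual inspection used on
published ensembles with automated heuristics: *solver sensitivity* (max
change of any sampled concentration when tolerances are tightened
tenfold), *brittleness* (max RMS change under ±0.1 % per-parameter
perturbation), and per-gene/time *patterning defects* — missing domains
(model < 10 % of the slice data maximum where data > 50 %), ectopic
domains (the converse), and wrong A–P ordering of expression peaks.  The
10 %/50 % thresholds are configurable.

# Parameter determinability

Around an estimate $\hat\theta$ with residual Jacobian $J$ (computed by
central finite differences of the weighted residual vector, relative step
$10^{-4}$ with absolute floor $10^{-6}$, masked columns omitted), the
$(1-\alpha)$ confidence ellipsoid is
$(\theta-\hat\theta)^{\!\top} J^{\top}\! J\, (\theta-\hat\theta) \le
\Delta$ with $\Delta = p\, s^2 F_\alpha(p, N_d - p)$ and
$s^2 = S(\hat\theta)/(N_d - p)$, where $p$ counts *free* parameters only.
Two per-parameter intervals are derived:

* **dependent** — the axis-parallel slice of the ellipsoid through the
  estimate, half-width $\sqrt{\Delta / (J^\top J)_{jj}}$ (underestimates
  the region when parameters correlate);
* **independent** — the ellipsoid's bounding box from the SVD
  $J = U\Sigma V^{\top}$, half-width
  $\sqrt{\Delta \sum_k V_{jk}^2/\sigma_k^2}$ (overestimates it).

By Cauchy–Schwarz the dependent interval always nests inside the
independent one.  Singular values below $10^{-10}\sigma_{\max}$ are
treated as zero and the affected parameters are reported with infinite
independent intervals (non-determinable) instead of failing.  $\alpha$
defaults to 0.05.  A one-parameter linear regression, where both
intervals collapse to the classical $t$-interval, pins correctness in the
test suite.

A regulatory weight is *determinable* if its independent interval lies
entirely within one category — repressing ($w < -0.005$), none
($|w| \le 0.005$), activating ($w > 0.005$) — *weakly determinable* if
the interval excludes exactly one category, and *non-determinable*
otherwise.

# Network and mechanism analysis

`classifyInteraction()` applies the 0.005 cutoff (boundary values count
as "none"); `interactionSummary()` reports per-pair
repressing/none/activating triplets over an ensemble with a
strict-majority consensus (ties are "ambiguous").

The *net effect* of an interaction is its weight multiplied by the
regulator's concentration summed over a region of overlapping expression,
normalised per nucleus-time so regions of different sizes compare fairly.
Overlap regions take all nuclei where both genes exceed 10 % of their own
slice maximum; for genes with multiple domains the posterior-most
contiguous run is used (the shift analysis concerns posterior overlaps).
By default net effects integrate over all post-division time classes;
whether the original analysis integrated over one time or several is not
stated, so both modes are exposed (`times` argument).

`mechanismReport()` computes ensemble fractions for the canonical
mechanisms: alternating cushions (mutual repression of *hb*/*kni* and
*Kr*/*gt*), per-gene auto-activation, the three domain-shift asymmetries
(net repression of *gt* by posterior Hb, of *kni* by Gt, of *Kr* by Kni,
each stronger than the reciprocal effect), the direction of net
repression between *hb* and *Kr*, Bcd+Cad activation (Bcd activates all
four gap genes, Cad activates *gt* and *kni*) and Tll+Hkb inhibition (Hkb
represses *hb*, Tll the other three).  The ensemble fraction is exactly
the mean of per-circuit indicators.

The reduced-data harness emulates minimal-data experiments:
`reduceBoundaries()` keeps a random `max(1, round(fraction * n))`
observations per (gene, time class, boundary) group — rounding half away
from zero, floored at one so no observed boundary disappears entirely —
and `reduceTimeclasses()` keeps `k` of the nine time classes with C13 and
T8 never removed.  Both are deterministic per seed.

# Synthetic data and the recovery benchmark

`synthDataset()` generates pseudo-data with the structure the method
assumes: simulate a known circuit, sample at the data times, add Gaussian
concentration noise (SD = `sigma` × max concentration, clamped at zero),
derive WLS weights from the normalised noisy values, and emit boundary
annotations by 50 %-of-maximum threshold crossings jittered independently
per pseudo-embryo (SD `jitterX` % A–P).  Boundary positions are extracted
from the noiseless profiles and the embryo-level variation enters through
the jitter, which keeps the two noise channels (concentration noise on
the dataset, position noise on the annotations) independently
controllable.  Everything is byte-reproducible given the scenario and
seed.

The standard benchmark (`benchScenario()`) is sized to run a full
recovery experiment in minutes on one CPU: two genes with mutual
repression (−0.1) and auto-activation (+0.05), two complementary
exponential inputs each activating one gene (+0.08), 20 nuclei across the
35–87 % trunk, five time points over 50 min, no division, concentration
noise `sigma = 0.05`.  The ground-truth weights are sized comfortably
away from the 0.005 interaction cutoff so that sign recovery is a
meaningful yardstick.  `recoveryExperiment()` runs synth → fit → compare
loops and reports the sign-agreement fraction of the free gap–gap
weights; the test suite requires a mean agreement ≥ 0.8 over 10 seeded
runs with a 6000-evaluation annealing budget, and that a shuffled-data
negative control (each gene's spatial profile permuted within every time
class) stays at chance level.

What the generator does *not* emulate: microscopy and staining noise,
embryo-to-embryo staging error, non-Gaussian variance structure, and the
information loss of the normalised-boundary representation itself
(synthetic datasets carry graded concentration profiles, real ones carry
spline-reconstructed ones).  Passing the recovery benchmark therefore
shows that the estimation machinery works on data of the assumed
structure, not that any particular real dataset is informative enough.

# Numerical choices and limitations

* Quadratic temporal scaling, weight formula and the Cad surface stand in
  for originally unpublished constructions; each sits behind a
  configurable interface and is validated by its stated contract.
* The integration tolerances (1e-6/1e-8), input grid step (1 min),
  finite-difference steps, rank tolerance (1e-10) and QC thresholds are
  package defaults chosen to keep discretisation error well below the
  effects being measured; the test suite checks tolerance-halving
  stability explicitly.
* Fitting the full 1804-point four-gene circuit to the packaged boundary
  table is supported (one cost evaluation ≈ 0.2 s) but obtaining
  publication-grade ensembles requires annealing budgets far beyond a
  desk machine; the shipped benchmark deliberately uses the reduced
  two-gene scenario.
* The model covers one division cycle and a 1-D lattice; head gap genes,
  pair-rule targets, posterior Kr regulation and protein–mRNA delays are
  out of scope.

# Session info

```{r}
sessionInfo()
```
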