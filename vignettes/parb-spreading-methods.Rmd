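---
title: "Models and methods behind ParBspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ParBspread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ParBspread implements the quantitative machinery used to study how the
bacterial partition protein ParB loads at its *parS* site, slides along
DNA, recruits further ParB dimers in cis and in trans, and thereby bypasses
DNA-bound roadblocks. This vignette documents the models, the parameter
choices, and the numerical decisions, in the depth a user needs to judge
what the package's tests do and do not establish.

## The residence-time model

A DNA-bound ParB dimer carries two CTP molecules that are hydrolysed
independently, each as a single-exponential process with rate $k_{CTP}$
(1/s). The time until both are hydrolysed is therefore the maximum of two
exponential variables,

$$P(t_{CTP}) = 2\,k_{CTP}\,e^{-k_{CTP}t}\left(1 - e^{-k_{CTP}t}\right),$$

with mean $3/(2k_{CTP})$. Under the *immediate-release* model the dimer
leaves the DNA at that moment. Under the *delayed-release* model an
additional exponential step with rate $k_{\mathrm{off}}$ follows, and the
total dwell time $T$ is the convolution of the two laws; `pdfTotalDwell()`
evaluates the closed form. We evaluate it in an expanded representation
(differences of single exponentials) because the compact factored form
multiplies a decaying against a growing exponential and overflows for
$t \gtrsim 10^3$ s in double precision.

Fluorophore photobleaching censors the observation: the apparent dwell is
$T' = \min(T, t_{bl})$ with $t_{bl}$ exponential at rate $k_{bl}$, giving

$$P(T') = P(T{=}T')\,e^{-k_{bl}T'} + k_{bl}e^{-k_{bl}T'}\,P(T{>}T').$$

The survival function $P(T>T')$ is *derived* by analytic term-by-term
integration of the dwell density rather than transcribed, and is verified
in the test suite against quadrature (tolerance $10^{-8}$) and against a
generative Monte-Carlo twin (Kolmogorov-Smirnov at $\alpha = 0.01$,
$n = 10^5$).

The closed forms are singular at the rate coincidences
$k_{\mathrm{off}} = k_{CTP}$ and $k_{\mathrm{off}} = 2k_{CTP}$. Inputs
within a relative $10^{-9}$ of a coincidence are nudged by a relative
$10^{-6}$; the tests show the perturbed values agree with nearby regular
rates to $10^{-3}$, far below any statistical resolution at realistic
sample sizes.

Reference rate values used throughout the examples and tests: hydrolysis
$k_{CTP} \approx 0.022$-$0.025$ s$^{-1}$, release
$k_{\mathrm{off}} \approx 0.025$-$0.06$ s$^{-1}$ depending on dye
(post-hydrolysis dwells of roughly 17-40 s), bleaching
$k_{bl} = 1.75\times10^{-4}$ s$^{-1}$ for Alexa647 and 0 for TMR.

## Maximum-likelihood fitting

`fitDwellModel()` maximizes $\sum_i \log P(T'=t_i)$ with $k_{bl}$ held
fixed. Parameters are optimized on the log scale (BFGS), which enforces
positivity without constraints; starts come from the method of moments
(immediate model: $k_{CTP} = 1.5/\bar t$; delayed: $k_{\mathrm{off}}$
seeded at twice $k_{CTP}$) plus jittered restarts to guard against local
optima. 68% confidence intervals are point estimate $\pm$ one standard
deviation from the inverse observed information, computed by central
finite differences with relative step $10^{-4}$ - a closed-form Hessian of
the censored density is error-prone and numerically unnecessary here.

The $(k_{CTP}, k_{\mathrm{off}})$ likelihood is a curved ridge: the dwell
law is a mixture of exponential scales $k_{CTP}$, $2k_{CTP}$ and
$k_{\mathrm{off}}$, and at $n \approx 300$ the two rates are only weakly
identified. Estimates scatter strongly along the ridge (the tests
therefore assert recovery via median z-scores over replicates), and
marginal CIs understate joint uncertainty. Model comparison uses
$\mathrm{BIC} = \nu\log N - 2\log\mathcal{L}$ with $\nu = 1$ (immediate)
or 2 (delayed); ties break toward fewer parameters.

Whether sub-frame dwells were excluded before fitting in the original
analyses is not documented; `fitDwellModel()` exposes a left-truncation
bound `minDwell` (the likelihood is conditioned on $T' \ge$ bound), off by
default.

## The coarse-grained DNA tether

DNA is a bead-spring chain: bead diameter $\sigma = 5.5$ nm (16 bp),
purely repulsive shifted-truncated Lennard-Jones (WCA) excluded volume,
FENE bonds with $k = 30\,\varepsilon/\sigma^2$ and $R_0 = 1.5\sigma$, and
a cosine bending term $k_\theta(1-\cos\theta)$ with
$k_\theta = 10\,k_BT$, which yields a persistence length of about 10
beads ($\approx 55$ nm) - verified in the acceptance tests from the decay
of bond-direction correlations. Terminal beads are frozen at a distance
$x\,(N{-}1)\,b_0$ apart ($b_0 \approx 0.96\sigma$, the FENE+WCA minimum),
mirroring the doubly surface-tethered geometry; the relative extension
$x$ is the experimental control variable, mapped to force by the
Marko-Siggia interpolation (`wlcForceFromExtension()`; 0.20 pN at 65%
extension with $L_p = 50$ nm).

**Integrator.** The default is BAOAB Langevin dynamics with $m = 1$,
$\gamma = 1$, $dt = 0.01\,\tau_B$. An inertial thermostat is what makes
$dt = 0.01$ stable against the stiff FENE/WCA bond (highest bond-mode
stiffness $\approx 4\times10^3\,\varepsilon/\sigma^2$); the overdamped
Euler-Maruyama variant, kept for short-time diffusion checks, is stable
only below $dt \approx 5\times10^{-4}$ and warns otherwise. Momentum
relaxes within $1\,\tau_B$, so all conformational observables are
diffusive. Thermal noise is variance-matched uniform rather than
Gaussian - the convention of the LAMMPS Langevin thermostat - which is
indistinguishable at the level of equilibrium observables and halves RNG
cost; equivalence is asserted on equilibrium observables (bond statistics,
persistence length, MSD), not on trajectories.

**Initialization.** Fresh chains are built with every bond at $b_0$ and
the transverse slack laid out as a smooth random walk, bridge-corrected
onto the anchor axis, then relaxed by a short capped steepest-descent
quench (`softSteps`, default $2\times10^4$) before dynamics. Runs at low
extension start from this perturbed-but-compact state rather than from
full conformational equilibrium; global Rouse relaxation of a 300-bead
chain takes $\sim10^3\,\tau_B$, so coupled runs begin with a 100 $\tau_B$
polymer-only equilibration and early-time looping statistics are somewhat
undersampled (conservative for bypass).

**Scale.** The desk-scale default is $N = 300$ beads with *parS* at the
middle bead and the roadblock at two-thirds of the chain - fractional
geometry, not absolute length, is the preserved quantity (the full-scale
1400-bead chain is available by setting `nBeads`). The unit map keeps both
the printed lattice-diffusion conversion (0.062 $\sigma^2$ per
$10^4\,dt$) and the value recomputed from its stated ingredients
($\approx0.059$), defaulting to the printed one.

## ParB on the lattice

ParB occupies beads. Every $100\,\tau_B$ ($10^4$ integration steps) each
loaded ParB attempts one $\pm1$ hop with total probability 0.125
(direction 50/50) - "total" rather than per-direction because the hop
probability is tied to $2D$ in the 1D mean-squared-displacement relation.
Moves onto occupied beads, the roadblock bead, or off the lattice are
rejected. Recruitment is a per-loaded-ParB Poisson process at
$10^{-6}\,\tau_B^{-1}$ (probability $10^{-4}$ per update; scheduled
per-ParB because recruitment is an action of a loaded dimer); an attempt
is in cis with probability $p_{cis}$ (random adjacent bead, loaded if
free and not the roadblock) and otherwise in trans: a uniform pick among
beads within 11 nm ($2\sigma$, about two ParB dimers) in 3D but farther
than the second-nearest neighbour in 1D, unoccupied, and not the
roadblock. Recruited ParB immediately obeys the same rules (symmetric by
default); there is no unloading unless an optional release rate is set.
The bypass flag is sticky and is checked after every ParB update - a
denser check than sampling-cadence detection, and equivalent here because
loaded ParB never leaves.

**Run lengths.** The roadblock-bypass checks use $N = 300$ with
$10^4\,\tau_B$ of coupled dynamics per run in the test suite and
$2\times10^4\,\tau_B$ in `scripts/acceptance.R` (16 runs each). At 75%
extension the result (0% bypass) is insensitive to run length: the 11-nm
trans cutoff cannot span the roadblock at that tension, and at the
physical recruitment rate a desk-scale run contains far less than one
recruitment attempt on average. For the same reason the *shape* results
at low force (bypass fractions near 80%, the cis/trans-ratio sweep) are
not desk-reproducible; the package covers them as properties - bypass
requires trans recruitment and slack DNA, is non-increasing in extension,
and vanishes when $p_{cis} = 1$ - exercised with an elevated recruitment
probability so that short runs sample trans events at all. Defaults
always keep the physical rate.

`theoreticalBypass()` provides the looping-integral estimate of the
relative bypass probability: either empirically (contact counting in a
sampled trajectory) or in closed form, combining a Shimada-Yamakawa /
Gaussian loop-closure factor with a tension penalty
$\exp(-F(x)\,x\,s\,b_0)$ for extracting a loop of contour $s$ beads from
a tether at extension $x$. The integration measure and bounds of the
looping integral are not fully constrained by the model definition; both
routes are relative curve shapes only.

## The colocalization null model

`simulateColocNull()` simulates kymographs in which parS-loaded molecules
(count $\sim\mathcal{N}(4,1)$, rounded, floored at 0) diffuse from the
*parS* position with $D = 0.066\ \mu m^2/s$ for residence times drawn
from $\mathcal{N}(76, 50)$ s truncated at one frame (truncation is
required for positivity and is not stated in the source procedure), while
nonspecific molecules (same count law) bind at uniform positions and
uniform start frames - the maximum-entropy choice where the binding-time
distribution is unstated. A colocalization is scored when a nonspecific
molecule *appears* within 300 nm and 3 frames of a loaded molecule,
because that appearance is the observable signature by which recruitment
is identified on a kymograph; counting any-time proximity instead would
saturate the null and make the comparison meaningless. Counting is per
loaded molecule, with a per-kymograph figure available - the source
procedure is ambiguous between the two. With the default parameters the
accidental fraction is a few percent, well below the observed ~12%
recruitment frequency.

## Kymograph analysis

Pixels and frames are 1-based (R convention); loading positions are
reported as the end-normalized fraction
$(x_{end}-\bar x_{\mathrm{1st\,second}})/(x_{end}-x_{start})$, so a
molecule at $x_{end}$ maps to 0. Preprocessing median-filters each
channel and removes background with a grayscale white tophat; the default
median radius is 1 (window 3) because on a kymograph a diffraction-limited
spot spans only ~3 pixels - the 10-pixel window of the original image
pipeline applies to raw 2D frames before axis integration
(`collapseToKymograph()`, 11 pixels across the DNA axis), and would
erase kymograph spots.

Tracking is frame-by-frame peak detection (local maxima above
median + 5 MAD, sub-pixel centroid) with greedy nearest-neighbour
linking. The per-frame link gate defaults to 300 nm (the diffraction
criterion) and grows with the square root of elapsed frames when bridging
detection gaps, as Brownian displacement does. For molecules at
$D = 0.066\ \mu m^2/s$ and 0.1 s frames the per-frame Brownian step is
115 nm, so a 300-nm gate truncates at 2.6 standard deviations and
fragments long traces; analyses of such data use a 450-nm gate
($\approx 4$ standard deviations), which is what the end-to-end tests do.
Tracking is validated only on synthetic data; it assumes the sparse
regime of at most a few molecules per tether and does no drift
correction.

Recruitment detection requires both halves of the experimental
signature: a $\ge1.5\times$ step in a trace's integrated spot intensity
(3 pixels, 20-frame windows; 1.5 is below the ~2x expected for a second
dimer at 74% labeling efficiency, which no printed threshold pins down)
and the subsequent appearance of a new trace within 300 nm / 3 frames
(the split). Roadblock localization takes the argmax of the
Savitzky-Golay-smoothed (window 11, order 1) time-averaged roadblock
channel with parabolic sub-pixel refinement; ties break to the lower
index with a warning. Arm intensities subtract a 100-frame pre-binding
background, discard 5 pixels on either side of the roadblock, and
median-filter over 21 frames. Recruitment profiles are decomposed into
one or two Gaussian components with BIC selection on an
intensity-weighted pseudo-sample (deterministic sub-pixel jitter, so the
decomposition is reproducible).

## Synthetic data

`renderKymograph()` emulates the raw observable: a DNA channel (uniform
tether profile with an AR(1) intensity wiggle whose amplitude shrinks
with extension - amplitudes are free parameters, chosen qualitatively), a
ParB channel with 300-nm-FWHM Gaussian spots along simulated traces,
Poisson shot noise and Gaussian read noise, an optional static roadblock
channel, at 110 nm/px and 0.1 s/frame. Scenes are either scripted
(explicit arrivals, dwells, recruitments with a conjunct phase before the
split) or stochastic (sequential *parS* loading under the delayed-release
law censored by bleaching, diffusion at $D = 0.066\ \mu m^2/s$). Every
dataset carries machine-readable ground truth.

Deliberately not emulated: camera-specific noise calibration,
illumination profiles, fluorophore blinking, stage drift, and overlapping
independent molecules in the stochastic mode (loading is sequential so
that dwell extraction is identity-unambiguous). Passing the end-to-end
tests therefore shows the pipeline is correct for sparse, drift-free,
well-separated traces - not that it is robust to every pathology of real
movies.

## Problem sizes

Chosen so the whole suite and the acceptance script each run comfortably
on a single CPU: dwell-sample sizes 332 (the experimental n) and 1000
(model selection, 50 replicates), $10^5$ for distributional oracles;
polymer runs of $2\times10^6$ steps for persistence length ($N = 80$);
16 coupled runs of $10^4$-$2\times10^4\,\tau_B$ at $N = 300$ for the
roadblock criterion; 1000 null-model scenarios; a ~100-molecule
synthetic movie (~80,000 frames) for the end-to-end recovery.
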