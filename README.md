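# ParBspread

Single-molecule kinetics and simulation of ParB spreading on DNA.

ParB (partition protein B) loads at the centromere-like *parS* sequence as
a CTP-dependent clamp, slides along the DNA by 1D diffusion, and can
recruit further ParB dimers from solution — either at an adjacent DNA
position (in cis) or onto a genomically distant but spatially proximal
segment reached by DNA looping (in trans). In-trans recruitment lets ParB
appear beyond tightly bound roadblocks such as dCas9, which 1D sliding
alone can never pass. ParBspread is aimed at single-molecule biophysicists
who want to fit dwell-time data from such experiments, simulate the
coupled polymer/lattice model behind them, and validate kymograph-analysis
pipelines on synthetic data with known ground truth.

The package implements:

- **Residence-time kinetics.** The dwell of a ParB dimer is
  `T = t_CTP + t_off`, where `t_CTP` is the maximum of two exponential
  hydrolysis times (rate `k_CTP` per monomer) and `t_off` an optional
  exponential release delay (rate `k_off`); observation is censored by
  photobleaching (`T' = min(T, t_bl)`, rate `k_bl`). Closed-form
  densities/survivals, a generative sampler, maximum-likelihood fitting
  with 68% CIs from the observed information, and BIC comparison of the
  immediate- vs delayed-release models.
- **A coarse-grained DNA tether**: bead-spring chain (WCA excluded volume,
  FENE bonds, `k_theta (1 - cos theta)` bending, persistence length ~10
  beads = 55 nm) with both ends anchored at a chosen fraction of the
  contour length, evolved by a compiled BAOAB Langevin engine; Marko-Siggia
  force/extension mapping.
- **ParB lattice dynamics on the polymer**: blocked 1D diffusion (hop
  probability 0.125 per update), stochastic in-cis/in-trans recruitment
  (11 nm trans cutoff, second-neighbour 1D exclusion), roadblock-bypass
  statistics with Wilson intervals, and a looping-integral estimate of the
  relative bypass probability.
- **A Monte-Carlo null model** for accidental colocalization of
  parS-loaded and nonspecifically bound molecules.
- **Kymograph analysis**: preprocessing, single-particle tracking,
  end-normalized loading positions, residence times, recruitment-event
  detection (intensity step + split), roadblock localization, arm
  intensities, Gaussian-mixture profile decomposition.
- **A synthetic-kymograph generator** with machine-readable ground truth,
  so every analysis stage is testable without raw imaging data.

## Worked example

Fit the delayed-release model to sampled dwell times at the Alexa647-like
rates and compare it against immediate release:

```r
library(ParBspread)

rates <- kineticRates(kCtp = 0.025, kOff = 0.06, kBl = 1.75e-4)
s <- sampleApparentDwells(rates, "delayed", n = 332, seed = 7)

fit <- fitDwellModel(s, "delayed", kBlFixed = 1.75e-4, seed = 1)
fit
#> FitResult (delayed model, n = 332, converged: TRUE)
#>   kCtp  = 0.031 1/s  (68% CI 0.02503 - 0.03698)
#>   kOff  = 0.03583 1/s  (68% CI 0.02403 - 0.04764)
#>   kBl fixed at 0.000175 1/s
#>   logLik = -1692.988, BIC = 3397.586

fitI <- fitDwellModel(s, "immediate", kBlFixed = 1.75e-4, seed = 1)
compareModelsBic(list(fit, fitI))$model
#> [1] "delayed"

meanTotalDwell(rates, "delayed")     # mean dwell, s
#> [1] 76.66667
postHydrolysisDwell(rates)           # mean post-hydrolysis residence, s
#> [1] 16.66667
```

The two fitted rates land on the curved likelihood ridge typical of this
weakly identified two-rate model (kCtp a little above, kOff a little
below the generating values, each within ~2 of its reported standard
deviations), and BIC prefers the generating (delayed) model — the
population-level mean dwell is ~77 s of which ~17 s follow CTP
hydrolysis.

Simulate the roadblock experiment at high tension (75% extension) and ask
how often ParB ends up beyond the roadblock:

```r
pp <- polymerParams(nBeads = 300, extension = 0.75)   # parS mid, roadblock 2/3
bp <- parbParams(pCis = 0.1, nUpdates = 200)
flags <- vapply(1:16, function(r)
  hasBypass(runCoupledSimulation(pp, bp, seed = r)), TRUE)
bypassFraction(flags)$fraction
#> [1] 0
wlcForceFromExtension(0.65)          # pN at 65% extension
#> [1] 0.2006351
```

A command-line wrapper for the main workflows lives in
`inst/cli/parb-tools.R` (`wlc-force`, `simulate-dwell`, `fit-dwell`,
`sim-bypass`, `sweep-bypass`, `coloc-null`, `make-synthetic`,
`analyze-kymo`).

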