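# localscr

Bayesian spatial capture–recapture (SCR) with **local evaluation of the
individual state-space**: per-individual square windows restrict where a
latent activity center may lie (AC window) and which detectors enter that
individual's detection likelihood (detector window). On large detector
arrays this removes the overwhelming majority of likelihood terms — all of
them numerically zero — and makes Bayesian SCR tractable at landscape
scale without biasing density estimates, provided the windows are wide
enough relative to the detection scale.

The package is aimed at ecologists estimating animal density from
individually identified detections (camera traps, hair snares,
noninvasive genetic sampling) over large spatial extents.

## The model

Individual *i* has a latent activity center *s<sub>i</sub>* uniform over
the suitable habitat of a state-space *S*, and is detected at detector
*j* with half-normal probability

> p<sub>ij</sub> = p₀ · exp(−d<sub>ij</sub>² / (2σ²)),  y<sub>ij</sub> ~ Bernoulli(p<sub>ij</sub>)

Abundance is estimated by data augmentation: inclusion flags
z<sub>i</sub> ~ Bernoulli(ψ<sub>i</sub>) with the habitat-proportion
correction ψ<sub>i</sub> = 1 − (1 − ψ₀)^prop.habitat<sub>i</sub>, so that
windows overlapping non-habitat or protruding past the domain edge do not
distort density. N̂ = Σz and d̂ = N̂ / area(S). A bespoke
Metropolis-within-Gibbs sampler (compiled core) evaluates each
individual's likelihood only over its local detector index; the classical
no-LESS model is the same sampler with domain-spanning windows.

## Worked example

Simulate the standard study design, build the window index, and fit:

```r
library(localscr)

detectors <- detector_grid(25, 25, spacing = 1)      # unit-spaced array
domain    <- scr_domain(detectors, buffer = 4)       # 33 x 33 du state-space
truth     <- sim_population(40, domain, sigma = 2, p0 = 0.07, seed = 11)
captures  <- sim_captures(truth, detectors)
captures
#> <scr_captures> 23 individuals, 48 detections at 625 detectors

less <- less_index(captures, detectors, domain,
                   ac_width = 10,      # 5 sigma
                   extension = 4,      # 2 sigma -> width-18 detector windows
                   n_expected = 40)
less
#> <less_index> 23 detected + 176 augmented (11 layers); AC width 10 du,
#>   extension 4 du; max 324 detectors/individual

fit <- scr_fit(captures, detectors, domain, less, seed = 5)
tidy(fit)
#> # A tibble: 5 x 6
#>   term    estimate std.error conf.low conf.high  rhat
#> 1 sigma     1.90     0.178     1.59      2.29    1.00
#> 2 p0        0.0972   0.0237    0.0556    0.149   1.00
#> 3 psi0      0.275    0.0564    0.177     0.393   1.01
#> 4 N        39.3      6.28     29        53       1.00
#> 5 density   0.0361   0.00577   0.0266    0.0487    NA
```

The true population here is 40 individuals at density 40/33² ≈ 0.037 per
du²; the posterior mean N̂ = 39.3 (95% CrI 29–53) recovers it, σ̂ = 1.90
against a true σ = 2, and all Gelman–Rubin statistics are ≤ 1.1. Density
surfaces come from `true_density_map()` / `predicted_density_map()` and
are compared with `mre()`; `autoplot()` draws traces and maps, and
`run_scenario_grid()` executes a factorial simulation design (window
widths × extensions × population sizes, with a no-LESS reference) into a
scenario × parameter table of relative bias, CV, coverage and MRE.

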