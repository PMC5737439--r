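---
title: "Motor-roadblock traffic on genes: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-roadblock traffic on genes: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelotonr)
```

## The model

`pelotonr` simulates and analyses a one-dimensional lattice gas of molecular
motors (RNA polymerase II, footprint $\delta_m = 35$ bp) translocating
through dynamically rebinding roadblocks (nucleosomes plus linker,
footprint $\delta_{rb} = 167$ bp). The bulk rules are those of a
footprint-generalized Bus-Route Model (BRM):

1. motors hop one site at a time in one direction, at rate $k_{ip}$ on bare
   track and $k_{tp} \le k_{ip}$ when hindered by a roadblock;
2. motors cannot overtake (hard-core exclusion of the $\delta_m$ footprint);
3. roadblocks bind any stretch of $\delta_{rb}$ contiguous free sites at
   rate $k_b$ per admissible leftmost position;
4. a roadblock ahead of a motor impedes its motion;
5. a passing motor evicts the roadblock; it can only rebind once the motor
   has cleared the footprint.

On an open lattice, motors initiate at rate $k_{in}$ whenever the
initiation footprint $[0, \delta_m - 1]$ is motor-free (it is kept
roadblock-free, as promoters are nucleosome-depleted), and leave when
their front passes the last site. Because a motor depletes roadblocks over
a trailing *shadow* $\Delta \approx v\tau + \delta_{rb}$, a trailing motor
inside the shadow is unhindered and catches up: motors condense into
*pelotons* — maximal groups with no interspersing roadblock — which is the
kinetic attraction at the heart of the model.

The closed-form layer implements the initiation-limited theory:

$$n_p \approx 1 + k_{in}\tau_\Delta, \qquad
  x_p = \frac{1/k_{in}}{1/k_{tp} - 1/k_{ip}}
        \frac{1}{\ln(1 + 1/(k_{in}\tau_\Delta))}, \qquad
  \tau_\Delta = \tau + \delta_{rb}/k_{tp},$$

exponential relaxation of motor density, motor velocity and roadblock
density with shared decay length $x_p$, the bulk-peloton scale
$(k_{ip}/k_{tp})^{\Delta/2}$, and the mapping of termination bursts onto a
two-state (telegraph) promoter,

$$k_{tr} = \frac{k_{in}\tau_\Delta}{1 + k_{in}\tau_\Delta}
           \frac{k_{tp}}{\delta_m}, \qquad
  k_{off} = \frac{1}{1 + k_{in}\tau_\Delta}\frac{k_{tp}}{\delta_m}, \qquad
  k_{on} \approx 1/\tau_\Delta,$$

with the exact identity $k_{tr} + k_{off} = k_{tp}/\delta_m$.

## Parameters

The `params_table1()` preset carries the literature estimates for highly
transcribed eukaryotic genes:

| parameter | value | meaning |
|---|---|---|
| `delta_m` | 35 bp | RNAP footprint |
| `delta_rb` | 167 bp | nucleosome + linker footprint |
| `k_ip` | 10 bp/s | elongation on bare DNA |
| `k_tp` | 3 bp/s | effective elongation through a nucleosome |
| `k_in` | 0.6–3 /min | initiation rate |
| `k_b` | 0.02 /s | binding-attempt rate per admissible position |
| `tau` | 0 s | analytic equilibration time (histones rebind on a sub-minute scale, so the shadow is dominated by $\delta_{rb}$) |

Rates accept `"/s"` and `"/min"` suffixes everywhere to prevent unit
mistakes; everything is normalized to seconds and sites internally.

## Eviction conventions

How exactly a motor removes a large roadblock is under-determined by the
rules above, and the choice matters quantitatively. Three conventions are
implemented:

* **`contact`** (uniform interaction, default): the roadblock disappears on
  first footprint contact and the motor is immediately fast again. This is
  the exact BRM at $\delta_{rb} = 1$ and the convention used for all
  $\delta = 1$ studies. For large roadblocks it makes the hindered crossing
  far too cheap (one slow step per nucleosome, effective speed
  $\approx 9.9$ bp/s at preset values).
* **`traversal`** (uniform interaction, the transcription convention used
  by the preset): the roadblock is likewise removed from the lattice on
  first contact — so the state dynamics, and therefore event replay and the
  exact small-system solver, are identical to `contact` — but the evicting
  motor keeps stepping at $k_{tp}$ until its front has traversed the
  remaining footprint length. An intact nucleosome is thus crossed at
  exactly the measured effective rate $k_{tp}$, smoothly (167 small slow
  steps, not one long dwell), while motors drafting behind it move at
  $k_{ip}$. This realizes the theory's two-speed caricature microscopically.
* **`dyad`**: only the central (dyad) site impedes. To preserve the mean
  crossing time the dyad-passage rate is renormalized to
  $k_{dyad} = 1/(\delta_{rb}/k_{tp} - (\delta_{rb}-1)/k_{ip})$
  ($\approx 1/39$ s$^{-1}$ at preset values, collapsing to $k_{tp}$ at
  $\delta_{rb} = 1$). Concentrating the whole slowdown in one exponential
  dwell preserves means but inflates velocity fluctuations roughly
  eighty-fold relative to distributed stepping; pelotons then coagulate
  unrealistically fast. The mode is kept as an exposed variant for
  studying exactly this sensitivity, not used by the preset.

## Simulation engine

The simulator is an exact continuous-time kinetic Monte Carlo (Gillespie)
over the full event catalogue, in C++. Roadblock binding uses exact
thinning: proposals fire at $k_b$ per candidate leftmost position across
the whole admissible coordinate range and are accepted only if the
footprint is free, which is equivalent in law to independent per-position
clocks without any admissible-set bookkeeping. Rates are recomputed only
for motors whose next site is affected by an event; determinism is
guaranteed by a single seeded generator (R's RNG). Snapshots every
`dt_sample` seconds after `burn_in` (default five transit times,
$5L/k_{tp}$) are the canonical observable source; per-site occupancy and
stepping accumulators are collected over the same window.

The local velocity estimator is realized steps per unit front-occupancy
time, $v(x) = \#\{\text{steps from } x\}/T_{\text{front}}(x)$. Aggregated
over a region this equals distance per unit time and is robust at low
density; note it is *time-weighted*, so it equals flux over density and is
the natural counterpart of the density profile.

## Observable extraction: numerical choices

* **Gap fits.** Single geometric by closed-form MLE; two-component
  geometric mixture by EM over a deterministic grid of about a dozen
  starting points built from sample quantiles (same intent as random
  restarts — escaping local optima — without hidden RNG state). Component
  1 is reported as the intra-peloton (large-$p$) component; degenerate
  samples (zero variance, or components collapsing onto each other) are
  flagged. Model preference is reported via BIC, not enforced. Fits in the
  acceptance checks use on the order of $5\times10^3$ pooled gaps: at that
  scale the geometric law is the preferred description in both TASEP
  limits, while an order of magnitude more data lets BIC resolve
  finite-ring corrections to the exact TASEP gap distribution — a
  statement about model-selection power, not about the traffic physics.
* **Relaxation fits.** Nonlinear least squares of $A - Be^{-x/x_p}$ over
  the first $4x_p$ lattice points (Levenberg–Marquardt), with the fit
  window starting at $x = \delta_m$: sites $x < \delta_m$ can only be
  covered by motors at positions $0..x$, a purely geometric entrance
  artifact that otherwise dominates the fit. Density profiles are smoothed
  over one roadblock footprint before fitting, matching how nucleosome-
  scale structure is averaged out.
* **Peloton statistics.** Pelotons are identified per snapshot from the
  gap classification; means are taken over pelotons selected by their
  trailing motor position, keeping the leading motor clear of the
  termination region (exiting pelotons are observed only partially and
  would bias the mean down). Requiring a peloton to fit entirely inside a
  narrow window biases against large pelotons and is avoided.
* **Burst statistics.** Fano factors (variance over mean of window counts)
  default to 1-minute windows, the scale of the mapped two-state rates;
  `fano_curve()` reports the window-size dependence since no single
  canonical window exists. Telegraph comparisons report Fano-curve
  distances and a Kolmogorov–Smirnov statistic on interarrivals; the
  mapping is approximate, so distances are reported rather than
  thresholded.

## What the simulations do and do not establish

The test suite validates the engine against an independently hand-coded
rule oracle, against exact event-log replay through the pure rule layer,
and — for a periodic $\delta = 1$ lattice small enough to enumerate
(L = 6, two motors, 240 states) — against the directly solved stationary
vector of the master equation (total variation below 0.02). In the
$\delta = 1$ open system the fitted relaxation length reproduces the
closed-form $x_p$ to within about 15%, matching the regime in which the
theory was originally validated.

At the transcription parameter set the simulator reproduces the bulk
velocity $v \approx k_{tp}$ beyond the formation region, the
transcriptional output, and (at 0.6/min) the mean peloton size, with no
free parameters. Two closed-form quantities are *not* reproduced by the
faithful microscopic model, and the corresponding acceptance assertions
are deliberately left failing rather than relaxed:

* **Formation distance at large footprints.** The theory assumes a chasing
  motor runs at $k_{ip}$ until it reaches the peloton ahead. With
  $k_b = 0.02$/s per position, the evicted corridor repacks within
  $\sim\delta_{rb}$ plus a 15–20 bp parking gap behind a peloton's tail,
  so a chaser is intercepted by a rebound nucleosome, drops to $k_{tp}$,
  and seeds a new peloton; the density relaxation length measured from
  simulation is consequently a factor $\sim$2–3 below the closed-form
  $x_p$. In the $\delta = 1$ limit interception costs a single slow step
  and the closed form is recovered.
* **Peloton size at high initiation.** At 3/min the motor transit time
  across the start-region rebinding window ($\delta_{rb} + 2\delta_m$
  sites) is comparable to $1/k_{in}$, so rebinding at the start is often
  occluded by traffic and pelotons form roughly twice as large as
  $1 + k_{in}\tau_\Delta$; at 0.6/min, where the initiation-limited
  assumption holds, simulated and predicted sizes agree within a few
  percent.

Initiation streams are Poisson thinned by initiation-site occlusion
(renewal theory predicts a Fano factor modestly below 1 at high
initiation), while termination streams are strongly super-Poissonian —
the burst contrast that the two-state mapping summarizes.

The simulations emulate an abstract lattice: sequence-dependent rates,
polymerase pausing and backtracking, partial (dimer-only) nucleosome
eviction, supercoiling, and mRNA degradation are all outside the model, so
agreement here demonstrates the crowding mechanism, not a complete account
of any particular gene.

## Problem sizes

Default study sizes used throughout the tests and the acceptance script:
3 kb genes simulated for 1.7–3$\times 10^4$ s (one to two million events,
a few seconds of CPU), the 240-state master-equation comparison at
$7\times10^5$ s of simulated time ($>10^6$ events), and gap fits pooled
from 50 snapshots of a 1000-site, 100-motor ring. These sizes give
sampling errors comfortably below the tolerances being tested.
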