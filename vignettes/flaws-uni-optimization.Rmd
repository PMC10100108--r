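---
title: "Joint MP2RAGE UNI and FLAWS protocol optimization with EPG simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint MP2RAGE UNI and FLAWS protocol optimization with EPG simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flawsopt)
```

## The problem

The MP2RAGE sequence acquires two rapid gradient-echo images (INV1, INV2)
at two inversion times after a shared adiabatic inversion pulse.  Their
complex ratio — the UNI image — is a T1-weighted image insensitive to
receive-field, proton-density and T2\* factors common to both readouts.
With a short first inversion time the same acquisition yields FLAWS
contrasts: INV1 with suppressed white matter, INV2 with suppressed CSF,
and their normalized minimum, a gray-matter-dominant image resembling a
double inversion recovery scan.  At 7 T the transmit field (B1+) varies by
tens of percent across the brain, scaling every nominal flip angle, so any
protocol optimization has to average over a realistic B1+ range rather
than assume the nominal angles.

`flawsopt` reproduces this optimization machinery end to end: an extended
phase graph (EPG) simulator of the MP2RAGE signal, a Monte-Carlo
contrast-to-noise (CNR) engine with a joint UNI + FLAWS objective, grid
searches over inversion times and flip angles, and the voxelwise UNI/FLAWS
combination operators, which apply equally to simulated signals and to
NIfTI volumes.

## Signal model

The magnetization of one tissue is carried as EPG configuration states
$F^+(k), F^-(k), Z(k)$.  One MP2RAGE cycle of length $TR_{MP2RAGE}$ is

1. adiabatic inversion with efficiency *eff* ($Z \to -\mathit{eff}\,Z$,
   transverse states crushed),
2. free recovery over $T_A$,
3. a block of $n_{exc}$ excitations at $\alpha_1 \cdot b_1$ spaced
   $TR_{GRE}$,
4. recovery over $T_B$, a second block at $\alpha_2 \cdot b_1$, and
   recovery over $T_C$ until the next inversion.

Each excitation applies the standard EPG rotation with a quadratically
cycled phase ($50^\circ \cdot n(n+1)/2$, the vendor RF-spoiling scheme);
every $TR_{GRE}$ applies $T_1$/$T_2$ relaxation, a one-order gradient
shift and diffusion attenuation with the b-factor of a linearly growing
dephasing moment ($k^2 + k + 1/3$ for transverse transitions, $k^2$ for
longitudinal states).  No ideal-spoiling assumption is made: transverse
coherences survive between pulses and, for long-$T_2$ CSF, between blocks.
The simulation iterates whole cycles from equilibrium until the two
recorded signals are periodic to a relative $10^{-9}$ (50-cycle cap) and
reports the demodulated complex signals of the excitation that acquires
the k-space center of each block.  Inversion times are measured from the
inversion pulse to that excitation; under 6/8 partial Fourier with linear
ordering the center line is `round(nInner * (pf - 1/2))`, which is what
allows short TI1 at high resolution.

A longitudinal-only closed form (per-pulse $\cos(\alpha b_1) E_1$
recursion, periodic steady state solved as the fixed point of the
one-cycle affine map) serves as an independent oracle: the EPG chain must
reduce to it when $T_2 \to 0$, and a brute-force Bloch simulation of 720
dephased isochromats checks the EPG operators themselves on short pulse
trains.  Both checks run in the test suite.

## Noise and the CNR objective

Complex Gaussian noise (SD $\sigma$ per channel) is added independently to
the INV1 and INV2 signals of each tissue 100,000 times; the UNI value is
computed from the noisy complex pairs and the FLAWS minimum from the noisy
magnitudes.  The CNR between two tissues is the mean of the contrast
difference divided by its SD, with the sign kept so that contrast
reversals penalize the objective.  Per flip-angle pair the signed CNRs are
averaged over the ten B1+ scales 0.5–1.4.  The joint objective is

$$\mathrm{CNR_{total}} = \frac{\mathrm{FLAWS_{min}}\,
\mathrm{CNR_{GM\text{-}CSF}} + \mathrm{FLAWS_{min}}\,
\mathrm{CNR_{GM\text{-}WM}} + \mathrm{UNI}\,\mathrm{CNR_{WM\text{-}GM}} +
\mathrm{UNI}\,\mathrm{CNR_{GM\text{-}CSF}}}{\sqrt{TR_{MP2RAGE}\
\mathrm{(ms)}}},$$

a CNR per unit time that lets protocols with different TRs compete
fairly.

$\sigma$ is anchored so that the INV2 image of white matter at nominal
flip angles and $b_1 = 1$ has SNR 20, and is then held constant for every
flip-angle combination scanned at the same $TR_{GRE}$ (noise is set by
bandwidth, not by flip angle).  We anchor at the screening protocol
(flip angles 5/4°, TI 650/2220 ms, TR 4000 ms) for all $TR_{GRE} =
7.26$ ms work and at the final protocol (4/5°, TI 650/2280 ms) for
$TR_{GRE} = 7.9$ ms.  Absolute CNRs scale with $1/\sigma$, so they inherit
this convention; CNR ratios between protocols do not.

## Tunable parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| Tissue T1/T2 (ms) | WM 1220/45.9, GM 2132/55, CSF 3350/1000 | adult 7 T literature values |
| Proton density | 0.69 / 0.82 / 1.00 | same source |
| ADC (mm²/s) | WM 0.70e-3, GM 0.80e-3, CSF 3.0e-3 | literature brain ADCs |
| RF phase increment | 50° quadratic | vendor sequence setting |
| Spoiler dephasing | 1 cycle/voxel per TR_GRE, voxel 0.65 mm | minimal unbalanced gradient; configurable |
| Inversion efficiency | 1.0 (0.96 supported) | hyperbolic-secant pulse, near-ideal in vivo |
| B1+ scales | 0.5–1.4, step 0.1 | 7 T transmit-field spread |
| INV2 WM SNR | 20 | sets \(\sigma\) per TR_GRE |
| Noise repetitions | 100,000 | CNR SE well below grid contrasts |
| MC seed | 20221109 | reproducibility |

## What the optimizer does

`ti_grid_search()` scans TI1 (600 ms upward, 200 ms steps) × TI2
(2000–3200 ms) at each TR, masking pairs whose inter-block delays would be
negative, and records the flip-angle-grid maximum of
$\mathrm{CNR_{total}}$ per TI pair.  `fa_cnr_maps()` evaluates all seven
channels on a flip-angle grid (fine grid 1–10° × 1–10°, 1° steps), and
`select_fa()` implements the constrained choice: among pairs retaining at
least 85% of the maximum total UNI CNR, maximize the total FLAWS CNR,
breaking ties toward smaller angles (lower SAR).  `t1_sensitivity()`
repeats the argmax over 16 (WM, GM) T1 combinations — the 4 × 4 Cartesian
grid of evenly spaced values in 800–1150 ms and 1550–1900 ms; only the
count and the ranges are prescribed, so the even grid is our choice —
and reports the mean ± SD of the optimal angles.

## Image path and the phantom

`combine_volume()` applies UNI, FLAWS\_min, FLAWS\_hc, or FLAWS\_hco
voxelwise after rescaling both inputs to a common range (joint 99.9th
percentile mapped to 4095 by default — the absolute scanner scale on
which the background constant was tuned is not recoverable, so the
constant is interpreted on this documented scale).  The
background-suppressed ratios use
$(INV2 - INV1 - \beta)/(INV1 + INV2 + 2\beta)$ with $\beta = 70$, which
sends empty voxels to $-0.5$ instead of amplified ratio noise; at
$\beta = 0$ the exact identity
$\min(hc, hco) = 2\,\mathrm{FLAWS_{min}} - 1$ holds and is tested.
Image-domain CNR divides mask-mean differences by the raw median absolute
deviation (no 1.4826 factor — a documented convention that rescales all
image CNRs by one constant) of the UNI white-matter signal.

The synthetic phantom is concentric shells (WM core with a central CSF
pocket, GM shell, CSF rim, empty background) with a smooth multiplicative
B1+ gradient and optional complex noise.  Masks are eroded by one voxel so
that no boundary voxel enters a metric, standing in for the strict
partial-volume threshold used when segmenting real data.  The phantom
exercises every image-path operation against known ground truth; it does
not emulate anatomy, bias fields, motion, or parallel-imaging noise
amplification, so image-path tests validate the operators, not in-vivo
performance.

## Numerical choices

* Configuration orders are truncated at amplitude $10^{-10}$ and the
  state carries at most $2 n_{exc} + 2$ orders; the compiled engine and
  the pure-R operator chain agree to $10^{-10}$ on full protocols.
* The quadratic phase counter resets at each inversion so that the
  one-cycle map is time-invariant and a periodic steady state exists.
* The signal is recorded immediately after the excitation, demodulated by
  the transmit phase (receiver tracks transmitter under RF spoiling), and
  rotated so that positive longitudinal magnetization gives a positive
  real signal; echo-time decay is not modeled because both images share
  TE and it cancels in every ratio contrast.
* Scan-duration line counting: `ceil(nOuter * pf / grappa) +
  acs * (1 - 1/grappa)` outer lines, one per cycle; printed protocol
  times are matched to ±2 cycles, which is the precision this convention
  supports.
* Flip angles of 0° and all-zero voxels are legal degenerate inputs
  (zero signal, background value) rather than errors; infeasible TI/TR
  combinations raise an error that the TI search catches as a mask.

## Known limitations

* The spoiler gradient moment and the diffusion coefficients are not
  observable from published protocol tables; with the defaults above the
  high CSF ADC suppresses all CSF transverse coherence pathways, i.e. CSF
  sits at its ideal-spoiling limit.  CNRs involving CSF — most visibly
  the UNI GM–CSF channel — are sensitive at the tens-of-percent level to
  this convention, while WM/GM quantities are essentially unaffected.
  The toggles in `simulate_steady_state()` expose this directly:
  disabling diffusion (keeping T2 and RF spoiling) retains CSF echoes and
  lowers UNI GM–CSF CNR by roughly a third at the screening protocol.
* The constrained flip-angle selection can sit exactly on the 85%
  UNI-retention boundary; sub-percent signal changes (e.g. inversion
  efficiency 0.96 vs 1.0) can then move the selection between near-tied
  neighboring grid cells without materially changing either objective.
* Magnetization transfer, exchange, slice profiles, off-resonance, B0,
  k-space reconstruction and T1 mapping are out of scope.

## Problem sizes used in the shipped checks

The test suite runs the full study conditions: fine 10 × 10 flip-angle
grids, all ten B1+ scales, three tissues and 100,000 noise repetitions
per grid cell for the reproduction checks, plus reduced grids (a few
angles, thousands of repetitions) for the functional unit tests.
Phantoms of 16³–26³ voxels are generated in memory.  These sizes were
chosen so that every check recomputes its quantity from scratch in
minutes on a single core.
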