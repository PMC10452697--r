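---
title: "Chamber-array digital PCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chamber-array digital PCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdpcr)
```

## The measurement principle

Digital PCR partitions a diluted template sample into many tiny,
independent reaction volumes, amplifies, and simply counts which
partitions light up. `chipdpcr` models a microfluidic chamber-array
implementation of this idea: a chip with 54 parallel fluid channels
feeding 108 rows of 198 cylindrical microchambers — 21,384 chambers of
87 um diameter and 120 um height, a nominal single-chamber volume of
0.71 nL. End-point fluorescence is read on a four-colour system in which
one channel carries a *universal reference probe* that detects every
template (wild-type or mutant) and the remaining channels carry
mutation-specific probes, up to three mutation types per chip.

The package implements, as tested code, the complete desk-side analysis
that such a chip requires: (i) a ground-truthed simulator of Poisson
template loading and fluorescence imaging, (ii) recovery of per-chamber
calls from channel images, (iii) absolute quantification, and (iv)
reference-gated mutation typing.

## Poisson absolute quantification

With template at concentration $C$ (copies/uL) loaded into chambers of
volume $V_d$ (uL), the number of molecules per chamber is Poisson with
mean $\lambda = C V_d$, so a chamber is negative with probability
$e^{-\lambda}$. Inverting the observed positive fraction $d/n$ ($d$
positive chambers out of $n$) gives the maximum-likelihood estimate

$$\hat C = \frac{-\ln(1 - d/n)}{V_d},$$

which needs no standard curve. The test suite verifies this closed form
against an independent brute-force maximization of the binomial
likelihood (agreement to 6 significant digits over random $(d, n)$
pairs), and checks the small-load limit $\hat C \to (d/n)/V_d$.

**Confidence intervals.** No interval method is canonical for chamber
counts; we use the Wilson score interval on $p = d/n$
(`stats::prop.test(correct = FALSE)`) pushed through the monotone map
$C(p) = -\ln(1-p)/V_d$. Wilson was chosen for its behaviour at the very
small $d$ of rare-mutation work ($d = 0$ included). Simulated coverage
at $\lambda \in \{0.01, \dots, 2\}$ is checked to be at least 92% for a
95% interval.

**Edge conventions.** $d = 0$ reports $C = 0$ with an interval covering
zero. $d = n$ leaves the formula undefined; the result is flagged
`saturated`, the reported $C$ is the finite value at $d = n - 1$ (a
lower bound), and the upper confidence limit is unbounded. Unfilled
chambers are excluded from both $d$ and $n$ by default
(`count_unfilled = TRUE` adds them to $n$ only, for comparison with
readers that cannot see filling). Replicate chips pool by summing $d$
and $n$ — equivalent to one larger chip.

## Reference-gated mutation typing

A chamber containing a mutant template is positive in **both** the
reference channel and the mutation channel ("double positive"); a
chamber positive only in a mutation channel is anomalous — consistent
with impurity interference or a sampling irregularity — and is counted,
reported, and excluded from the mutant estimate. The mutation rate is
the ratio of the two Poisson concentration estimates,

$$P = \frac{C_{\text{mut}}}{C_{\text{ref}}} \times 100\%,$$

with $C_{\text{mut}}$ computed from double-positive chambers only and
$C_{\text{ref}}$ from all reference-positive chambers. An ungated mode
(`gate = FALSE`, all mutation-channel positives) exists for comparison.
Because the two estimates come from the same chambers they are
correlated; the interval on $P$ is propagated conservatively by interval
arithmetic, $[C^{lo}_{\text{mut}}/C^{hi}_{\text{ref}},\;
C^{hi}_{\text{mut}}/C^{lo}_{\text{ref}}]$, and is documented as wider
than exact. A mutation is flagged *detected* when at least one
double-positive chamber is found — the rule under which the simulated
0.2% fraction series below is detected on every chip. Two three-plex
chips merge into one six-mutation report (`panel_report()`), with
duplicate assignments rejected and missing panels reported as partial.

Multi-template co-occupancy needs no special handling: each channel's
positive count is inverted through the Poisson formula independently, so
chambers holding both a wild-type and a mutant molecule are counted
correctly on both channels.

## What the simulator emulates

`simulate_partition()` draws independent Poisson counts per chamber and
species (the dilute-limit equivalent of multinomial assignment of a
fixed molecule pool), applies a per-molecule detection efficiency, an
optional unfilled-chamber probability, and derives true channel
positivity through the probe panel. `render_images()` draws each filled
chamber as a disk at its grid position with a two-component intensity
model and adds per-pixel Gaussian background noise, yielding one 16-bit
image per channel plus the ground-truth centre table.

Key defaults, and why:

* **Chamber volume for loading: `7.1e-4` uL** — the chip's nominal
  0.71 nL printed volume. The geometric cylinder volume of the default
  layout is 0.7134 nL (`chamber_volume()` reports it at full precision);
  the <0.5% difference cancels in any simulate-then-estimate round trip,
  and the nominal value is what an instrument operator would enter.
* **Dilution factor 3.5/31.7** — the template's volume fraction in the
  reaction mix (3.5 uL template in a 31.7 uL mix); stock concentrations
  are scaled by it before loading. In-chamber concentrations are never
  printed on instrument reports, so the simulator exposes this factor
  explicitly.
* **Intensity model: `mu_neg` 5,000 / `mu_pos` 30,000, sigmas 1,500,
  background 2,000 (SD 200) on the 16-bit scale** — arbitrary but widely
  separated (about 8 within-class SDs to the midpoint), matching the
  clean separability of end-point chamber fluorescence; all overridable,
  with an optional uniform "rain" fraction between the modes.
* **Pitch 110 um** — rendering-only (chambers must not touch when
  drawn); it has no effect on any statistic.
* **Seeds are mandatory** for every stochastic entry point and are
  echoed into truth CSVs, config echoes and run manifests; identical
  seeds reproduce TIFFs bit for bit.

What it deliberately does **not** model: optics (no point-spread
function, no chamber cross-talk), flat-field/illumination gradients,
volume variability between chambers, amplification kinetics, or probe
chemistry failure modes beyond a scalar detection efficiency. Passing
the synthetic suites therefore demonstrates the correctness of the
statistical pipeline, not the performance of any physical instrument;
real images with uneven illumination would need a flat-field step this
package does not provide.

## Image analysis choices

* **Grid registration, not blob detection.** The layout is always known,
  so chamber centres are found by registering the nominal grid to the
  image: row/column projection profiles are correlated with the disk's
  chord-length kernel over integer translations up to half a pitch, ties
  broken toward zero shift. This guarantees exactly
  `total_chambers(layout)` centres in row-major order — the `n` that
  quantification divides by — and tolerates global translation; it does
  not handle rotation or scale error.
* **Intensity extraction** averages pixels in a disk shrunk to 0.8 of
  the chamber radius, avoiding edge pixels where disk meets background.
* **Thresholding** is exact two-class 1-D clustering: the split of the
  sorted intensities minimising within-class sum of squares (the global
  two-means optimum, found by scanning all splits — deterministic and
  affine-equivariant, unlike a random-restart k-means), with the
  threshold at the centroid midpoint. If the centroid gap is below 3
  pooled within-class SDs there is no positive population and all
  chambers are called negative: a single Gaussian population splits at
  about 1.6 SD gap, well below 3, while even one genuine positive
  chamber at the default separation sits far above it. A 256-bin Otsu
  threshold is available by configuration. "Rain" is handled by the
  threshold alone; no exclusion band is applied.
* Filling status is **not** inferred from images; it comes from the
  truth table (simulations) or defaults to all-filled.

## Problem sizes used by the test suites

The statistical suites run at the scale a desk reproduction needs, not
larger: the dilution series uses 4 tenfold levels (stock
2×10^1 – 2×10^4 copies/uL) × 20 chips of 21,384 chambers and requires
log–log $R^2 \ge 0.9998$; the detection-limit series runs 100 chips at
each fraction of {100%, 10%, 1%, 0.2%} (and 0%), expecting 100/100
detections down to 0.2% — at 0.2% a chip carries ~67 expected
double-positive chambers, so a missed detection is a
$\sim e^{-67}$ event; mutation-rate recovery averages 100 chips per
fraction and requires the mean within 10% relative error. Fraction-level
statistics use truth-derived call tables (partitioning and gating are
what these suites test); full image rendering and recovery is exercised
separately, once noise-free (bit-exact round trip required) and once at
default noise (99.9% call accuracy required). Unit tests use a 240-chamber
chip with the same geometry.

## A worked example

```{r example, eval = FALSE}
pan <- panel_config(c("Cy5", "HEX"), "Cy5", c(G12D = "HEX"))
cfg <- simulation_config(
  layout = default_chip_layout(), panel = pan,
  species_concentrations = c(
    G12D = in_chamber_concentration(0.01 * 2e4),
    WT   = in_chamber_concentration(0.99 * 2e4)),
  seed = 1)
truth <- simulate_partition(cfg)
calls <- calls_from_truth(truth, use_intensities = TRUE)
mutation_rate(calls, pan)
```

## Known limitations

* The confidence interval on $P$ is conservative; an exact treatment of
  the ratio of correlated binomial functionals is out of scope.
* Registration assumes translation-only misalignment and a regular grid;
  rotated or warped images are rejected rather than corrected.
* The detection-efficiency model is per molecule and channel-independent;
  probe competition and partial hybridisation are not modelled.
* Saturated chips ($d = n$) report only a lower bound; the default
  dilution keeps the top series level below saturation (~79% positive).
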