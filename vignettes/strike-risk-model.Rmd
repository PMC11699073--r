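---
title: "The vessel strike encounter risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vessel strike encounter risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strikerisk)
```

## The model

`strikerisk` simulates lethal collisions between vessels and large whales —
motivated by the North Atlantic right whale (*Eubalaena glacialis*) on the
U.S. East Coast shelf — on a regular 10 × 10 km grid. The unit of
computation is one *transit*: one vessel track segment crossing one grid
cell in one month. Annual mortality for a size class is the triple sum over
months $i$, cells $j$ and transits $k$ of

$$
M_{\mathrm{year}} \;=\; \sum_i \sum_j \sum_k
\; \lambda_e t_{ijk}\; \cdot\; p_{\mathrm{strike\,depth}}
\;\cdot\; (1 - p_{\mathrm{avoid}})_{ijk} \;\cdot\;
p_{\mathrm{lethality}}_{ijk} \;\cdot\; N_{w_{ij}},
$$

where $\lambda_e t$ is the per-capita encounter expectation for the transit,
$p_{\mathrm{strike\,depth}}$ the probability the whale occupies the upper
water column within the vessel's draft, $p_{\mathrm{avoid}}$ the binary
outcome of a vertical avoidance dive, $p_{\mathrm{lethality}}$ the
probability a strike kills, and $N_w$ the expected whale count in the cell
that month from a density surface. In each bootstrap iteration the strike,
avoidance and lethality components are drawn afresh for every transit;
1000 iterations is the default. Contributions are real-valued — the binary
per-transit outcome is scaled by the density-derived $N_w$ rather than
integerised — so annual totals are real numbers.

### Encounter kernel

The encounter component treats whale and vessel as randomly moving points
in the cell. We use the Gerritsen–Strickler swept-path form: with whale
speed $u$, vessel speed $v \ge u$, detection radius $R$ (one body length,
13.5 m) and cell area $A$,

$$
\lambda_e t = \frac{2R}{A}\,\tilde v\, t, \qquad
\tilde v = \frac{u^2 + 3v^2}{3v},
$$

over the cell transit time $t$. The antecedent encounter-risk literature
describes the two-dimensional random-movement model without restating a
formula, so the kernel is isolated behind `encounter_probability()` and can
be swapped; the test suite validates the implemented form against a
brute-force moving-points Monte Carlo oracle (uniform whale placement and
heading on a torus, exact minimum point-to-segment distance) and against
the swept-strip limit $2RL/A$ for a stationary whale. The whale swim speed
is not a quantity the source framework fixes; the default is 1 m/s and it
is an ordinary config entry. $\lambda_e t$ is an expected count: it is
multiplied by $p_{\mathrm{strike\,depth}}$ (and the Small/Medium correction
factor, below) and clamped into $[0,1]$ before being used as the Bernoulli
strike probability.

### Depth exposure

Whether the whale is within the vessel's draft is a Bernoulli draw with a
regional probability: the proportion of time tagged whales spend above 5 m
(for vessels under 350 ft) or above 15 m (for ocean-going vessels, OGVs).
The shipped defaults are tag-derived weighted regional averages
(`default_depth_profiles()`): Northeast 0.392/0.587, Cape Cod Bay
0.910/0.953, Mid-Atlantic 0.876/0.969, Southeast 0.564/0.930 (above
5 m / above 15 m). These are inputs, not estimates of this package; the
exposure threshold is tied to size class rather than to an individual
vessel's (usually missing) AIS draft.

### Avoidance geometry

A struck-at whale dives: from a uniform start depth on $[0, D]$ ($D$ the
class nominal draft: 5 m, 5 m, 15 m), at a uniform descent rate on
$[0.81, 2.0]$ m/s, beginning at a uniform reaction distance on
$[10, 1200]$ m. When the vessel arrives the whale is at
`start + rate × distance / vessel_speed`. It avoids the strike only if it
is then *strictly* deeper than the strike zone (draft × propeller-suction
scalar; the scalar is 2 for OGVs, giving a 30 m strike zone at the 15 m
nominal draft) **and** the bottom strictly exceeds strike zone + whale
height (3 m). Ties count as struck — the conservative reading of the
"greater than" geometry. The three dive quantities are stated in the source
framework as ranges only; independent uniforms are the least-assumption
default, and both ranges are config entries. A direct consequence is an
*unavoidable zone*: for OGVs, any water shallower than 33 m yields
avoidance 0 regardless of the dive.

### Lethality

Given a non-avoided strike, mortality is Bernoulli with an inverse-logit
probability in vessel speed (knots), size class, a 0/1 species indicator
and a speed × species interaction. The fitted coefficients behind the
published lethality curve are not public, so they are required config
inputs here; `default_lethality_coefficients()` is a clearly labelled
placeholder set chosen so that lethality rises steeply with speed for the
sub-350-ft classes while OGV strikes are near-certainly lethal at any
speed. A coefficient table can be imported from CSV
(`read_lethality_coefficients()`), and a property test confirms that
maximum-likelihood refits of outcomes simulated from known coefficients
recover them with near-nominal confidence-interval coverage.

### Small/Medium correction factor

Most vessels of 26–65 ft carry no AIS transponder, so observed traffic in
that class undercounts interactions. `derive_correction_factor()` computes
the class-level ratio of registered to AIS-observed unique vessels
(category-weighted mean with AIS-count weights, which equals total
registered over total observed); the default config value is 3.5. The
factor multiplies the Small/Medium encounter probability before clamping —
equivalent in expectation to duplicating transits, but cheaper.

## Randomness and pairing

Each bootstrap iteration owns a substream: iteration seeds are derived once
from the run seed, and within an iteration the five draw vectors (strike
uniform, start depth, descent rate, reaction distance, lethality uniform)
are generated unconditionally, positionally, in transit-id order. Two runs
that share a seed and transit ids therefore consume identical variates, so
a counterfactual comparison holds "all randomly-selected parameters besides
speed" equal. This makes several properties exact rather than statistical:
doubling the density surface doubles every replicate; forcing avoidance
off can only increase mortality; and the slow-all transform can only
decrease it (see below).

## The slow-all counterfactual

`slow_all_transform()` models a universal 10-knot speed restriction: every
non-exempt transit above 10 knots is reassigned a speed uniform on
$[9.5, 10]$ knots; exempt transits (e.g. military and government vessels)
are untouched. The transform is idempotent.

A design choice worth making explicit: by default the observed elapsed
times are **kept** rather than recomputed as `segment_length / new_speed`.
Recomputing would lengthen the cell transit time of a slowed vessel by
~40% (for a 14 → 10 kn slowdown) and raise its encounter exposure by the
same factor; because OGV lethality is near 1 at every speed, that would
nearly cancel the avoidance benefit and an OGV speed restriction would show
no effect — inconsistent with the sizeable OGV risk reductions reported for
this management question. Holding elapsed time fixed also makes the paired
slow-vs-real comparison monotone draw by draw (encounter probability,
arrival depth and lethality all move in the whale's favour as speed drops).
Users who want the exposure trade-off can set `recompute_elapsed = TRUE`;
the paired monotonicity guarantee then no longer holds.

## The synthetic scenario generator

`generate_scenario()` produces complete, validated inputs with no
download: a shelf bathymetry monotone offshore (with nearshore cells below
the 3 m whale-depth cutoff and early-shelf cells inside the 33 m OGV
unavoidable zone), monthly density surfaces from Gaussian hotspots that
migrate north in summer and south in winter with a month-specific
in-domain fraction of a 350-whale population, and Poisson traffic per
cell-month: OGVs in an offshore lane at ~14 kn, Large vessels spread over
the shelf at ~10 kn, Small/Medium traffic nearshore, summer-peaking and
fast (~18 kn), with a 5% exemption rate. Speeds are clipped into the valid
0.2–50 kn range and elapsed times are kinematically consistent with
segment length and speed.

What the generator does *not* emulate: port-network routing, within-track
autocorrelation, behavioural whale movement, inter-annual density
variability, and real coastline geometry (the grid is planar, with region
boundaries supplied as polygons — by default four latitude bands in the
fixed tie-break order Southeast, Mid-Atlantic, Cape Cod Bay, Northeast).
Passing tests on synthetic scenarios therefore demonstrates the
correctness of the model composition and its invariances, not the
realism of any particular mortality number.

```{r}
sc <- generate_scenario(scenario_spec(seed = 7))
sc
fit <- strike_risk(sc, run_config(n_iterations = 200, seed = 7))
summary(fit)
```

## Numerical choices

* The strike probability is `min(1, lambda_t * p_depth * correction)`;
  clamping is required because the swept-path expectation can exceed 1 for
  extreme parameters.
* Strict inequalities throughout the avoidance geometry; the 3 m cell
  filter is also strict ("less than 3 m" removed, 3.0 m retained).
* Length bins for class assignment: 26 ≤ L < 65 ft Small/Medium,
  65 ≤ L ≤ 350 ft Large, L > 350 ft OGV; lengths below 26 ft are outside
  the modelled fleet and dropped with a logged count.
* Speed filters keep the closed interval [0.2, 50] kn.
* Missing length/draft are imputed by uniform draws from same-category
  donors; missing speed or elapsed time is a filter failure, never imputed.
* Point-in-polygon region assignment is boundary-inclusive with a
  documented first-match tie-break, so a centroid on a shared edge is
  assigned deterministically.
* Degenerate inputs: empty transit sets simulate to exactly zero; a
  scenario with all-zero density yields exactly zero mortality; a
  zero-radius encounter kernel returns 0.

## Problem sizes used by the test suite

The checks in this package run on deliberately small instances, chosen as
the smallest sizes at which each statistical comparison has power: the
expectation oracle uses a 4-cell, 12-transit scenario with 2000 bootstrap
iterations against a 301-point-per-dimension quadrature of the avoidance
integral; the encounter oracle uses 10^5 Monte Carlo placements per
parameter set (3 standard-error agreement bands); the paired slow-all
monotonicity property is asserted over 100 generated scenarios of an
8 × 10 grid at 20 iterations each — the property is exact per draw, so
iteration count affects only runtime; and coefficient-recovery coverage
uses 200 refits of 5000 simulated strike outcomes.

## Limitations

Beyond the generator simplifications above: dive behaviour is constant
within region (no monthly or life-history variation); avoidance is purely
vertical (the empirical basis found no lateral avoidance, and none is
modelled); the propeller-suction scalar is a two-level class constant; the
lethality defaults are placeholders pending user-supplied coefficients;
and the per-vessel AIS draft is ignored in favour of class nominal drafts,
mirroring the sparsity of draft fields in real AIS records.
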