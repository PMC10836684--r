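---
title: "Virtual multi-domain hydrogel photopatterning: models, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual multi-domain hydrogel photopatterning: models, parameters, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapdh)
```

# The problem this package addresses

Multi-domain DNA-functionalized hydrogels are fabricated by repeated rounds of
microfluidic ink exchange and mask-shaped UV photopolymerization: an ink
(PEGDA monomer, LAP photoinitiator, acrydite-modified DNA strands) is flowed
into a chamber, the stage moves to a target site, a digital micromirror device
(DMD) shapes the exposure, and a wash removes the ink before the next round.
Because each patterned domain carries its own DNA, the finished architecture
can respond addressably: complementary strands quench specific fluorophores,
and hairpin "swelling signals" drive hybridization-chain-reaction (HCR)
swelling of specific DNA-crosslinked domains.

`mapdh` reimplements this workflow *as software against a simulated
instrument*: the image-to-protocol compiler, the flow/pattern/wash scheduler,
a virtual chamber that executes protocols (including sacrificial-layer
lift-off and collection), a synthetic micrograph renderer, and the
quantification procedures used on real micrographs. The point is to design,
dry-run, and analyze experiments — and to test every piece of the software
stack — without hardware.

# Pipeline and models

## Image decomposition

A raster image is binned to an `n x n` color grid (per-channel block means;
remainder pixels fold into the last row/column block, so a 355-px side with
`n = 15` uses fourteen 23-px blocks and one 33-px block). Binned cell colors
are clustered in RGB space by k-means, and each cluster becomes a binary
*location map*; the maps always partition the grid. Binning precedes
clustering so that anti-aliased art averages toward its dominant colors
before palette extraction.

k-means here is Lloyd's algorithm under k-means++ initialization with up to
50 restarts, plus two safeguards that matter on small discrete palettes:
a Hartigan-style single-point refinement pass after convergence, and
alternation of k-means++ with random-partition initializations across
restarts. Both are needed because Lloyd fixed points reached from
data-point initializations are demonstrably not always SSE-optimal on
such inputs; with the safeguards, the result matches exhaustive partition
enumeration on every grid small enough to enumerate (this is tested).
Clusters are ordered by descending cell count, so the largest domain becomes
ink 1 unless the caller reorders.

## Protocol grammar

A *patterning round* is `FLOW(vial)`, then per site `MOVE`, `FLOW(vial,
reflow)`, `PATTERN(mask)`, and a terminal `WASH` — including after the final
round. The short pre-exposure re-flow (default 3 s) mirrors bench practice:
re-flowing the round's ink just before exposure keeps patterned sizes
uniform. Validation checks, without executing: at most 4 distinct ink vials
(a 5th port carries wash buffer), a minimum working volume per vial
(default 100 uL, with a documented override down to 50 uL — the conservative
body-text value is the default, the lower bound is the demonstrated
extreme), round grammar (no `PATTERN` without an ink `FLOW` in its round),
and a terminal wash.

Protocols serialize to schema-versioned JSON (YAML accepted on read); parsing
is strict — unknown fields and ops are rejected with field context — and
`parse(serialize(p))` is the identity.

## Virtual chamber

`execute()` interprets the command stream against a chamber state: vials with
volumes, chamber content, patterned domains, sacrificial-layer status.
Choices worth knowing:

* **Flow rate** defaults to 0.1 uL/s. Chamber volumes are on the microliter
  scale, so second-scale flows move fractions of a microliter; this is what
  makes a 225-site pixel-art run feasible from a 150-uL vial. The value is a
  package default (the source experiments do not state rates) and is
  configurable in `hardware_profile()`.
* **Size bias**: polymerized size = nominal mask size + bias. The default
  bias is 0 (ideal optics). `paper_size_bias` is a *calibration table*, not
  physics: it echoes reported mean sizes (+1.5 um at 50-um masks, +7.1 at
  20, +3.7 at 10) for users who want simulated sizes to match bench
  measurements.
* **Lift-off and collection** are Bernoulli: while the sacrificial layer is
  intact, each WASH detaches each attached architecture with probability
  `p_washoff` (default 0.25; over three rounds this predicts ~14.5 of 25
  three-domain architectures lost, within binomial sampling error of the
  observed 12), and `COLLECT` recovers each free architecture with
  probability `p_collect` (default 2/13, the observed multi-domain
  collection fraction). These are outcome calibrations, not mechanistic
  models of adhesion.
* **Overlapping footprints** merge into one mechanically contiguous
  architecture (union of compositions; detachment acts on whole
  architectures). There is no interpenetration physics.

## Quenching and swelling

Hybridization of a solution strand to its anchored complement raises that
strand's quenched fraction by a saturating first-order law,
`q <- 1 - (1 - q) exp(-k c t)` (default `k` = 0.006 /nM/h); emission scales
by `1 - q`, so full quenching silences the channel exactly. Only domains
containing the complement change, and only in that fluorophore's channel —
this locality is a tested invariant.

No kinetic law is published for the HCR swelling of this system, so the
package uses a labeled stand-in: per matching crosslink system,
`L(t)/L0 = 1 + A * (1 - exp(-t / tau))` per free edge, with constrained
edges (those shared with a non-swelling neighbor) scaled by `c_edge`.
Defaults: `tau = 8 h` (an order-of-magnitude anchor — most single-system
swelling occurs within the first ~10 h), `c_edge = 0.5` (the constrained
edge swells about half as much, matching the observed ~50% edge
difference), and two amplitude profiles: `single_domain` (`A_S1 = 0.51`,
the measured single-domain endpoint) and `multi_domain` (`A_S1 = 0.4`,
`A_S2 = 0.6`, the free-edge endpoints in the constrained three-domain
architecture). The two profiles exist because the measured endpoints differ
between those experiments; the package does not pretend one constant
explains both. A swollen constrained domain is rendered as an axis-aligned
trapezoid whose height interpolates between its two vertical sides, so a
bounding-box measurement reads out the free-edge length.

## Rendering and measurement

Per channel, pixel intensity = background + gain x (sum of unquenched
fluorophore-strand concentrations of covering domains) + Gaussian noise
(defaults: background 100, sd 10, gain 1 count/nM), clamped at zero,
deterministic per seed. Measurement mirrors the bench analysis: Otsu
binarization (256-bin histogram, between-class variance maximization),
largest 8-connected component (run-length union-find labeling), axis-aligned
bounding box; length = box height x pixel size. `dL/L0` curves divide by the
first (pre-signal) measured length, so they start at exactly zero and
propagate measurement — not nominal — baselines, as on the bench.
Round-to-round homogeneity uses one-way ANOVA at alpha = 0.05 (the original
analysis names no test; ANOVA is the natural choice for a 12-round x 5-post
design).

# What the synthetic data does and does not establish

The synthetic generator states a world: four-color 355x355 pixel art whose
binning blocks are pure colors; squares of known size under Gaussian noise;
swelling time-lapses generated by the stand-in law above. Green tests
establish that the *software stack* — compiler, scheduler, executor,
renderer, measurement — is internally consistent and recovers configured
parameters through the full render-and-measure loop (e.g., the measured
60-h single-domain `dL/L0` is 0.51 within +/-0.05 across 50 seeds). They do
*not* validate the stand-in kinetics against chemistry, reproduce optical
artifacts (no PSF, no defocus, no autofluorescence gradients), or predict
bench detachment rates beyond the Bernoulli calibration. Physical outcomes
reported from the wet lab (e.g., 51.5-um prints from 50-um masks, 189 vs
195 um after collection) enter only as documented calibration profiles.

# Numerical and degenerate-input choices

* Otsu requires >= 2 distinct intensities; constant images raise a
  degenerate-image error rather than returning an arbitrary cut.
* Threshold ties resolve to the lowest maximizing bin edge; binarization is
  strict (`> threshold`).
* Binning requires `n <= min(H, W)`; k greater than the number of distinct
  colors collapses with a warning rather than fabricating empty clusters.
* Masks that round to zero DMD pixels are errors, not silent no-ops.
* Detached domains can never re-attach; chamber time is monotone; negative
  time increments are errors.
* All randomness (clustering restarts, detachment, collection, render noise)
  is scoped under explicit seeds; identical inputs and seeds give bit-for-bit
  identical outputs, which the suite asserts.

# Known limitations

* No reaction-diffusion or polymer-network mechanics; swelling is kinematic.
* No optical model beyond per-pixel Gaussian noise.
* Footprints are axis-aligned rectangles/trapezoids; named mask shapes
  (circle, plus, triangle) are carried as roles, not rasterized outlines.
* The YAML reader accepts hand-written protocols but JSON is canonical;
  YAML 1.1 boolean-key quirks are worked around only for the `y` coordinate
  key.
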