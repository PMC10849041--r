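---
title: "Mapping corticostriatal inputs onto reconstructed neurons: models and methods"
author: "striomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping corticostriatal inputs onto reconstructed neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striomap)
```

# The problem

Single striatal neurons — spiny projection neurons (SPNs) and fast-spiking
interneurons (FSIs) — receive convergent excitatory input from the primary
motor (M1) and somatosensory (S1) cortices. Given a 3D reconstruction of a
filled neuron and tables of detected presynaptic puncta per channel, the
analysis must decide which puncta are inputs *to that cell*, where each
input sits (spine, shaft, or soma; how far from the soma along the
dendrite), and whether inputs from the two cortical areas cluster near one
another. A parallel electrophysiological arm extracts action-potential
features from current-clamp sweeps to classify each recorded cell.

`striomap` implements this chain end to end and validates every stage by
parameter recovery on synthetic data, since per-cell raw data for studies
of this kind are typically not deposited.

# Geometry model

A neuron is a rooted tree of typed, radius-bearing nodes in µm (SWC
format; type 1 = soma, 3 = shaft, and a configurable custom code, default
10, for spines — standard SWC has no spine type). Parent–child node pairs
define frusta whose lateral surfaces model the dendritic membrane; the
soma is a single sphere at the root (multi-node somata are merged into the
largest-radius node, because the measurement of record is one
cross-sectional soma diameter). The first segment of each primary dendrite
takes the child's radius at both ends so the giant soma radius does not
leak into shaft membrane area; soma membrane is accounted once, as the
sphere.

Two distances matter:

* **Edge distance** of a punctum (a sphere; spot objects carry one
  diameter, so a spherical model is exact to the available data): the
  minimum over frusta of the centre-to-axis distance minus the linearly
  interpolated local radius, minus the punctum radius; the soma enters as
  sphere-to-sphere clearance. Negative values mean overlap and are legal.
  A punctum is a putative input when this clearance is **≤ 0.5 µm,
  inclusive** (the convention "within 0.5 µm" does not specify open or
  closed; we chose inclusive and test the boundary).
* **Path (geodesic) distance**: from the root centre along the unique root
  path, plus the partial arc on the addressed segment. Somatic inputs get
  the Euclidean distance from the root centre to their surface attach
  point (one soma radius), which places them in the first 10 µm bin — the
  somatic peak any along-dendrite histogram of such data shows.

"Field diameter" is operationalized as the caliper (maximum pairwise)
distance among node XY projections, matching a measurement made on a 2D
maximum projection. The z-range is computed from node coordinates; on real
reconstructions this equals the imaging-stack range only if the
reconstruction spans the stack — a caveat, not an assumption we exploit.

# Compartment assignment

Retained inputs are labelled with precedence **spine > soma > shaft**,
mirroring the subtraction order of the original measurement procedure
(spine contacts counted on a spines-only reconstruction, soma contacts
next, shaft contacts as the remainder). Labels therefore partition the
retained set exactly — the package tests this as an invariant. Densities
divide counts by the membrane area of the addressed compartments, scaled
to inputs per 10 µm²; the "dendrite" density of a spiny cell uses shaft
plus spine area. (Figure captions in this literature sometimes say
"contacts per 10 µm" where the computation divides by membrane area; we
consistently report per 10 µm².)

# Distribution and clustering statistics

Along-dendrite histograms use half-open 10 µm bins `[10k, 10(k+1))`.
Regions are proximal `[0, 30)`, medial `[30, 100)`, distal `[100, ∞)` µm —
the printed conventions "0 < 30", "30 < 100", "> 100" put 30 in medial and
100 in distal. Nearest-neighbour (NN) statistics are directional (S1→M1
need not equal M1→S1) and use centre-to-centre Euclidean 3D distance,
matching spot-to-spot statistics of reconstruction software; geodesic
variants can be computed from the attachment points but Euclidean is the
reported default. Cross-channel pairs within 5 µm count as clusters;
per-cell clustered fractions are tested against the 50% chance level with
the gated one-sample test. All per-cell summaries are averaged across
cells with equal weight (mean ± SEM over N cells, never pooled spots).

# AP feature extraction

The marking rule for AP threshold is the first sample whose forward slope
reaches 20 mV/ms before a peak (configurable; feature-extraction libraries
differ and the choice is not critical for the features used here). An
event stays open until the voltage falls back below its threshold voltage,
so a double-peaked rise yields one event whose peak is the global maximum;
the AHP is the minimum between the peak and the next threshold or the step
offset. The half-height width resamples the threshold→AHP stretch onto
1,000 evenly spaced points by linear interpolation and subtracts the first
rising from the last falling crossing of the half-amplitude level
(crossings refined linearly between interpolation samples; the error bound
on piecewise-linear templates is two interpolation steps). ISI uses
consecutive threshold times; IFF = 1000/ISI (Hz); MFF = max(IFF).

Passive properties are unspecified in the source conventions, so we chose:
RMP = mean voltage over the 50 ms before step onset averaged across
sweeps; input resistance = least-squares slope of the steady-state
deflection (last 10% of the step window) against injected current. No
liquid-junction correction is applied. Cells must reach steady-state
firing (CV of the last half of ISIs < 0.25) to be classified; the
classification cuts, HHW 0.8 ms and IFF 50 Hz, sit midway between the two
populations' group means (FSI ≈ 0.40 ms / 75 Hz; SPN ≈ 1.28 ms / 26 Hz)
and are exposed in the configuration.

# Statistical test selection

Each group is gated by Shapiro–Wilk at α = 0.05 (the gate level is a
choice; sources rarely state it). Normal groups: unpaired comparisons use
an F test on variances to pick Student vs Welch t; paired use the paired
t; one-sample use the t against the stated null (1 for ratios, 50 for
percent-chance). Any non-normal group routes to Mann–Whitney U, the
matched-pairs Wilcoxon, or the one-sample Wilcoxon. The same gate is
applied uniformly to one-sample tests. Levene's test (robust to small,
unequal groups) is used when comparing variability *between* cell types.
Constant data are routed to the nonparametric branch (Shapiro–Wilk is
undefined there), and zero-variance input to a t test is an explicit
degenerate-input error. All tests are two-tailed; the decision trail
(gate p-values, branch taken) is recorded in every result. The suite
verifies by simulation (10,000 null replicates) that the full selector's
type-I error at α = 0.05 stays within [0.04, 0.06].

# The synthetic-data generator

The generator defines the study conditions; its defaults are the group
values of the system being emulated and are not adjusted per run.

**Morphology.** `n_primary` shafts (5 for SPN, 7 for FSI) grow from a
soma (diameter 14.08 / 17.86 µm) by a seeded random walk: 5 µm steps,
persistent direction with jitter and a slight outward bias, branch
probability per 10 µm (0.22 / 0.28, chosen to give realistic total cable
of roughly 2–4 mm), radii tapering toward 0.3 µm, z-components shrunk
(z_scale 0.15) so the z-extent lands near the ~60 µm typical of slice
reconstructions. The XY coordinates are then rescaled so the caliper field
diameter matches the target (256.1 / 242.0 µm) within ±2%. SPNs get
single-node spine heads (neck 0.8–1.8 µm, head diameter 0.6–1.2 µm,
inside the spine-detection bounds of 0.6–2.5 µm) at 0.5 per µm of shaft
distal to the first branch point — spines are prominent only beyond the
first ramification in these cells. FSIs are aspiny by construction.

**Puncta.** Per cell, a total input count ~ Poisson(352.4 for SPN, 309.6
for FSI) splits between M1 and S1 by a per-cell proportion π drawn from a
Beta distribution. The Beta is the one point where two printed group
statistics must be reconciled: the across-cell mean M1 percentage
(61.66%) and the across-cell mean of per-cell M1/S1 ratios (1.802) cannot
both hold for a fixed proportion (0.6166 gives odds 1.608); a between-cell
distribution with E[π] = 0.6166 and E[π/(1−π)] = 1.802 pins
Beta(14.95, 9.29), whose implied between-cell spread (sd 9.7%) agrees
with the spread implied by the reported SEM (sd ≈ 8.8% over 12 cells).
The FSI analogue, from 55.05% and 1.867, is Beta(3.56, 2.91). Poisson
counts (not fixed) are the default so SEM behaviour across simulated
cells mimics between-cell variability; a fixed-count mode exists for
exact bookkeeping tests.

Each input samples a compartment (SPN spine/shaft/soma =
0.6046/0.1641/0.2313; FSI dendrite/soma = 0.7921/0.2079), an
area-weighted location on that compartment's surface, and a radial offset
making its edge clearance uniform in [−0.2, +0.5] µm — every planted
input passes the edge filter. A planted label must be *unambiguous under
the same precedence the assignment applies*: a shaft location whose
punctum would also touch the soma sphere (or a spine) is re-drawn, so
compartment recovery measures assignment fidelity rather than
boundary-assignment conventions. With probability `p_cluster` an S1 input
is relocated onto the tree near a uniformly chosen M1 input (on-surface
projection, centre distance kept within the 5 µm threshold); the
remaining S1 inputs are rejection-sampled to lie beyond 5 µm of every M1
input, re-drawing the compartment each try because a soma tiled by tens
of M1 inputs can have no admissible location — with this exclusion the
measured colocalized fraction estimates `p_cluster` directly. Background
puncta (off-cell spots that the edge filter must reject) are added at
0.04 per 1000 µm³ of bounding volume, a density chosen so roughly a third
of raw spots are rejected, qualitatively matching dense neuropil; this is
deliberately arbitrary and exposed in the parameters. A ground-truth
record (counts per channel × compartment, clustered pairs, the drawn π)
is self-audited against the emitted files on every generation.

**Sweeps.** Eleven current steps (−500 to +500 pA, 100 pA, 500 ms) at
20 kHz. Subthreshold sweeps settle exponentially (τ = 10 ms) to the Ohmic
deflection I·R_in; spiking sweeps hold a plateau at the AP threshold
voltage and carry piecewise-linear AP templates (threshold −45 → peak
+40 → AHP −55 mV → 2 ms recovery). The template's rise time is snapped to
the sample grid and its fall time solved so the *analytic* half-height
width equals the planted value; threshold times follow the planted ISI,
snapped to the grid. Snapping makes generator↔extractor round trips exact
to machine precision, while off-grid ISIs (e.g. 1000/75.21 ms) are
recovered to <0.4%. Planted values default to the group means (SPN HHW
1.282 ms, ISI 42.11 ms, R_in 117.7 MΩ, RMP −75 mV nominal; FSI 0.4043 ms,
13.65 ms, 108.6 MΩ, −67.94 mV). Traces are noise-free by default so
recovery is exact; Gaussian noise is available as a parameter.

# Numerical choices and degenerate inputs

* Edge rule inclusive at 0.5 µm; retained sets are monotone in the
  threshold and filtering is idempotent.
* Ties in the minimum-clearance segment resolve to the first segment in
  canonical order (deterministic).
* Empty puncta tables, empty compartments, cells with no spikes, and
  single-AP trains return empty/flagged results, not errors; structural
  defects in SWC files (cycles, multiple roots, self-parents, unknown
  type codes) are errors naming the offending node.
* All generators are deterministic under a fixed seed; emitted files are
  byte-identical across reruns.

# Problem sizes used in validation

The test-suite and acceptance runs use the cohort sizes of the emulated
study: 12 simulated SPNs for proportion/ratio/clustering recovery, 7 FSIs
for the dendrite/soma split, 500 puncta × 500 segments for the
edge-distance oracle equivalence, 20 seeded cells for the partition
invariant, 50 replicates of a 215-point Poisson cable for the L/(2n)
spacing law, and 10,000 null replicates for selector calibration. These
sizes keep each run in the seconds-to-a-minute range while giving the
recovery checks standard errors well inside their acceptance bands.

# What passing tests do and do not show

The generator plants spherical puncta on an idealized frustum surface with
exactly known clearances; real confocal data add segmentation error,
ellipsoidal spots, diameter-estimation error on thin dendrites, and
z-anisotropy of the point-spread function. Recovery tests therefore
demonstrate that the *measurement chain* is correct and unbiased under its
own geometric model — not that the 0.5 µm edge rule identifies true
synapses (the original validation against presynaptic markers is an
experimental question). Likewise the AP templates are piecewise-linear;
they validate the interpolation and marking logic, not biophysical
realism of spike shapes. Sholl-type branch-order analyses, voxel-level
image processing, and D1/D2 SPN distinctions are out of scope.
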