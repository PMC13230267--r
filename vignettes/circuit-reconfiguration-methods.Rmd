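---
title: "Methods: dynamic reconfiguration of receptor-defined brain circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic reconfiguration of receptor-defined brain circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitDyn)
```

# The analysis in one paragraph

circuitDyn studies whether the brain regions richest in monoaminergic
receptors and transporters (serotonin 5-HT1a, 5-HT2a and 5-HTT; dopamine D1,
D2 and DAT; noradrenaline NAT) reorganize their network affiliations
differently in people with multiple sclerosis (pwMS) who experience fatigue.
Region-averaged BOLD time series are windowed (27 volumes, step 1; 300
volumes give 274 windows), each region is assigned in every window to the
resting-state network (RSN) it is most connected to, and the resulting
label sequences are summarized per region as **flexibility** (fraction of
window transitions with a network switch), **promiscuity** (fraction of the
K = 8 networks ever visited), **cohesion** (switches made simultaneously
with at least one other region to the same destination) and
**disjointedness** (switches made alone). Metrics are averaged within
receptor-defined circuits and globally, and compared between healthy
controls and pwMS grouped by fatigue severity with ANCOVA (sex, age, years
of education as covariates) under Benjamini-Hochberg correction per outcome
family. A synthetic-cohort generator with planted switching structure stands
in for scan data, so every stage is testable end to end.

# Circuit delineation

Per receptor/transporter map, regional densities are normalized to their
maximum (`normalizeDensity`), restricted to the regions that survive
coverage quality control, and sorted. The cut-off between circuit members
and the rest is the elbow of the sorted curve (`detectElbow`): both axes are
scaled to [0, 1] and the elbow is the point of maximum perpendicular
distance from the chord joining the first and last values. Two conventions
complete the rule:

* When the maximum distance is below `linearityThreshold` (default 0.02,
  i.e. 2% of the value range) the curve is declared linear and the top 5%
  of regions is taken instead (`selectTopFraction`, ceiling rounding:
  ceil(0.05 × 224) = 12). The threshold is a design choice: it is small
  enough that any visually apparent knee (our planted knees at sharpness 2
  sit several times higher) is kept, while sampling jitter on a straight
  ramp stays well below it.
* When the chord crossing falls inside a cliff — the max-distance point
  lies below the chord while its predecessor lies above — the cut-off is
  the predecessor. A step function (7 regions at 1.0, the rest at 0.1) then
  selects exactly the plateau, while smoothly sagging curves keep the knee
  itself. Ties in density are broken by region id, making selection
  deterministic.

Maps that select identical member sets are merged under a joint name
("D2/DAT"); the merge compares member sets, not density values.

Quality control precedes selection: participants with more than 12
zero-coverage regions are excluded, then regions with coverage below 30% in
more than 10% of the retained participants are excluded (both inequalities
strict; a fixture of 224 regions with 22
built to fail retains 202).

# Connectivity transform chains

Static: Pearson correlation over the full series, Fisher r-to-z with |r|
clipped to 1 − 1e−7 (so perfectly correlated pairs stay finite at
atanh(1 − 1e−7) ≈ 8.4), absolute value, then division by the off-diagonal
maximum, giving values in [0, 1] with max exactly 1. The literal printed
order (normalize, then z-transform) is numerically impossible — the maximal
element would map to atanh(1) = ∞ — so normalization is applied last; the
applied chain is recorded in `transformLog`. Windowed matrices use the same
chain *without* max-normalization: the allegiance argmax is invariant to a
global positive rescaling, and normalizing per window would only reweight
windows against each other. Windows are rectangular (no taper), and the
diagonal is NA everywhere so no summary can accidentally include
self-connectivity.

# Allegiance assignment and reconfiguration metrics

In each window, a region's allegiance is the network whose members
(excluding the region itself; self-connectivity would trivially anchor each
region to its home network) have the highest mean windowed |z| with it.
Exact ties keep the previous window's label when it is among the maxima and
otherwise take the lowest network index — ties then never create switches,
and the assignment is deterministic.

The four metrics are fractions of the W − 1 window transitions (promiscuity:
of the K networks). A switch is cohesive when at least one other region
switches at the same transition to the same destination, with no condition
on the source labels: this reading makes every switch either cohesive or
disjoint, so cohesion + disjointedness = flexibility — exactly at the
switch-count level, and to within one unit of double rounding on the stored
fractions (two correctly rounded quotients c/n and d/n can differ from
(c+d)/n by one ulp). Circuit and global values are unweighted means over
member regions and over all retained regions, respectively.

# The synthetic cohort

The generator emulates a realistic MS fatigue cohort: four groups (60 HC, 87
non-fatigued, 77 mildly/moderately fatigued, 53 severely fatigued by
default), 224 regions (210 cortical over 7 networks, 14 deep-gray forming
the 8th), 300 volumes, FSMC totals drawn inside each group's band
(validation rejects bands that straddle a classification cut-off), HADS
scores below the exclusion threshold, covariates typical of such samples (age ≈ 30 ± 8 in HC vs ≈ 38–41 ± 9–11 in pwMS, education ≈ 17 ± 3 vs
≈ 14–15 ± 3, ~53–67% female), and MS phenotypes ~89% relapsing-remitting.

Each network has an independent unit-variance Gaussian latent signal per
volume; a region's signal is its current network's latent plus N(0,
noiseSd²) noise (default noiseSd = 0.5, i.e. within-network correlation
0.8). White latents are the simplest model under which within-network
correlation exceeds between-network correlation, which is all the
assignment step assumes.

Planted switching is realized as **transient visits**: a region departs its
home network at window transition t (first changed volume t + width − 1),
dwells in the destination for width + 3 transitions, and returns. Visits
rather than one-way moves are essential: with one-way switches at realistic
rates nearly every region drifts off its home network within a 300-volume
scan, dissolving the fixed network structure that allegiance assignment
measures against. Three further identifiability constraints keep the
planted truth recoverable by construction:

* **Anchors.** Two thirds of each network's regions never depart. A
  network's faithful anchors then always outweigh both a visitor's
  co-moving home neighbours and any cohesive group arriving from another
  network (which transiently mimics its home network inside the
  destination).
* **Slot-based cohesion.** At each transition and network, a "slot" fires
  with probability π and every clear mobile member then departs
  independently with probability s, where π·s = rate/2. Co-departing
  members share one destination and return together, so both of their
  switches are cohesive; a lone departure is disjoint. s is set from
  `cohesiveFraction` (default 0.7), the target probability that a departure
  has at least one co-mover; much higher values produce co-visiting groups
  comparable to a network's mobile pool, for which the argmax margin
  degenerates.
* **Clear spacing.** A region is eligible ("clear") again one full window
  width after its return, and departures stop early enough that every visit
  has fully interior windows on both sides. Each visit then contributes
  exactly two recoverable switches.

Because each mobile region departs with probability rate/2 per clear
transition and each visit is two switches, the expected number of switches
per clear transition equals the group's `switchRate`. Defaults are HC
0.020, non-fatigued 0.022, mild/moderate 0.028, severe 0.035: the severe −
HC difference of 0.015 mirrors the order of magnitude of group
differences reported in the MS fatigue literature, and the absolute level respects the constraint that
planted events be separable (≲ 1/width). The raw flexibility of real BOLD
data is an order of magnitude higher because it includes an estimator noise
floor the noiseless planted events do not emulate — passing recovery tests
therefore demonstrate correct counting and assignment machinery, not
realistic absolute flexibility levels.

A switch planted at transition t contaminates the windows overlapping the
changed volume; `windowTruth` marks those boundary windows NA and recovery
is asserted on interior windows only. `interiorFlexibility` removes each
region's boundary windows before counting, which is the boundary correction
used for rate recovery. Recovery of cohesive/disjoint *rates* is tested on
the window-domain label matrices the schedules imply: co-movers from
different source networks desynchronize by a window or two in windowed-FC
recovery (the correlation crossover depends on each region's own old
latent), so the FC pipeline is held to switch counts and label equality,
and the counting metrics are held to the planted modes.

The generator does not emulate: hemodynamic convolution or autocorrelated
BOLD spectra, head motion, scanner drift, voxel-level structure (coverage
defaults to 1 and fixtures set it explicitly), lesion anatomy, or FSMC item
-level responses (only scale totals, since the pipeline consumes totals).

# Group statistics

`runAncova` fits outcome ~ sex + age + education + group by least squares
with the covariates entered first; the group F uses the sequential sum of
squares for the group block, equivalent to the group term of the single
stated model. Pairwise contrasts are t-tests on adjusted group-mean
differences (covariates held at their sample means) with the full-model
residual variance, uncorrected across the six group pairs — a Tukey-style
correction is deliberately not applied by default since per-contrast
reporting is the convention this analysis follows. Sex enters as a single
binary indicator. Singular designs fail naming the aliased column.

`runPlan` organizes outcomes into families mirroring the result-table
blocks — volumes, static FC across circuits, flexibility (global + circuits),
promiscuity (global + circuits) — with Benjamini-Hochberg correction within
each family (`bhAdjust`, delegating to `stats::p.adjust`). Cohesion and
disjointedness are gated: they are computed only for units whose adjusted
flexibility effect is significant at α = 0.05, and are flagged post hoc.
Family membership and α are arguments, not constants, because the exact
family boundaries are a reporting convention.

# Problem sizes used by the test suite

Tests choose sizes so the full suite runs in a few minutes while keeping
every scientific property intact: property tests of the metrics use up to
10 regions × 12 windows against a brute-force enumerator (1000 matrices);
full-pipeline recovery cohorts use 80 regions × 300 volumes × 20 subjects
(80 regions keep ≥ 10 members per network so the argmax margins of the
identifiability analysis hold); the ANCOVA power criterion uses 200
replicate 20-subject cohorts at the default cohort geometry (224 regions × 300
volumes) with subject flexibility taken from generator ground truth, the
windowed-FC pipeline having been tied to that ground truth in the same
test; calibration uses 1000 null ANCOVAs at n = 40. The acceptance script
scales the power and null runs down (100 and 500) to stay fast while
reporting the same quantities.

# Known limitations

* Allegiance is argmax-to-fixed-RSN, not multilayer community detection;
  the two agree only when the fixed parcellation matches the data's
  community structure.
* The max-normalization of static FC divides by a per-subject maximum, so
  static FC values are comparable within subject but only approximately
  across subjects.
* The planted-rate estimator divides by the realized number of clear
  transitions, which is itself outcome-dependent; this inflates the
  recovered rate by roughly 2–3% (a negative-binomial-style ratio bias),
  well inside the Monte-Carlo tolerance used for recovery but visible in
  the acceptance report's bias entry.
* Real receptor-density curves need not have a single knee; the elbow
  detector returns one cut-off and flags near-linearity, nothing more.
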