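---
title: "Locating re-entrant drivers of atrial fibrillation from simulated electrograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating re-entrant drivers of atrial fibrillation from simulated electrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Catheter ablation of atrial fibrillation (AF) aims to destroy the small
patches of tissue — re-entrant circuits, or drivers — that keep the atria in
fibrillation. Mapping catheters record electrograms at a handful of sites at
a time, and limited mapping resolution makes it hard to decide where the
driver actually is. This package implements, in a deliberately simple
lattice model of atrial tissue, a search strategy that localizes drivers
from *indirect* electrogram measurements: statistical features of a few
multi-electrode recordings, fed to random forests that predict where the
driver lies relative to the probe, iterated until the probe lands on the
circuit.

Everything is simulated: the package generates its own tissues, drivers,
electrograms, training corpora and evaluation ensembles. It is a research
codebase for studying the *method*, not a clinical tool.

# The tissue model

The tissue is an `L x L` cellular automaton (`L = 200` by default). Each row
is a muscle fibre: neighbouring cells in a row are always coupled, and the
two row ends are open boundaries. Adjacent fibres are coupled at each column
independently with probability `nu` (default 0.2), and rows wrap
periodically — a cylinder, longitudinally fibrous, transversally sparse.
Low `nu` stands for fibrotic decoupling of fibres; 0.2 is the regime where
paroxysmal fibrillation appears in this model family.

Cells cycle through resting, excited (one step) and refractory (`tau = 50`
steps). A resting cell excites when any coupled neighbour is excited.
Pacemaker cells along the left column fire every `T_pace = 220` steps. One
step represents 3 ms, so the refractory period is 150 ms and sinus rhythm
beats every 660 ms — physiological atrial values. A fraction `delta` of
cells can be dysfunctional (failing to fire with probability `epsilon`);
the default working limit is `delta = 0`: rather than waiting for circuits
to form spontaneously from conduction block, the package *inserts* them at
known positions, which is what makes supervised training possible.

An inserted circuit decouples the 28 cells to the right of a random anchor
from the fibres above and below, guaranteeing the two transverse couplings
at the ends of the span: a closed rectangular loop over two fibres and 30
columns, of path length 60. Since 60 exceeds `tau`, an excitation can chase
its own refractory tail around the loop for ever, re-exciting every cell of
the footprint exactly every 60 steps and radiating wavefronts into the
surrounding tissue — a stable driver. Seeding places one excited cell at
the rightmost cell of the lower fibre with a descending refractory wake of
`min(tau, 59)` cells behind it along the loop, which forces one circulation
direction. `initialize_af()` then runs the automaton until activity has
reached every column and the fibrillation criterion (more than `1.1 * L`
excited cells, i.e. strictly more than 220 — more than any single paced
plane wave can produce) has held at least once.

# Electrograms

A unipolar electrode at height `h = 1` cell above the plane sees a
current-dipole sum over coupled cell pairs,

    Phi = sum over bonds (i, j) of (u_i - u_j) * [(r_i - r_j) . (r_m - r_e)] / |r_m - r_e|^3,

with `u` a membrane potential surrogate (excited = 1, linear repolarization
to 0 across the refractory stages, resting = 0), `r_m` the bond midpoint
and `r_e` the electrode. Bonds crossing the periodic row seam use
minimum-image displacements; no bonds cross the open column ends. Voltages
are in arbitrary units — only morphology matters — and a plane wave passing
under an electrode produces the classic single biphasic deflection, once
per pacing period in sinus rhythm. Contributions are truncated beyond an
in-plane radius of 25 cells (`cutoff`); with the inverse-square falloff the
neglected tail is orders of magnitude below the near-field deflections, and
the truncation is what makes corpus generation tractable. The mapping
catheter is modelled as a 3 x 3 grid of such electrodes spaced 3 cells
apart (a 7 x 7 cell footprint), recorded simultaneously for 120 steps: two
60-step circuit cycles, i.e. 360 ms, within the sub-400 ms window a search
recording is allowed.

# Features

Each electrode series is reduced to 12 statistics: extremes, mean,
variance, standardized skewness and kurtosis, first-stationary-point index,
maximum one-step voltage change, intensity (summed |V|), dominant nonzero
Fourier frequency (cycles/window) and its magnitude, and the count of
threshold-crossing activations. For every statistic the mean
finite-difference gradient along x and along y across the grid (per cell,
averaging all six parallel electrode pairs — which damps the local zig-zag
of discrete wavefronts) joins the feature vector.

Relative timing across the grid is the most informative signal, and a
single threshold crossing proved a poor estimator of it: on held-out
recordings the plane-fit wavefront bearing from 25%-threshold activation
times agreed only weakly with the true driver bearing. The packaged
feature vector therefore estimates each electrode's delay relative to the
centre electrode by windowed cross-correlation (lag search +/- 15 steps),
which uses every wavefront crossing in the window and roughly doubles the
bearing agreement of the same plane fit.
The nine delays, their two gradients and the fitted wavefront direction
(angle and unit vector) complete the 146-dimensional vector. The
threshold-based `activation_times()` remains available. Vector feature maps
(`build_vfm()`) aggregate any feature by displacement from the driver
centre across many simulations. Under this package's kernel, the
dominant-frequency magnitude map separates the along-fibre sweep region
from the fragmented transverse region, while the source bin itself stands
out most strongly in waveform skewness and mean voltage — the map
structure that motivates learning location from electrogram features.

# The four forests

A training corpus (`generate_training_set()`) simulates `n` tissues with
one random driver each and records 64 uniformly placed multiprobes per
tissue — `n * 64 * 9` electrode recordings (2,880,000 at the full scale of
5000 tissues). Each row is labelled with the probe's signed displacement
from the driver centre (columns open, rows minimum-image) and with on-band
indicators: the probe is *on the driver's X-band* if its 7 x 7 window's
columns overlap the circuit's 30-column extent, analogously for rows, and
*on the circuit* iff both (for these rectangular footprints the conjunction
is exactly window-footprint overlap).

Four random forests (100 trees, default mtry, via ranger) are trained:
binary classifiers for the X- and Y-bands, and two probabilistic locators
over signed displacement bins of 5 cells. The locator trees are grown
with leaves of at least 25 samples, which both regularizes their vote
distributions (higher end-to-end localization accuracy than fully grown
trees) and keeps them an order of magnitude cheaper to evaluate.
Displacements, not absolute
coordinates, are learned: the features are translation invariant, so
absolute-coordinate learning would be ill-posed; the probe's known position
converts a displacement class back to a tissue coordinate. Class
probabilities are ensemble vote fractions, `P_i = k_i / k`. On-band
positives are rare (about 18% for x, 4% for y), and inverse-frequency class
weights left the classifiers essentially blind to the positive class at
desk scale; the band classifiers therefore use a balanced bootstrap (equal
per-class draws per tree), which restores useful held-out sensitivity to
the on-band class.

# The search

A search starts at a uniform random probe placement with the whole tissue
admissible. Each jump records two cycles, extracts features, and first asks
the two band classifiers: if both assert, the search ends positively, and
the *reported ablation target* is the locators' final prediction — the
probe refined by the predicted displacement, clamped to at most one probe
footprint (10 columns, 5 rows), with the row component replaced by the
sub-bin vertex of the grid-row delay parabola whenever the delay field is
convex (a source straddled by the electrode rows makes the delays
v-shaped; the vertex locates its row to a cell or two, finer than the
5-cell locator bins). Without this refinement most near-misses stop one
window just outside the 2 x 30 footprint. If the classifiers do not
assert, each locator's vote distribution is restricted to
the admissible region, renormalized, and its argmax bin (ties: nearest the
region midpoint, then the smaller coordinate) proposes the next centre,
clipped to the region and to valid placements.

The admissible region is maintained per axis as masks over columns and
rows. The sign of each accepted proposal's displacement marks the half
space (half circle across rows) inferred to contain the driver, and the
region is intersected with it. Two refinements, calibrated on held-out
predictions, harden this mechanism: cuts keep a safety margin of 8 cells
behind the probe (and past the antipode in y), so the frequent small-
displacement sign errors and the ambiguous near-antipodal row inferences
do not expel the driver; and the column cut is applied only when the
proposed row displacement is at most 12 cells, because the column-sign
inference is unreliable while the driver is far across rows but highly
accurate once it is predicted y-near — so the search effectively resolves
the row coordinate first and then bisects the column. A *prediction error* is declared when
the region narrows below one probe footprint (7 cells) on either axis or a
proposal revisits an earlier centre; it restarts the search from a fresh
random placement under its initial constraints, keeping the cumulative
jump count, and only a search that exhausts the 30-recording jump budget
inside a prediction-error state reports it as its failure mode (the error
state initiates a restart rather than terminating the search). Success is
assessed against
ground truth: a positive final probe whose window overlaps a circuit
footprint marks tissue whose ablation would terminate that circuit.

For several drivers, the package exploits wavefront collisions: waves from
a driver run both ways around the row-periodic tissue and collide at its
antipodal row. After the first driver is found, two probes straddling the
expected collision row 12 rows apart each measure the local transverse
flow (the sign of the top-minus-bottom mean electrode delay). Converging
flows mean the wave trains collide between the probes; a common direction
is through-traffic whose source — the next driver — lies on the opposite
side, confining the next search to that row arc; diverging flows mean a
wave source sits between the probes and the next search is confined to
that band. A detected collision is then localized by bisecting on the flow
sign: a collision line displaced by more than 5 rows from the expected row
betrays a second driver close to the first (the line sits at
`(d1 + d2)/2 + L/2`, so `d2 = d1 + 2 * displacement`), and the next search
is confined to the implied band; an on-centre collision ends the search
with no further driver detectable. All collision-probing recordings count
as jumps of the following search. Found drivers are protected by an 8-row
exclusion band (wide enough that no admissible window can overlap the
found circuit again). The collision reasoning is one-dimensional by
design, and the forests remain those trained on single-driver tissues; the
second search therefore operates under interference from the first
driver's wave field, which keeps its success rate well below the first
driver's — its residual failures concentrate in the mixing region between
the two wave domains.

# Scale, defaults, and what the tests show

The packaged study conditions are desk scale: 500 training tissues
(32,000 labelled recordings) and evaluation ensembles of 200 tissues per
driver count, against the reference scale of 5000 and 1500. All seeds are
explicit, and a (configuration, seed) pair reproduces corpora, bundles and
evaluation summaries exactly. The random-placement chance level — the
fraction of probe placements whose window touches the circuit, by exact
enumeration about 0.74% — is the baseline the guided search is measured
against; the trained search exceeds it by two orders of magnitude.

The synthetic generator *is* the study system here, so passing tests
demonstrate that the method works in this model's world: stable artificial
drivers of fixed period and footprint, clean noiseless electrograms, a
cylindrical topology, uniform refractory period, conduction at one
coupling per step. None of that guarantees performance on clinical
electrograms, where fractionation, noise, catheter geometry and true 3-D
anatomy intervene; the package's claim is methodological.

# Numerical choices and degenerate inputs

* Dysfunctional-cell failures (`epsilon`) are drawn per excitation attempt
  per step; the default `delta = 0` makes the dynamics fully deterministic
  given the tissue, which the replay and mirror-symmetry tests exploit.
* Constant voltage series define skewness and kurtosis as 0 and have no
  dominant frequency (magnitude 0); an all-zero series has undefined
  delay/activation (NA, encoded as 0 with an undefined direction flag in
  the feature vector).
* The wavefront plane fit needs at least 3 finite delays and declares the
  direction undefined when the fitted gradient is numerically zero
  (simultaneous arrival).
* Circuit insertion near the right boundary is a placement error (the
  decoupled span must fit inside the open boundary); an unsustainable
  circuit (path length not exceeding `tau`) warns at seeding and raises an
  initialization failure when the activity dies.
* Coordinates are 1-based `(row, col)` matrices as idiomatic in R; rows
  wrap, columns do not.
* Tie-breaking everywhere is deterministic (documented in
  `propose_position()`), so evaluation summaries are seed-reproducible.
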