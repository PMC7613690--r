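---
title: "Methods: detecting and quantifying distal AIS relocation from simulated HD-MEA footprints"
author: "aistrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying distal AIS relocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The axon initial segment (AIS) — a sodium-channel-dense microdomain on the
proximal axon — relocates distally in response to chronic activity
perturbations, a form of homeostatic structural plasticity. Tracking this
relocation non-invasively in many neurons at once would require reading it
out from extracellular recordings. High-density microelectrode arrays
(HD-MEAs) resolve the spatial pattern of a neuron's spike-triggered
extracellular potentials (its *footprint*) at tens-of-micrometer pitch, and
because the AIS dominates the extracellular field during the action
potential, a relocating AIS should leave a systematic signature in the
footprint. `aistrack` implements, entirely in simulation, the machinery to
(i) generate such footprints from biophysical neuron models, (ii) learn to
detect AIS relocation and regress its magnitude from footprint feature
changes, and (iii) estimate the AIS position of an arbitrary neuron from a
library of linear impulse-response kernels derived from a minimal model,
without per-neuron morphological knowledge.

## Biophysical model

**Morphologies.** The reference model is a ball-and-stick neuron: a
spherical soma (16 um diameter), a 1 mm cylindrical dendrite (2 um
diameter) and a 1 mm axon (1 um diameter). A contiguous 30 um span of the
axon starting `d_ais` um from the soma surface is tagged as the AIS;
`d_ais` varies over 5–40 um. Moving the AIS relabels a sub-span of the
axon — total cable length and diameters never change. A procedural
generator (`build_synthetic_detailed()`) produces branched "detailed"
morphologies (>= 5 dendritic branches, a 5 um tapering hillock, a 30 um
AIS, a straight 500 um axon at a configurable orientation, default
-115.6 degrees) as a stand-in for reconstructed neurons; it is
deterministic given its seed. SWC import/export is provided, with radius
repair (interpolation of radii <= 0.1 um, 15-sample moving-average
smoothing per path) for raw reconstructions.

**Channels.** Densities (pS/um^2): soma g_Na = 50, g_K = 100, g_Kv7 = 1;
AIS g_Na = 7000, g_K = 2000, g_Kv7 = 7; dendrite g_Na = 20, g_K = 0.3,
g_Kv7 = 1. The AIS is therefore 140x more Na-dense than the soma, which
makes it the spike initiation site. Reversals: E_Na = 55 mV,
E_K = -98 mV. The distal (non-AIS) axon's densities are not constrained
by the reference density table; we assume a moderately excitable
unmyelinated axon (g_Na = 300, g_K = 100, g_Kv7 = 1), and the hillock
uses somatic densities. Kinetics are Traub–Miles-type rat cortical rate
functions (threshold parameter vT = -55 mV) for transient Na (m^3 h) and
delayed-rectifier K (n^4), plus a first-order M-type Kv7 gate; the exact
rate functions are documented in `src/cable_solver.cpp`. We chose this
standard cortical set over squid-type HH rates deliberately: with the
20 ms step stimulus used here, squid-type inactivation
(h_inf(-55 mV) ~ 0.26) silences the somatic AP before the first spike,
whereas cortical kinetics yield the expected overshooting somatic AP with
the characteristic onset kink. Rates are Q10 = 3 temperature-scaled;
default temperature 34 degC (heated culture preparations). Passive
parameters are standard cortical values: Ra = 150 Ohm cm,
cm = 1 uF/cm^2, g_leak = 1/30000 S/cm^2 (30 ms membrane time constant),
E_leak = -80 mV. All of celsius/Ra/cm/leak are declared assumptions — the
quantitative claims the package tests are ratios and recoveries, which are
robust to them.

**Solver.** The cable equation on the section tree is integrated by
backward Euler with the Hines ordering (exact O(n) tree solve per step);
gates advance by exponential relaxation to their steady state before each
voltage solve (staggered scheme). dt = 2^-5 ms (32 kHz sampling; output is
not resampled), 30 ms per simulation. Spatial discretization is <= 2.5 um
on the hillock, AIS and proximal axon (so 1–2 um AIS steps are
resolvable), 10–25 um on the distal axon and 25 um on dendrites. The soma
is a single equivalent-area spherical compartment. Per-compartment
transmembrane current is computed as the net axial inflow, which accounts
the electrode current at the injected compartment: the total over the
closed cell is exactly zero at every step (asserted to 1e-10 in the
tests).

**Stimulus.** A somatic current step (duration 20 ms, onset 2 ms). The
amplitude is 1.5x rheobase, found by bisection within 0.3–2 nA to
0.05 nA tolerance; a "spike" is a 0 mV crossing during the stimulus
followed by repolarization below -30 mV within 3 ms (a passive membrane
charged past 0 mV by a strong step is not flagged). Models that stay
subthreshold at 2 nA are flagged in metadata rather than raising.

## Probe and forward model

The default probe is a 30 x 30 electrode grid at 17.5 um pitch
(9.3 x 5.45 um electrodes), with the central 12 x 12 block designated for
in-depth analysis. Electrodes are treated as points at their centers
(pitch >> electrode size). Extracellular potentials use the standard
homogeneous volume-conductor forward model with conductivity
sigma = 0.3 S/m: the analytic line-source integral for cylindrical
compartments and a point source for the soma, with the radial distance
clamped at the compartment radius.

The neurite plane sits `z_height` above the electrode plane. We default
to 2.5 um: adherent neurites in 2D cultures lie within a few micrometers
of the substrate, and this height reproduces the ~100 uV footprint trough
amplitudes typical of HD-MEA recordings of such cultures (a 10 um height,
plausible for the soma center but not for the axon, attenuates the
footprint several-fold below that scale). The soma's effective distance
is still bounded below by its 8 um radius through the clamp.

## Simulation grid

Footprint features are sensitive to the sub-pitch alignment of the neuron
to the lattice, so each AIS position is simulated at 4 soma offsets —
(0,0), (8.75,0), (0,8.75), (8.75,8.75) um, i.e. half-pitch jitter — and
the neuron is rotated fully around the vertical axis through the soma.
Full grids: 1 degree rotations and 1 um AIS steps over 5–40 um for the
ball-and-stick model (1,440 placements per AIS position, 36 positions);
5 degree rotations and 2 um steps over 5–39 um for detailed models (288
per position, 18 positions). A first-class *reduced* grid (15 degree
rotations, 5 um AIS steps, 2 offsets) sizes the whole pipeline for a
single CPU; the tests and the acceptance script run at this scale, and
the full grid remains configuration-only. Because rigid placement does
not enter the cable equations, the family runner solves the cable model
once per AIS position and recomputes only the extracellular projection
per placement — an exact optimization.

## Footprints, features, and the labeled dataset

A footprint cutout is anchored at the electrode with the earliest trough
below the detection floor (-30 uV default): 96 samples (3 ms) for the
ball-and-stick profile, 177 samples (ca. 5.5 ms) for detailed profiles,
with one third of the window before the anchor (the split is a package
choice; it is constant per profile). The same indices apply to every
electrode. The 26 electrodes with the largest trough amplitudes are
selected and then ordered by trough latency (ties: deeper trough, then
lower electrode id), so electrodes near the AIS come first and ranks
correspond roughly across footprints. Per electrode we extract: trough
amplitude (relative to the mean of the first 10 cutout samples), latency
to the footprint's earliest trough, half-width at half trough amplitude,
peak-to-peak amplitude, and the waveform slopes at the two half-amplitude
crossings. Waveforms that never recross half amplitude get the window
length as half-width and a flag.

For each (offset, rotation) group, the feature vectors of every AIS
position are differenced electrode-id-wise against the 5 um baseline,
giving *valid* Δ-vectors labeled with the relocation magnitude
(d_ais - 5). *Sham* vectors permute the 26 electrode slots of each
comparison feature independently per feature (seeded; identity
permutations are redrawn) before subtraction — physiologically
implausible footprint transformations labeled invalid. The sham:valid
ratio is exactly enforced (default 1, so detector chance level is 0.5).
Placements without any suprathreshold trough are dropped and recorded, as
an experimental pipeline drops undetected units; at the reduced grid this
affects 2 of 384 placements (the most distal AIS at unfavorable lattice
alignments).

## Detection and magnitude regression

**NCA feature selection.** Diagonal neighborhood components analysis:
maximize the expected leave-one-out stochastic nearest-neighbor accuracy
`(1/n) sum_i sum_{j in class(i)} p_ij - lambda sum_l w_l^2` with
`p_ij ∝ exp(-d_ij / sigma)` and the weighted-L1 distance
`d_ij = sum_l w_l^2 |x_il - x_jl|` over standardized features
(lambda = 3e-5, sigma = 1). The squared-weight parameterization makes
updates multiplicative, so irrelevant weights decay geometrically;
optimization is seeded minibatch gradient ascent with nonnegativity
clipping. Features with weight below 10% of the maximum are discarded.
On clean, noiseless Δ-vectors most features carry signal and may all
survive; the selected count is data-dependent and not a target.

**Detector.** A random forest (100 trees, sqrt(p) features per split) on
the NCA-selected features. Rows split 60/20/20 into train/validation/
hold-out; the confusion matrix, TPR and FPR are reported on the hold-out
only. A 5-fold cross-validation mode serves small (detailed-profile)
datasets.

**Magnitude regressor.** A wide neural network — one hidden layer of 100
ReLU units, linear output — on the full Δ-amplitude vector of valid rows
(no NCA), trained with Adam on minibatches, early-stopped on the 20%
validation split (best-weights restore, patience 30, <= 500 epochs),
inputs and target standardized internally. Hold-out R^2 and RMSE are
reported. Fewer than 50 training rows is an error; a constant target is
flagged degenerate.

Label-permutation controls (both models collapse to chance under permuted
labels) are part of the test suite.

## The kernel-library method

Each electrode of a footprint pair is modeled as a linear time-invariant
filter: the relocated waveform is the baseline waveform convolved with a
finite impulse response, `y[n] = (h * x)[n]`, estimated with an N x L
Toeplitz convolution matrix `X` (L = 25, N >= L) by least squares
(`qr.solve`); if cond(X'X) exceeds 1e8 the ridge pseudoinverse
`(X'X + 0.01 I)^-1 X'y` is used instead (the condition-number threshold
is a declared package choice). Fit quality is the
range-normalized RMS error
`E = sqrt(mean((yhat - y)^2)) / (max(yhat) - min(yhat))`; a flat estimate
returns a flagged NA.

A kernel library is compiled from the ball-and-stick family: one kernel
per selected electrode (M = 26), AIS position and rotation, always fit
against the 5 um baseline of the same (offset, rotation) group; kernels
are stored per offset and queries average errors over offsets (an
offset-min mode exists for offset-matched self-consistency checks).

To estimate an unknown neuron's AIS position from a (baseline, relocated)
footprint pair, each target electrode is matched, per candidate AIS
position and per library entry, to the library electrode whose kernel
predicts its relocated waveform with the lowest E; matched errors are
averaged over the M electrodes, aggregated over offsets, and minimized
over rotation angles, giving an error curve over candidate positions. A
cubic polynomial is fit to the curve by ordinary least squares and the
estimate is the fit's minimizing position (closed-form root of the
derivative), clamped to the tested interval; a curve without an interior
minimum returns the boundary estimate with a `non_convex` flag.

**Rank-windowed matching.** At reduced library resolution (15 degrees /
5 um instead of 1 degree / 1 um) the unrestricted electrode search is
degenerate in both directions: the diverse kernel dictionary at distal
positions can absorb any target (estimates saturate at the far boundary),
while freezing one global match per electrode over-penalizes off-grid
targets (estimates collapse to the baseline end). Because both footprints
order electrodes by latency, ranks correspond approximately across
morphologies, and the default search is restricted to library electrodes
within +/-5 latency ranks of the target electrode. This recovers AIS
positions with ~2 um mean absolute error on cross-morphology sweeps at
desk scale. `rank_window = Inf` restores the unrestricted search, and
`match_electrode()` always performs the exhaustive scan.

## What the generator emulates — and what it does not

The synthetic data reproduce the study conditions: noiseless forward
simulations of single neurons at known placements, with footprint
variability arising only from AIS position, rotation and sub-pitch
offset. Real recordings add electrode and biological noise, spike-sorting
errors, overlapping units, electrode-size averaging, tissue
inhomogeneity, drift that is not a pure rigid transform, and morphologies
richer than the procedural trees here. Passing tests therefore
demonstrate the internal consistency and recoverability of the method
under its own model class, not field performance on real data. The
detector's shams bound natural variability from above by construction
(shuffled footprints span a superset of plausible configurations), which
is the intended direction of conservatism.

## Problem sizes and numerical choices in the shipped tests

The test-suite and acceptance runs use the reduced grid: 24 angles x 8
AIS positions x 2 offsets (384 placements; 382 usable), a balanced
dataset of 764 Δ/sham vectors with 156 features, a kernel library of 26
electrodes x 8 positions x 24 angles x 2 offsets, and a cross-morphology
recovery sweep over 5 true positions at one orientation. These sizes are
the package's chosen desk-scale defaults; the full-scale grids
(51,840 and 5,184 placements) are enumerated and validated by counting,
and are reachable through configuration alone.

Other numerics: rotation is an exact rigid transform (group property
tested to 1e-9); the moving-average smoother truncates its window at path
edges; latency ties break deterministically; zero baselines raise a
singular-input error in kernel estimation; sham permutation redraws
identity permutations; all stochastic stages consume explicit seeds, and
re-running any stage with the same seeds is byte-identical.

## Known limitations

Channel kinetics are a documented standard cortical set applied at the
density table above, not axon-specific kinetics fit to nodal/AIS
recordings; absolute voltages, rheobases and dV/dt values are therefore
kinetics-dependent, and only ratio and ordering claims are asserted. Myelin, axon-carrying dendrites,
multiple AISs, AIS length/density plasticity, synaptic input, electrode
filtering and noise are out of scope (extension points exist in the
kernel parameterization). The procedural detailed morphology is a
stand-in, not a reconstruction; the shipped analyses use one canonical
instance (generator seed 1) as a fixed study neuron, in the same way
reconstructed target morphologies are fixed. Recovery quality varies
across random morphologies: in a ten-seed scan of the generator, nine
trees recovered AIS positions with 1.8–3.5 um mean absolute error at
desk scale while one outlier reached ~8 um, so per-neuron validation
remains necessary before applying the reduced-resolution library to
unfamiliar morphologies.
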