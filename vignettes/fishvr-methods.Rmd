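---
title: "Methods: virtual-reality avoidance learning, neural ensembles and prediction-error plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-reality avoidance learning, neural ensembles and prediction-error plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishvr)
```

This vignette is the package's own account of its models and numerical
choices. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The task and its synthetic stand-in

A tethered fish swims along a one-dimensional virtual corridor. Tail-beat
frequency times a gain (10 in closed loop, 0 in open loop) gives the forward
speed, and motion is forward-only. GO trials (blue near side, red goal)
require an escape to the goal within the 10 s limit; NOGO trials (red near
side) require stillness; failures end in a shock. A training session has 60
trials in three blocks of 20, each block holding ten GO and ten NOGO trials
in random order, 15 s apart. We precede it with a 20-trial adaptation
session without shocks and follow it with a 20-trial open-loop session
(gain 0), because the ensemble classifier needs all three epochs.

The synthetic fish (`simulate_agent_behavior()`) is deliberately scripted,
not a behavioral model: `naive` never beats its tail, `learner` expresses
the learned policy after a configurable number of training trials, and
`learner_with_halts` additionally pauses mid-escape, emulating the halting
phenotype. Learned GO trials fail deterministically at a 1-in-10 cadence
rather than by coin flip so that failed post-learning GO trials — which the
SFPE signature needs — are guaranteed to exist in every session. Spontaneous
short bouts (probability 0.2 per unlearned trial) keep pre-learning behavior
from being perfectly still. Track geometry is configuration: the start
region is 60 distance units long, so a learner at gain 10 beating at
~2.5 Hz reaches the goal in ~3 s, within the range real learners show.
These choices emulate trial structure, closed-loop feedback and halting;
they do not emulate tail biomechanics, latency distributions, or inter-fish
variability of learning speed, so passing tests say nothing about those
aspects of real data.

Neural traces are built from each ensemble's binary drive (its activation
signature evaluated on the behavior), passed through a single-exponential
calcium kernel with τ = 1.5 s — plausible for the G-CaMP7 indicator and
slow enough to give trial-resolved peaks at the ~3 Hz effective sampling of
three-plane imaging — scaled by per-neuron weights in [0.7, 1.3], plus
Gaussian noise (default sd 0.1 ΔF/F₀). Member neurons are placed around
their ensemble's spatial center (sd 15 µm), non-members uniformly over the
384.9 µm field, which is what makes the correlation-versus-distance analysis
meaningful. Ensemble amplitudes are free parameters, not calibrated to any
recording.

## Imaging

Registration measures integer-pixel displacements at the peak of the
frequency-domain cross-correlation; there is no subpixel refinement because
the downstream pipeline is pixel-based. The reference is built in two
passes: shifts of all frames against the global mean, then the 1000 (or all,
if fewer) least-displaced frames are aligned by their measured shifts and
averaged. Vacated margins after translation are filled with the frame
median; filling with zeros would create artificial near-constant edge
pixels whose (max − median)/(MAD + ε) score explodes and would dominate the
peaky-ness threshold.

Peaky-ness is scored per pixel as (max − median)/(MAD + ε). The exact
historical formulation behind this score is not fixed by its description,
so the package uses this scale-free transient detector and exposes it; the
seeding threshold is the mean score over all pixels. ROI growth joins the
4-connected neighborhood pixels of each seed whose temporal correlation with
the seed reaches the threshold (default 0.5, configurable — the value used
on the real recordings was set empirically and is not published), within a
51 × 51 window. Overlapping ROIs keep the larger area, ties keep the
earlier (higher peaky-ness) seed, and ROIs below 4 pixels are discarded as
single-pixel noise seeds. A practical note: a seed's connected component
extends beyond the seed only if one of its four direct neighbors passes the
correlation threshold, so the detector tests those four pixels before
computing the full window — an exact shortcut that dominates the running
time on noise seeds.

The median filter (radius 2) is delegated to `EBImage::medianFilter`, which
quantizes intensities on a 2¹⁶-level grid over the movie range (~1e-5
relative error). 512×512 movies are downsized to 256×256 by 2×2 block
averaging. ΔF/F₀ uses the session-mean baseline, so each neuron's ΔF/F₀ has
exactly zero temporal mean; neurons with non-positive baselines are dropped
with a warning. Plane-interleaved sampling (one value per cell every three
microscope frames) is filled by cubic splines onto the common frame grid.

## Template matching and NMF

Templates are the element-wise mean of the first 2 s of every successful
trial of a type after the learning criterion; similarity is the Pearson
correlation between the vectorized template and each 2-s sliding window
(zero-variance windows score 0), clamped to [−1, 1] against floating-point
overshoot. Pearson correlation is used because the similarity index is
interpreted on a −1/0/+1 scale; a dot-product variant would not be bounded.

NMF minimizes ‖D − PT‖² by Lee–Seung multiplicative updates (a
gradient-descent family) with five independent random restarts and up to
4000 iterations per attempt as `nmf_factorize()` defaults; the error is
checked every 10 iterations and iteration stops when its relative change
falls below 10⁻⁶. Negative ΔF/F₀ values are clipped to zero before
factorization, as non-negativity is what gives the parts-based
decomposition. Model order uses the Gaussian-residual form
`AIC(k) = N ln(Error/N) + 2k(n + t)`, N = n·t. The order scan
(`select_order_aic()`) defaults to lighter settings (3 restarts, 600
iterations, tol 10⁻⁵) because order selection needs the error's magnitude,
not a polished optimum; both tolerances are arguments.

## Ensemble identification

Candidates are NMF activation rows whose Pearson correlation with the
environment regressors B(t) or R(t) (indicator of the fish being in blue /
red) is strictly greater than 0.25. Candidates are then classified from
per-trial peak statistics of the self-maximum-normalized activation,
evaluated in epochs: adaptation, first ten training trials, post-criterion
successful/failed closed-loop GO, post-criterion NOGO, and open-loop GO.
"Active" means the epoch mean exceeds 0.3 (normalized units); rule and SFPE
labels must additionally exceed 3× their adaptation baseline (floored at
0.05), and every label must be color-specific: the defining color's epoch
mean must exceed 2× the opposite clean-color epoch mean. The specificity
contrast uses the NOGO start-color windows because calcium decay after a
blue period bleeds into the post-goal red window. The decision order is:
blue-active in adaptation and after learning → blue perception; silent in
adaptation, active in open-loop GO and failed GO but not successful GO →
SFPE; silent in adaptation, active in successful post-criterion GO → "blue
is dangerous"; red-dominant, silent in adaptation, active in red after
training (including after goal arrival) → "red is safe"; anything else is
abandoned. These rules are a reconstruction of the reported signatures, not
a verbatim copy of an unpublished flow chart, and all thresholds are
exposed.

The color-specificity requirement is not cosmetic: the pairwise-swap
shuffle (two random time points swapped per neuron, repeated n = timeline
length times) leaves an untouched fraction of about e⁻² ≈ 13.5% of time
points, and because those residues carry the same coherent signal in every
member neuron, NMF pools them into a weak but real component whose
correlation with B(t) can graze the 0.25 threshold. Such components are
active everywhere, fail the specificity test, and are abandoned — which is
exactly the role the abandonment step plays in the original selection
procedure. The shuffle control runs three independently shuffled sets, each
with its own AIC order selection (scanning k = 2…4; shuffled data never
supports more).

## Spatial and resampling statistics

The ten most-contributing neurons per ensemble (ties broken by neuron
index) give 45 pairs of trace correlation versus Euclidean centroid
distance, averaged in 37.6 µm bins; the null curve redraws ten random
neurons, permutes their positions, and averages ten repeats. The
permutation test fixes the group sizes (9 fish with an SFPE ensemble, 19
without), recomputes the mean difference over 1000 random regroupings and
reports the one-sided p for the SFPE group halting *less* — the direction
of the scientific claim; the raw subtraction order in the original
description is ambiguous about sign handling, so `alternative` and the +1
finite-sample correction ((#extreme + 1)/(n + 1), which avoids p = 0) are
arguments, with raw-fraction behavior available.

## The plasticity simulator

Per step, `x_SF(t) = sig(W·x_BP(t − t_l) − h)` and the swim decision is
Bernoulli with probability `x_SF(t − t_l)`; x_BP history before the trial
is zero (white inter-trial interval), so the first 2·t_l = 20 steps of
every trial run at the naive rate sig(−2.4) ≈ 0.083 for both agents. The
scenery-flow prediction is `x_SFP(t) = sig(U·x_BP(t) − h′)`, the flow
prediction error `x_SFPE = ReLU(x_SFP − x_BF)` with x_BF = 1 on closed-loop
swim steps, and, when enabled, W gains η_SFPE·x_SFPE at every step. At
trial end `x_RP = sig(V·x_BP(t_init) − h″)`, `x_RPE = ReLU(x_RP − p)` with
punishment p = 1 on failure: the RPE update (ΔW = η_RPE·x_RPE,
ΔU = η′·x_RPE, ΔV = −η″·x_RPE) therefore fires only on success and is
evaluated once per trial — the error is defined by whether the expected
punishment was avoided; a per-step variant would collapse V within a single
trial. Constants: h = 2.4, t_l = 10, η_RPE = 0.2, η_SFPE = 0.002, h′ = 6,
η′ = 1.6, h″ = 4, η″ = 1.6, W = U = 0, V = 8, 100 steps per trial; the
sigmoid is the logistic function.

Task geometry is not fixed by the published constants, so it is a design
choice: a swim step advances 4 distance units and the goal sits 30 units
ahead (both arguments). The product matters: with ~8 swims needed, a naive
agent reaches the goal by chance often enough for the RPE rule — which
cannot learn from failures — to bootstrap, while halting in blue remains a
meaningful readout. With one unit per swim no agent would ever experience a
first success (P(Bin(100, 0.083) ≥ 30) ≈ 10⁻¹⁰); with very large steps the
trial ends almost immediately and the halt contrast between agents
degenerates. Trials end at goal arrival or step 100, and the halt count is
the number of stop decisions taken while still in blue. The qualitative
contrast — the RPE-only agent's V depresses until its RPE extinguishes,
freezing W at a level that leaves persistent halts, while the SFPE agent
keeps potentiating W whenever it halts in blue — holds for goal distances
20–40, which the acceptance suite sweeps.

## Problem sizes and determinism

Desk-scale defaults keep the full pipeline and its tests tractable:
synthetic sessions use 60 neurons (the generator default is 300, the order
of one real imaging plane; the count only scales the NMF rows), 100 trials
at 3 Hz ≈ 7500 frames, ROI fixtures 30 cells on 256×256 × 240 frames, NMF
recovery fixtures 100 × 2000, simulator contrasts 20 seeds × 100 trials.
All randomness flows from one user seed fanned out to named substreams
(`schedule`, `behavior`, `activity`, `nmf`, …), so identical configurations
reproduce byte-identical reports, and every generator restores the caller's
RNG state.

## Known limitations

Registration is rigid and integer-valued; z-drift, non-rigid motion and
neuropil contamination are out of scope. The ROI detector assumes
transient-bearing somata and will merge touching cells whose traces
correlate above the threshold. The ensemble classifier needs all three
epochs (adaptation, training past criterion, open loop); without open-loop
trials the SFPE label is flagged unavailable. The synthetic generator's
ensembles are cleaner than real recordings — membership is disjoint and
drives are binary — so recovery rates on it are upper bounds, and the
shuffle control inherits the generator's high signal-to-noise ratio.
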