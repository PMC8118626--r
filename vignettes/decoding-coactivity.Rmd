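---
title: "Decoding behavior from correlated population activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding behavior from correlated population activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactr)
```

# The question coactr addresses

A population of imaged neurons can carry information about a binary
behavioral variable (say, social interaction versus home-cage exploration)
in two distinct ways: individual neurons can change their **activity levels**
between conditions, or groups of neurons can change their **coactivity** —
becoming coactive in the same frames more often than their rates predict —
while individual rates stay put. Standard ensemble analyses (neurons
up- or down-modulated relative to a shuffle null) see only the first channel.
coactr implements a workflow that measures both and, crucially, separates
them:

1. detect binary activity events from fluorescence traces;
2. decode the behavioral condition with a classifier that *can* exploit
   coactivity;
3. re-test the trained decoder on surrogate rasters that conserve
   condition-specific activity levels while either destroying (swap shuffle)
   or preserving (SHARC) the correlation structure — the accuracy gap is the
   contribution of correlations;
4. corroborate the population-level result at the microstructure level with
   three-neuron coactivity combinations scored against swap-shuffled nulls.

Everything operates on a single container: the **event raster**, a binary
neurons x frames matrix at a fixed frame rate (20 Hz by default). A raster
is equivalently a collection of **blocks of activity** (maximal runs of
consecutive active frames of one neuron); blocks are the unit that the
surrogate generators move. Interval metadata (epochs, bouts) uses 0-based
half-open coordinates, matching the on-disk formats; R-side frame index
vectors are ordinary 1-based column indices.

# Event detection

`detect_events()` turns a surround-corrected dF/F0 trace into a binary row
with a threshold cascade. The trace is first neuropil-corrected (ROI mean
minus surrounding-annulus mean), normalized by F0 = median of the surround
signal, and low-pass filtered with a linear-phase FIR design (normalized
passband edge 0.5, stopband edge 0.65, 1 dB ripple, 25 dB attenuation;
group delay compensated). The noise scale sigma is the SD of the trace over
its least active half, ranking frames by 1-s-smoothed |dF/F0| so that
transients do not inflate it (the estimate is mildly downward-biased by the
selection, which is the point).

A candidate onset is any frame whose max-minus-min rise within the trailing
1-s window reaches 3 sigma; the onset is placed at the window minimum. A
candidate is kept only if the rise reaches 15 sigma within 2 s of onset, the
area under the curve over the event extent is at least 250 sigma-frames,
and the peak crosses 0.0125 dF/F0 absolute (the one deliberately
scale-breaking threshold, guarding against surround-subtraction artifacts).
The neuron is then marked active from onset until the signal drops 30% from
the event peak, capped at 2 s.

Two numerical choices matter in noisy traces. The pre-event baseline is the
*median* of the window preceding the onset, because the onset itself sits at
a window minimum and is biased low. And the search for the return to
baseline (which closes the event extent, defines the peak and the AUC, and
controls the merging of overlapping candidates) starts only at the frame
that achieves the 15-sigma confirmation rise; starting it at the first small
bump lets pre-rise noise close the extent before the transient begins, which
silently swallows real events.

On synthetic traces, performance is scored event-wise: sensitivity is the
fraction of true transients overlapped by a detected event, and specificity
the fraction of detected events that overlap a true transient. Frame-wise
specificity on sparse traces is uninformative (almost every frame is a true
negative), so the event-wise reading is the meaningful one. Detected onsets
can precede the true transient start by up to the 1-s candidate window,
because the onset is the minimum of a noisy window; event matching allows
for this.

# Surrogate rasters

**Swap shuffling** exchanges the neuron identities of randomly paired
blocks, leaving every block's start time and duration untouched. This
conserves, exactly: the number of active neurons in every frame, and the
number of blocks per neuron. Per-neuron *activity levels* (time active) are
conserved only approximately, since block durations vary. Two
implementation rules keep the conservation laws exact: a proposed placement
that would make a neuron active in overlapping frames is rejected and
resampled, and so is a placement *adjacent* to existing activity of the
receiving neuron — adjacency would merge two blocks into one and change the
block count under re-decomposition. With `scope = "epoch"` each epoch's
sub-raster is shuffled independently and reassembled, which preserves
condition-specific activity levels while destroying correlations — the
"rate-only" surrogate of the central comparison.

**SHARC** (shuffling activity to rearrange correlations) also moves blocks,
but steers the reassignment toward a target pairwise correlation matrix
(by default, the source raster's own). After an initial swap shuffle, every
block is revisited `reassignment_passes` (default 5) times. For block *i*,
each already-assigned overlapping block *j* casts a vote over candidate
neurons, weighted by `r_j / (L_i * L_j)` (overlap length over the two block
lengths) times the gap between the target correlations of *j*'s neuron and
the current correlations of the partially rebuilt surrogate; block *i* goes
to the neuron with the largest total vote, ties broken uniformly at random.
Neurons whose occupancy conflicts with the block (overlap or adjacency) are
excluded. Per-neuron activity budgets are enforced through a ledger of net
blocks gained and lost relative to the source raster: a neuron at +4 net
gain cannot receive, and a block whose neuron is at -3 net loss cannot be
given away, so every per-neuron block-count change stays within [-3, +4].
When no overlapping block has been assigned yet (no votes), the receiver is
drawn with probability proportional to `exp(-net_gain / temperature)` —
net donors are the most likely receivers, pulling the budgets back toward
balance, which is the only reading of the fallback rule consistent with its
purpose of matching the originally observed activity levels.

A property worth knowing: SHARC tracks whatever target it is given,
including the *sampling noise* in the correlation matrix of a raster of
genuinely independent neurons. On such a raster the SHARC surrogate's
correlation similarity to the target is far above the swap surrogate's even
though there is no "real" structure — the method reconstructs the matrix it
is aimed at, not the generative truth. The surrogate is still a genuine
rearrangement (cell-level overlap with the source stays at the chance
rate). Interpret SHARC-vs-swap gaps as "what the observed correlation
pattern adds", not "what the true correlations add".

**Circular shuffling** builds the per-neuron null for condition-specific
activity: the neuron's full-session row is rotated by a random offset, the
condition's frames re-extracted, and the observed percent-time-active scored
as a mid-rank percentile of the null (10,000 rotations by default,
implemented via FFT cross-correlation over all rotations and verified
against direct enumeration). Percentiles above the 90th (below the 10th)
label the neuron positively (negatively) modulated. Under a stationary
null, about 10% of neurons land in each tail by construction; ties in the
discrete counts pull the mid-rank percentile slightly toward the center,
so the realized tail fraction sits marginally below the nominal rate.

# The decoder

`build_network()` draws a fixed binary input-connection matrix: 1,000
hidden units, each connected to every neuron independently with probability
`p_connect` (0.3 by default, where accuracy peaks in the connection sweep).
Hidden units are linear pools — no bias, no nonlinearity — and only the
output weights (one per hidden unit, initialized at zero) are trained, with
a logistic output unit and the delta rule
`dw_i = lr * y * (1 - y) * (z - y) * x_i` at learning rate 0.05, 500 passes
over the eligible training frames in fresh random order each pass. Frames
enter training or testing only when labeled and when at least 3 neurons are
active. Train/test partitions are alternating 500-frame blocks laid on the
unfiltered session timeline.

One scaling decision is load-bearing. If `x_i` is the raw summed input, the
first weight update already drives the output pre-activation tens of units
away from zero: the sigmoid saturates, `y(1 - y)` vanishes, and training
freezes at chance — with 1,000 hidden units there is no learning rate that
is simultaneously printed-on-the-page and functional for raw sums. coactr
therefore defines a hidden unit's activity as its summed input divided by
the square root of its connection count (a variance-stabilizing
normalization that makes the drive's scale independent of how many neurons
a unit pools) times a gain (default 1.5) chosen so that a single-frame
update moves the pre-activation by order one. In that regime the stochastic
per-frame updates can latch onto coactivity statistics — distributions that
differ between conditions in shape but not in mean — which is precisely the
regime in which the decoder's characteristic behavior appears: above-chance
accuracy on correlation-coded data where optimal linear classifiers sit at
chance, and parity with linear classifiers on rate-coded data. The trained
decoder is, at test time, a fixed linear score followed by a sigmoid —
`evaluate_classifier()` is checked against an independently coded
closed-form oracle — so everything the training achieved lives in *which*
linear direction the stochastic dynamics found. Outputs of exactly 0.5
(possible when no connected neuron is active) are resolved by a seeded coin
flip.

The linear baselines are an L2-regularized logistic regression with the
penalty chosen by k-fold cross-validation on the training frames (glmnet),
and a linear-kernel SVM (e1071, C = 1). Cross-validating the ridge penalty
matters: unpenalized maximum likelihood on ~100 correlated binary
predictors overfits in a way that *anti-generalizes* slightly on
correlation-coded data, landing visibly below 0.5; the cross-validated
penalty detects that no linear signal generalizes and collapses the model
to chance, which is the behavior one wants from an "optimal linear
classifier" reference.

# Classifier-derived ensembles

After training, hidden units are ranked by output weight: the 25 most
negative form the social units (they push the output toward the condition
labeled 0), the 25 most positive the home-cage units, and the 25 with
weights nearest zero the neutral units (ties broken by unit index; the
group size is configurable). `input_similarity()` correlates the binary
input vectors of every unit pair; units sharing a preference tend to draw
input from the same neurons. `define_ensembles()` scores each neuron by its
connection count into a unit group and keeps the top 20% — the
classifier-derived ensemble, the set of neurons the decoder actually
consults for that condition. `ensemble_condition_stats()` then reports each
ensemble's mean activity and mean within-ensemble pairwise correlation per
condition over matched frame sets; matched set sizes keep the correlation
estimates comparable. The signature dissociation: a rate-coded change moves
the activity but not the correlation; planted coactivity moves the
correlation at fixed activity. Input connections here are features of the
decoder, not claims about anatomical connectivity.

# Three-neuron combinations

`count_triplets()` counts, per frame with k >= 3 active neurons, all
`choose(k, 3)` unordered triplets (sparse hash storage; the dense
n-cube is infeasible and semantically identical). `triplet_enrichment()`
compares each observed triplet's count against its counts in 1,000
whole-session swap-shuffled surrogates — the null that respects both each
neuron's activity budget and the frame-by-frame population rate — and
reports a mid-rank percentile (ties between the real count and surrogate
counts contribute half, the convention that keeps the null calibrated for
discrete counts). Enrichment uses the 95th percentile by default, 99.9 for
a strong criterion. `specificity_and_overlap()` labels triplets
condition-specific (enriched above 95 in one condition, below 50 in the
other), applies a repetition filter (at least 2 distinct bouts, so a single
burst cannot masquerade as behavioral specificity), and tallies, for every
pair of opposite-condition triplets sharing exactly two neurons, whether
the left-out neuron participates in some enriched triplet of the opposite
condition — distinguishing "neurons only active in one condition" from
"neurons active in both but re-partnered".

Because percentiles are computed within condition frame sets from
whole-session surrogates, the default matches an analysis in which
surrogates are generated once over the entire dataset; condition-restricted
surrogates can be had by passing a restricted raster.

# The synthetic two-state generator

The generator exists so that every mechanism above is testable end to end
with known ground truth. A **State A** raster assigns, in each frame,
`round(N * A * (1 + sin(2*pi*f/period)))` uniformly chosen distinct neurons
(N = 100 neurons, A = 5% mean activity, 6,000 frames per state by default),
i.e. a population rate oscillating around its mean — the global rate
confound that enrichment and decoding analyses must survive. The default
period is 100 frames (5 s at 20 Hz): a slow fluctuation that is still short
relative to the 500-frame train/test blocks, so every block samples all
phases. A period that is an integer multiple of twice the block length
would instead put training and testing on systematically different phases
of the rate cycle — a pure partition confound — which is why the period is
deliberately not set near 1,000 frames.

**Correlation-coded State B** plants 1-5 disjoint 8-neuron assemblies into
a copy of State A: whenever an assembly's first neuron is active, other
members are made coactive through reciprocal swaps (a non-assembly neuron
active in that frame donates its slot; the member repays it in another
frame where the member is active and the donor silent); in frames with
fewer active neurons than the assembly size, a random subset of the
assembly is coactivated. Both marginals are conserved *exactly*: State B
differs from State A only in its correlation structure. Donors are
preferentially drawn from neurons outside every assembly so that later
assemblies do not cannibalize earlier ones.

**Rate-coded State B** transfers, for each donor neuron i in the first half
paired with recipient i + N/2, a uniformly drawn proportion (up to
`modulation_bound`, default 0.5) of the donor's blocks to the recipient at
the same frames — column sums conserved, individual rates shifted in
opposite directions in the two halves.

What the generator does *not* emulate: calcium indicator kinetics beyond a
rise-plus-exponential-decay transient template, sequential or
history-dependent structure, behavioral covariates (motion, arousal), and
assemblies with graded or overlapping membership. Tests passing on these
fixtures demonstrate that the machinery measures what it claims to measure
under known ground truth — not that real cortical data satisfy the
generative assumptions.

# Reproducibility and problem sizes

Every stochastic routine routes through R's RNG (including the compiled
kernels), so a single `set.seed()` — or the `seed` field of an
`experiment_config()` — makes runs bit-reproducible; `run_experiment()`
derives per-run seeds from the master seed and identical configs produce
byte-identical serialized bundles. The test suite and the acceptance script
run the study conditions at the generator's defaults (100 x 6,000 per
state, 1,000 hidden units, 500 passes, 1,000 surrogates where surrogate
counts matter), with ten independent runs for accuracy summaries; smaller
fixtures appear only in unit tests of exact combinatorial identities, where
problem size is irrelevant to the property under test.

# Known limitations

- The decoder's accuracy on correlation-coded data depends on the
  stochastic training regime; the gain default keeps it there, but extreme
  hyperparameter combinations (very small `p_connect` times very few
  neurons) can re-enter the frozen regime.
- Swap conflict handling (reject-and-resample, bounded retries) can in
  principle leave a block unswapped in pathologically dense rasters; the
  count is reported in the `skipped` attribute and is zero on data in the
  sparse regime this package targets.
- The enrichment null treats frames as exchangeable given block timing;
  strong within-block temporal structure beyond block durations is not
  modeled.
- `circular_null_percentile()` assumes the session is long relative to the
  condition windows; for very short sessions the rotation null is coarse.
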