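---
title: "Methods: a synaptic-pruning spiking network for few-shot digit classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synaptic-pruning spiking network for few-shot digit classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikeprune)
```

## The model

`spikeprune` implements a spiking neural network classifier whose training
mechanism is synaptic pruning rather than gradient descent. Each digit class
gets its own four-stage network — 224 rate-coding inputs, 150 and 50
integrate-and-fire (IF) neurons, and a single IF output neuron — and the
only trainable weights are the 224 x 150 synapses between the first two
layers. After training, weak synapses are deleted, leaving a sparse
"information channel" that responds preferentially to its own class. A test
image is assigned to the class whose network's output neuron fires fastest.

The pipeline, stage by stage:

**Rate coding.** A 28 x 28 image with intensities 0-255 is normalised to
`u = pixel / 255`; values below the retention threshold `theta = 0.4` are
zeroed (weak ink carries no shape information), and the rest become per-bin
spike probabilities `p_max * u` with `p_max = 0.63`. Time is discretised
into 100 bins of 10 ms, so a saturated pixel drives a Bernoulli generator
at 63 Hz. `theta`, `p_max`, the bin width, and the horizon are all
configurable; the defaults are the values above.

**Half-plane regions.** The canvas is bisected four ways (horizontal,
vertical, two diagonals). Each of the eight resulting half-planes is sliced
into 28 strips parallel to its cutting line, giving 8 x 28 = 224 pixel-sets;
each set's generators feed one first-layer neuron whose input current per
bin is the set's spike count. Strips aligned with a stroke collect many
correlated bright pixels and fire near every bin, while strips crossing a
stroke catch only its thickness — this alignment sensitivity is what makes
the region code a line-and-arc feature detector. Two choices here are ours
because the geometry underdetermines them: a pixel lying exactly on a
cutting diagonal joins the upper half of that cut (assignments must be total
and deterministic), and a pixel shared by several regions is re-sampled
independently in each (sharing one train would correlate regions for no
modelling gain). Empty clipped strips are kept so that every region
contributes exactly 28 neurons and the 224-count is invariant.

**IF dynamics.** Discrete Euler updates
`V' = V + (dt/tau) ((E_L - V) + I)` with a spike and reset to `V_reset`
when `V' > V_th` (strict; ties do not fire). The defaults are honeybee
olfactory constants: `tau = 0.01 s`, `E_L = V_reset = -0.065 V`,
`V_th = -0.01 V`, `V_0 = -0.03 V`, `dt = 0.01 s`. The drive `I` is the raw
weighted spike count added inside the leak parenthesis, without unit
conversion — the model's arithmetic is reproduced as specified, not
re-dimensioned. Because `dt = tau`, the update is memoryless: a neuron
fires in a bin exactly when `I > V_th - E_L = 0.055`, a closed form the
test suite holds the simulator to. Voltages restart at `V_0` for every
sample presentation; no refractory period is modelled. The output neuron
uses the same constants with its own threshold (default `0.01`, sweepable
over -0.03..0.03).

**Learning rule.** After each time window (default: four windows ending at
250/500/750/1000 ms) every synapse `(i, j)` is updated from the difference
of window-mean rates `Delta = f_i - f_j` through the odd sigmoid
`g(Delta) = (1 - e^-Delta) / (1 + e^-Delta) = tanh(Delta/2)`:
potentiation `alpha * g(Delta)` when the presynaptic neuron out-fires the
postsynaptic one, depression `beta * g(Delta)` otherwise, and no change at
`Delta = 0` (the continuous limit of both branches). Defaults
`alpha = 0.2`, `beta = 0.6`. Rates are window-local, not cumulative —
"update at the end of each interval" reads as interval-local — and later
windows of the same presentation already use the updated weights. Weights
are clipped to `[0, 1]`: initial weights are uniform on that interval and
the pruning threshold lives on it, so unbounded growth would make the
threshold meaningless. After all presentations the matrix is pruned once at
`mu = 0.8` (pruning per window would interact with the window count, and
the procedure specifies deletion at the end of training). Trained channels
are frozen; evaluation never updates or deletes synapses.

**Feedback inhibition.** The first layer carries an activity-dependent
suppression: each spike in a bin is deleted with probability
`P = exp(-phi * C)`, where `C` is the layer's mean activity and `phi` is
the inhibition parameter (smaller `phi` = stronger inhibition; `phi = 0`
silences the layer, `phi -> Inf` passes everything). Two readings were
open. First, `C` ("average activity at time t") is taken as the
instantaneous fraction of neurons spiking in the current bin, computed
before suppression — a running average would make the suppression depend on
presentation length. Second, inhibition is drawn only on the first layer,
where the architecture places the inhibitory neuron.

**Where inhibition acts.** We apply inhibition in the readout forward pass
but not during training, and this is the package's most consequential
design decision, so the reasoning is spelled out. At readout the converging
pathway is an OR-chain: with `dt = tau`, any single spike through a weight
above 0.055 fires the next neuron, so with full first-layer drive the
output neuron of *every* network saturates at one spike per bin and the
argmax is meaningless. Inhibition thins first-layer activity so that
downstream rates stay graded and proportional to how many of a channel's
surviving synapses the image actually drives — it "prevents over-firing"
exactly as the architecture intends, and the default `phi = 0.1` (the
reported optimum) corresponds to strong thinning. During training the
opposite holds: the learning signal is the *difference* between first- and
second-layer rates, and the second layer saturates whenever any
super-threshold weight remains. Suppressing the first layer while the
second still fires drives `Delta` negative for every synapse — aligned
strips included — so the whole matrix is uniformly depressed below the
pruning threshold and every channel comes out empty. Training therefore
presents samples at full drive, where aligned strips hold `f_i = f_j = 1`
(their synapses are left at their initial values and survive pruning when
they started above `mu`) while crossing and inactive strips are depressed
away. The inhibition flag and `phi` remain configurable for studying the
suppression itself.

**Classification.** One network per class; a test image is encoded once
(one shared raster across the ensemble, so networks are compared on the
same evidence; per-network seeds cover only network-side draws) and the
class with the maximum output rate wins. Exact ties are broken toward the
lowest class label and flagged, so downstream analysis can excise them.
Overall accuracy is the unweighted mean of per-class accuracies, matching
the per-class framing of the accuracy definition; the micro-average is also
reported. Activity distances use the root-mean-square element-wise
difference so that distance and similarity `S = 1 - d` both live on
`[0, 1]` for any vector length; the raw Euclidean distance is exposed
alongside for unnormalised plots.

## The synthetic stroke-digit generator

The generator exists so that the full pipeline can be exercised and tested
without downloading handwritten data. Glyphs are line segments and circle
arcs on a normalised canvas — the premise that written digits decompose
into lines and circles, made literal — rasterised at 28 x 28 with a
one-pixel soft edge, then jittered: whole-glyph translation (default
+/- 1 px), stroke thickness (3 +/- 0.5 px, matching the few-pixel strokes of
handwritten digits on this canvas), Gaussian intensity noise (s.d. 15 on
the 0-255 scale, small enough that ink stays above the retention
threshold), and pixel dropout (2%). The built-in ten-glyph library shares
primitives between visually confusable digits (0/6 share the circle, 3/8
the right-hand arcs) so that the hard pairs of handwritten data have hard
synthetic counterparts.

What the generator does *not* emulate: curvature and slant variation,
stroke-width variation along a stroke, elastic deformation, and the heavy
tails of real handwriting. Passing tests on synthetic data therefore
demonstrate that the mechanism recovers class structure when classes are
separable in strip space — they do not certify handwritten-digit accuracy.
The IDX reader exists precisely so the identical pipeline can be pointed at
the real dataset when it is available.

Tests that need *well-separated* classes use three parallel horizontal bars
at distinct heights: their aligned strips are disjoint by construction, the
cleanest realisation of "separated" in this architecture's feature space.

## Numerical and procedural choices

- `g(Delta)` is evaluated via the exponential form, branch-split by sign to
  avoid overflow for large `|Delta|`; tests pin it to `tanh(Delta/2)` at
  `1e-12`.
- The gain's `beta` accepts values up to 2 (the studied sweep range) even
  though the printed constraint is `[0, 1]`.
- Membrane reset happens on the pre-inhibition spike: inhibition deletes
  the transmitted spike, not the neuron's own reset.
- All randomness flows from one root seed through a Lehmer-style
  `split_seed(seed, index)`, with disjoint index spaces per purpose
  (encoding, networks, inhibition, sweeps), so every result row and every
  channel is replayable in isolation; per-network classification seeds are
  keyed to class rank, not storage order, making predictions invariant to
  reordering the ensemble.
- Epochs re-encode raw images into fresh spike trains per presentation;
  pre-encoded samples are re-presented with their fixed raster.
- Connectivity masks are i.i.d. Bernoulli per edge ("mean connection per
  neuron"); exact-degree sampling is available as an option.

## Problem sizes in the test suite

The suite exercises the recovery properties at sizes chosen to give clear
Monte-Carlo margins: 1,000 generators for the 63 Hz encoding check, 10,000
currents for the closed-form spike rule, three classes at 10 training and
100 test samples per class for discrimination and above-chance recovery,
and 20 replicates of the 1-vs-20 training-size comparison. Sweep unit
tests run on two-class bar datasets of a few samples, which already
exercise every code path.

## Known limitations

- With `dt = tau` the neuron is a per-bin threshold gate; the simulator
  supports `dt != tau` (and the reference tests cover it), but the default
  operating point has no temporal integration memory.
- Channel formation relies on initial weights above `mu` being frozen at
  saturated strips; with very long training schedules, slow depression of
  almost-saturated strips (window rate just below 1) erodes channels. The
  window count is part of the study conditions, not a free dial.
- The OR-chain readout compresses rate differences; classes that overlap
  heavily in strip space (e.g. a circle crossed by every column strip)
  separate far less than stroke-disjoint classes, and channel density
  imbalances bias the argmax toward densely-channelled classes.
- Classification of all-silent inputs returns the lowest class with a tie
  flag; callers should treat flagged predictions accordingly.
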