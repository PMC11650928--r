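---
title: "Methods: patch-based shark photo-ID with twin networks and boosted fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based shark photo-ID}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(patchid)
```

This vignette is the package's own account of its model and of the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The verification model

Photo-ID of epaulette sharks is framed as *verification*, not
classification: the model answers "are these two photographs the same
individual?" so new animals can enter a catalogue without retraining. Four
skin regions drive the decision — head, pectoral/gill (pec), dorsal ahead
of the first dorsal fin (FDF), dorsal behind it (FDB) — each annotated as
a rotated box aligned with the vertebral line, with the box x-axis marking
the head direction.

Each patch type has its own twin network. A frozen backbone maps each of
the two patches to a spatial feature map; global average pooling reduces
each map to an F-vector; the two vectors are concatenated (ordered — the
network is deliberately not symmetrized, and the asymmetry is measured in
tests rather than hidden) and passed through a 32-unit ReLU dense layer
and a 1-unit sigmoid. The output is the similarity index $s \in (0,1)$.
Only the head's dense weights train, by binary cross-entropy with
minibatch gradient descent (plain SGD by default; Adam available in
config); the backbone is frozen and audited bit-exactly by checksum.

The four indices are concatenated into $X = (s_{head}, s_{pec}, s_{FDF},
s_{FDB})$ and fused by a gradient-boosted regression-tree ensemble,

$$\mathrm{final\ similarity} = b + \sum_{i=1}^{M} a_i\, T_i(X \mid r_{i-1}),
\qquad r_0 = 0,$$

with base score $b = 0.5$, shrinkage $a_i = 0.1$, depth-3 trees, and $M$
chosen by early stopping on a held-out fifth of the fusion pairs (cap
200). Regression trees can leave the label range, so the raw prediction is
clipped to $[0,1]$. The decision rule is strict: *same* iff the final
index exceeds 0.5.

### Backbone contract

The backbone is a pluggable contract: declared input side, declared input
intensity range, a forward pass, and the feature dimension F. The
reference configuration is EfficientNetB4 (input 380 px, F = 1792); the
package constructs that architecture layer-by-layer from its published
compound-scaling definition (width 1.4, depth 1.8, SE ratio 0.25, width
rounding to multiples of 8 with the 90% floor) and counts 17,673,823
parameters for the feature extractor, including the 7 parameters of the
input normalization layer and 4 per batch-norm channel. Pretrained weights
are an external artifact the package does not download, so the default
*working* backbone is `tiny_backbone()`: a 4-layer stride-2 3×3
convolution stack (channels 3→16→32→64→64, He-initialized from a seed,
frozen), input 64 px, F = 64. It exercises the full twin/fusion contract
in seconds. Random frozen features are far weaker than pretrained ones;
several pipeline defaults below exist specifically to make them workable,
and a green test establishes contract correctness and qualitative
behaviour, not state-of-the-art accuracy.

## The synthetic world

Real labelled photo catalogues of this kind are rarely shareable, so the
generator is a first-class module, not a fixture. It renders each shark as a capsule body with a dark
ocellus landmark behind the pec region (a stable anatomical anchor), an
individually unique set of spots, and four rotated patch boxes at fixed
body-relative positions. Photographic nuisance per shot: free in-plane
view angle (0–360°), gamma 0.8–1.25, blur up to 0.7 px, sensor noise
0.5–2.5%, and a plain/gravel/sand background (removed by the mask).
Baseline replicates of a shark share the same drift time (same-day
photographs); time-series images advance the drift clock, marker $T_k$
sitting at $t = k + 1$ steps after baseline.

Ontogenetic drift is the generator's invented, documented law (no
quantitative model exists in the literature): per time step every spot
center takes an isotropic Gaussian step with per-axis standard deviation
`drift_rate × body_length`, and each spot is independently deleted — and a
new one born elsewhere — with probability `drift_rate`. Stage defaults are
0 (adult), 0.02 (juvenile), 0.08 (neonate): adults are a trivially stable
fixed point, and a neonate loses most pattern correspondence within about
six steps, mirroring the months-scale transformation reported for young
sharks. Spot *count* is drawn once per individual from a species-typical
range (34–42) common to all stages: identity is carried by the spatial
arrangement of spots. (An earlier draft gave each stage its own count
level; that handed the model a stage signature that survives drift and
made drifting neonates spuriously identifiable, so it was removed.)

What the generator does **not** emulate: 3-D pose, water-column optics,
photorealistic skin, partial occlusion, and any drift in spot count.
Because births exactly replace deaths, count is an identity cue that
survives drift; with the narrow common count range its influence is small,
but it is one reason synthetic neonates are sometimes more re-identifiable
than real ones. A green acceptance run therefore establishes that the
pipeline separates stable from drifting patterns under photographic
nuisance — not that real photographs would score at comparable levels.

## Pipeline design choices

**Patch orientation.** The box x-axis points toward the head; the patch
u-axis runs along it, so a zero-angle box covering a subimage reproduces
that subimage exactly, and 90°-multiple extractions are exact pixel
permutations (tested bit-exactly against an independent remap oracle).
Arbitrary angles use bilinear interpolation with out-of-image samples
reading 0.

**Photometric standardization.** Before embedding, every patch is mapped
to mean 0.5 / fixed spread and clipped (`standardize_patch()`). Gamma and
linear-contrast nuisance, which a random frozen backbone cannot absorb,
largely cancels; this serves the stated purpose of augmentation in this
kind of pipeline — learning patterns, not colours.

**Augmentation.** `augment()` implements the full recipe — X/Y flips,
90/180/270° rotations, Gaussian noise and blur, gamma and linear contrast,
in a fixed order with independently drawn parameters, reproducible from a
seed. The *pipeline default* enables only the photometric part. Rationale:
extraction already orientation-normalizes patches along the body axis, so
geometric variation never occurs at inference; and random frozen conv
features are not rotation-invariant, so independently rotated positives
become indistinguishable from negatives in embedding space and head
training collapses (measured directly during development: per-patch
held-out AUC dropped from 0.66–0.88 to 0.50–0.60 with geometric
augmentation on). With a pretrained, augmentation-robust backbone the full
recipe is appropriate; both patches of a pair are always augmented
independently.

**Head training.** Embeddings are standardized per feature (mean/sd over
the training embeddings, with a floor of $10^{-3}$ times the strongest
feature's sd so near-dead random channels cannot explode). Initialization
is difference-oriented: hidden units start as paired $(+r,-r)$ / $(-r,+r)$
projections of the two embeddings, so the head begins as "similar unless
the embeddings differ" and gradient descent refines from there; the
architecture is unchanged and training can leave this structure. Defaults:
50 epochs, learning rate $10^{-3}$, batch 16 for the module API; the
pipeline config uses Adam, 150 epochs, batch 64.

**Fusion fitting.** Boosted trees fitted on the heads' own training pairs
are degenerate: those indices sit at 0/1, any single feature separates
them, and the ensemble collapses to a step function of one patch. The
pipeline therefore reserves one training shark per stage as a fusion
holdout (heads never see them) and fits the ensemble on (a) balanced
augmented baseline pairs of those sharks plus (b) their exhaustive
unaugmented cross-session pairs, so the trees see realistically noisy
indices including drifted positives. Stochastic boosting (row subsample
0.5 per tree) keeps the fitted function from degenerating into a few-step
staircase. With fewer than two holdout sharks the pipeline falls back to
the same-pool fit.

**Evaluation.** Shark-based groups are formed per (shark, session):
the baseline replicates are one group and each time marker is another.
The overall shark-based report includes, per the K1×K2 construction, a
same-shark instance for every group with ≥ 2 images by halving it — these
are same-day comparisons and are what gives shark-based evaluation its
precision advantage. The *per-stage* AUCs, in contrast, use cross-session
group pairs only: re-sighting identifiability is the quantity of interest,
and same-day halves would dilute it. Stages with at least two test sharks
use within-stage pairs only; a single-shark stage (the held-out juvenile
and neonate, under the default 6/3/4 split) takes its negatives from group
pairs involving that shark across stages. Precision with zero positive
predictions is reported as undefined (`NaN` with a flag), not as 0.

**MAE** is computed on binarized decisions, which forces the exact
identity `accuracy + MAE = 1` visible in every report.

**Seeds.** One master seed is split hierarchically (population → shark →
shot → stage-specific streams) through a hash; every artifact is
byte-reproducible from the config, and tests assert byte-identical re-runs.

## Numerical choices and degenerate inputs

* ROC is swept over all distinct thresholds; trapezoid AUC equals pairwise
  concordance with ties counted half (asserted against an $O(n^2)$ oracle).
* Single-class label sets make AUC undefined (`NA` in reports; an error in
  `roc_auc()` itself).
* cos/sin are snapped at multiples of $\pi/2$ so 90° geometry is bit-exact.
* JSON persistence writes doubles with 17 significant digits, which
  round-trips IEEE doubles exactly; model save→load is tested to
  reproduce similarities to $10^{-12}$ and backbone checksums exactly.
* Tree splitting uses midpoint thresholds between distinct sorted values,
  minimum five observations per leaf; degenerate (pure) nodes stop
  splitting.

## Known limitations

* The acceptance-scale backbone is random-frozen; absolute accuracies are
  far below what a pretrained EfficientNetB4 would give on real
  photographs, and per-patch rankings (which patch is "best") carry no
  information about real photographs.
* With the default split the held-out set has 2 adults, 1 juvenile and
  1 neonate; per-stage statistics are high-variance, so the acceptance
  suite averages five consecutive seeded runs rather than trusting one.
* The drift law preserves spot count; real neonates change count as they
  grow.
* The temporal verdict is a threshold rule on group means; no uncertainty
  is attached to it, and no capture–mark–recapture modelling is attempted.
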