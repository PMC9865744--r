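---
title: "Methods: state labeling, CNN classification and layer-wise relevance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state labeling, CNN classification and layer-wise relevance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

conformotif classifies molecular-dynamics (MD) frames of a G-protein-coupled
receptor (GPCR) into three conformational states — active, intermediate,
inactive — with a one-dimensional convolutional network over per-residue
center-of-mass (COM) coordinates, and then explains those predictions at the
level of individual residues and receptor regions with layer-wise relevance
propagation (LRP). This vignette describes the models and procedures, the
parameters that matter, the numerical conventions, and what the synthetic
data used in the tests can and cannot show about real trajectories.

## The classification problem

Each MD frame is reduced to the mass-weighted mean position (COM) of each of
its M residues, giving an M x 3 table per frame. Frames are flattened
residue-major into a length-3M vector (x1, y1, z1, x2, ...), so residue i
always owns features 3i-2..3i; for the 282-residue adrenergic receptor the
input length is 846. Features are min-max normalized per feature, with the
scaler fitted on the training split only and applied unclipped to
validation data. Fitting on the training split is this package's contract
(it is the only leakage-free reading); not clipping keeps held-out inputs a
linear image of the raw coordinates, which matters because the relevance
analysis multiplies by the input activations.

The state label comes from a single geometric criterion: the Euclidean
distance between the alpha-carbon atoms of a configured probe pair of
residues (defaults 131 on helix 3 and 272 on helix 6). A frame is

* **active** when the distance is >= 14 A,
* **inactive** when it is <= 8.5 A,
* **intermediate** otherwise.

Both boundaries are inclusive on their own side, so the three predicates
partition the distance axis and the labels are monotone in the distance.
Because the label criterion uses alpha-carbon atoms while the features use
residue COMs, the distance is computed during ingestion (before atom detail
is discarded) and carried in the canonical COM table. A COM-based distance
is available as a documented, approximate fallback.

State ensembles from activation trajectories are heavily dominated by
intermediate frames, so the dataset stage first randomly undersamples every
class to the minority count and then performs a stratified 70/30
train/validation split. Undersample-then-split is the order that guarantees
exact per-class balance in both subsets. (The canonical per-class split
counts reported for this problem, 1060/550, correspond to a 65.8/34.2
split of 1610; the package honors the stated 70/30 fraction instead of
reverse-engineering that table.) Both operations are pure functions of
their inputs and a seed.

## The network

The classifier is a block-growth 1D-CNN: each block is convolution
(kernel 3, stride 1, no padding) -> ReLU -> max-pool (window 2), with the
filter ladder 64/128/256/512 over four blocks, followed by flatten ->
dense 1024 -> ReLU -> dropout 0.5 -> dense 3. On an 846-long input the
shape recursion is 846 -> 844/422 -> 420/210 -> 208/104 -> 102/51, a
flattened length of 512 x 51 = 26112, and per-layer trainable parameter
counts 256 / 24,704 / 98,560 / 393,728 / 26,739,712 / 3,075 (27,260,035 in
total). `parameter_count()` derives these analytically and the tests
verify they equal the scalars actually allocated. Adding blocks until the
length drops below the kernel is rejected at construction: pooling would
have discarded the remaining signal.

Training follows the reference protocol: softmax cross-entropy, Adam
(learning rate 1e-4, weight decay 1e-5 folded into the gradient),
mini-batches of 1024, 500 epochs, Kaiming-uniform initialisation. We use
the canonical He form of that initialiser — weights uniform on
+/- sqrt(6 / fan_in) (the ReLU-gain bound), biases zero. Dropout is active
only during training (inverted dropout); prediction and relevance recording
always see the deterministic network. Class order is fixed everywhere as
(active, intermediate, inactive); argmax ties break toward the lowest
class index. All randomness — shuffles re-derived each epoch from the
master seed, per-batch dropout masks — is explicit, so training is
reproducible seed-for-seed on a fixed platform (bit-level identity across
BLAS implementations is not promised).

Evaluation reports per-class precision, recall and F1, their unweighted
(macro) mean, accuracy, and the row-normalized confusion matrix. The
implementation is closed-form and cross-checked in the tests against an
independent package.

## Layer-wise relevance propagation

LRP redistributes one output logit backwards through the network. With j,
k indexing units in consecutive layers, a_j the (post-ReLU) activations,
w_jk the weights and z_k = sum_j a_j w_jk + b_k:

* **basic rule (LRP-0)**: R_j = sum_k (a_j w_jk / z_k) R_k
* **epsilon rule**: R_j = sum_k (a_j w_jk / (z_k + eps_k)) R_k

The backward pass is seeded at the output with the raw logit of the
explained class (all other entries zero). Conventions adopted, each chosen
once and tested:

* The bias participates in the denominator but its relevance share is
  absorbed, not propagated; conservation statements are therefore exact
  only for bias-free networks.
* The stabiliser is sign-matched, eps_k = eps * sign(z_k) with
  sign(0) = +1, so it never flips a share's sign; eps defaults to 1e-2 and
  is configurable. No downstream result in this package depends on a
  specific eps.
* Convolution layers propagate exactly as a dense layer on the unrolled
  convolution matrix; the implementation avoids unrolling but is tested
  against an explicit unrolled-matrix oracle.
* Max-pooling redistributes winner-takes-all to the recorded argmax of the
  forward pass, splitting exact ties equally — this conserves relevance
  through pooling by construction.
* ReLU and dropout are identity during propagation (the a_j already are
  rectified outputs).
* An exact zero denominator under the basic rule aborts with a pointer to
  the epsilon rule, except when the incoming relevance is itself zero
  (dead ReLU paths), where the 0/0 share is taken as 0.

Two identities anchor the engine. First, with eps = 0 and zero biases the
total relevance of every layer equals the seeded logit (verified to 1e-9
relative). Second, for bias-free ReLU networks LRP-0 equals gradient x
input elementwise; the tests verify this against an analytic gradient
oracle on randomized networks. For eps > 0 the denominators grow in
magnitude, so relevance is absorbed layer by layer; with all-positive
denominators this absorption is monotone, which is also property-tested.

## Residue and region aggregation

Input-feature relevance is collapsed to residues by summing each residue's
x/y/z shares and dividing by the number of coordinates (three). Per-class
maps average the residue maps of frames that are sampled from 100 randomly
chosen trajectories, keeping an equal number of *correctly predicted*
frames per state (each frame explained with its own true class). The equal
count defaults to the largest available and is capped by configuration;
the cap in the shipped analyses is 30 frames per state, which keeps the
explanation stage around a hundred backward passes.

Key residues ("motifs") are the outliers of a class's relevance
distribution: residues outside [Q1 - f*IQR, Q3 + f*IQR], strict
exceedance, with quartiles computed by linear interpolation
(`stats::quantile` type 7) and the Tukey default f = 1.5. The quartile
convention is fixed so motif sets are reproducible bit-for-bit; f is
exposed and nothing downstream depends on its value.

Region summaries report, per region (helices H1-H7, loops ICL1-3/ECL1-3,
termini), the total relevance of its residues over all selected frames and
the average per residue per frame (total / (residue count x frame count)).
The per-residue-per-frame convention for the average is this package's
documented choice; totals are additive over any refinement of the region
partition, which is property-tested. The bundled 282-residue region map is
a synthetic stand-in (real helix boundaries are not enumerated in the
sources this package follows); it is constrained to place every
residue-region pair used in the reference key-residue tables correctly and
is user-replaceable.

## The synthetic generator

`generate_ensemble()` produces multi-trajectory ensembles with the
statistical structure the pipeline assumes, so that every stage is
testable without external simulation data:

* The probe distance follows a reflected bounded random walk (Gaussian
  steps, mirror reflection at the bounds). The bounds must straddle both
  thresholds or construction fails — otherwise a state would be
  unreachable. A reflected walk was chosen over an Ornstein-Uhlenbeck
  process as the simplest process with controllable dwell times in all
  three distance bands.
* Labels are always produced by `label_state()` on that distance — the
  generator cannot bypass the labeling module.
* Planted residues are displaced by a fixed random unit vector times delta
  per (residue, state), so the state signal lives exactly where the
  featurization looks; every residue also receives isotropic Gaussian
  noise of sd sigma.
* The probe pair carries explicit alpha-carbon positions separated by
  exactly the walk distance, exercising the atom-level labeling path.
* `class_imbalance_preset()` parks the walk mid-band with small steps,
  producing the intermediate-dominated ensembles seen in real activation
  data, to exercise undersampling.

The reference study condition used throughout the tests is M = 60
residues, 200 trajectories x 30 frames, 6 planted residues,
delta/sigma = 5 (0.75 A / 0.15 A), walk step 1.2 A in [5, 18] A. Under
this condition a compact 3-block network (filters 16/32/64, dense head
128 -> 3, batch 256, learning rate 1e-3 — a deliberately reduced
architecture and training budget suited to a 180-feature problem) reaches
validation accuracy above 0.99 within 50 epochs, and the planted residues
dominate the per-class relevance rankings. All sizes were fixed once,
before inspection of results, as what a desk-scale emulation of a
multi-trajectory ensemble reasonably looks like.

What the synthetic data do **not** emulate: physical force fields, solvent,
bonded geometry, autocorrelated residue motion beyond the probe walk, and
cross-residue covariance. Passing the planted-recovery tests shows the
pipeline's plumbing and attributions are sound — that relevance
concentrates on the features that actually carry class information — not
that any particular biological motif claim transfers to real receptors.

## Degenerate inputs and edge conventions

* Constant features min-max-normalize to 0 (no division error); held-out
  values outside the training range are not clipped.
* Pooling drops a trailing remainder shorter than the window (floor
  semantics); pooling and convolution reject inputs shorter than their
  window/kernel.
* Empty trajectories are valid I/O objects (header-only tables); empty
  evaluation sets are errors.
* Coordinates are stored with 6-decimal fixed precision in A, which
  round-trips exactly through the canonical CSV.
* Residue indices are 1-based and contiguous; each region must be one
  contiguous run of indices.

## Known limitations

* Only the basic and epsilon LRP rules are implemented; alpha-beta, gamma
  and flat input-layer rules are out of scope, as are surrogate-model
  explainers.
* Only the probe-distance labeling criterion is implemented; other
  published state criteria for this receptor are not.
* The CNN trains on CPU; the reference 500-epoch protocol on a full-size
  ensemble is compute-heavy, and the shipped analyses use reduced
  configurations (documented above).
* Training reproducibility is best-effort across platforms: seeds fix
  initialisation, shuffling and dropout exactly, but floating-point
  reductions may differ between BLAS builds.
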