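---
title: "Latent token healing for unsupervised PET anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent token healing for unsupervised PET anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-body PET shows metabolically active tissue. Most of the signal is
physiological — the heart, the kidneys and bladder where tracer collects —
and a small part may be pathological (lesions). An unsupervised detector
must learn what "normal" uptake looks like and flag deviations, and it
should keep working when the training scans themselves contain lesions,
because curated healthy whole-body PET collections rarely exist: these
scans are mostly acquired on suspicion of disease. `vqheal` implements a
detection pipeline built on that premise, exercised end-to-end on
synthetic paired functional/anatomical phantoms.

## The model

**Discrete latent space.** A vector-quantised autoencoder maps a volume
$x \in \mathbb{R}^{H\times W\times D}$ to a grid of latent vectors, each
snapped to its nearest entry $e_k$, $k \in 1,\dots,K$, of a learned
codebook; the decoder reconstructs $x$ from the quantised grid. In this
package the encoder and decoder are small per-patch MLPs over
non-overlapping $f^3$ patches (so a $H \times W \times D$ volume becomes
an $(H/f)(W/f)(D/f)$-token grid); straight-through gradients pass the
quantiser and the codebook is updated by EMA (default) or by gradient. An
optional patch discriminator adds an adversarial term; it is off by
default because tiny training runs do not need it and it destabilises
them.

**Autoregressive prior.** The latent grid is flattened by a fixed 3D
raster scan (axis 1 slowest, axis 3 fastest) and modelled by a pre-norm
transformer with causal self-attention:
$p(s) = \prod_i p(s_i \mid s_{<i})$. A begin-of-sequence token with id
$K$ primes the sequence. With anatomical conditioning, a cross-attention
block after every self-attention layer reads the full anatomical token
sequence $c$ (same rasterisation, spatially aligned, produced by a
separately trained anatomical codec), giving
$p(s_i \mid s_{<i}, c)$: the model may consult *all* of the anatomy,
including positions ahead of $i$, which is what lets it explain
physiological hotspots away. Exact softmax attention is the reference
implementation — desk-scale sequences (128 tokens) do not need linear
attention approximations. Forward and backward passes are hand-written
matrix algebra, verified in the test suite against numerical gradients to
$10^{-4}$ relative error.

**Healing.** At inference the observed token sequence is scored once,
teacher-forced. Positions with $p(s_i) < t$ (strict inequality) form a
binary resampling mask. The threshold defaults to $t = 0.01$, but a
well-calibrated model concentrates probability mass and therefore flags
fewer positions at any fixed $t$ than a weaker one does, so the pipeline
grid-searches $t$ per sequence model on the validation split
(`t_grid`, selected by mean per-image best residual-map Dice) -- without
this, comparisons across models confound model quality with flag rate. Masked tokens are then
replaced left-to-right by draws from the model's full-vocabulary
multinomial at temperature 1, so later replacements condition on earlier
ones; the mask itself is frozen from the initial pass — re-deriving it
iteratively is a different algorithm, not implemented. Decoding the
healed sequence yields a "healthy" version $x_r$ of the input.

**Anomaly maps.** Two routes:

* *Residual*: $\max(x - x_r, 0)$. Negative residuals are suppressed
  because functional anomalies present as elevated uptake.
* *KDE*: repeat the resampling $n$ times (default 16) and decode each
  healed sequence with a fresh spatial-dropout mask mid-decoder
  (default $p = 0.1$), giving ensemble values $x_1,\dots,x_n$ per voxel.
  A Gaussian-kernel density
  $\hat f_h(x) = \frac{1}{nh}\sum_i K\!\left(\frac{x - x_i}{h}\right)$
  is fitted per voxel with the Silverman rule-of-thumb bandwidth
  $h = (4\hat\sigma^5 / 3n)^{1/5}$, floored at $h_{\min} = 0.05$ so that
  voxels where the ensemble agrees exactly remain scorable. The anomaly
  score is the negated log-density of the observed intensity, evaluated
  with log-sum-exp so far-tail scores do not underflow. Because
  functional anomalies present as *elevated* uptake -- the same fact that
  motivates the residual positivity filter -- the observed intensity is by
  default clamped at the ensemble mean from below, so only the upper tail
  of the density is scored; scoring both tails (available via
  `positive_only = FALSE`) measurably adds lower-tail false positives
  where reconstructions overshoot, e.g. at organ boundaries. The point of the
  KDE route is that reconstruction error distributions are frequently
  bi- or multi-modal (the decoder resolves ambiguous tokens to distinct
  intensities); a z-score map would rank the midpoint between two modes
  as *less* anomalous than the modes themselves, and the KDE map ranks it
  more anomalous — the test suite asserts exactly this.

**Segmentation.** Maps are thresholded at `scores >= tau`; the clinical
40% rule then grows every connected component to include all voxels
reachable through intensities at or above 40% of that component's own
maximum uptake, iterated to a fixed point so the operation is idempotent
and monotone. Boundary voxels at exactly 40% are included (`>=`), which
is the clinically inclusive reading; strictness is a switch.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `t` | 0.01 | token-likelihood threshold for the resampling mask |
| `n_ensemble` | 16 | healed reconstructions per input; KDE sample size |
| `h_min` | 0.05 | KDE bandwidth floor, intensity units |
| `dropout_p` | 0.1 | decoder spatial dropout; drives ensemble spread |
| `K`, `n_z` | 32, 8 | codebook size and latent vector length |
| `downsample_factor` | 8 | voxels per latent token per axis |
| `connectivity` | 26 | neighbourhood for components and growing |
| `frac` | 0.4 | clinical growing level, fraction of component max |

The likelihood threshold and the bandwidth floor are the two knobs that
shape detection behaviour most directly: `t` controls how aggressively
tokens are healed (too high and normal anatomy is resampled; too low and
lesions survive into the reconstruction), and `h_min` sets the score
scale at voxels where the ensemble is confident. `fit_pipeline()`
calibrates a deployment segmentation threshold on the validation split by
maximising mean Dice of the *ungrown* KDE segmentations; growing is a
post-processing step, and letting it into the calibration allows
degenerate extreme thresholds to win whenever a moderate one grows into
the background.

Sequence models are trained with decoupled weight decay
(`lm_weight_decay`, default 2 in units of the learning rate, applied to
weight matrices only). The conditional model carries roughly twice the
parameters of the unconditional one, and without regularisation it
overfits 60-sample training sets badly enough that its held-out NLL rises
above the unconditional model's, inverting the very conditioning benefit
the architecture exists for; with decay both models improve by about 10%
held-out NLL. Optional early stopping on validation NLL
(`lm_early_stop`) is available but off by default -- with few validation
sequences the epoch selection is noisy.

## What the phantom generator emulates — and what it does not

Each phantom is a pair of aligned volumes normalised to roughly
$[0, 1]$: an anatomical channel (air 0, soft-tissue ellipsoid 0.30, one
distinct density per organ) and a functional channel (baseline uptake
0.1 inside the body, organ uptake 4–8$\times$ baseline, lesion uptake
3–5$\times$ baseline). Organs are axis-aligned ellipsoids from a fixed
template list (heart, kidneys, bladder, liver, spleen analogues) with
per-sample jitter in position and size; lesions are small spheres
(radius 1–4 voxels) placed uniformly inside the body, rejected if they
touch an organ, and present in the functional channel only. That
construction makes "physiological vs pathological" separable only
through the anatomical channel, which is precisely the property the
cross-attention conditioning is meant to exploit. Training sets keep
their lesions by default — the contaminated regime the method targets:
lesions are spatially incoherent across patients, so they sit in the
tail of the learned token distribution even though the model saw them.
Noise is additive Gaussian truncated at zero, applied inside the body
envelope.

Not emulated: SUV physics, attenuation and scanner effects, respiratory
motion, registration error between the modalities, organ-shape
variability beyond affine jitter, and lesion texture. Passing tests
therefore show that the pipeline's machinery behaves as specified under
its own assumptions, not that it reaches any particular performance on
real scanner data.

## Numerical choices

* Quantisation ties break to the lowest codebook index; the distance
  computation is the same arithmetic as the brute-force oracle, so the
  tie-break is exact rather than floating-point-lucky.
* $\hat\sigma$ is the population (ddof = 0) standard deviation, the
  convention under which the Silverman rule is usually stated.
* KDE maps score both tails: the positivity filter is a residual-map
  rule. Voxels where the observation sits *below* the ensemble still
  score as anomalous.
* Threshold grids for best-Dice searches are quantiles log-spaced toward
  the upper tail: lesion voxels are rare, so all operative thresholds
  sit in the top percentiles of a map and an evenly spaced grid wastes
  almost all its points in the background bulk.
* The grown-segmentation search prunes exactly: growing only enlarges a
  mask, so Dice after growing is bounded by $2|T|/(|M|+|T|)$, and
  thresholds whose bound cannot beat the incumbent are skipped without
  computing the growth.
* Zero-variance paired differences in `paired_ttest()` are reported as
  an explicit degenerate case instead of NaN.
* Training aborts with a diagnostic on non-finite losses rather than
  continuing silently.

## Design decisions

* **Per-image best-Dice in the ablation.** Best achievable Dice is a
  theoretical upper bound, so `run_ablation()` reports the mean of
  per-image maxima. A single threshold shared across the evaluation set
  (`best_dice_set()`, also provided, and used for validation-split
  calibration) interacts badly with 40% growing on phantoms: at a shared
  threshold one imprecise component on the flat body plateau floods the
  whole body and collapses the score for reasons unrelated to the
  growing rule itself.
* **Ablation metrics over lesioned test cases only**, mirroring an
  all-cancer hold-out set; AUPRC is undefined and Dice degenerate for
  empty truth.
* **Dice of two empty masks is 1**, so lesion-free phantoms evaluate
  sensibly in calibration.
* **Dead codebook entries are left in place** (no re-seeding): the
  simplest reproducible behaviour.
* **One shared rasterisation order for both modalities**, so functional
  and anatomical tokens are spatially aligned position by position.
* **Every stage seed derives from the experiment seed** (data, codecs,
  sequence models, calibration, per-case healing and dropout), making a
  config a complete description of a run; `run_ablation()` re-run with
  the same config reproduces its table exactly.

## Problem sizes used in the bundled experiments

The package's own experiments (`desk_experiment_config()`, the test
suite, and `scripts/acceptance.R`) use 16×16×32 phantoms with factor-4
codecs — 4×4×8 = 128-token sequences, the same sequence length a
32×32×64 volume yields at factor 8 — a codebook of 24, a 2-layer,
2-head, width-32 transformer, ensembles of 16, and 60/11/12
train/validation/test splits with contaminated training. These sizes
keep a full multi-seed ablation within minutes on a single CPU while
preserving every structural element of the pipeline. The acceptance
script averages the ablation over three experiment seeds and also
reports a random-scores baseline evaluated on the same phantoms and the
mean log-likelihood gain of healing at resampled positions.

## Known limitations

* The per-patch MLP codec has no overlap between patches, so block
  boundaries are visible in reconstructions at high compression; a
  convolutional codec would smooth them but is not needed to exercise
  the pipeline's logic.
* Linear-attention approximations for long sequences are not
  implemented; `attention = "favor_plus"` errors by design.
* The healing sweep resamples masked tokens in one left-to-right pass.
  Joint or iterative refinement of the mask is out of scope.
* The clinical 40% rule can percolate through background noise: when a
  lesion's 40%-of-maximum level falls below the noise ceiling of the
  body (contrast below roughly $3.2\times$ background at the default
  noise), 26-connected growth floods the body plateau and the grown
  segmentation collapses for that case -- a known fragility of
  fixed-percentage thresholding for faint lesions, visible here because
  the threshold search covers such cases too.
* Phantom realism is deliberately minimal (see above); absolute metric
  values on phantoms do not transfer to clinical data, only the
  relative ordering of the method variants is meaningful — and the test
  suite asserts the ordering, not the values.

## Running an experiment

```{r}
library(vqheal)
ab <- run_ablation(desk_experiment_config(seed = 1, calibrate = FALSE))
ab$table
```
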