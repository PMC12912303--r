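---
title: "Multi-expert hierarchical multi-label learning for 12-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-expert hierarchical multi-label learning for 12-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical ECG interpretation produces *sets* of diagnostic terms, and those
terms are not independent: they live in a hierarchy (sinus tachycardia is a
sinus rhythm; a positive child term implies its parent), some pairs can
never be true of the same recording (a heart cannot be simultaneously
tachycardic and bradycardic), and the term frequencies are strongly
long-tailed — a few rhythms are everywhere while most morphologies are rare.
A plain per-label sigmoid + binary cross-entropy classifier ignores all
three structures and happily emits contradictory label sets: both members
of a mutually exclusive pair, or a child without its parent.

`ecgexperts` implements a training framework that injects this structure
through the loss rather than through post-hoc rules, and does so with an
ensemble of "good but different" experts aimed at the long tail.

## Label correlations from annotations

Everything starts from the annotation counts. With $N$ records, per-label
positive counts $N_i$ and co-occurrence counts $N_{ij}$, the
conditional-probability matrix is

$$ r_{ij} = N_{ij} / N_j , $$

the probability that a record known to carry label $j$ also carries label
$i$. Two binary relations are thresholded from it with *exact integer
tests* (never float tolerances — only the extreme values 0 and 1 encode
logical structure):

* **mutually exclusive**: $r^{ME}_{ij} = 1$ iff $N_{ij} = 0$ — the labels
  never co-occur;
* **mutually symbiotic**: $r^{MS}_{ij} = 1$ iff $N_{ij} = N_j$, $i \ne j$ —
  every record with $j$ also has $i$, i.e. $i$ behaves as an ancestor of
  $j$.

Self-pairs are excluded from both by construction. Because the symbiosis
test is data-driven and transitivity of chains holds in chain-complete
annotations, $R^{MS}$ covers *all* ancestor–descendant pairs, not only
immediate parents; the hierarchy table is treated as metadata, not as the
source of $R^{MS}$. Labels below a minimum positive count (default 50) are
dropped before any of this, since their correlation estimates are
meaningless.

## The activation family

For logits $z$ the package provides, in increasing order of structural
awareness:

* **sigmoid** $\sigma_i = (1 + e^{-z_i})^{-1}$ — fully independent labels;
* **concurrent softmax**
  $\sigma_i = e^{z_i} / (\sum_j (1-r_{ij})^\tau e^{z_j} + e^{z_i})$ —
  softmax whose cross-class suppression is attenuated by co-occurrence;
* **local softmax** — the $\tau \to \infty$ limit:
  $\sigma_i = e^{z_i} / (\sum_j r^{ME}_{ij} e^{z_j} + e^{z_i})$. Each label
  competes *only* against the labels it can never co-occur with, which
  keeps softmax's suppression of impossible co-diagnoses while leaving
  legitimate multi-label combinations untouched.

A label with no exclusive partner has nothing to compete against under
local softmax and saturates at $1-\varepsilon$; the package warns once and
continues (the gradient there is zero), and offers `add_other_class()` —
an artificial class exclusive to everything — as the documented remedy.
We deliberately train through the saturation rather than failing, so mixed
hierarchies (roots that co-occur with everything) still train; saturated
labels are simply not learned by the local-softmax experts and the sigmoid
experts carry them.

The hierarchy is enforced by the **symbiotic ranking regularizer**, a
pairwise ranking penalty

$$ \log\Big(1 + \sum_{(i,j)\,:\,r^{MS}_{ij}=1} e^{\sigma_j - \sigma_i}\Big) $$

pushing every ancestor's activation above its descendants'. The argument
is the expert's own activated output $\sigma$ (not the raw logits): the
regularizer and the cross-entropy then see the same quantity, and the
penalty is bounded and scale-free. Its coefficient defaults to 1 and is
exposed as `srr_weight`.

## Twelve experts and the long tail

Long-tailed training is addressed with additive logit priors. With
$v^1_i = \log(N/N_i - 1)$ and $\pi^1_i = \log(N_i/N)$, and `Inversed`
denoting the permutation that hands the most frequent label the rarest
label's prior (stable ties by label index), each base activation comes in
three variants:

| variant | sigmoid family | local-softmax family |
|---|---|---|
| long-tailed | $\sigma(z)$ | $LS(z)$ |
| balanced | $\sigma(z - v^1)$ | $LS(z + \pi^1)$ |
| inverse | $\sigma(z - v^1 + v^2)$ | $LS(z + \pi^1 - \pi^2)$ |

The balanced sigmoid has the pleasant property $\sigma(-v^1_i) = N_i/N$:
at zero logits every label predicts exactly its prevalence. Four bases
(sigmoid, symbiotic sigmoid, local softmax, symbiotic local softmax) times
three variants give the twelve expert losses; each is a class-weighted
($w_i = N/N_i$) binary cross-entropy of its own adjusted activation, plus
the ranking regularizer for the symbiotic bases. The total loss is their
plain sum. Class weights are applied in all twelve experts (they are part
of the base objective), with a switch to disable them since their
interaction with the logit priors is a genuinely open modelling question.
Predictions are aggregated by the arithmetic mean of the twelve activated
outputs — activations, not logits, because sigmoid- and local-softmax-based
experts live on different logit scales.

## The network

The backbone is a 1-D multi-scale residual network: every convolution runs
four parallel kernels of lengths 3/5/9/17 with the output channels split
evenly across branches, followed by batch normalization and ReLU.
Residual blocks hold two such modules (the first with stride 2), dropout
0.2 after the second, and a parameter-free shortcut (stride-2 subsampling
with zero-padded channels). Block $k$ (of 8, $k = 0..7$) has $64 + 16k$
output channels; global average pooling and a linear layer finish the
18-layer network. Three choices are deliberate and load-bearing for the
parameter budget:

* convolutions carry **no bias** (each is followed immediately by BN);
  with biases the budget rounds to 2.08 M instead of the printed 2.07 M;
* shortcuts are **parameter-free**; 1×1 projections would add ~0.11 M;
* only the **first** conv of each block strides; two strided convs per
  block would annihilate a 7500-sample input over 8 blocks.

At the full configuration (12 leads × 7500 samples, 254 labels) the single
network counts 2,074,782 ≈ 2.07 M trainable scalars. The multi-expert
variant shares the stem and blocks 0–5 and gives each expert its own
blocks 6–7 plus linear head; this reconstruction counts 12.66 M against a
printed 12.78 M — a ~0.9 % gap whose source (head/shared boundary details)
cannot be pinned down from the architecture description alone, so the
package treats 12.78 M as a ±1 % consistency check rather than an exact
target.

Training follows the reference regimen: SGD (momentum 0.9, weight decay
1e-5), Kaiming initialization, and a one-cycle-plus-sawtooth learning-rate
schedule — linear 0.001→0.01 over 45 epochs, linear decay back over 45,
rapid decay to 1e-6 over 10, then three 10-epoch sawtooths restarting at
0.005. "Rapid decay" is implemented as geometric decay to the floor within
the phase (the decay law is not otherwise specified). Runs shorter than
the canonical 130 epochs evaluate the same schedule at proportionally
scaled epochs. Two ensemble schemes exist: *private* (12 full networks,
one per loss) and *shared* (one trunk, 12 heads, loss = sum). Model
selection keeps the epoch with the best validation macro AUPRC of the
aggregate — selection is on a held-out validation split, never on the test
set, and class priors and correlation matrices are computed from the
training split only.

Both the forward pass and backpropagation are implemented in the package
(im2col convolutions in C++, batch-norm/ReLU/dropout/shortcut algebra in
R), and the backward pass is verified against central finite differences
in the test suite, as are the analytic gradients of all twelve losses.

## Evaluation protocol

Metrics are computed label-wise (per class across records) and exam-wise
(per record across labels, counts then averaged): AUROC as the normalized
Mann–Whitney statistic with ties counting one half; AUPRC as step-wise,
non-interpolated average precision (the estimator is stated because
interpolated variants differ at the third decimal on small label counts);
sensitivity, specificity, F1 and accuracy after thresholding. "Micro
AUPRC" in per-label displays means the per-label values and "macro" their
mean; no pooled-micro computation is used. Decision thresholds default to
the break-even point — the threshold minimizing |precision − recall| over
the observed scores, ties resolved toward the lower threshold (higher
sensitivity). Labels with no positives in a split yield undefined metrics
and are excluded from macro averages with a logged count rather than
imputed. Two consistency diagnostics operationalize the structural failure
modes: the fraction of records predicting any mutually exclusive pair, and
the fraction predicting a label without its symbiotic ancestor.
Model-to-model comparisons use Bland–Altman agreement and two-sided paired
t-tests on per-label AUPRC at $\alpha = 0.05$.

## The synthetic generator

Real hierarchical ECG corpora are proprietary, so the generator produces
datasets with the same *structure*: a deterministic 3-level tree (default
branching 2/2/2, 14 labels) with designated exclusive sibling groups (a
rate-class pair under the first root, modelling the tachy/brady exclusion,
and one sub-type pair one level down); leaf prevalences
$p_k \propto k^{-1.5}$ from 0.5 down — spanning more than an order of
magnitude, like the long tail it emulates; leaf draws per record with
conflicts suppressed and ancestors completed, so every record is
chain-complete and exclusivity-consistent by construction; and a top-up
pass guaranteeing every label its minimum positive count (default 40 at
the 2000-record test scale, mirroring the ≥50-at-full-scale filter
proportionally).

Waveforms are quasi-periodic Gaussian-bump beat trains (60–75 bpm) on 12
leads with canonical per-lead scaling. Label effects are deliberately
exaggerated relative to noise so that small models learn them in minutes
on a CPU: the rate-class pair doubles/halves the beat interval, an
ectopy-class subtree inserts off-grid bumps, other labels scale amplitude,
and — the main discriminative cue — every label adds a sinusoidal
signature at its own frequency (2–45 Hz) and lead pattern. Baseline wander
(0.3 amplitude at 0.25 Hz, below the 0.5 Hz preprocessing cutoff) and
white noise (sd 0.15 against unit-amplitude beats) are added last. What
passing tests on this data show is that the optimization, the losses and
the consistency mechanics behave as designed; they do not show clinical
performance — real ECG morphology, inter-patient variability and label
noise are all absent by design.

The study-scale test conditions are fixed once: 2000 records at 100 Hz ×
5 s, the 14-label tree, shared-backbone training for 5 epochs at batch 64
(a reduced network of 4 blocks, stem 8, growth 8, proportional to the full
8-block design), three seeds. At these sizes one training run takes about
90 s on one CPU core.

## Numerical choices

* Activations are computed with max-subtraction in the exponentials and
  clamped to $[10^{-7}, 1-10^{-7}]$ before any logarithm; gradients are
  zero where the clamp is active, consistent with the clamped forward
  value.
* The inverse-order prior permutation breaks ties by ascending label index
  (a stable sort); with all counts equal it degenerates to the identity on
  the (constant) prior vector.
* Break-even thresholds return the midpoint of the separating gap between
  candidate scores, and a small offset below the minimum score when every
  score is identical (predict-all-positive, the sensitivity-favouring
  degenerate case).
* The 0.5 Hz 5th-order Butterworth high-pass is implemented as cascaded
  second-order sections (bilinear transform with prewarping) and applied
  forward–backward with odd-reflection padding sized to the filter's
  settling time and steady-state initial conditions. A single expanded
  5th-order recursion at a normalized cutoff of 0.002 is too
  ill-conditioned: its initial-state solve alone loses five digits, which
  is visible as spurious edge transients. Zero-phase filtering is chosen
  because diagnostic ECG must not have waveform morphology phase-shifted.
  The source text states both 5 Hz and 0.5 Hz in consecutive sentences;
  the final, explicit sentence (0.5 Hz) is followed and the cutoff is
  configurable.
* Concurrent softmax converges to local softmax like
  $\max_j (1-r_{ij})^\tau$; at $\tau = 64$ this residual is $\sim 10^{-3}$
  for conditional probabilities near 0.1, so agreement to $10^{-6}$ only
  holds for $r \gtrsim 0.35$ (or larger $\tau$). The test suite asserts
  the true convergence behaviour and documents this bound.

## Known limitations

* The generator's waveform model is a structural stand-in, not a
  physiological ECG simulator (no P-QRS-T morphology).
* Fuzzy correlation values strictly between 0 and 1 are deliberately not
  used in the structural matrices, and manual expert editing of the
  matrices is out of scope.
* The shared-backbone scheme trains all heads on one trunk; gradient
  interference between experts is mitigated only by the heads' private
  blocks, as in the reference design.
* WFDB import covers header + format 16/80 single-file records (the
  PTB-XL layout); multi-file records are rejected.
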