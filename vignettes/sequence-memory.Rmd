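---
title: "Sequence memory with active dendrites: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence memory with active dendrites: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htmseq)
```

## The model

`htmseq` models one cellular layer of cortex as `N` mini-columns of `M`
cells. All cells of a column share a feedforward receptive field; we
assume a feedforward inhibitory process has already selected the set
`W^t` of `k` winning columns for each input, so the encoder maps each
input symbol directly to a fixed random `k`-of-`N` column set (2%
sparsity at the default `k = 40`, `N = 2048`).

Each cell carries dendritic segments, independent coincidence
detectors. A segment holds potential synapses to other cells, each with
a scalar *permanence* in [0, 1]; the synapse contributes (weight 1)
only while its permanence exceeds the connection threshold (0.5). A
segment fires — an NMDA-spike analogue — when strictly more than
`theta_activate` of its connected synapses have active presynaptic
cells; a firing basal segment depolarizes its cell, marking it
*predictive* for the next step.

Per step, three phases:

1. **Activation.** In each winning column, previously predictive cells
   fire and silence their column-mates; if none were predictive the
   whole column bursts. Active cells form the binary matrix `A^t`,
   predictive cells `Π^t`.
2. **Learning** (Hebbian, local, online). Segments that correctly
   predicted a now-active cell are reinforced: synapses with active
   presynaptic cells gain `p_plus` while every positive synapse loses
   `p_minus` — the rule decrements everything and increments the active
   subset, so active synapses net `p_plus − p_minus`. In a bursting
   column, the segment with the largest
   positive-synapse overlap with `A^{t−1}` is reinforced if that
   overlap reaches `theta_match`, and is topped up with new synapses;
   otherwise a new segment grows on the live cell with the fewest
   segments. Segments that fired without their cell becoming active
   decay by `p_decay` — the mechanism that retires chance and obsolete
   predictions. Permanences that reach 0 delete their synapse.
3. **Prediction.** All segments are scored against `A^t`; owners of
   firing segments form `Π^t`. The network's prediction for `t+1` is
   the set of columns containing predictive cells.

An optional *apical* channel gives each cell segments onto a feedback
axon space. Cells recognized apically are depolarized too, and a cell
counts as predicted if either channel depolarizes it. With a constant
feedback pattern present while a sequence is (basally) learned, the
feedback alone later depolarizes the whole chain at once, priming the
network to interpret inputs as part of the expected sequence and to
flag anything else by bursting.

### Where new synapses come from

New and topped-up segments sample the previous step's **winner cells**
— the one-cell-per-column context code (predicted-active cells, or the
designated learning cell of a bursting column) — not the full burst.
This matters: a segment grown from a burst would have to be re-learned
once its predecessor sparsifies, serializing learning across sequence
positions; winner sampling lets every position learn from its first
exposure, which is what makes the network reach the stream ceiling
within ~2000 elements. Match scoring, reinforcement and decay still use
the full `A^{t−1}`, because a stored winner code is always a subset of
a later burst of the same columns — that subset property is what keeps
unpredictable sequence starts anchored.

Two bookkeeping rules keep segments healthy over long runs and after
damage: when a full segment needs room to grow, its weakest synapses
onto currently inactive sources are destroyed first; and when a top-up
adds a column's newly designated winner, the segment's obsolete
inactive synapse(s) in that same column are replaced rather than
accumulated. Without these, segments clogged with synapses onto dead or
redesignated cells can never re-learn, and degenerate segments
concentrated inside chronically bursting columns block fresh growth.

## Exact sparse-representation combinatorics

A segment with `s` synapses and threshold `θ` falsely matches a random
pattern of `a` active cells among `n` with probability

$$P = \sum_{b=\theta}^{s} \binom{s}{b}\binom{n-s}{a-b} \Big/ \binom{n}{a},$$

the hypergeometric upper tail. `false_match_probability()` evaluates it
in the log domain (log-binomials + log-sum-exp): values like 1e-20 are
far below what a naive floating-point sum can resolve, while the log
route keeps relative error around 1e-11. Terms outside the support
contribute zero. The unit tests check this against exhaustive
enumeration of all patterns for small `n` and against the independent
`stats::phyper` tail as a second route.

Worth knowing: at the canonical operating point (`n` = 200,000,
`a` = 2000), 10 synapses at `θ` = 10 give `P ≈ 9.8e-21`; doubling the
synapses to 20 (50% noise tolerance) gives `P ≈ 1.65e-15` by this
formula. `representation_count()` uses exact big-integer arithmetic
(32^40 has 61 digits), and `shared_segment_false_match()` estimates by
Monte Carlo the extra error when several stored synapse sets share one
segment — the overlap of a random pattern with a fixed set is exactly
hypergeometric, so trials draw that overlap directly.

## The synthetic stream

`stream_spec()` defines the training stream: blocks of one embedded
six-element sequence followed by 4 filler symbols drawn uniformly and
independently from a disjoint 50-symbol alphabet. Embedded sequences
come in pairs of the form `X A B C D E` / `Y A B C F G` — shared
three-element interior, distinct first and final two elements — so the
last transitions are only predictable with more than one step of
context. Two pairs (four sequences) are in the pool by default; each
block picks one uniformly. Within a sequence every transition after the
first element is deterministic given full history, so 5 of every 10
elements are predictable: the accuracy ceiling is 50%. At the first
block boundary past `swap_at` (default 3000) the pool is replaced with
freshly named pairs, modelling a change in the world's statistics.

Accuracy is scored by **exact column-set match**: a prediction counts
only if the predicted column set equals the next input's columns. This
choice penalizes union predictions, which is what separates the
first-order control (one cell per column): after the shared interior it
must predict both branches, scoring zero there. Under this rule the
first-order ceiling on this stream is 4 of 10 transitions (40%) — the
shared-interior and unique-tail transitions remain first-order
predictable — and the measured control converges to ~40%. How far a
first-order model falls below the high-order ceiling depends on the
stream composition and on the scoring rule; both are stated explicitly
here so the gap is interpretable.

What the generator does *not* emulate: real streams have non-uniform
symbol statistics, overlapping and nested sequences, noise inside
sequences, and drifting vocabularies. Passing these experiments shows
the mechanism works under clean high-order structure; it does not
certify performance on natural data.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_columns`, `cells_per_column`, `k` | 2048, 32, 40 | layer geometry; 2% column sparsity |
| `theta_activate` | 15 | connected synapses needed for a segment to fire (strict >) |
| `theta_match` | 8 | minimum positive overlap for a bursting column to reuse a segment |
| `max_segments_per_cell` | 128 | per-cell segment budget (least recently active evicted) |
| `max_synapses_per_segment` | 40 | per-segment synapse budget |
| `sample_size` | 30 | synapses grown per learning event |
| `perm_connected`, `perm_init` | 0.5, 0.21 | connection threshold; birth permanence (new patterns act only after several presentations) |
| `p_plus`, `p_minus`, `p_decay` | 0.1, 0.01, 0.02 | reinforcement, punishment, mistaken-prediction decay |

The learning rates deserve a note. Rates for this family of models are
tuned per dataset in practice, with values typically below 0.1. We
calibrated the defaults on the synthetic stream itself: `p_plus` at
the canonical upper value 0.1 so a new segment connects after four
exposures, and `p_decay = 0.02` — five-fold below `p_plus`, so genuinely
recurring contexts always win — because obsolete branch predictions
(grown while a pair's second member still shared the first member's
interior code) saturate near permanence 1 and must retire within a few
dozen exposures for the network to reach the ceiling inside 3000
elements. With decay an order of magnitude smaller, those stale
segments linger thousands of elements and converged accuracy stalls
around 0.45.

`theta_match = 8` also carries design weight: a burst-trained segment
(30 synapses over a 1280-cell burst) overlaps a later 40-cell sparse
code by ~1 synapse, so the floor cleanly separates "this segment knows
this context" from coincidence; an unconditional argmax would let
near-zero matches capture and corrupt unrelated segments.

## Numerical and procedural choices

* Strict inequality in the segment-firing rule, as specified.
* Ties in the best-match selection and in winner-cell choice are broken
  uniformly at random from the network's private seeded stream; whole
  runs are bit-reproducible given `(params, stream)`.
* Cells and columns are 1-based; cell `i` of column `j` has flat id
  `(j−1)·M + i`.
* The experiment streams are continuous — no state resets between
  sequences. Resets (`tm_reset()`) exist for probes such as the worked
  examples.
* Degenerate inputs: an empty winning set produces an empty step;
  inputs of the wrong size are processed with a warning; a fully
  lesioned column simply never activates.
* Moving averages use a trailing 200-step window; "converged accuracy"
  is the mean raw correctness over the 500 elements before the swap
  (or end of run).
* Problem sizes: the bundled experiments run the full-scale network
  (2048×32) for 3000–6000 elements and a scaled configuration (512×16)
  for qualitative checks; both reach their ceilings with the same
  dynamics.

## Lesion experiments and a known limitation

`run_lesion_experiment()` trains to stability, kills a random cell
fraction in an independent copy, and measures accuracy immediately and
after continued learning. Because the converged code is one cell per
column, the exact-match score drops immediately after any substantial
lesion — each transition needs all 40 of its chain cells alive — and
recovery is driven by regrowth among survivors. At 60% cell death the
network relearns to near its ceiling within a few thousand elements; at
40% recovery is slower, because surviving half-damaged segments still
match bursts and compete with fresh growth. A robustness claim of the
form "moderate damage has almost no immediate effect" is only
reproducible under a containment-style accuracy metric (predicted ⊇
actual), not under the exact-match metric used throughout this package;
we report the exact-match numbers.

## Other limitations

* Feedforward encoding is fixed and random; no spatial-pooler learning,
  no topology, no scalar encoders.
* The apical channel uses a committed simplification: basal-or-apical
  disjunction for the predicted state, and apical learning restricted
  to cells with a basal learning event in the same step.
* Sub-millisecond timing, spike-timing plasticity, and biophysical
  dendritic dynamics are out of scope; the model operates at the level
  of discrete steps and binary activations.
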