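---
title: "CE-GCN: methods, design decisions, and what the synthetic studies show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CE-GCN: methods, design decisions, and what the synthetic studies show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cegcn)
```

## The problem

Multimorbidity — two or more chronic diseases in the same person — becomes
the norm rather than the exception past middle age. If diseases are nodes
and an edge joins two diseases that co-occur in at least one patient, a
cohort defines a *multimorbidity network*, and because disease onsets carry
ages, it defines a whole sequence of networks indexed by age. Predicting
which disease pairs will become linked at the next age is a dynamic
link-prediction problem, and its answers are directly actionable: a pair
predicted to co-occur flags patients with one of the diseases as candidates
for early screening of the other.

`cegcn` implements CE-GCN, a model for this task: a graph convolutional
network (GCN) whose layer weights are not static but *evolved along the age
axis* by a gated recurrent unit (GRU), with node features built from
common-neighbour counts. The package also contains everything around the
model — network construction from patient records, temporal splitting,
ranking evaluation, a static-GCN baseline, and a synthetic cohort generator
with a known generative mechanism, so that each claim the model makes can be
tested against a ground truth.

## From records to snapshot sequences

The raw input is long-form records `(patient_id, disease_id, onset_age)`.
Cohort filtering keeps onsets inside the age window (45–90 by default) and
drops patients with fewer than two distinct diseases — a single-disease
patient contributes no edge and therefore no signal. `build_snapshots()`
produces one graph per integer year of age. In the default *cumulative*
mode, a patient contributes the pair \((i, j)\) at every age
\(t \ge \max(\text{onset}_i, \text{onset}_j)\): an edge persists once
formed, which matches how the field draws these networks (edges thicken and
accumulate as cohorts age) and makes the edge sets monotone along the
sequence. An *incident* mode (a pair counts only at the age it completes) is
available behind a flag; incident weights summed over ages equal the
cumulative weights at the final age, which the test suite asserts.

Nodes are fixed to the disease catalog for every age: a disease with no
edges yet is an isolated node, never a missing one, so matrices at different
ages stay conformable. Edge weights (patient counts) are kept for reports;
the model itself consumes the binary adjacency, because the edge definition
is binary.

## Node features: one-hot common-neighbour scores

For each snapshot, squaring the adjacency gives \((A^2)_{ii} = \deg(i)\) and
\((A^2)_{ij} = |N(i) \cap N(j)|\) for \(i \ne j\). The node feature is the
row sum

\[ f(i) = (A^2 \mathbf{1})_i = \deg(i) + \sum_{j \ne i} |N(i) \cap N(j)|, \]

a single integer combining the node's global position (degree) with its
local similarity structure (total common neighbours). Each distinct value of
\(f\) observed in the *training* ages gets one dimension of a one-hot
encoding; one extra dimension is reserved for out-of-vocabulary values. Two
consequences are worth stating explicitly:

* the vocabulary is built from training snapshots only, so no future network
  structure leaks into the feature space, and the feature dimension \(d\)
  stays constant over the whole sequence (the evolving weight matrices must
  keep one shape);
* values first seen at later ages map to the OOV slot rather than being
  snapped to the nearest known value — deterministic, and free of any hidden
  metric assumption on score space. The flip side is that reports computed
  far beyond the training block degrade, because late-age scores are
  increasingly out-of-vocabulary; the ranked-pair report is therefore most
  meaningful at or near the last training age.

The phrase "combining degree and common neighbours" is implemented as the
single scalar \(f(i)\), not as a concatenation of two one-hots: the row-sum
identity above is the only reading in which the two quantities combine into
one number per node, and it is what the score formula states. The
concatenated alternative is noted as a possible extension point.

## The model

Each layer applies the standard normalized propagation

\[ H^{(l+1)} = \sigma\!\left( \tilde D^{-1/2} \tilde A \tilde D^{-1/2}
   H^{(l)} W_t^{(l)} \right), \qquad \tilde A = A_t + I, \]

with ReLU on hidden layers and identity on the last (embeddings feed a
scorer, so clipping them at zero would discard half the signal). The
self-loop makes the operator well defined for isolated nodes, and its
eigenvalues lie in \([-1, 1]\) (property-tested on random graphs).

### Evolving the weights

The defining step is that \(W_t^{(l)}\) changes with age via a GRU:

\[ Z_t = \mathrm{sigmoid}(U_Z S_t + C_Z W_{t-1} + B_Z), \quad
   R_t = \mathrm{sigmoid}(U_R S_t + C_R W_{t-1} + B_R), \]
\[ \tilde W_t = \tanh(U_W S_t + C_W (R_t \circ W_{t-1}) + B_W), \quad
   W_t = (1 - Z_t) \circ W_{t-1} + Z_t \circ \tilde W_t . \]

Feeding an \(n \times d_{in}\) embedding matrix and a
\(d_{in} \times d_{out}\) weight matrix into one GRU is not conformable as
written; this is the largest gap any implementation has to close. The
package closes it the way the recurrent-weight-evolution literature does:
the layer input is *summarized* to \(d_{out}\) rows by deterministic learned
top-k pooling — each node is scored by the projection of its embedding onto
a learned direction \(p\) (\(y = Xp/\lVert p \rVert\)), the \(k\) top rows
are kept (ties broken by row index), each scaled by \(\tanh(y_i)\), and
zero-padding covers \(n < k\) — then transposed to the weight's shape. Every
entry of \(W_t\) is a convex combination of the previous and candidate
entries, so with \(\tanh\)-bounded candidates the weight trajectory is
bounded for any sequence length; the suite asserts both the convexity and
the boundedness on repeated snapshots.

All layers evolve by default; a config flag (`evolve = "first"`) restricts
evolution to the first layer, and `evolve = "none"` is exactly the static
baseline. Whether one or all layers should evolve is not determined by the
method's statement; evolving all is the more general choice and the
restriction is one flag away.

Initialization is Glorot-uniform under the config seed. The update-gate bias
starts at \(-2\), so early in training \(Z_t \approx 0.1\) and the model
behaves almost like a static GCN, learning temporal deviations gradually —
the usual recurrent gate-bias initialization, which in our experiments
removed a systematic early-training disadvantage of the evolving model
relative to the static baseline.

### Scoring pairs and the loss

A pair \((i, j)\) is represented as the concatenation \([h_i \,\|\, h_j]\)
and scored by a two-layer MLP; the logit is averaged with the swapped
ordering so \(s(i,j) = s(j,i)\) holds exactly, by construction rather than
by approximation. Training minimizes class-weighted binary cross-entropy
(positive weight 10 by default — new edges are rare among all pairs),
accumulated over the training transitions: embeddings at age \(t\) predict
the target edges of age \(t+1\). Positives are the new edges of
\(G_{t+1}\) (default mode) or all edges; negatives are sampled from every
remaining pair *including* already-linked ones, at 5 negatives per positive.
Keeping existing edges in the negative pool matters: the scorer must learn
that an already-formed pair is not a future new edge, otherwise ranked
reports are dominated by the densest existing edges.

The default target mode is `new_edges`, because surfacing hidden future
relationships — rather than re-ranking edges that already exist — is the
stated purpose of this kind of model; `all_edges` is available since
published evaluation protocols often do not state which convention they use.

### Optimization

Adam (lr 0.01, 200 epochs max by default) with early stopping on validation
MAP, patience 20; when a validation block contains no positive pairs the
training loss is monitored instead. Every random choice (initialization,
negative sampling) derives from the config seed, and the suite asserts
bit-identical losses and parameters across repeated runs.

The gradients come from a small reverse-mode automatic-differentiation tape
over dense matrix operations written for this package; it is verified
against central finite differences through the *complete* computation
(pooling, GRU, convolutions, scorer, weighted loss) to ~1e-11, including
gradient accumulation when one node appears in several scored pairs.

## Splitting and evaluation

`temporal_split()` cuts the age axis into contiguous train/validation/test
blocks (70/15/15 of ages by default: 32/7/7 for ages 45–90), each at least
one age. Evaluation is strictly temporal: a transition belongs to the block
containing its *target* age.

For each test transition and each disease with at least one relevant
partner, all eligible partners are ranked exhaustively — at these graph
sizes there is no reason to sample candidates — with a deterministic
tie-break (descending score, then ascending partner id). AP is the discrete
precision-at-relevant-ranks average; MAP its mean over queries; MRR the mean
reciprocal rank of the first relevant item, zero when none is retrieved.
One query per (target age, node with a relevant partner) defines the query
count; a per-edge alternative would weight busy ages more and is easy to
derive from the returned per-query table. The metric kernels are tested
against exhaustive enumeration of all rankings up to length six.

## The synthetic cohort generator

Real CHARLS-style patient data is available only on request, so the package
ships a generator whose mechanism is known exactly, and every pipeline stage
is validated against that mechanism.

Each patient carries exposures to a small number of latent risk factors
(gamma, mean 1); each disease loads on one factor (or on a user-supplied
loading matrix); a per-disease lognormal multiplier spreads marginal
prevalences. The yearly onset probability is
\(1 - \exp(-\lambda_0\, m_d\, (1 + \text{loading\_scale} \cdot x_p^\top
\ell_d)\, g(a))\) with the linear ramp \(g(a) = 1 + (a - 45)/45\); the first
success year is the onset age. Diseases sharing a factor co-occur above
chance — the same "shared aetiology" story that motivates common-neighbour
reasoning — and `loading_scale = 0` gives an exact independence null with a
closed-form expectation, which the suite checks to Monte-Carlo precision.

The default baseline hazard (8e-4 per year) was calibrated once so that the
default cohort reproduces the reference cohort's multimorbidity burden of
about 2.6 diseases per retained patient; the per-disease lognormal spread
(sd 0.4 on the log scale) then yields marginal prevalences spanning roughly
10–45%, the right order for the published prevalence table. The generator
does not attempt survey design, mortality, censoring, or remission; what
passing tests show is that the *pipeline* behaves as designed under a
plausible mechanism, not that the model's real-data metrics are reproduced.

### Planting the temporal rule

`plant_temporal_rule()` makes the core hypothesis — pairs with many common
neighbours link in the future — literally true: walking the age axis, with
probability `min(1, rule_strength/2)` per age, the unlinked pair with the
highest current common-neighbour count gains an injected patient carrying
both diseases at the next age. At most one injection per age keeps the
planted set sparse (no saturation of the pair space) and spreads planted
links across the whole age range, including the test ages, so test-block
evaluation always has positives. Selecting the arg-max pair, rather than
sampling broadly among high-CN pairs, makes the planted trajectory
predictable from any one snapshot, which is what a recovery test needs.

## The two synthetic studies

**Null calibration.** Ten cohorts with independent diseases and no planted
rule; CE-GCN is trained and its test MRR compared with the Monte-Carlo
distribution of a random ranking of the same query sets. The mean gap must
sit within three standard errors of zero. This is the leakage guard: any
pathway from test-age structure into training would show up as systematic
excess MRR on data with no learnable signal.

**Signal recovery.** Five cohorts with the planted rule at strength 2 (one
planted link per age). The recovery study deliberately uses a 20-disease
catalog and a sparse base cohort (120 patients, baseline hazard 4e-4): the
power of a top-decile enrichment test scales with the number of disease
pairs (190 pairs give a 15–16-draw decile among unlinked candidates, against
4–9 draws at 14 diseases, where even a perfect ranking often cannot reach
p < 0.01), and the sparse base keeps roughly half the pair space unlinked at
the end of training. Two properties are checked: the median paired
difference in test MAP between CE-GCN and the static baseline is
non-negative, and planted future pairs are enriched in the top decile of the
ranked report at the last training age (hypergeometric test, median
p < 0.01 over the five cohorts). In our runs the enrichment is the sharper
signal (median p around 1e-4); the MAP advantage over the static baseline is
positive in median but small and seed-sensitive — consistent with the small
printed advantage this model class reports on real data, and worth knowing
before reading too much into any single run.

All statistical tests run on fixed seeds and are therefore deterministic;
problem sizes (80–250 patients, 46 snapshots, 15–80 epochs) were chosen so
the full suite completes in a few minutes on one CPU.

## Numerical and interface choices

* Ids are 1-based internally (R convention); catalogs with 0-based
  contiguous ids are renumbered on input.
* Ties in every ranking break by ascending node id; ties in top-k pooling by
  ascending row index. Both are declared rather than left to sort
  stability.
* Degenerate inputs: an empty graph normalizes to the identity operator; an
  empty cohort yields all-zero snapshots; a query with an empty relevant set
  is excluded from MAP and signalled; an all-zero pooling direction leaves
  scores at zero rather than dividing by a zero norm.
* Checkpoints are a single JSON file (parameters with shapes, config, split,
  vocabulary, training curve) — human-readable and dependency-free.
* The loss with all-zero logits and unit class weight is exactly
  \(\log 2\) per pair, used as an analytic anchor in the tests.

## Known limitations

* Fourteen-node graphs make exhaustive pair scoring trivial; nothing in the
  implementation is tuned for large graphs (dense matrices throughout).
* The pair scorer sees only the two endpoint embeddings; whether a specific
  pair is already linked is not directly expressible from them, which is why
  ranked reports separate candidates by the `already_linked` flag.
* Out-of-vocabulary features accumulate beyond the training block, so
  reports far past the last training age flatten.
* The published real-data MAP/MRR values cannot be reproduced without the
  restricted cohort data; the package's claims about the model are the
  synthetic-study claims above, no more.
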