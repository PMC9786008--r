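---
title: "moladr: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{moladr: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moladr)
```

## The problem

Adverse drug reactions (ADRs) are harmful responses to a drug beyond its
therapeutic effect. At the preclinical stage the only information reliably
available for a candidate compound is its chemical structure, so moladr
frames ADR prediction as *multi-label* classification from structure alone:
a drug $d_i$ is mapped to a binary label vector $(l_1, \dots, l_{N_l})$,
$l_j = 1$ when the drug belongs to ADR class $j$. Typical settings are
$N_l = 27$ system-organ classes (SOC) or $N_l = 4$ organ-toxicity outcomes
in OMOP-style drug-safety benchmarks. Because one drug usually triggers
many ADR classes at once (a label *cardinality* of 16.5 over 27 classes,
i.e. density 0.61, is typical of curated ADR corpora), every component of
the package — loss, metrics, protocols — is multi-label throughout.

## The model

Each molecule is read by two independent encoders whose outputs are
concatenated ("multi-level feature fusion").

### Graph channel

The SMILES string is parsed (Open Babel, via ChemmineOB) into a heavy-atom
graph. Nodes carry `(atomic number, chirality)`, edges carry
`(bond type, bond direction)` — deliberately nothing else (no degree,
hybridisation or aromatic-atom flags), keeping the attribute set minimal.
A graph isomorphism network (GIN) runs $T$ rounds of message passing:

$$ m_u^{t+1} = \sum_{v \in N(u)} M_t(h_u^t, h_v^t, e_{uv}), \qquad
   h_u^{t+1} = U_t(h_u^t, m_u^{t+1}) $$

with both $M_t$ and $U_t$ linear layers sharing one square matrix $W_t$.
The description "linear layers with the same dimension weight matrix $W$"
leaves the exact argument wiring open; moladr fixes the simplest reading
consistent with it:

$$ M_t(h_u, h_v, e_{uv}) = W_t\,(h_v + \mathrm{emb}(e_{uv})), \qquad
   U_t(h_u, m) = W_t\,(h_u + m), $$

with no nonlinearity between rounds (only linear layers are described; we
follow the text rather than inserting a ReLU). Initial node states are the
sum of the atomic-number and chirality embeddings; edge embeddings the sum
of bond-type and bond-direction embeddings (the attributes are listed
without a combination rule; summation is the standard choice in pretrained
GIN encoders). The readout is the element-wise maximum over final node
states. Three independently parameterised encoders, tagged after the
self-supervised objectives Infomax (`m`), Edge (`e`) and Context (`c`),
produce $X^m, X^e, X^c$, each of width `dim`.

Defaults `T = 5`, `dim = 300` follow the conventions of pretrained
molecular GIN encoders; neither value is dictated by the architecture.
Full-scale self-supervised pretraining on a molecule corpus is out of
scope: `gin_params()` gives seeded random initialisation, `toy_pretrain()`
offers desk-scale Edge and Infomax objectives (binary discrimination of
true bonds vs sampled non-bonds, and of own-graph vs other-graph mean
summaries, by node-state dot products), and `load_gin_weights()` accepts
externally pretrained tensors. The Context objective deliberately signals
not-implemented. Whether the graph encoders should be fine-tuned during
supervised training is not fixed by the architecture either; moladr
exposes `finetune_gin` and defaults to fine-tuning.

### Sequence channel

Open Babel's FP2 path fingerprint marks 1024 bits for the linear fragments
of the molecule. To avoid feeding a sparse bit vector, groups of four bits
become one hexadecimal digit: a 256-token sequence over a 16-symbol
alphabet, each token summarising four path substructures. The hex dialect
is fixed once: digit $k$ (0-based) is formed from bits $4k..4k+3$ with bit
$4k$ most significant, rendered lowercase.

The encoder is one transformer-style block. Tokens index a $16 \times
\mathrm{dim}'$ embedding table; each embedded row is layer-normalised
(mean and variance across the embedding dimension, learnable affine,
$\epsilon = 10^{-5}$). Per head $h$, projections $W_q^h, W_k^h, W_v^h$
($\mathrm{dim}' \times d_v$, $d_v = \mathrm{dim}'/H$ enforced exactly)
give scaled dot-product attention
$\alpha_{s,j} = \mathrm{softmax}_j(Q_s^\top K_j / \sqrt{d_v})$ and outputs
$O_s = \sum_j \alpha_{s,j} V_j$ — the weighted sum runs over positions
$j$ (reading the attention output as a sum of value vectors weighted over
source positions, the standard formulation; a literal per-position value
would make the sum collapse). Head outputs are concatenated, projected by
$W_o$, added to the input (residual) and layer-normalised again.

The feedforward unit flattens the $256 \times \mathrm{dim}'$ output
(token-major order) and computes, in exactly this nesting,

$$ X^f = \mathrm{LeakyReLU}\big(\mathrm{BN}(\mathrm{flatten}(O)\,W_1)\,W_2\big), $$

batch normalisation *between* the two linear maps and the activation
outermost. LeakyReLU uses negative slope 0.01; batch-norm uses
$\epsilon = 10^{-5}$, momentum 0.1 for the running statistics, and falls
back to running statistics in evaluation mode and for single-sample
forwards. No positional encoding is used — none is part of the design, so
the attention block is permutation-equivariant over token positions (a
tested property); positions influence the output only through their token
values. Defaults `dim' = 64`, `dim_ff = 1024` and output width
`dim = 300` (matching the graph channel) are package choices.

### Fusion, prediction, training

The drug representation is $X = [X^m, X^e, X^c, X^f] \in
\mathbb{R}^{4\,\mathrm{dim}}$ (enforced at construction), mapped by a
single linear layer and a sigmoid to per-label probabilities
$P = \sigma(X W_{\mathrm{pred}})$. The loss is mean per-label binary
cross-entropy — the natural likelihood for independent sigmoid outputs;
no loss is dictated otherwise. The optimizer is Adam at learning rate
$\xi = 0.001$ with L2 regularisation $\delta = 0.001$ added to every
learnable tensor's gradient; attention-head count $H = 2$ and dropout
$\varepsilon = 0.5$ complete the reference hyperparameter setting.
Dropout is applied where transformer practice puts it — on attention
weights and on the feedforward hidden layer — and only in training mode;
evaluation is deterministic. Epochs (100) and batch size (32) are exposed
defaults. Binarization uses threshold $\tau = 0.5$ with the tie rule
$\geq$ (documented so that the probability-0.5 edge case is
deterministic). All backpropagation (through max-pool readout, message
passing, softmax attention, both norms and the batch statistics) is
implemented in base R matrix algebra and verified against central finite
differences in the test suite; no deep-learning framework is involved.

## Evaluation

Accuracy is sample-wise label (Hamming) accuracy averaged over samples:
the per-sample index in its defining sum runs over samples, so each
sample contributes the fraction of its labels predicted correctly. (The
alternative, subset accuracy, scores a sample 1 only when all labels
match; the per-sample count form points to the Hamming reading.)
Precision and recall pool TP/FP/FN counts per label and macro-average
over labels — a literal per-label inner sum without a normaliser would be
dimensionally inconsistent, and macro averaging over the label set is the
stated convention. Labels with undefined denominators (never predicted
positive; no positives present) are excluded from the macro mean and
reported, rather than silently averaged as zeros. ROC-AUC uses the
Mann-Whitney rank formula (ties count one half); PR-AUC is average
precision by step integration over distinct thresholds. Both are
macro-averaged over labels containing both classes. No installed R
package provides PR-AUC, so it is implemented directly and tested against
an explicit threshold-sweep oracle; ROC-AUC is additionally cross-checked
against pROC.

Three protocols are provided: a seeded 90/10 holdout with the floor rule
on the training side (2248 records split 2023/225), seeded k-fold
cross-validation (default 5) with validation folds differing in size by
at most one, and the jackknife (leave-one-out, one model per record,
held-out predictions pooled before a single evaluation). Cross-validation
is unstratified by default, matching a plain random split.

## The synthetic generator

`generate_synthetic()` emulates a multi-label drug dataset with known
ground truth. Each molecule is a methylene backbone of `C(unit)` groups
whose units are 1–3 filler fragments from a fixed pool of 40 drug-like
fragments (shipped as `inst/extdata/fragment_pool.smi`) plus, with
probability `marker_prevalence` (default 0.35) per label, that label's
marker substructure (trifluoromethyl, nitrile, sulfonamide, nitro,
chloro, bromo, iodo, carboxyl — chosen to be chemically disjoint and
absent from the fillers). Label $j$ is 1 exactly when marker $j$ was
attached, then flipped independently with probability `label_noise`. At
zero noise the labels are recoverable by SMARTS matching of the markers
(a tested invariant), so a model that reads structure faithfully can
reach perfect held-out ranking — which is what the parameter-recovery
test demands (held-out macro AUC at least 0.95 on 200 molecules, 4
labels, zero noise).

What the generator does *not* emulate: real pharmacological label
structure (labels here are independent given the markers, with only
incidental co-occurrence), scaffold diversity (one backbone family),
class imbalance beyond the prevalence parameter, and any
structure-activity relationship subtler than substructure presence.
Passing the recovery test therefore shows that the two channels transmit
substructure information end to end through training — not that the model
reaches any particular accuracy on curated ADR corpora, which require the
original datasets and full-scale pretraining.

## Problem sizes in the shipped tests

The test-suite and acceptance-script runs use desk-scale widths
(`dim` 6–32, `dim'` 4–16, `dim_ff` 8–64, `T` 1–3, 200 molecules), chosen
so the whole suite exercises every code path — including full training —
at small problem sizes; the architecture is identical at the default
widths, only slower. Oracle comparisons use tolerance $10^{-9}$ for exact
re-computations and $10^{-6}$ where floating-point summation order
differs (e.g. node relabeling).

## Numerical choices and degenerate inputs

* Softmax is computed with max-subtraction; attention rows always sum
  to 1.
* Layer/batch norm $\epsilon = 10^{-5}$; a constant embedding row
  normalises to the zero vector before the affine.
* BCE clamps probabilities to $[10^{-12}, 1 - 10^{-12}]$.
* Initialisation: variance-scaled Gaussians (`sd = 1/sqrt(fan_in)` for
  projections; 0.1 for embedding rows; `0.5/sqrt(dim)` for GIN weight
  matrices so that repeated linear rounds neither explode nor vanish).
* Single-node graphs have an empty neighbour sum; the empty graph is
  rejected. Non-finite training loss aborts with the epoch index.
* `toy_pretrain` uses plain gradient descent with global gradient-norm
  clipping (maximum norm 5, step size 0.01): because the message-passing
  rounds are purely linear, unclipped gradients can explode on denser
  graphs.
* Open Babel silently repairs some malformed SMILES, so a syntactic
  well-formedness check (balanced brackets, paired ring closures, legal
  bare atoms) runs first and raises a featurization error carrying the
  offending string.
* Bond direction tags are reconstructed from the parser's cis/trans
  annotation on stereo double bonds (trans → both flanking bonds "up",
  cis → "up"/"down"), equivalent to SMILES `/` `\` tags up to a global
  flip, which carries no information.
* Chirality uses the parser's atom parity (+1 → `cw`, −1 → `ccw`);
  both stereo attributes only index embedding tables.

## Known limitations

* No stacked encoder blocks, learning-rate schedules, early stopping or
  class-imbalance weighting.
* The Context pretraining objective is not implemented; Edge and Infomax
  are desk-scale simplifications, not reproductions of the cited
  pretraining pipelines.
* Training is pure R; it is comfortable at hundreds of molecules and
  reduced widths, but full-width training on thousands of molecules is
  slow.
* The SOC ontology mapping (collapsing raw ADR terms to 27 classes) is
  out of scope; the loader consumes already-binarised label columns.
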