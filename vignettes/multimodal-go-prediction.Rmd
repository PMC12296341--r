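---
title: "Multi-modal GO-term prediction from frozen protein embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal GO-term prediction from frozen protein embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Annotating a protein with Gene Ontology (GO) terms is a hierarchical
multi-label classification problem: each protein carries a binary label
vector over the retained terms of one GO aspect (biological process,
molecular function or cellular component), and the labels live on a DAG
whose `is_a`/`part_of` edges encode the true-path rule. Modern practice
starts from a frozen protein language model (PLM) that emits one embedding
per residue; a light head is then trained on top (linear probing). This
package implements a fusion pipeline that folds three further modalities of
the GO knowledge base into that frozen representation — term text
descriptions, species identity, and the GO relation graph — and evaluates
the result with CAFA-style protein-centric metrics.

The upstream embedders themselves are out of scope: sequence and text
embeddings enter through a generic archive interface (`read_archive()`),
and a synthetic generator (`generate_cohort()`) produces desk-scale cohorts
with planted, recoverable signal so every stage is testable without GPU
inference.

## The model

Write $x^{seq} \in \mathbb{R}^{d \times l}$ for a protein's per-residue
embedding and $x^{text}_j \in \mathbb{R}^{d' \times l'_j}$ for the embedding
of term $j$'s name/definition text.

**Text alignment.** Each text is projected into sequence space by a learned
linear map $P \in \mathbb{R}^{d \times d'}$ and scored against the sequence
by the mean per-position cosine
$\frac{1}{K}\sum_{k=1}^{K} \cos(P x^{text}_{\cdot k}, x^{seq}_{\cdot k})$
with $K = \min(l, l')$. The formula indexes both modalities by the same
position, which is only well defined up to the shorter length; running the
sum to $K$ is the literal reading we adopt. Texts with positive relevance
are kept, ordered by relevance (ties broken by GO id) and capped at
`top_k_texts` (default 5) so the attention cost stays linear in practice.
Positional-encoded sequence and selected texts are concatenated and passed
through parameter-free multi-head dot-product attention,

$$\mathrm{Attention}(X) = \mathrm{softmax}\!\left(\frac{X^\top X}{\sqrt{d_h}}\right) X,$$

with 8 heads realized as contiguous $d/8$ row slices ($d_h = d/8$), followed
by a position-wise feed-forward network ($d \to 2d \to d$, rectified linear)
with a residual connection. The input serves as query, key and value; the
learnable capacity lives in $P$ and the FFN. Concatenations longer than 512
positions are split into fragments attended independently; a text block
never straddles a fragment boundary. Dropout 0.3 is applied to the
attention output during training only.

**Taxonomy encoding.** The fused residue-level features are mean-pooled
over all positions to a protein-level vector $x^{pro}$, then mixed with a
learned species embedding (label encoding: a $(n_{species}+1) \times d$
table, row 0 reserved for unknown species):

$$x^{mix} = \mathrm{LE}(species) \cdot w_{tax} + x^{pro}, \qquad w_{tax} = 0.1.$$

Only the leaf (species) rank is encoded. $w_{tax} = 0$ reproduces the
taxonomy-off ablation bitwise.

**Graph-convolution head.** The label space is pruned by annotation
frequency (below), and the retained DAG is summarized by the symmetric
normalized adjacency $\hat A = D^{-1/2}(A + I)D^{-1/2}$ over the undirected
union of `is_a` and `part_of` edges — the standard self-looped
graph-convolution normalization; its spectrum lies in $[-1, 1]$. Scores are

$$F(x^{mix}) = \sigma\!\left(\hat A\,(\sigma_1(x^{mix} W_1 + b_1) W_2 + b_2)\, W_A\right),$$

with $\sigma_1$ rectified-linear, hidden width $2d$, and a dense
$\gamma \times \gamma$ mixer $W_A$. For batched input the printed form is
dimensionally ambiguous; $\hat A$ must act on the label axis to use the GO
subgraph, so we right-multiply the $b \times \gamma$ logits by $\hat A$ and
then by $W_A$, keeping $b_2$ inside the convolution per the printed
parenthesization. The convolution is applied once. `W_A` is initialized at
the identity plus small noise so early training approximates the graph-free
baseline; $W_1, W_2$ use Kaiming-style initialization.

**Training.** All learnable parts — $P$, the FFN, the taxonomy table and
the head — are optimized jointly by Adam ($\beta_1 = 0.9$, $\beta_2 =
0.999$, $\varepsilon = 10^{-9}$) on element-wise binary cross-entropy,
batch size 16, 30 epochs, initial learning rate $2 \times 10^{-4}$ decayed
by 0.6 every 5 epochs (a `variant = "small"` schedule, $4 \times 10^{-5}$
decayed by 0.5, matches the recipe used for the largest embedders).
Gradients are exact backpropagation through the fusion stack; the hard text
selection is treated as non-differentiable (the filter decides *which*
texts contribute, the gradient flows through the contribution itself).
Whether the projection is trained jointly or separately was an open choice;
we train jointly end-to-end, which lets the relevance filter improve as $P$
aligns the two spaces. One model is trained per aspect.

## Label-space construction

Terms annotated fewer than `threshold` times are pruned (default 21, which
is about 0.015% of the CAFA5 cohort of 142,246 proteins;
`auto_threshold()` recomputes the rule for any cohort size). A pruned node
is *contracted*, not deleted: its parents are connected to its children, so
ancestor reachability between retained terms is exactly preserved — an
induced subgraph would fragment the DAG and starve the graph convolution of
structure. This is verified against a brute-force transitive-closure oracle
in the test suite. Annotations to pruned terms are dropped rather than
remapped to ancestors; column order is deterministic (lexicographic by GO
id). True-path propagation of annotations is available
(`build_label_matrix(..., propagate = TRUE)`) but off by default, since
curated label files are conventionally pre-propagated and the reference
per-aspect counts cannot disambiguate whether counting preceded
propagation.

## Evaluation

`fmax()` sweeps thresholds over $0.01, 0.02, \ldots, 1.00$ (the CAFA
convention): precision is averaged over proteins with at least one
prediction at $\tau$, recall over all proteins with at least one true
label, and ties in $\tau$ break toward the smaller threshold. Example-based
F1 and micro MCC are evaluated at the fixed operating point $\tau = 0.5$
(the operating threshold is not standardized; 0.5 is the conventional
choice and is exposed as an argument). A protein with an empty prediction
*and* empty truth contributes F1 = 1 (configurable). AUPR is
micro-averaged over all protein–term pairs with step-wise (non-trapezoid)
integration, robust under the extreme label sparsity of GO prediction.

`pair_matching_rate()` cross-checks predictions against an external
interaction-confidence table: proteins with per-protein precision
$\geq 0.75$ at $\tau = 0.5$ are paired when the Jaccard similarity of
their positive predicted term sets is $\geq 0.70$ ("70% shared terms" does
not name a coefficient; Jaccard is the natural reading on positive sets),
and a pair counts as matched at confidence $\geq 70$ on the 0–99.9 scale.
The precision floor's threshold is likewise unstated upstream; we use
$\tau = 0.5$ and flag it in the output.

## The synthetic generator

`generate_cohort()` plants exactly the structure the three modules exploit,
and nothing else:

* labels are drawn by sampling leaf terms of a random rooted DAG and
  propagating to ancestors, so they are true-path-consistent — the graph
  smoothing presupposes hierarchical coherence and the generator must not
  contradict it;
* per-residue sequence embeddings are a broadcast linear image
  $s \cdot G y$ of the label vector plus i.i.d. Gaussian noise (one mixing
  matrix $G$ per cohort);
* term texts tilt toward their own column of $G$ through a fixed
  down-projection, so the cosine filter has genuine signal to find;
* a `taxonomy_effect` fraction of leaf terms is up-weighted (factor 4) in
  the species that favors them, giving the species code weak label
  information.

Defaults — 500 proteins, 30 terms per aspect, $d = 64$, $d' = 48$, residue
lengths uniform on 20–60, text lengths on 5–15, signal strength 5, unit
noise, text relevance 0.8, taxonomy effect 0.2, 6 species — are sized so a
full train-plus-evaluate cycle runs in about a minute on one CPU; these are
the reference conditions for the regression bounds in the test suite. What
the generator does *not* emulate: real ESM/BERT embedding geometry,
amino-acid composition, realistic GO topology beyond the rooted-DAG shape,
or annotation incompleteness. A passing suite therefore demonstrates that
the machinery recovers planted signal of the assumed form, not that it
reaches any particular accuracy on real CAFA data.

On these conditions the held-out micro-AUPR ordering reproduces the
expected module ranking — full model first, then relation-only, text-only,
taxonomy-only, and the bare linear probe — with taxonomy contributing the
least (its information is weak by construction, mirroring the
species-agnostic character of most GO vocabulary).

## Numerical choices

* Softmax rows are stabilized by subtracting the row maximum before
  exponentiation.
* BCE clips scores to $[10^{-12}, 1 - 10^{-12}]$; the loss is finite
  whenever scores are.
* Cosines against zero-norm columns are defined as 0 (logged once per
  session).
* Archives store IEEE doubles little-endian; the write–read round trip is
  bit-exact and seed metadata travels in a JSON sidecar.
* Train/test splitting enforces that every retained term keeps at least
  one positive training example: after the seeded random split, each
  uncovered term's lowest-indexed carrier is moved into train
  (deterministic repair; the principle is stated upstream, the mechanism
  is ours).
* Determinism contract: identical cohort, configuration and seed give
  identical loss traces to $10^{-6}$ and identical checkpoints under a
  fixed thread count.

## Worked example

```{r}
library(gofusion)

ch <- generate_cohort(sim_config(seed = 0))
ann <- ch$annotations[ch$annotations$aspect == "BP", ]
ls <- prune_by_frequency(ch$graphs$BP, ann, threshold = 1)
sp <- split_cohort(ch, test_fraction = 0.1, seed = 0, label_space = ls)

fit <- train_model(sp$train, "BP", label_space = ls,
                   config = train_config(seed = 0))
glance(fit)
ev <- evaluate_model(fit, sp$test)
ev
autoplot(ev)

# ablations: drop any subset of c("text", "taxonomy", "relation")
probe <- train_model(sp$train, "BP", label_space = ls,
                     modules = character(),
                     config = train_config(seed = 0))
evaluate_model(probe, sp$test)$aupr
```

## Known limitations

* The attention is parameter-free by design (no learned Q/K/V maps); a
  learned-projection switch is deliberately not implemented to keep the
  fusion faithful to the published operator.
* `W_A` is dense $\gamma \times \gamma$; at CAFA-scale label spaces
  (thousands of terms) this is memory-hungry — the package targets pruned
  or desk-scale label spaces.
* Only the species leaf rank is encoded; no taxonomy-tree traversal.
* No term-centric or information-accretion-weighted CAFA metrics, and no
  bootstrap confidence intervals.
* LoRA-style fine-tuning of the upstream embedder requires the real PLM
  and is out of scope; configuration keys are reserved but inert.
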