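# gofusion

Multi-modal Gene Ontology (GO) term prediction on top of frozen protein
embeddings.

Protein function annotation via GO terms is a hierarchical multi-label
problem: each protein carries a binary vector over the retained terms of
one GO aspect (BP, MF or CC), and the terms live on an `is_a`/`part_of`
DAG. The dominant recipe is *linear probing*: a frozen protein language
model (PLM) emits per-residue embeddings and only a light head is trained.
`gofusion` augments that recipe with the three other modalities of the GO
knowledge base, each behind its own switch:

* **text alignment** — GO-term descriptions, embedded by any text encoder,
  are selected per protein by mean per-position cosine relevance
  (`cos > 0`, top-k) after a learned projection, then fused with the
  sequence by positional-encoded, parameter-free multi-head dot-product
  attention, `softmax(XᵀX / √d_h) X`, plus a position-wise feed-forward
  network;
* **taxonomy encoding** — a learned species embedding table mixed into the
  pooled protein feature: `x_mix = LE(species)·w_tax + x_pro` with
  `w_tax = 0.1`;
* **GO relation graph** — a two-layer perceptron head whose per-term
  logits are smoothed by one graph convolution over the symmetric
  normalized adjacency `Â = D^{-1/2}(A + I)D^{-1/2}` of the pruned label
  DAG: `scores = σ(Â(σ₁(X W₁ + b₁) W₂ + b₂) W_A)`.

Around the core sit an OBO parser (three GO namespaces, `is_a`/`part_of`
only), frequency-based label-space pruning with path-preserving node
contraction (default threshold 21 ≈ 0.015% of the CAFA5 cohort),
coverage-guaranteed train/test splitting, CAFA-style evaluation (Fmax over
the 0.01-step threshold grid, example-based F1, micro AUPR, micro MCC), a
pair-similarity / interaction matching-rate statistic, ablation and
pruning-threshold sweeps, and a synthetic cohort generator that plants
recoverable signal in all three modalities so the entire pipeline is
testable on a laptop. Everything is trained jointly by Adam on binary
cross-entropy with exact hand-written backpropagation (no GPU, no
autodiff dependency).

Upstream embedders are out of scope by design: embeddings enter through a
portable binary-archive interface with a JSON sidecar, and the bundled
generator stands in for them at desk scale.

## Worked example

```r
library(gofusion)

ch <- generate_cohort(sim_config(seed = 0))        # 500 proteins, 30 terms/aspect
ann <- ch$annotations[ch$annotations$aspect == "BP", ]
ls <- prune_by_frequency(ch$graphs$BP, ann, threshold = 1)
sp <- split_cohort(ch, test_fraction = 0.1, seed = 0, label_space = ls)

fit <- train_model(sp$train, "BP", label_space = ls,
                   config = train_config(seed = 0))
glance(fit)
#> # A tibble: 1 × 7
#>   aspect gamma modules                epochs initial_loss final_loss n_train
#>   <chr>  <int> <chr>                   <int>        <dbl>      <dbl>   <int>
#> 1 BP        30 relation+taxonomy+text     30         1.01      0.170     450

evaluate_model(fit, sp$test)
#> <gofusion_eval> n=50, gamma=30 | Fmax=0.8644 (tau=0.44), F1@0.5=0.8509, AUPR=0.9532, MCC@0.5=0.8169
```

The fitted model halves its training loss many times over (1.01 → 0.17
mean BCE) and recovers the planted signal on the held-out split: Fmax is
the CAFA protein-centric maximum F-measure with its argmax threshold, F1
and MCC are evaluated at the 0.5 operating point, and AUPR is
micro-averaged over all protein–term pairs. Dropping modules
(`modules = c("relation")`, `modules = character()`, ...) reproduces the
ablation variants; `ablation_sweep()` runs all eight switch subsets, and
`autoplot()` / `tidy()` / `glance()` work on both fits and evaluation
reports. A thin command-line front end over the same functions ships in
`inst/cli/gofusion.R` (subcommands `simulate`, `train`, `evaluate`,
`prune-sweep`, `ablate`, `pair-match`).

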