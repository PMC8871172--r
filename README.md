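# fgir — global–local aware features for fine-grained image retrieval

Fine-grained image retrieval must return images of the same *subordinate*
category as the query — the same bird species, dog breed, or aircraft
model — not merely the same super-category. The regime is hard because
interclass distinctions are small while intraclass variance is large, and
it defeats representations built from either a global view or isolated
local parts alone.

`fgir` implements an unsupervised two-stream representation computed from
the activation tensor `T` (`h × w × d`, non-negative) that a rectified
convolutional layer produces for an image:

* **Global stream.** Sum `T` over channels into the `h × w` *aggregation
  map* `A`; threshold it strictly at its mean `δ` (`A'[i,j] = 1` iff
  `A[i,j] > δ`); flood-fill `A'` and keep the largest connected component
  as the salient object; max+avg pool the selected deep descriptors into
  `f_G` (length `2d`).
* **Local stream.** Binarize each of the `d` feature maps at its own mean;
  treat each feature map as a *transaction* whose *items* are its activated
  spatial positions; mine frequent co-activation patterns with an FP-tree
  and FP-growth at a minimum support count `minsupp`; max+avg pool the
  descriptors at the union of maximal-pattern positions into `f_L`
  (length `2d`). Co-activated positions capture part constellations (beak
  with tail with feet) that discriminate between visually close classes.
* **Retrieval.** Aggregate `F = f_G + α·f_L`, rank a database by cosine
  similarity `S(F_Q, F_D) = F_Qᵀ F_D / (|F_Q||F_D|)`, and evaluate with
  mean average precision, `mAP = (1/Q) Σ_q AP(q)` and
  `AP = (1/R) Σ_k p(k)·rel(k)`, under a leave-one-out protocol.

The package is backbone-agnostic: any callable mapping an image to a fixed
`h × w × d` non-negative tensor can stand behind the pipeline (the
reference configuration is the last pooling layer of a VGG-16-class
network, `7 × 7 × 512`). It ships a weight-free deterministic synthetic
backbone, a plain-text tensor store for precomputed activations, a
deterministic synthetic-scene generator (planted salient blobs, planted
co-activation sets, background clutter with bounded item support), a
brute-force mining oracle, and command-line entry points.

## Worked example

```r
library(fgir)

corpus <- generate_corpus(n_classes = 4, n_per_class = 5,
                          shape = c(7, 7, 64), seed = 1)
#> <synthetic_corpus: 20 image(s), 4 class(es), 7 x 7 x 64 tensors>

tensor <- corpus$tensors[["class01_img01"]]
fG <- global_feature(tensor)
attr(fG, "region")
#> 0 3 8 9 10 15 16 17          # flat ids of the salient component

mine_patterns(build_transactions(tensor), minsupp = 4, mode = "maximal")
#> <pattern_set: 1 maximal frequent pattern(s), support mask of 10 position(s)>
#>   {0,3,8,9,10,15,16,17,39,44}: 8

fL <- local_feature(tensor, minsupp = 4)
F  <- aggregate_features(fG, fL, alpha = 1)   # length 2d = 128

index <- build_index(corpus$tensors, corpus$labels,
                     mode = "global_local", minsupp = 4)
evaluate_index(index)
#> <eval_report: mAP = 1.0000 over Q = 20 queries (mode 'global_local')>

run_ablation(corpus$tensors, corpus$labels, minsupp = 4, alpha = 1)
#>           mode       map
#> 1     original 0.3595704
#> 2       global 0.5436206
#> 3        local 1.0000000
#> 4 global_local 1.0000000
```

Reading the numbers: the mined maximal pattern is the class's planted
co-activation set (positions 39 and 44) joined with the shared salient
blob, at its exact channel support (8). On this corpus — classes differ
*only* in their part co-activation sets, under heavy background clutter —
plain full-grid pooling (`original`) is badly corrupted by clutter, the
global stream recovers the shared object but little class identity, and
the pattern-mined local stream separates the classes; the aggregate keeps
that advantage.

## Command line

A thin wrapper over the exported functions lives at
`system.file("cli/fgir.R", package = "fgir")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fgir.R", package="fgir"))')" \
    index --tensors tensors.txt --labels labels.tsv --out index.tsv --minsupp 4
# likewise: query, evaluate, ablate, mine  (see --show-config)
```

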