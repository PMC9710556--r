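# orgeval

Evaluation metrics for multi-channel predictions of subcellular
organization ("in silico labeling"). When a separate model predicts each
organelle's fluorescence channel from a shared transmitted-light image,
pixel losses alone cannot tell you whether the predicted organelles
(a) overlap each other in ways real organelles cannot, or (b) have the
right shapes and positions. `orgeval` quantifies both.

**For whom:** computational microscopists and method developers who train
label-free prediction or generative cell models and need quantitative,
calibrated criteria beyond MSE.

## What it computes

* **Exclusivity** (pixel level): the mean margin between the highest and
  second-highest predicted channel value — overall, per organelle
  (restricted to that organelle's argmax pixels, `NA` when it is never the
  argmax), and for each directed organelle pair. Plus the matching loss
  term for retraining, `-mean(|pred - others_max|)`, the combined loss
  `base + p * ExcLoss`, the exclusivity/MSE ratio criterion for choosing
  `p`, and the decreasing-exclusivity retraining order.
* **Shape divergence** (object level): organelle instances are fitted with
  real spherical-harmonic surface descriptors (order 31 by default, with
  ellipsoidal parameter normalization and degree-weighted ridge
  regularization), pooled, reduced by PCA to 3 components, and compared by
  the k-NN purity score
  `mean( p_i log(p_i/q) + (1-p_i) log((1-p_i)/(1-q)) )` (nats), where
  `p_i` is the fraction of object *i*'s k nearest neighbours from
  population 1 and `q = m/(m+n)`; significance by label permutation.
* **Spatial divergence**: object centroids mapped into a unit-sphere cell
  frame (nuclear centroid → centre, membrane → radius 1, major-axis
  alignment), Gaussian-kernel densities on the ball, and KL divergence
  between populations.
* **Segmentation agreement**: simple threshold/26-connectivity instance
  segmentation, image-wise Jaccard similarity, object counts, and
  Hausdorff-distance QC of every surface fit.
* **Synthetic 3D cells**: a seeded generator of cells, nuclei, organelle
  instances and rendered channels with controlled shape (elongation shift
  δ), placement (Beta radial profiles), blur, crosstalk and noise — with
  full ground-truth bookkeeping, so every metric above is tested as
  parameter recovery.

## Worked example

```r
library(orgeval)

# simulate a ground-truth cell and a degraded "prediction"
cell <- simulate_cell(simulate_config(), seed = 7)
pred <- simulate_prediction(cell$truth, blur_sd = 0.3, crosstalk = 0.2,
                            noise_sd = 0.01, seed = 3)

exclusivity_report(pred)
#> <exclusivity_report> 3 channels, 73728 pixels
#> overall exclusivity: 0.01679 (pixel-intensity units)
#> # A tibble: 3 x 3
#>   organelle exclusivity occupancy
#>   <chr>           <dbl>     <dbl>
#> 1 orgA           0.0225     0.358
#> 2 orgB           0.0131     0.317
#> 3 orgC           0.0142     0.325

overall_exclusivity(cell$truth)
#> [1] 0.02746027
```

The degraded prediction keeps only ~61% of the truth's overall exclusivity
— exactly the kind of organelle confusion the metric is built to expose.
Crosstalk mixing is monotone by construction: at mixing fractions 0, 0.2,
0.4, 0.6 the overall exclusivity of this cell is 0.0275, 0.0192, 0.0110,
0.0027.

The object-level half in one flow:

```r
pop   <- simulate_population(simulate_config(), 5, seed = 2024)
preds <- lapply(1:5, function(i)
  simulate_prediction(pop$truths[[i]], 0.3, 0.15, 0.01, seed = 2024 + i))

report <- run_full_evaluation(preds, pop$truths, pop$records,
                              evaluation_config(L = 15, seed = 17))
tidy(report)     # per-organelle tibble: exclusivity, MSE, Jaccard,
                 # object counts, shape divergence + permutation p,
                 # spatial KL, QC pass rate
autoplot(report) # shape-vs-spatial divergence summary scatter
```

A thin command-line wrapper over the same functions ships in
`inst/cli/orgeval.R` (subcommands `simulate`, `exclusivity`, `segment`,
`jaccard`, `shape-div`, `spatial-div`, `evaluate`).

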