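# mwfnet — multi-view gated fusion classification of 3D neuron morphologies

Neuronal cell types are distinguished to a large extent by the shape of
their arbors — apical trunks, tuft density, local plexus structure. Digital
reconstructions (the 7-column SWC text format: id, type, x, y, z, radius,
parent) describe an arbor as a sparse 3D tree, which is awkward input for
volumetric classifiers. `mwfnet` classifies a neuron from multiple 2D binary
projections instead, for researchers who need a reproducible, CPU-friendly
morphology classifier and a fully synthetic benchmark to validate it on.

## Method

For a reconstruction with nodes $V = \{v_1,\dots,v_n\}$:

1. **Projection.** PCA-align the coordinates into a canonical frame
   (deterministic skewness-based sign convention), then for
   $\theta_k = k\varphi$, $k = 0,\dots,\lfloor 360/\varphi\rfloor - 1$
   (default $\varphi = 45^\circ$, so $N = 8$ views) rotate about the
   $y$- then $z$-axis by $\theta_k$ and rasterize the x–y projection as a
   binary image of nodes plus 8-connected child–parent strokes.
2. **View encoding.** A shared convolutional backbone maps each view to a
   feature map $F \in \mathbb{R}^{C\times H\times W}$; learned
   generalized-mean pooling
   $f_c = \big(\frac{1}{|\chi_c|}\sum_{x\in\chi_c} x^{p_c}\big)^{1/p_c}$
   ($p$ learnable, init 3; $p{=}1$ is average pooling, $p\to\infty$ max
   pooling) plus batch normalization yields a descriptor per view.
3. **Gated view measurement (GVMM).** Each view's raw map is min–max
   normalized and thresholded at $T_1 = 0.9$; a small head reduces the
   salient map to a scalar $s$, and the view weight is
   $d = \sigma(\log|s|) \in (0,1)$.
4. **Gated view enhancement (GVEM).** A row-softmax similarity matrix
   $a_{ij} = \mathrm{softmax}_j(L_1(x_i)^\top L_2(x_j))$ is gated at
   $T_2 = 0.8$: high-similarity pairs are suppressed ($e^{-a}$),
   low-similarity pairs amplified ($e^{a}$), renormalized, and mixed into
   enhanced descriptors $X' = A' L_3(X)$.
5. **Fusion and classification.** The instance descriptor $X_t = D X'$
   (weighted sum over views, with residual batch normalization) feeds two
   200-unit fully connected layers and a softmax over classes;
   training is Adam on cross-entropy (learning rate 0.001, batch 16).

The training engine — convolution, pooling, both gates, fusion, classifier —
is implemented in base R with hand-derived exact gradients (validated
against finite differences in the test suite). A synthetic morphology
generator with class-dependent branching statistics makes the whole pipeline
trainable and testable without any downloads.

## Worked example

```r
library(mwfnet)

cfg   <- mwfnet_config(image_size = 64, epochs = 10, batch_size = 8)
ds    <- make_dataset("separable-3", per_class = 10, seed = 1)
views <- project_dataset(ds, cfg)

test  <- kfold_split(ds$labels, folds = 5, seed = 1)[[1]]
train <- setdiff(seq_along(views), test)
fit   <- mwfnet(views[train], ds$labels[train], cfg, seed = 1)
print(fit)
#> Multi-view gated fusion neuron classifier (mwfnet)
#>   views: 8 (phi = 45 deg), descriptor channels: 16
#>   modules: GVMM on, GVEM on, residual on
#>   classes: bushy, sparse, tufted
#>   trainable parameters: 51,965
#>   final training loss: 0.0168 (10 epochs)

evaluate_mwfnet(fit, views[test], ds$labels[test])
#> accuracy 0.8333   macro-F1 0.8222   (n = 6)
#> per-class F1:
#>  bushy sparse tufted
#> 0.8000 1.0000 0.6667
#> confusion matrix (rows = truth):
#>         predicted
#> truth    bushy sparse tufted
#>   bushy      2      0      0
#>   sparse     0      2      0
#>   tufted     1      0      1

round(mwfnet_forward(views[[test[1]]], fit), 3)
#>  bushy sparse tufted
#>  0.026  0.594  0.380
```

The fitted object prints its module toggles and parameter budget; the
evaluation report gives overall accuracy, per-class and macro F1 and the
confusion matrix (row sums are the per-class test counts). The last call
shows the class-probability vector for one held-out neuron — here a
`sparse` cell correctly receiving the highest probability. Training on six
neurons per class for ten epochs is deliberately small; `mwfnet_cv()` with
30 neurons per class and 18 epochs (the shipped study conditions) reaches
mean 10-fold accuracy around 0.97 against a chance level of 0.33.

Module ablations (`ablate_mwfnet()`), manual view weights
(`mwfnet_config(manual_weights = ...)`), threshold sweeps over `t1`/`t2`,
and SWC/PNG import-export (`read_swc()`, `write_swc()`, `write_views()`)
are documented on their help pages. A thin command-line front end with
`synth`, `project`, `train` and `evaluate` subcommands ships in
`inst/cli/mwfnet.R`.

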