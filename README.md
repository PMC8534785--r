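# attnvgg

Benign-versus-malignant classification of breast-ultrasound lesions with
an attention-gated VGG16 and a cross-entropy + log-cosh ensemble loss —
implemented entirely in R on BLAS-backed matrix operations (no
deep-learning framework), with a synthetic speckle-phantom generator so
the whole pipeline runs end to end without any imaging data.

The package is for people who want to study, test or teach this model
family — the additive attention gate, the ensemble objective, and the
six-metric evaluation protocol — on a single CPU with fully reproducible
runs.

## The model

A 13-conv VGG16 backbone (3×3 kernels, ReLU, stride-2 max-pool per
block). An additive attention gate takes the block-4 features *x*
(16×16 at a 128-px input) and the coarser block-5 pool output *g* (4×4)
and computes per-pixel coefficients

    A_i = ψᵀ ReLU(W_xᵀ x_i + W_gᵀ g_i + b_g) + b_ψ,   δ_i = sigmoid(A_i) ∈ [0, 1]

which rescale the features, `x̂_i = δ_i · x_i`. The gated map is fused
with the upsampled context, global-average pooled and classified by a
10-unit dense head with dropout and a 2-way softmax.

Training minimises the weighted ensemble

    L = α·L_CE + β·L_logCosh,   L_CE = −Σ y log ŷ,  L_logCosh = Σ log cosh(ŷ − y)

with α = β = 0.5, optimised by RMSprop with time-based learning-rate
decay. Evaluation reports sensitivity, specificity, precision, accuracy,
F1 and the Matthews correlation coefficient from the confusion matrix
(malignant = positive class).

## Worked example

`separable_benchmark()` runs the whole pipeline — phantom generation,
stratified 75/10/15 split, train-set z-scoring, desk-profile training of
the attention model with the CE-logCosh loss, test evaluation:

```r
library(attnvgg)
bench <- separable_benchmark(seed = 1)
bench$fit
#> <attnvgg_fit> 30 epochs, best val accuracy 1 (epoch 30), loss ce_logcosh
bench$test$metrics
#> # A tibble: 1 × 6
#>   sensitivity specificity precision accuracy    f1   mcc
#>         <dbl>       <dbl>     <dbl>    <dbl> <dbl> <dbl>
#> 1        0.75       0.875     0.857    0.812   0.8 0.630
bench$test$confusion
#> Confusion matrix (positive class: malignant)
#>            predicted
#> truth       malignant benign
#>   malignant         6      2
#>   benign            1      7
```

(Output from a run of this exact script.) The model reaches perfect
validation accuracy within 30 epochs; on the 16 held-out test phantoms it
detects 6 of 8 malignant lesions (sensitivity 0.75) with one false alarm,
a truth/prediction correlation (MCC) of 0.63 — at this deliberately tiny
scale single test images move the metrics by ~0.06. `autoplot(bench$fit)`
draws the loss/accuracy curves, `plot_attention(bench$fit, img)` the
gate's coefficient map, and `compare_grid()` reproduces the
2-model × 3-loss comparison table. The individual stages
(`generate_dataset()`, `split_dataset()`, `prepare_samples()`,
`compute_normalization()`, `build_model()`, `train_model()`,
`evaluate_model()`) compose the same pipeline piecewise; see the methods
vignette — in particular, from-scratch desk-scale training wants z-scored
inputs, not per-image min-max.

A command-line wrapper ships in `inst/cli/attnvgg`
(`generate` / `train` / `compare` subcommands).

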