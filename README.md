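# palpebral

Non-invasive hemoglobin (Hb) estimation from eye photographs, at desk
scale, fully tested. The palpebral conjunctiva — the capillary-rich lining
of the everted lower eyelid — pales as blood Hb falls; this package
implements the two-stage pipeline that turns that observation into a
quantitative estimator:

1. **Causal region extraction.** Only conjunctival pixels are causally
   related to Hb; sclera, pupil, lashes and skin correlate with it only
   through the patient. The image is restricted to the eyelid region via a
   binary mask (`apply_mask()`, modes `zero-background` / `bbox-crop` /
   `masked-crop`). Masks come from the simulator's ground truth, PNG
   files, or any external instance segmenter; mask quality is scored with
   AP/AR at IoU thresholds 0.50–0.95 and mIoU (`evaluate_segmentation()`).

2. **Label-distribution regression.** The scalar label y ∈ [6, 18] g/dL is
   encoded as a discrete Gaussian over a support grid k₁ < … < k₁₅
   (centers of 15 bins on [5, 20]):

       p_k(y, σ) ∝ exp(−(k − y)² / 2σ²),   Σ_k p_k = 1

   A compact SE-headed CNN (`hb_ldl()`) ends in a 15-way softmax p̂ and is
   trained with the composite loss

       ℓ = Σ_k p_k ln(p_k / p̂_k)  +  λ·|ŷ − y|,   ŷ = Σ_k k·p̂_k

   by SGD (momentum 0.9, weight decay 5e-4, batch 64, LR 0.01) with early
   stopping on validation MAE. Predictions are decoded by expectation, so
   they always lie inside the support interval.

Because clinical eyelid datasets are private, a synthetic simulator
(`generate_dataset()`) with ground-truth masks stands in: eyelid redness is
a noisy linear function of Hb (the causal signal), while distractor-region
color tracks Hb only through a configurable confound. That makes the
central claim — masked inputs generalize better than whole images —
checkable against known ground truth. SMOTE balancing for the skewed label
(`smote_balance()`), regression metrics with bootstrap CIs
(`regression_metrics()`, `bootstrap_ci()`), stratified k-fold CV
(`kfold_evaluate()`), color-feature baselines (`fit_baseline()`), and a
three-arm input ablation (`run_ablation()`) complete the pipeline.

The CNN (including its backward pass) is written in vectorized base R —
im2col gathers plus BLAS matrix products — and its gradients are verified
against finite differences in the test suite.

## Worked example

```r
library(palpebral)

cfg <- simulator_config(noise_sd = 2, confound_strength = 0.5, seed = 7)
ds  <- generate_dataset(260, cfg)
x   <- palpebral:::prepare_inputs(ds, "masked-crop", 64L)  # masked inputs

fit <- hb_ldl(x[1:200, , , ], ds$hb[1:200],
              x_val = x[201:260, , , ], y_val = ds$hb[201:260],
              epochs = 40, seed = 1)
print(fit)
#> Label-distribution hemoglobin regressor (hb_ldl)
#>   network: 4 conv blocks, channels 8/16/32/64, SE reduction 4, 15-way head
#>   support: [5, 20] in 15 bins; sigma = 1, lambda = 1
#>   trained 40 epochs (best at 37), final train loss 2.2563

pred <- predict(fit, x[201:260, , , ])
bootstrap_ci(ds$hb[201:260], pred, seed = 1)
#> R2   0.494 (0.353, 0.565)
#> EVS  0.527 (0.467, 0.575)
#> MAE  1.116 (0.899, 1.367)

round(head(cbind(truth = ds$hb[201:260], predicted = pred), 4), 2)
#>      truth predicted
#> [1,] 16.05     13.49
#> [2,] 13.72     12.75
#> [3,] 11.95     12.11
#> [4,] 13.20     12.65
```

Read: on 60 held-out synthetic eyes, the model explains about half the
label variance and is off by ~1.1 g/dL on average after a 40-epoch run on
200 training images; the per-eye rows show truth against the decoded
expectation. Larger training sets and the default 80-epoch budget push
held-out R² to ≈ 0.95 under the same low-noise conditions (that run takes
a couple of minutes; see the vignette for the study conditions).

`summary(fit)`, `residuals(fit)`, `plot(fit)` (training curves),
`predict(fit, type = "distribution")` (per-image label distributions) and
`simulate(fit, newdata = ...)` (draws from those distributions) behave as
for any fitted R model.

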