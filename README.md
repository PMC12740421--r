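# lungfuse

Multimodal dynamic fusion for COPD risk prediction in R.

Early chronic obstructive pulmonary disease (COPD) hides from any single
data source: spirometry (FEV1/FVC) misses early structural lesions, chest
imaging misses functional decline, and environmental exposure (PM2.5) is
informative but indirect — and often simply missing from the record.
`lungfuse` implements, end to end and in pure R, a fusion architecture for
binary COPD risk stratification from three modalities, together with a
synthetic case-control cohort generator so the whole pipeline trains,
evaluates and reproduces at desk scale on one CPU.

The architecture has three authored components:

* **Dual-tower contrastive alignment** — a convolutional image tower and an
  MLP tower over the encoded clinical record are projected into one shared
  space, L2-normalized, and trained with a symmetric temperature-scaled
  InfoNCE objective over the batch cosine-similarity matrix
  (`similarity_matrix()`, `contrastive_loss()`, temperature `T = 0.05`), so
  matched image/tabular pairs agree.
* **Conditional WGAN-GP imputation** — a generator maps (clinical
  condition, noise) to (PM2.5, exposure years); a critic scores
  (condition, environment) pairs under the Wasserstein objective with
  gradient penalty (`gradient_penalty()`, coefficient 10). Masked
  environmental cells are filled with (multiple-)imputation draws
  (`train_cgan()`, `impute_environment()`).
* **Dynamic gating fusion** — an MLP gate on the clinical vector emits
  per-patient softmax weights over the CT, lung-function and environment
  embeddings (`gating_weights()`, hidden width `h = 128`); fusion is the
  convex combination (`fuse_features()`) ahead of a linear risk head.

Training (`train_mmdf()`) minimizes
`L_total = L_cls + 0.5 * L_contrast + 0.2 * L_WGAN` and logs the breakdown
per epoch. The experiment harness mirrors a clinical evaluation:
`evaluate_metrics()` (rank AUC with tie-halving, sensitivity/specificity at
a Youden threshold), `run_ablation()` (drop the contrastive term, the
generative imputer, or the gate), `run_modality_baselines()` (all fusion
weight forced onto one modality), and `subgroup_weight_report()` (learned
weights by smoking status, disease stage, or PM2.5 >= 40 µg/m³).

## Worked example

```r
library(lungfuse)

spec <- cohort_spec(n_copd = 80, n_control = 80, env_missing_rate = 0.25,
                    seed = 7)
cohort <- generate_cohort(spec)
dplyr::count(cohort, label, stage)
#>   label   stage        n
#> 1 control none        80
#> 2 COPD    mild        34
#> 3 COPD    moderate    31
#> 4 COPD    severe      15

cfg <- mmdf_config(epochs = 30, seed = 1, gan_iters = 200,
                   gate_warmup = 10, equalize_levels = 64)
model <- train_mmdf(cohort, cfg,
                    img_params = image_params(height = 32, width = 32))
model
#> <mmdf_model> d=64, tower=tiny, epochs=30, seed=1
#>   final losses: cls 0.3908 + 0.50*con 0.8305 + 0.20*wgan -1.0657 = 0.5929
#>   validation AUC 0.879

evaluate_mmdf(model, cohort, split = "test")
#>     auc sensitivity specificity    f1 precision recall threshold     n
#> 1 0.930         100        87.5 0.941     0.889      1     0.491    32
```

The cohort prints 80 cases split over mild/moderate/severe stages and 80
controls. The trained model reports the per-epoch loss breakdown (the
`-1.07` adversarial term is the generator loss of the environmental GAN,
entering the total with weight 0.2) and held-out discrimination: test AUC
0.930 with sensitivity 100% and specificity 87.5% at the Youden-optimal
threshold 0.491. `subgroup_weight_report(model, cohort, "smoking")` then
shows how the gate distributes modality weight per subgroup, and
`autoplot(model)`, `tidy(model)`, `glance(model)` expose the training trace
in the usual broom/ggplot2 idioms.

A thin CLI over the same functions lives in `exec/lungfuse`
(`generate`, `train`, `ablate`, `report-weights`), writing CSV outputs and a
JSON run-manifest per invocation.

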