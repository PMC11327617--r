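# gliosurv

Multimodal discrete-time survival prediction for glioblastoma in R:
a self-supervised 3D vision-transformer encoder for multi-parametric MR
volumes, cross-attention fusion of the frozen image encoding with clinical
and molecular-pathologic covariates, and a DeepHit-style discrete-time
survival head that outputs each patient's individual survival function.
The package is aimed at methods researchers in neuro-oncology and
biostatistics who want a fully inspectable, CPU-scale implementation of
this model class together with the evaluation machinery needed to judge it.

## What it implements

* **Discrete-time survival head.** Five time bins bounded by the
  {10,30,50,70,90}th percentiles of the training survival times plus a
  beyond-horizon cell; a single softmax over cells gives the cumulative
  incidence F̂ and survival S(t) = 1 − F̂(t), linearly interpolated to
  monthly resolution (1 month = 30.44 days). Training minimizes a
  likelihood term (right-censoring aware) plus a pairwise ranking term
  exp{−(F̂ᵢ(bᵢ) − F̂ⱼ(bᵢ))/σ} over acceptable pairs.
* **Self-supervised image encoder.** A small 3D ViT pretrained with two
  proxy tasks on two augmented views per volume (random patch swapping +
  cutout): context restoration (mean absolute voxel error of a linear
  decoder) and NT-Xent contrastive learning on pooled projections, combined
  as `rec + λ·con·rec` by default. The trained encoder is frozen downstream.
* **Cross-attention fusion.** softmax(QαKβᵀ/√d_k)Vβ applied twice (each
  modality enriched by the other), a final attention with the clinical
  projection as query over the concatenated sequences, attention pooling,
  and two fully connected output layers.
* **Evaluation suite, from scratch.** Antolini time-dependent concordance
  (Ctd), Graf censoring-weighted Brier scores and their integral (IBS),
  Kaplan–Meier, the two-group log-rank test, a Breslow-tie Cox fit with
  Newton–Raphson, the Grambsch–Therneau Schoenfeld proportionality test,
  and 12-month dichotomization by predicted median survival.
* **Synthetic multimodal cohorts with ground truth.** Clinical covariates
  with stated log-hazard-ratio effects, volumes whose lesion volume
  fraction carries survival signal, discrete-time hazards and independent
  calibrated censoring — plus the Bayes-optimal oracle Ctd computed from
  the true hazards, so model recovery can be measured against a ceiling.

Everything neural runs on a compact reverse-mode autodiff core over base-R
matrices that ships inside the package; there is no deep-learning runtime
in the dependency list.

## A worked example

Generate a small multimodal cohort, run the two-stage pipeline
(pretrain → freeze → survival training) and read the held-out report:

```r
library(gliosurv)

cfg <- experiment_config(
  n_subjects = 200, modality = "multimodal",
  volume_shape = c(32, 32, 32),
  seed_data = 11, seed_model = 1,
  pretrain = list(epochs = 4, batch_size = 8, lr = 1e-3))
ex <- run_experiment(cfg)

ex$test_report$ctd    # time-dependent concordance on the held-out split
ex$test_report$ibs    # integrated Brier score over the monthly grid
round(ex$model$log$val_ctd, 2)  # validation concordance per epoch
```

On the synthetic benchmark the acceptance script runs (seed 1, a
400-subject cohort of 32³ volumes: 200 subjects for modeling, 200 for
evaluation; survival-model results are 3-seed medians), the pipeline
prints:

```
ctd_clinical        0.584     # clinical covariates only
ctd_multimodal      0.624     # + frozen self-supervised image encoding
ctd_oracle          0.712     # Bayes-optimal ceiling from the true hazards
ibs_multimodal      0.209
probe_r2_pretrained 0.973     # lesion-size linear probe, pretrained encoder
probe_r2_random     0.716     # same probe, random-init encoder
```

Read: fusing the frozen image encoding with the tabular covariates lifts
test concordance by ~0.04 toward the oracle ceiling, and the
self-supervised encoder carries substantially more linearly readable lesion
information than a random one — the two qualitative claims at the heart of
the model, reproduced end to end on a cohort with known ground truth.

Individual survival curves come from `predict_survival()`:

```r
p <- predict_survival(ex$model,
                      X = ex$X[1:2, , drop = FALSE],
                      img_tokens = ex$img_tokens[1:2])
p$monthly   # one row per subject: S at months 1, 2, ... up to the horizon
```

A thin command-line front end for simulation, training and evaluation is
in `inst/cli/gliosurv.R` (`simulate`, `run`, `evaluate` subcommands).

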