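# namts — neural additive models for multichannel physiological time series

`namts` predicts **individual neonatal apnea and hypopnea events** from
multichannel polysomnography, seconds before they occur, with a classifier
that is interpretable by construction. It is aimed at researchers in
neonatal respiratory monitoring and clinical machine learning who need
event-level prediction *and* an account of which signals drove each
prediction.

## The model

Six signal modalities are used: nasal pressure (NP), the standardized sum
of thoracic and abdominal respiratory effort (TA), heart rate (HR),
photoplethysmogram (PPG), SpO₂ and transcutaneous PCO₂. Each modality
`x_i` is a short preprocessed time series feeding its own small
fully convolutional network `f_i`, and the prediction is a **neural
additive model**:

```
p̂ = σ( Σ_i α_i f_i(x_i) + β )
```

Each subnetwork is three blocks of (same-padded 1-D convolution → batch
norm → ReLU, 20 hidden channels), a per-timepoint linear collapse to one
**activation map**, and global average pooling. Two exact identities make
the model interpretable:

* the logit is the sum of per-modality **additive contributions** plus a
  shared bias — the spread of a modality's contributions across windows
  measures its importance;
* each contribution equals the time-mean of that modality's activation
  map, which localizes the discriminative signal segments inside the 30 s
  window.

The task is binary classification of 30-second windows: **targets** end
15 s (the prediction horizon) before an apnea/hypopnea onset; **controls**
lie at least 3 min from every event boundary. Training uses binary
cross-entropy, Adam, 10 epochs, learning rate 1e-4, weight decay 0.01,
with per-patient undersampling of the majority class. Evaluation is
patient-based leave-one-out cross-validation with nested hyperparameter
selection, per-patient permutation tests of AuROC, and Wilcoxon
signed-rank model comparisons. Engineered-feature baselines (logistic
regression and an MLP on 24 time/spectral moment features) and a
non-additive "blackbox" counterpart are included for comparison.

Because the clinical dataset is not bundled, the package ships a
**synthetic cohort generator** that emulates the target regime (six
modalities at native rates 200/50/100/1/2 Hz, tens of clustered events per
hour, pre-event breathing irregularity and SpO₂ dips with configurable
strength and span) so the entire pipeline is testable with known ground
truth. See `vignette("namts-methods")` for the model, the generator and
every numerical choice.

## Worked example

```r
library(namts)

## a small synthetic cohort: 4 patients, 1 h each, strong pre-event signatures
coh <- generate_cohort(cohort_config(n_patients = 4, duration_s = 3600, seed = 11))
ds  <- cohort_window_set(coh$recordings, coh$annotations)  # extract + preprocess
table(ds$label)
#>   0   1
#> 239  34

## leave-one-patient-out evaluation of the NAM
rep <- loocv(ds, "nam", cfg = eval_config(train = train_config(batch_size = 16),
                                          seed = 1))
rep
#> <namts_cv_report> nam, 4 patients: mean AuROC 0.771 (sd 0.191)
rep$per_patient[, c("patient", "auroc", "n_windows", "p_perm")]
#>   patient     auroc n_windows p_perm
#> 1     P01 0.7690909        61  0.006
#> 2     P02 0.5042882        64  0.482
#> 3     P03 0.9340659        92  0.086
#> 4     P04 0.8767677        56  0.001
```

Each per-patient row is that patient's windows scored by a model trained
only on the other patients: AuROC (0.5 is chance), window counts, and the
permutation p-value for better-than-chance performance. Even at this toy
scale (one hour per patient) three of four patients are predicted above
chance; the full desk-scale experiments in `scripts/acceptance.R` use
two-hour recordings, where the mean leave-one-out AuROC rises above 0.95.

For one window, the full interpretability output:

```r
input <- prepare_window(extract_windows(coh$recordings[[1]], coh$annotations[[1]])[[1]])
nam   <- train_model(build_nam(hyperparams(), seed = 1),
                     undersample(ds, seed = 1),
                     train_config(batch_size = 16, seed = 1))
nam_forward(nam, input)
#> <NAM prediction> p = 0.526 (logit 0.105 = bias 0.002 + sum of:)
#>      NP      TA     PPG      HR    SPO2    PCO2
#> -0.1467 -0.0340  0.0850 -0.1622  0.1933  0.1668
```

The probability decomposes exactly into per-modality contributions, each
the time-mean of that modality's activation map; `plot_activation_maps()`
draws the per-timepoint maps behind the traces. A thin command-line
interface (`inst/cli/namts`) exposes the same pipeline as
`simulate / extract / featurize / train / evaluate / explain / run-all`
subcommands driven by a YAML config.

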