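# rfed — robust federated learning for multicenter, class-imbalanced lesion-image prognosis

`rfed` is an R implementation of a personalized federated learning
framework for predicting patient outcomes from lesion images when the data
sit in several hospitals and cannot be pooled. It targets the two failure
modes of naive federated averaging in medical imaging — **inter-center
heterogeneity** (different scanners/protocols make the averaged model worse
than local ones) and **class imbalance** (progression events are a ~20%
minority) — and ships everything needed to study the method end to end on
synthetic multicenter data: the aggregation rule, the losses, the staged
transfer schedule, a trainable CNN engine, a downstream feature-based
classifier, the evaluation metrics, and a seeded image generator.

## The method

Each center *k* keeps two models: a **deputy** `D_k` that talks to the
server and a **personalized** model `P_k` that never leaves the center.

**Fourier-domain partial aggregation.** At round *t* of *T*, clients
upload deputy parameters θ_k; the server computes amplitude/phase spectra
`A_k, P_k = FFT(θ_k)`, averages them bin-wise
(`A_avg = mean(A_k)`, `P_avg = mean(P_k)`), reconstructs
`F_avg = A_avg · exp(i·P_avg)`, and shares only the lowest-frequency band,
whose width grows as

    r(t) = r_max / (T − t),   r_max = 0.3

Each client's new deputy is the inverse transform of the shared low band
plus its **own** high-frequency bins, so most of the model stays local
while a slowly widening common backbone emerges.

**Personalized loss.** With class scores `η_c = W_c·z + b_c` and margins
`η_c/‖W_c‖`, per-class trainable calibration `(ω_c, β_c)` reshapes the
logits to `ω_c·η_c + β_c·‖W_c‖` before the cross-entropy (equal to plain
cross-entropy at ω=1, β=0), counteracting majority-class margin crowding.
An InfoNCE-style term aligns each client's classifier-layer parameters
with the global model's against the other clients' as negatives. The total
loss is `ℓ_MARC + α·ℓ_CPC` with α = 0.6.

**Three-stage transfer.** Knowledge moves P→D (stage I), mutually (II),
then D→P (III), with transitions gated by per-center validation AUC and a
mean-feature distribution-alignment term tying the learner to the frozen
reference. Each center finally deploys whichever of `P`/`D` validates
better.

**Downstream classifier.** Trained models become feature extractors
(spatial mean of every conv channel; 7,616 features for the ResNet-34
topology, 24 for the benchmark CNN), pooled per patient, z-scored,
reduced by greedy minimum-redundancy maximum-relevance selection, and
classified by a Bayesian extreme learning machine (random hidden layer +
evidence-maximized Bayesian ridge on the outputs). Evaluation: ROC AUC
(Mann–Whitney), F1, sensitivity at fixed specificity, and decision-curve
net benefit.

## Worked example

Four synthetic centers (96/224/72/56 patients, 20% progression prevalence,
distinct offset/contrast/noise/blur), 20 communication rounds, the
federated method against plain federated averaging:

```r
library(rfed)

manifest <- generate_multicenter_dataset(default_benchmark_configs(32),
                                         seed = 101, out_dir = "data")
data  <- load_center_data(manifest)
cfg   <- training_config(rounds = 20, seed = 101)

state <- run_federated_training(data, cfg, method = "rfed")
sc    <- federated_scores(state, data)            # per-patient test scores
sapply(split(sc, sc$center), function(s) roc_auc(s$score, s$label))
#>    A    B    C    D
#> 1.00 0.98 1.00 1.00       (mean 0.994)

state2 <- run_federated_training(data, cfg, method = "fedavg")
sc2    <- federated_scores(state2, data)
mean(sapply(split(sc2, sc2$center), function(s) roc_auc(s$score, s$label)))
#> 0.932
```

The per-center AUCs are the probability that a randomly chosen progressing
patient scores above a non-progressing one; the gap to the averaging
baseline is concentrated on the most corrupted center (B), which is where
personalization pays. Across three replicate seeds the method averages
test AUC 0.92 versus 0.886 for federated averaging.

A thin command-line front end over the same functions lives at
`inst/cli/rfed.R`:

```sh
Rscript inst/cli/rfed.R simulate-data --out data --seed 7 --image-size 32
Rscript inst/cli/rfed.R train --manifest data/manifest.csv --out run --method rfed
Rscript inst/cli/rfed.R evaluate --scores run/scores.csv --out run/report.json
```

## Scope

The synthetic benchmark demonstrates the mechanics of the method under
controlled heterogeneity and imbalance at desk scale (32×32 images, a
two-conv CNN). It is not a clinical validation: the clinical cohorts the
method was designed around are private, and their headline numbers are not
reproducible from this package. See `vignettes/rfed-methods.Rmd` for the
models, assumptions, parameter choices and limitations.
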