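# riskseq

Sequence models and relative-contribution statistics for short-horizon
adverse-event prediction from longitudinal EHR-style data.

## The problem

Cohorts defined by a qualifying diagnosis (for example, patients carrying a
dual psychiatric diagnosis) face elevated risk of adverse events — new
diagnoses such as suicide-related events, substance-use disorders,
depression, or death. Two questions matter clinically: *who* is at risk in
the next three months, and *which* recorded factors — medications, abnormal
lab results, diagnoses, individual and neighborhood social determinants of
health (SDoH) — push that risk up or down.

`riskseq` addresses both with one pipeline:

1. **Cohort construction.** From a long event table (one row per
   patient/date/code), every encounter of a case patient whose 90-day
   window captures the first new-onset event becomes a training sample
   (encounter-level augmentation); controls are seeded draws from
   event-free encounters; splitting is 8:1:1 *by patient*.
2. **Encoding.** Multimodal codes become tokens (`DX:`, `RX:`,
   `LAB:<code>:<flag>` for ABNORMAL/HIGH/LOW results only, `SD:` individual
   SDoH, `NB:<feature>:Q<k>` quantile-binned zip-level indices), grouped
   into per-date visits; the vocabulary is built on the training fold only.
3. **Models.** Two recurrent classifiers, written from scratch in
   RcppArmadillo with analytically verified gradients: a stacked LSTM with
   tanh gate activations, and a RETAIN-style two-RNN reverse-time attention
   model producing visit-level attention weights. Adam, early stopping on
   validation loss, fully seeded and bit-reproducible.
4. **Feature screen.** Perturbation (occlusion) contributions per patient,
   and for each feature the relative contribution

       RC = mean(FC | event) / mean(FC | no event)

   with delta-method variance on the log scale
   `Var(ln RC) = (sd_e/m̄_e)²/m + (sd_c/m̄_c)²/n`, 95% CI
   `exp(ln RC ± 1.96·√Var)`, two-sided z-test, and Bonferroni + FDR
   correction. RC > 1 flags risk factors, RC < 1 protective ones.
5. **Synthetic EHR generator.** A seeded simulator with planted
   multiplicative effects (per-90-day-window Bernoulli hazard, 365-day
   lookback) so every stage is testable without any private data.

See `vignettes/riskseq-methods.Rmd` for the models, the statistic, and the
design decisions.

## Worked example

Simulate a 1,000-patient cohort with one planted risk medication (odds 4.0)
and one protective medication (odds 0.25), train the 2-layer tanh-LSTM, and
screen all features:

```r
library(riskseq)

sim <- sim_config(n_patients = 1000,
                  planted_effects = c(RX_RISK = 4.0, RX_PROT = 0.25),
                  seed = 11)
ds <- generate_dataset(sim)

cc <- cohort_config(qualifying_codes = "Q_INDEX",
                    adverse_event_codes = c("AE_A", "AE_B"), seed = 11)
mc <- model_config("tlstm", embedding_dim = 32, hidden_size = 32,
                   num_layers = 2, max_epochs = 20, seed = 11)

res <- run_pipeline(ds$events, cc, mc, sdoh = ds$sdoh, seed = 11)
round(res$fit$test_metrics, 3)
#> auroc precision    recall        f1
#> 0.882     0.921     0.769     0.838
head(res$report[, 1:5], 4)
#>     Feature Name          RC    95%CIup   95%CIdown        FDR_Q
#>           <char>       <num>      <num>       <num>        <num>
#>  1:   RX:RX_PROT  0.13497599  0.2524856 0.072156660 4.213084e-08
#>  2: LAB:L004:HIGH 0.06180262  0.2604047 0.014667799 7.919177e-03
#>  3: LAB:L008:HIGH 0.01621781  0.1430366 0.001838811 7.919177e-03
#>  4:   RX:RX_RISK 10.59938071 42.8899642 2.619420965 2.680194e-02
```

The test AUROC (0.88) measures how well the model separates encounters
followed by an event within 90 days from event-free ones. In the ranked
screen both planted medications surface at FDR q < 0.05 with the correct
direction: the protective one at RC ≈ 0.13 (top of the list), the risk one
at RC ≈ 10.6. Two unplanted abnormal-lab tokens also clear q < 0.05 at this
cohort size — a reminder that the delta-method interval is fragile for
features with very few carriers; at the 3,000-patient scale the acceptance
checks run at, the empirical false-positive rate of outcome-independent
tokens sits near the nominal 5%.

A YAML-driven interface (`rs_simulate()` / `rs_run()` / `rs_report()`) and
a thin command-line wrapper (`inst/cli/riskseq simulate|run|report`) cover
the same pipeline for scripted use.

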