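# bowaves

Interpretable classification of long-term single-channel EEG by
**bag-of-waves** (BOW) features: occurrence counts of short canonical
waveforms learned directly from the signal.

The package is aimed at neurophysiology groups who record hours-to-days
of EEG from individuals (e.g. mouse disease models) and want to ask
whether genotype or phenotype can be read off the recording — and, when
it can, *which waveforms carry the signal*.

## The method

A waveform dictionary $C = [c_1, \ldots, c_K]^\top \in \mathbb{R}^{K
\times P}$ is learned per class by **shift-invariant k-means**: each
$L$-sample window $\tilde{x}_i$ ($P < L$) is assigned to the waveform and
shift maximizing the cosine similarity $\mathrm{sim}(W_\tau(\tilde{x}_i),
c_k)$, and each waveform is updated as the average of its aligned
sub-windows. A recording segment is encoded as the vector of assignment
counts over its non-overlapping windows, concatenated across the
per-class dictionaries, TFIDF-weighted
($w_k = \log\frac{1+N_\mathrm{train}}{1+N_k}+1$) and
$\ell_2$-normalized. Individuals are classified by $\ell_2$-regularized
logistic regression on counts pooled across segments, under a
leave-one-individual-out protocol with nested stratified-group CV for
the regularization strength and two-fold dictionary cross-validation.
Waveform importance is summarized by linear-model Shapley values
$\varphi_k = \beta_k (x_k - \mathbb{E}[x_k])$ and their class-signed
averages across the leave-one-out models (ACSSV); spectral
character comes from Welch spectra of the learned waveforms.

Bag-of-spectra (BOS) and soft-counted waveform (SCW) baseline
featurizations, corrected resampled t confidence intervals, merged
ROC/AUC, combinatorial majority baselines, a synthetic EEG cohort
generator with planted waveforms, and minimal EDF/CSV recording I/O are
included.

## Worked example

Simulate a 12-mouse cohort in which heterozygous and wild-type animals
share two 6/min rhythms and differ only in the rate of one transient
(1.0 vs 0.1 events/min), then run the full two-fold leave-one-out
protocol:

```r
library(bowaves)

bank <- make_waveform_bank(n_transient = 1, n_rhythm = 2, P = 128,
                           rate = 256, seed = 11)
spec <- cohort_spec(
  genotypes = list("A-Het" = list(rates_per_min = c(6, 6, 1.0)),
                   "A-WT"  = list(rates_per_min = c(6, 6, 0.1))),
  subjects_per_genotype = 6, duration = 14400, rate = 256,
  noise_sd = 0.01, one_over_f = 1, seed = 3)
sim <- simulate_cohort(bank, spec)

cfg <- run_config("desk", seed = 5, segments_per_subject = 12, K = 32)
res <- run_split(sim$recordings, sim$cohort, task = "tsc", cfg)
print(res)
#> <split_result> task=tsc: 12 subjects, accuracy 100.0%
confusion_matrix(res$predictions)
#>      predicted
#> true  Het WT
#>   Het   6  0
#>   WT    0  6
```

Every subject is predicted from counts pooled over twelve 10-minute
segments by a model that never saw any of its data (dictionaries from the
other fold, hyperparameter selection and fitting with the subject held
out). Accuracy 100% on 12 subjects says the planted 10× rate difference
in a single transient is recoverable end-to-end; the per-subject
probabilities and selected `C` values are in `res$predictions`.

To see which waveforms carried the decision:

```r
loo0  <- res$by_fold[["0"]]
dicts <- learn_fold_dictionaries(sim$recordings, sim$cohort, 0, cfg)
tab   <- acssv(loo0, "Het", bags_by_subject = res$bags_by_fold[["0"]])
top_waveform_report(tab, n_top = 3, dicts = dicts, rate = 256)
#>   feature acssv mean_coefficient rate_in rate_out positively_correlated
#> 1      21 1.591           110.24   0.554    0.117                  TRUE
#> 2      49 0.698             9.66   4.824    4.825                  TRUE
#> 3      19 0.217            17.28   2.460    2.442                  TRUE
#>   dictionary peak_freq
#> 1      A-Het      12.2
#> 2       A-WT       1.0
#> 3      A-Het       5.0
```

The top-ranked feature is exactly the heterozygous dictionary's
transient-matched centroid (shift-max cosine 1.00 against the planted
transient): highest ACSSV, strongly positive mean coefficient, a 12.2 Hz
spectral peak matching the planted carrier, and an in-class occurrence
rate about five times its out-of-class rate (0.55 vs 0.12 counts/minute;
the planted 1.0 vs 0.1 events/minute, attenuated by windowing and the
assignment floor).

Cohort-composition baselines use only a metadata table. For the bundled
45-mouse TSC1-panel table:

```r
cohort <- tsc_panel_cohort()
100 * naive_majority_loo_accuracy(cohort, "strain", covariate = "sex")
#> [1] 20
100 * naive_majority_loo_accuracy(cohort, "tsc", covariate = "sex")
#> [1] 60
```

i.e. a classifier that only knows each mouse's sex would score 20% on
strain and 60% on disease genotype — reference points that any claimed
EEG signal has to beat.

## Command-line pipeline

A thin Rscript driver (`inst/cli/bowaves.R`) exposes the pipeline stages
`simulate | learn-dict | encode | train | evaluate | interpret` over RDS
artifacts that embed the run configuration; stages refuse to combine
artifacts from different configurations. See the script header for
usage. Run configurations are YAML (`run_config()`,
`read_run_config()`), with `"full"` (full-scale) and `"desk"`
(minutes-scale) profiles.
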