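# cnvlrr

Calling-based versus continuous-intensity association testing at a common
gene deletion, rebuilt as a tested simulation study.

## The problem

Common full-gene deletions — the canonical case is the glutathione
S-transferase mu 1 locus on 1p13.3, homozygously deleted in roughly half of
European-ancestry individuals — are trivially genotyped by targeted assays
(qPCR, MLPA) yet can be *completely invisible* to SNP-array CNV callers. The
failure is in the normalization, not the hidden Markov model. The Log R Ratio

    LRR = log2(R_obs / R_exp)

compares a sample's total probe intensity `R_obs` with the intensity
`R_exp` expected for a two-copy sample, read off per-probe genotype clusters.
When those clusters are fitted from the analysis cohort itself and the cohort
is majority-deleted at the locus, the clusters sit on the deleted samples:
`R_exp ≈ R_obs` for a homozygous-null individual, its LRR lands near 0
instead of the 0-copy state mean −3.53, and the caller reports *zero*
deletions in a cohort where ~91% of samples carry at least one. The signal is
still there, though: regressing disease on the per-probe LRR, or fitting a
CNVtools-style latent-class mixture in which class membership drives a
logistic disease model, recovers the known protective per-copy effect.

This package provides, for anyone studying calling failure at common CNVs:

- `simulate_cohort()` — a case-control cohort (773 cases / 759 controls) at a
  5-probe deletion locus with control genotype-class frequencies
  ≈ 53/38/9% (copy number 0/1/2), two-channel intensities, covariates, and a
  configurable disease model;
- `normalize_intensities()` — theta/R polar transform, per-probe genotype
  cluster models in **cohort** or **reference** mode, LRR/BAF;
- `qc_table()` / `apply_qc()` — the four PennCNV-style sample QC metrics with
  the published exclusion thresholds;
- `call_cnvs()` — a 5-state (0–4 copies) Viterbi caller emitting LRR and BAF,
  with deletion-segment extraction and locus deletion counts;
- `probe_lrr_tests()`, `trend_test()`, `fit_joint_mixture()` — the three
  association strategies, covariate-adjusted, on one IRLS logistic core;
- `run_pipeline()` — the whole comparison end to end, seeded.

## Worked example

The numbered drivers under `analysis/` run the study stage by stage and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # cohort: 1532 samples x 2005 probes
Rscript analysis/02_normalize.R   # cohort- vs reference-mode LRR
Rscript analysis/03_qc.R          # sample QC
Rscript analysis/04_call.R        # HMM deletion calls per mode
Rscript analysis/05_associate.R   # the three association analyses
```

Stage 2 prints the mechanism — mean locus LRR by true copy number:

```
       mode copy_number mean_locus_lrr sd_locus_lrr
     cohort           0         0.0251       0.1384
     cohort           1         2.6371       0.0996
     cohort           2         3.5278       0.1037
  reference           0        -3.4789       0.1459
  reference           1        -0.8509       0.1077
  reference           2         0.0206       0.1083
```

Under cohort normalization the deleted classes are pulled to or above zero
(the null class, 57% of this cohort, sits at +0.03); under reference
normalization the null class sits at the −3.53 state mean. Stage 4 shows the
consequence:

```
cohort mode:    0 of 1532 samples get a locus deletion call
reference mode: 1420 of 1532 samples get a locus deletion call  (every true carrier)
```

and stage 5 the rescue by continuous-signal association (this cohort was
simulated with a protective per-copy odds ratio of 0.74 on disease):

```
       method  predictor    or ci_low ci_high  p_value
 lrr_logistic rs12068997 0.826  0.767   0.888 2.88e-07
 lrr_logistic  rs4147567 0.827  0.769   0.890 3.90e-07
 lrr_logistic  rs1056806 0.828  0.769   0.891 4.94e-07
 lrr_logistic rs12562055 0.827  0.769   0.890 4.06e-07
 lrr_logistic  rs2239892 0.827  0.769   0.890 4.06e-07
        trend      trend 0.655  0.556   0.772 4.17e-07
      mixture    mixture 0.600  0.488   0.737 1.05e-06
```

Every per-probe odds ratio is below 1 (more signal, less disease), the trend
test on reference-called copies estimates the per-copy effect, and the joint
mixture association detects the carrier effect while its maximum-posterior
classes stay ≥ 93% concordant with truth even at the compressed,
realistic-noise signal level (stage 5 prints 98.6% on that fixture).

A single YAML file drives everything; see `inst/config/default.yaml` and
`read_pipeline_config()` / `run_pipeline()` for the one-call version.

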