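#!/usr/bin/env Rscript
# Stage 3: PennCNV-style sample quality control.
#
# Computes the four per-sample metrics (LRR standard deviation, BAF median in
# the heterozygous band, BAF drift, wave factor) on the cohort-mode signal and
# applies the published exclusion thresholds. On the default fixture the
# generator and the thresholds are mutually consistent: essentially every
# sample passes, so the calling contrast of stage 4 is not driven by QC.

library(cnvlrr)

cohort <- readRDS("results/cache/cohort.rds")
signals <- readRDS("results/cache/signals.rds")

qc <- apply_qc(qc_table(signals$cohort, cohort$samples$sample_id))
write.table(qc, "results/03_qc_metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(qc, "results/cache/qc.rds")

message(sprintf("%d of %d samples pass QC (%.1f%%)", sum(qc$pass), nrow(qc),
                100 * mean(qc$pass)))
summary_tbl <- data.frame(
  metric = c("lrr_sd", "baf_median", "baf_drift", "wave_factor"),
  median = sapply(qc[c("lrr_sd", "baf_median", "baf_drift", "wave_factor")],
                  median),
  q99 = sapply(qc[c("lrr_sd", "baf_median", "baf_drift", "wave_factor")],
               quantile, 0.99),
  threshold = c("<= 0.28", "in [0.45, 0.55]", "<= 0.002", "in [-0.04, 0.04]")
)
write.table(summary_tbl, "results/03_qc_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summary_tbl, row.names = FALSE)
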