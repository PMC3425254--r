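#' Sample quality-control thresholds
#'
#' The four exclusion criteria applied to array samples before CNV calling:
#' LRR standard deviation over all probes > 0.28, median BAF outside
#' [0.45, 0.55], BAF drift > 0.002, or wave factor outside [-0.04, 0.04].
#'
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_lrr_sd = 0.28,
                          baf_median_range = c(0.45, 0.55),
                          max_baf_drift = 0.002,
                          wave_factor_range = c(-0.04, 0.04)) {
  stopifnot(baf_median_range[1] <= baf_median_range[2],
            wave_factor_range[1] <= wave_factor_range[2])
  structure(list(max_lrr_sd = max_lrr_sd,
                 baf_median_range = baf_median_range,
                 max_baf_drift = max_baf_drift,
                 wave_factor_range = wave_factor_range),
            class = "qc_thresholds")
}

#' Per-sample quality-control metrics
#'
#' * `lrr_sd`: sample standard deviation of LRR over all probes.
#' * `baf_median`: median BAF over probes in the heterozygous band
#'   (BAF in (0.25, 0.75)); the statistic targets the heterozygote band
#'   center, which should sit at 0.5.
#' * `baf_drift`: mean squared distance of BAF to the nearest canonical
#'   diploid value (0, 0.5 or 1).
#' * `wave_factor`: spread of local LRR level -- the population standard
#'   deviation of per-window median LRR over non-overlapping windows of
#'   `window` probes (trailing probes short of a full window are dropped).
#'   The median summarizes each window robustly, so that a handful of probes
#'   inside a genuine CNV cannot masquerade as a genome-wide wave on a small
#'   panel.
#'
#' @param lrr_row,baf_row Numeric vectors of equal length (one sample).
#' @param window Window size in probes for the wave factor.
#' @return Named list with the four metrics.
#' @export
qc_metrics <- function(lrr_row, baf_row, window = 50) {
  stopifnot(length(lrr_row) == length(baf_row))
  if (length(lrr_row) < window) {
    stop("fewer probes (", length(lrr_row), ") than one window (", window, ")")
  }
  lrr_sd <- stats::sd(lrr_row)
  het <- baf_row > 0.25 & baf_row < 0.75
  baf_median <- if (any(het)) stats::median(baf_row[het]) else NA_real_
  dev <- pmin(abs(baf_row), abs(baf_row - 0.5), abs(baf_row - 1))
  baf_drift <- mean(dev^2)
  n_win <- floor(length(lrr_row) / window)
  win_levels <- apply(matrix(lrr_row[seq_len(n_win * window)], window, n_win),
                      2, stats::median)
  wave_factor <- sqrt(mean((win_levels - mean(win_levels))^2))
  list(lrr_sd = lrr_sd, baf_median = baf_median, baf_drift = baf_drift,
       wave_factor = wave_factor)
}

#' QC metrics for every sample of a signal set
#'
#' @param signal A `cnv_signal`.
#' @param sample_ids Optional character vector of sample identifiers.
#' @param window Passed to [qc_metrics()].
#' @return Data frame, one row per sample.
#' @export
qc_table <- function(signal, sample_ids = NULL, window = 50) {
  n <- nrow(signal$lrr)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    as.data.frame(qc_metrics(signal$lrr[i, ], signal$baf[i, ], window))
  })
  cbind(data.frame(sample_id = sample_ids, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Apply exclusion thresholds to a QC metrics table
#'
#' A sample fails if any criterion is violated; `reasons` lists every violated
#' criterion.
#'
#' @param metrics Data frame from [qc_table()].
#' @param thresholds A `qc_thresholds`.
#' @return The metrics table with added `pass` (logical) and `reasons`
#'   (comma-separated character) columns.
#' @export
apply_qc <- function(metrics, thresholds = qc_thresholds()) {
  reasons <- vector("list", nrow(metrics))
  fail <- function(cond, label) {
    cond[is.na(cond)] <- TRUE
    lapply(seq_along(cond), function(i) if (cond[i]) label else NULL)
  }
  checks <- list(
    fail(metrics$lrr_sd > thresholds$max_lrr_sd, "max_lrr_sd"),
    fail(metrics$baf_median < thresholds$baf_median_range[1] |
           metrics$baf_median > thresholds$baf_median_range[2],
         "baf_median_range"),
    fail(metrics$baf_drift > thresholds$max_baf_drift, "max_baf_drift"),
    fail(metrics$wave_factor < thresholds$wave_factor_range[1] |
           metrics$wave_factor > thresholds$wave_factor_range[2],
         "wave_factor_range")
  )
  reasons <- vapply(seq_len(nrow(metrics)), function(i) {
    paste(unlist(lapply(checks, `[[`, i)), collapse = ",")
  }, character(1))
  metrics$pass <- reasons == ""
  metrics$reasons <- reasons
  metrics
}
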