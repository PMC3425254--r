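# Readers and writers for the plain-text interchange formats: a GenomeStudio
# Final-Report-like TSV of per-sample per-probe intensities, sample sheet,
# truth table, LRR/BAF matrices, BED-like calls, and the YAML pipeline config.

#' Write a Final-Report-like intensity TSV
#'
#' One row per sample x probe with columns `Sample ID`, `SNP Name`, `Chr`,
#' `Position`, `X`, `Y` (tab-separated). Optionally appends precomputed
#' `Log R Ratio` and `B Allele Freq` columns.
#'
#' @param intensities List with `X`, `Y` matrices (samples x probes).
#' @param samples Sample sheet (uses `sample_id`).
#' @param probes Probe panel.
#' @param path Output file.
#' @param signal Optional `cnv_signal` whose `lrr`/`baf` are appended.
#' @export
write_final_report <- function(intensities, samples, probes, path,
                               signal = NULL) {
  n <- nrow(intensities$X)
  p <- ncol(intensities$X)
  stopifnot(nrow(samples) == n, nrow(probes) == p)
  df <- data.frame(
    `Sample ID` = rep(samples$sample_id, each = p),
    `SNP Name` = rep(probes$probe_id, n),
    Chr = rep(probes$chromosome, n),
    Position = rep(probes$position, n),
    X = as.vector(t(intensities$X)),
    Y = as.vector(t(intensities$Y)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!is.null(signal)) {
    df$`Log R Ratio` <- as.vector(t(signal$lrr))
    df$`B Allele Freq` <- as.vector(t(signal$baf))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a Final-Report-like intensity TSV
#'
#' Returns intensity matrices and the probe table. When the file carries
#' precomputed `Log R Ratio` and `B Allele Freq` columns they are returned as
#' well (flag `has_signal`), so the normalization stage can be skipped.
#'
#' @param path Input file.
#' @return List with `X`, `Y` (samples x probes), `probes`, `sample_ids`,
#'   `has_signal`, and optionally `lrr`, `baf`.
#' @export
read_final_report <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Sample ID", "SNP Name", "Chr", "Position", "X", "Y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("final report is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df[c("Sample ID", "SNP Name")])) {
    dup <- df[duplicated(df[c("Sample ID", "SNP Name")]), ][1, ]
    stop("duplicated sample x probe row: ", dup$`Sample ID`, " / ",
         dup$`SNP Name`)
  }
  sample_ids <- unique(df$`Sample ID`)
  probe_ids <- unique(df$`SNP Name`)
  key_s <- match(df$`Sample ID`, sample_ids)
  key_p <- match(df$`SNP Name`, probe_ids)
  shape <- function(v) {
    m <- matrix(NA_real_, length(sample_ids), length(probe_ids),
                dimnames = list(NULL, probe_ids))
    m[cbind(key_s, key_p)] <- v
    m
  }
  first <- !duplicated(df$`SNP Name`)
  probes <- data.frame(probe_id = df$`SNP Name`[first],
                       chromosome = as.character(df$Chr[first]),
                       position = as.integer(df$Position[first]),
                       full_signal = 1,
                       is_locus_probe = FALSE,
                       stringsAsFactors = FALSE)
  out <- list(X = shape(df$X), Y = shape(df$Y), probes = probes,
              sample_ids = sample_ids,
              has_signal = all(c("Log R Ratio", "B Allele Freq") %in%
                                 names(df)))
  if (out$has_signal) {
    out$lrr <- shape(df$`Log R Ratio`)
    out$baf <- shape(df$`B Allele Freq`)
  }
  out
}

#' Write/read a samples-by-probes signal matrix as TSV
#'
#' @param mat Numeric matrix with probe columns.
#' @param sample_ids Character vector of row identifiers.
#' @param path File path.
#' @export
write_signal_matrix <- function(mat, sample_ids, path) {
  df <- data.frame(sample_id = sample_ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- NULL
  attr(m, "sample_ids") <- df[[1]]
  m
}

#' Write deletion calls as a BED-like TSV
#'
#' Coordinates are 0-based half-open intervals derived from the 1-based probe
#' positions (`start = start_position - 1`, `end = end_position`).
#'
#' @param calls Calls data frame from [call_cnvs()].
#' @param path File path.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$chromosome,
                    start = calls$start_position - 1L,
                    end = calls$end_position,
                    sample_id = calls$sample_id,
                    copy_number = calls$copy_number,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Every field of the simulation configuration is a key under `simulation`;
#' pipeline-level keys select the normalization modes, association methods,
#' mixture components and QC thresholds.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's value.
#' @return A `pipeline_config` list (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation
  if (!is.null(sim_args$genotype_class_freqs)) {
    sim_args$genotype_class_freqs <- as.numeric(sim_args$genotype_class_freqs)
  }
  if (!is.null(seed)) sim_args$seed <- as.integer(seed)
  sim <- do.call(simulation_config, sim_args)
  pipeline_config(
    sim = sim,
    modes = y$modes %||% c("cohort", "reference"),
    association = y$association %||% c("probe_lrr", "trend", "mixture"),
    K = y$K %||% 2,
    qc = do.call(qc_thresholds, y$qc %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
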