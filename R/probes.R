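#' Default probe panel: a five-probe deletion locus plus diploid background
#'
#' Builds the probe definition table used throughout the package. The deletion
#' locus consists of the five array probes that fall inside the deleted gene on
#' chromosome 1 (positions in base pairs, 1-based); background probes are
#' ordinary diploid SNP probes, half of them flanking the locus on chromosome 1
#' and half on chromosome 2, so that the hidden Markov model always decodes the
#' locus in its genomic context.
#'
#' @param n_background Number of background (diploid) probes. Default 2000.
#' @param full_signal Expected total two-channel intensity R of a noiseless
#'   two-copy sample, shared by all probes (the intensity scale unit).
#' @return A `data.frame` with columns `probe_id`, `chromosome`, `position`,
#'   `full_signal`, `is_locus_probe`, ordered by chromosome then position.
#' @export
default_probe_panel <- function(n_background = 2000, full_signal = 1) {
  stopifnot(n_background >= 0, full_signal > 0)
  locus <- data.frame(
    probe_id = c("rs12068997", "rs4147567", "rs1056806", "rs12562055",
                 "rs2239892"),
    chromosome = "1",
    position = c(110032359L, 110034047L, 110034670L, 110034988L, 110035809L),
    full_signal = full_signal,
    is_locus_probe = TRUE,
    stringsAsFactors = FALSE
  )
  if (n_background == 0) {
    return(locus[order(locus$position), , drop = FALSE])
  }
  n1 <- ceiling(n_background / 2)
  n2 <- n_background - n1
  n_left <- ceiling(n1 / 2)
  n_right <- n1 - n_left
  bg1 <- data.frame(
    probe_id = sprintf("bg1_%04d", seq_len(n1)),
    chromosome = "1",
    position = c(
      seq(110032359L - 20000L * n_left, 110032359L - 20000L, by = 20000L),
      seq(110035809L + 20000L, 110035809L + 20000L * n_right, by = 20000L)
    ),
    full_signal = full_signal,
    is_locus_probe = FALSE,
    stringsAsFactors = FALSE
  )
  panel <- rbind(locus, bg1)
  if (n2 > 0) {
    bg2 <- data.frame(
      probe_id = sprintf("bg2_%04d", seq_len(n2)),
      chromosome = "2",
      position = seq(1000000L, by = 20000L, length.out = n2),
      full_signal = full_signal,
      is_locus_probe = FALSE,
      stringsAsFactors = FALSE
    )
    panel <- rbind(panel, bg2)
  }
  panel <- panel[order(panel$chromosome, panel$position), , drop = FALSE]
  rownames(panel) <- NULL
  validate_probe_panel(panel)
  panel
}

validate_probe_panel <- function(probes) {
  required <- c("probe_id", "chromosome", "position", "full_signal",
                "is_locus_probe")
  missing <- setdiff(required, names(probes))
  if (length(missing) > 0) {
    stop("probe panel is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(probes$position <= 0)) stop("probe positions must be positive")
  if (any(probes$full_signal <= 0)) stop("full_signal must be positive")
  if (anyDuplicated(probes$probe_id)) stop("duplicated probe_id in panel")
  loc <- probes[probes$is_locus_probe, ]
  if (nrow(loc) > 0 && is.unsorted(loc$position)) {
    stop("locus probes must be sorted by position")
  }
  invisible(probes)
}
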