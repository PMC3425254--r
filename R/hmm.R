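#' Parameters of the five-state copy-number HMM
#'
#' Hidden states are copy numbers 0-4 over position-ordered probes; emissions
#' are the LRR (Gaussian per state, means at the PennCNV defaults -3.53, -0.66,
#' 0, 0.40, 0.68, plus a small uniform outlier component on
#' `[lrr_outlier_span[1], lrr_outlier_span[2]]` so that a wild LRR value does
#' not default to the widest state) and the BAF (per-state mixtures of
#' truncated Gaussian bands at the canonical B-allele fractions, uniform for
#' the 0-copy state, plus a small uniform outlier component absorbing
#' genotyping error). Transitions are
#' a fixed sticky prior: stay probability 0.9996 with the off-diagonal mass
#' split equally. The initial distribution favours the diploid state.
#'
#' @param lrr_means,lrr_sds Numeric length-5, LRR emission mean/sd per state.
#' @param baf_band_sd Standard deviation of each BAF band.
#' @param baf_outlier_weight Weight of the uniform outlier component in the
#'   BAF emission of states 1-4.
#' @param lrr_outlier_weight,lrr_outlier_span Weight and support of the
#'   uniform outlier component in the LRR emission of every state.
#' @param stay_prob Self-transition probability.
#' @param initial Initial state distribution.
#' @param min_probes Minimum run length for a reportable deletion call.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(lrr_means = c(-3.53, -0.66, 0, 0.40, 0.68),
                       lrr_sds = c(1.0, 0.30, 0.18, 0.22, 0.24),
                       baf_band_sd = 0.04,
                       baf_outlier_weight = 0.01,
                       lrr_outlier_weight = 0.01,
                       lrr_outlier_span = c(-6, 6),
                       stay_prob = 0.9996,
                       initial = c(0.01, 0.02, 0.94, 0.02, 0.01),
                       min_probes = 3) {
  stopifnot(length(lrr_means) == 5, length(lrr_sds) == 5, all(lrr_sds > 0),
            stay_prob > 0, stay_prob < 1, length(initial) == 5)
  trans <- matrix((1 - stay_prob) / 4, 5, 5)
  diag(trans) <- stay_prob
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-12))
  initial <- initial / sum(initial)
  bands <- list(NULL,                                  # state 0: uniform BAF
                c(0, 1),
                c(0, 0.5, 1),
                c(0, 1 / 3, 2 / 3, 1),
                c(0, 0.25, 0.5, 0.75, 1))
  structure(list(lrr_means = lrr_means, lrr_sds = lrr_sds,
                 baf_bands = bands, baf_band_sd = baf_band_sd,
                 baf_outlier_weight = baf_outlier_weight,
                 lrr_outlier_weight = lrr_outlier_weight,
                 lrr_outlier_span = lrr_outlier_span,
                 transition = trans, initial = initial,
                 min_probes = min_probes),
            class = "hmm_params")
}

# BAF mixture density for one state (state as copy number 0..4), vectorized.
baf_density <- function(baf, state, params) {
  bands <- params$baf_bands[[state + 1]]
  if (is.null(bands)) return(rep(1, length(baf)))     # uniform on [0, 1]
  sd <- params$baf_band_sd
  per_band <- lapply(bands, function(m) {
    stats::dnorm(baf, m, sd) /
      (stats::pnorm(1, m, sd) - stats::pnorm(0, m, sd))
  })
  dens <- rowMeans(matrix(unlist(per_band), length(baf), length(bands)))
  w <- params$baf_outlier_weight
  (1 - w) * dens + w
}

#' Log emission likelihood of one state
#'
#' Sum of the Gaussian LRR log density and the BAF mixture log density for the
#' given copy-number state.
#'
#' @param lrr,baf Numeric vectors of equal length; `baf` in `[0, 1]`.
#' @param state Copy-number state, integer in 0..4.
#' @param params An `hmm_params`.
#' @return Numeric vector of log densities.
#' @export
emission_loglik <- function(lrr, baf, state, params = hmm_params()) {
  if (length(state) != 1 || !state %in% 0:4) {
    stop("state must be a single integer in 0..4")
  }
  if (any(baf < 0 | baf > 1, na.rm = TRUE)) stop("baf must lie in [0, 1]")
  w <- params$lrr_outlier_weight
  span <- diff(params$lrr_outlier_span)
  lrr_dens <- (1 - w) * stats::dnorm(lrr, params$lrr_means[state + 1],
                                     params$lrr_sds[state + 1]) +
    w / span * (lrr >= params$lrr_outlier_span[1] &
                  lrr <= params$lrr_outlier_span[2])
  log(lrr_dens) + log(baf_density(baf, state, params))
}

# Tie-break preference: diploid first, then toward higher copy number.
# Makes the caller conservative (fewer sub-diploid calls) on exact ties.
.state_pref <- c(3L, 4L, 2L, 5L, 1L)   # 1-based indices for states 2,3,1,4,0

#' Viterbi decoding for a whole cohort over one ordered probe set
#'
#' Maximum a posteriori state paths in log space, computed jointly for all
#' samples (rows). Ties break deterministically toward the diploid state.
#'
#' @param lrr,baf Matrices (samples x probes), probes ordered by position.
#' @param params An `hmm_params`.
#' @return Integer matrix of decoded copy-number states (samples x probes).
#' @export
viterbi_paths <- function(lrr, baf, params = hmm_params()) {
  if (is.null(dim(lrr))) lrr <- matrix(lrr, 1)
  if (is.null(dim(baf))) baf <- matrix(baf, 1)
  n <- nrow(lrr); p <- ncol(lrr)
  if (p == 0) stop("empty probe list")
  if (any(!is.finite(lrr))) stop("non-finite LRR passed to the decoder")
  E <- lapply(0:4, function(s) {
    matrix(emission_loglik(as.vector(lrr), as.vector(baf), s, params), n, p)
  })
  logT <- log(params$transition)
  V <- vapply(1:5, function(s) log(params$initial[s]) + E[[s]][, 1],
              numeric(n))
  V <- matrix(V, n, 5)
  back <- vector("list", p)
  for (j in seq_len(p)[-1]) {
    Vnew <- matrix(NA_real_, n, 5)
    bp <- matrix(NA_integer_, n, 5)
    for (s in 1:5) {
      best <- V[, .state_pref[1]] + logT[.state_pref[1], s]
      arg <- rep(.state_pref[1], n)
      for (sp in .state_pref[-1]) {
        cand <- V[, sp] + logT[sp, s]
        upd <- cand > best
        best[upd] <- cand[upd]
        arg[upd] <- sp
      }
      Vnew[, s] <- best + E[[s]][, j]
      bp[, s] <- arg
    }
    V <- Vnew
    back[[j]] <- bp
  }
  path <- matrix(NA_integer_, n, p)
  last <- rep(.state_pref[1], n)
  best <- V[, .state_pref[1]]
  for (sp in .state_pref[-1]) {
    upd <- V[, sp] > best
    best[upd] <- V[upd, sp]
    last[upd] <- sp
  }
  path[, p] <- last
  if (p > 1) {
    for (j in p:2) {
      path[, j - 1] <- back[[j]][cbind(seq_len(n), path[, j])]
    }
  }
  path - 1L   # to copy-number states 0..4
}

#' Viterbi decoding for a single sample
#'
#' @param lrr,baf Numeric vectors over position-ordered probes.
#' @param params An `hmm_params`.
#' @return Integer vector of copy-number states.
#' @export
viterbi <- function(lrr, baf, params = hmm_params()) {
  drop(viterbi_paths(matrix(lrr, 1), matrix(baf, 1), params))
}

#' Extract deletion calls from a state path
#'
#' Maximal runs of identical sub-diploid states (0 or 1) of length at least
#' `min_probes` become calls.
#'
#' @param path Integer vector of states over the probes in `probes` order.
#' @param probes Probe panel rows corresponding to `path` (one chromosome,
#'   position-ordered).
#' @param sample_id Identifier copied into the calls.
#' @param min_probes Minimum probes per reportable call.
#' @return Data frame with columns `sample_id`, `chromosome`, `start_probe`,
#'   `end_probe`, `start_position`, `end_position`, `copy_number`, `n_probes`
#'   (zero rows if no call).
#' @export
extract_deletions <- function(path, probes, sample_id = "S1", min_probes = 3) {
  stopifnot(length(path) == nrow(probes))
  runs <- rle(path)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values %in% c(0, 1) & runs$lengths >= min_probes
  data.frame(sample_id = rep(sample_id, sum(keep)),
             chromosome = probes$chromosome[starts[keep]],
             start_probe = starts[keep],
             end_probe = ends[keep],
             start_position = probes$position[starts[keep]],
             end_position = probes$position[ends[keep]],
             copy_number = runs$values[keep],
             n_probes = runs$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Call CNVs for a whole cohort
#'
#' Runs the Viterbi decoder per chromosome and extracts deletion calls per
#' sample.
#'
#' @param signal A `cnv_signal`.
#' @param probes Probe panel matching the signal columns.
#' @param params An `hmm_params`.
#' @param sample_ids Optional sample identifiers.
#' @return List with `paths` (integer matrix, samples x probes, panel order)
#'   and `calls` (data frame of deletion calls).
#' @export
call_cnvs <- function(signal, probes, params = hmm_params(),
                      sample_ids = NULL) {
  n <- nrow(signal$lrr)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(n))
  paths <- matrix(NA_integer_, n, nrow(probes))
  colnames(paths) <- probes$probe_id
  calls <- list()
  for (chr in unique(probes$chromosome)) {
    idx <- which(probes$chromosome == chr)
    idx <- idx[order(probes$position[idx])]
    pth <- viterbi_paths(signal$lrr[, idx, drop = FALSE],
                         signal$baf[, idx, drop = FALSE], params)
    paths[, idx] <- pth
    for (i in seq_len(n)) {
      cl <- extract_deletions(pth[i, ], probes[idx, ], sample_ids[i],
                              params$min_probes)
      if (nrow(cl) > 0) calls[[length(calls) + 1]] <- cl
    }
  }
  calls <- if (length(calls) > 0) {
    do.call(rbind, calls)
  } else {
    extract_deletions(rep(2L, 3), utils::head(probes, 3), "none", 99)[0, ]
  }
  rownames(calls) <- NULL
  list(paths = paths, calls = calls)
}

#' Count samples with a deletion call overlapping the locus
#'
#' @param calls Data frame from [call_cnvs()].
#' @param probes Probe panel; the locus is `probes$is_locus_probe`.
#' @return Integer: number of distinct samples with at least one deletion call
#'   overlapping at least one locus probe.
#' @export
count_locus_deletions <- function(calls, probes) {
  if (nrow(calls) == 0) return(0L)
  loc <- probes[probes$is_locus_probe, ]
  hit <- vapply(seq_len(nrow(calls)), function(i) {
    pos <- loc$position[loc$chromosome == calls$chromosome[i]]
    any(pos >= calls$start_position[i] & pos <= calls$end_position[i])
  }, logical(1))
  length(unique(calls$sample_id[hit]))
}

#' Per-sample called copy number at the locus
#'
#' Majority state over the locus probes (ties toward the higher state), capped
#' at two copies for use in trend association.
#'
#' @param paths Integer state matrix from [call_cnvs()].
#' @param probes Probe panel.
#' @return Integer vector in 0..2, one value per sample.
#' @export
locus_copy_number <- function(paths, probes) {
  loc <- which(probes$is_locus_probe)
  apply(paths[, loc, drop = FALSE], 1, function(s) {
    tab <- table(s)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(max(cand), 2L)
  })
}
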