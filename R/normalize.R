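#' Polar transform of two-channel intensities
#'
#' `theta = (2/pi) * atan(Y/X)` (0 for pure A signal, 1 for pure B) and
#' `R = X + Y`. Cells with `X = Y = 0` get `theta = 0.5`.
#'
#' @param X,Y Nonnegative numeric matrices of equal shape (samples x probes).
#' @return List with matrices `theta` and `R`.
#' @export
compute_polar <- function(X, Y) {
  if (!all(dim(X) == dim(Y))) stop("X and Y must have the same shape")
  if (any(X < 0) || any(Y < 0)) stop("channel intensities must be nonnegative")
  theta <- (2 / pi) * atan2(Y, X)
  theta[X == 0 & Y == 0] <- 0.5
  list(theta = theta, R = X + Y)
}

# Windowed mode: center of the densest blob, measured as the observation with
# the most neighbours within +/- h, h = rel_window * median. For tight
# unimodal clusters (relative spread below the window) this is just the
# median, which also covers degenerate noiseless input exactly. Robust against
# a minority blob at a different intensity level even when the two blobs hold
# comparable mass, because it compares local densities, not halves.
windowed_mode <- function(x, rel_window = 0.05) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  med <- stats::median(x)
  h <- rel_window * abs(med)
  if (n < 10 || h == 0 || (x[n] - x[1]) <= 2 * h) return(med)
  lo <- findInterval(x - h, x, left.open = TRUE) + 1L
  hi <- findInterval(x + h, x)
  counts <- hi - lo + 1L
  i <- which.max(counts)          # ties: lowest R, deterministic
  mean(x[lo[i]:hi[i]])
}

#' Fit per-probe genotype cluster models
#'
#' Samples are partitioned by theta at the fixed thresholds 1/3 and 2/3 into
#' AA/AB/BB candidate clusters. Each retained cluster gets a theta center (the
#' member median) and an expected intensity `r_expected`, the windowed mode
#' of member R values -- the densest intensity blob, so that at a locus where
#' deleted samples dominate the clusters the expectation latches onto them.
#' In `"cohort"` mode all samples are used; in `"reference"` mode only the
#' samples flagged in `reference_mask` (a known-diploid panel). Clusters with
#' fewer than `min_cluster_size` members are dropped; probes then fall back to
#' the nearest retained cluster when expectations are interpolated.
#'
#' @param theta,R Matrices from [compute_polar()].
#' @param mode `"cohort"` or `"reference"`.
#' @param reference_mask Logical vector (length = samples), required in
#'   reference mode.
#' @param min_cluster_size Minimum members for a cluster to be retained.
#' @return A `data.frame` of class `cluster_model` with columns `probe_id`,
#'   `cluster`, `theta_center`, `r_expected`, `n_members`, and attribute
#'   `mode`.
#' @export
fit_cluster_model <- function(theta, R, mode = c("cohort", "reference"),
                              reference_mask = NULL, min_cluster_size = 3) {
  mode <- match.arg(mode)
  if (mode == "reference") {
    if (is.null(reference_mask)) {
      stop("reference mode requires a reference_mask of known two-copy samples")
    }
    stopifnot(length(reference_mask) == nrow(theta))
    theta_fit <- theta[reference_mask, , drop = FALSE]
    R_fit <- R[reference_mask, , drop = FALSE]
  } else {
    theta_fit <- theta
    R_fit <- R
  }
  probe_ids <- colnames(theta)
  if (is.null(probe_ids)) probe_ids <- sprintf("p%d", seq_len(ncol(theta)))
  out <- vector("list", ncol(theta))
  for (j in seq_len(ncol(theta))) {
    th <- theta_fit[, j]
    r <- R_fit[, j]
    bin <- findInterval(th, c(1 / 3, 2 / 3))  # 0 = AA, 1 = AB, 2 = BB
    rows <- list()
    for (g in 0:2) {
      m <- bin == g
      if (sum(m) >= min_cluster_size) {
        rows[[length(rows) + 1]] <- data.frame(
          probe_id = probe_ids[j],
          cluster = c("AA", "AB", "BB")[g + 1],
          theta_center = stats::median(th[m]),
          r_expected = windowed_mode(r[m]),
          n_members = sum(m),
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows) == 0) {
      stop("all genotype clusters empty at probe ", probe_ids[j])
    }
    out[[j]] <- do.call(rbind, rows)
  }
  model <- do.call(rbind, out)
  rownames(model) <- NULL
  if (any(model$r_expected <= 0)) {
    bad <- model$probe_id[model$r_expected <= 0][1]
    stop("nonpositive expected intensity at probe ", bad)
  }
  attr(model, "mode") <- mode
  class(model) <- c("cluster_model", "data.frame")
  model
}

#' Compute LRR and BAF from theta/R and a cluster model
#'
#' The expected intensity `R_exp(theta)` is the linear interpolation of
#' `r_expected` between the probe's cluster theta centers (constant beyond the
#' outermost center); `LRR = log2(R / R_exp)`. BAF is the piecewise-linear
#' interpolation of theta through the same centers mapped to canonical B-allele
#' fractions 0, 0.5, 1, clipped to `[0, 1]`. Cells with `R = 0` get the
#' configured LRR floor and are flagged.
#'
#' @param theta,R Matrices from [compute_polar()].
#' @param model A `cluster_model` covering every probe.
#' @param lrr_floor LRR value assigned to zero-intensity cells.
#' @return A list of class `cnv_signal` with matrices `theta`, `R`, `lrr`,
#'   `baf`, logical matrix `dropout` (floored cells), and the model `mode`.
#' @export
compute_lrr_baf <- function(theta, R, model, lrr_floor = -10) {
  probe_ids <- colnames(theta)
  if (is.null(probe_ids)) probe_ids <- sprintf("p%d", seq_len(ncol(theta)))
  covered <- unique(model$probe_id)
  missing <- setdiff(probe_ids, covered)
  if (length(missing) > 0) {
    stop("cluster model does not cover probe(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  lrr <- baf <- matrix(NA_real_, nrow(theta), ncol(theta),
                       dimnames = dimnames(theta))
  split_model <- split(model, model$probe_id)
  canonical <- c(AA = 0, AB = 0.5, BB = 1)
  for (j in seq_len(ncol(theta))) {
    pm <- split_model[[probe_ids[j]]]
    pm <- pm[order(pm$theta_center), ]
    th <- theta[, j]
    if (nrow(pm) == 1) {
      r_exp <- rep(pm$r_expected, length(th))
      bafj <- rep(canonical[[pm$cluster]], length(th))
    } else {
      r_exp <- stats::approx(pm$theta_center, pm$r_expected, xout = th,
                             rule = 2)$y
      bafj <- stats::approx(pm$theta_center, canonical[pm$cluster], xout = th,
                            rule = 2)$y
    }
    if (any(r_exp <= 0)) stop("nonpositive R_exp at probe ", probe_ids[j])
    lrr[, j] <- log2(pmax(R[, j], 0) / r_exp)
    baf[, j] <- pmin(pmax(bafj, 0), 1)
  }
  dropout <- !is.finite(lrr)
  lrr[dropout] <- lrr_floor
  out <- list(theta = theta, R = R, lrr = lrr, baf = baf, dropout = dropout,
              mode = attr(model, "mode"))
  class(out) <- "cnv_signal"
  out
}

#' One-step normalization: polar transform, cluster fit, LRR/BAF
#'
#' @param intensities List with `X`, `Y` matrices.
#' @param mode,reference_mask,min_cluster_size Passed to [fit_cluster_model()].
#' @param lrr_floor Passed to [compute_lrr_baf()].
#' @return A `cnv_signal` (with the fitted `cluster_model` attached as
#'   attribute `"model"`).
#' @export
normalize_intensities <- function(intensities, mode = c("cohort", "reference"),
                                  reference_mask = NULL, min_cluster_size = 3,
                                  lrr_floor = -10) {
  mode <- match.arg(mode)
  polar <- compute_polar(intensities$X, intensities$Y)
  model <- fit_cluster_model(polar$theta, polar$R, mode, reference_mask,
                             min_cluster_size)
  signal <- compute_lrr_baf(polar$theta, polar$R, model, lrr_floor)
  attr(signal, "model") <- model
  signal
}

#' @export
print.cnv_signal <- function(x, ...) {
  cat("CNV signal matrices (", x$mode, "-mode normalization ): ",
      nrow(x$lrr), " samples x ", ncol(x$lrr), " probes\n", sep = "")
  cat("LRR range:", paste(round(range(x$lrr), 3), collapse = " .. "),
      "| floored cells:", sum(x$dropout), "\n")
  invisible(x)
}
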