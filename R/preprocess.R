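## Everything between the raw matrix and the model-ready matrix: detection
## filtering, log2 transform, cubic-spline quantile normalization, and chip
## (batch) assessment/adjustment.

#' Filter probes on detection p-values
#'
#' A probe is retained if at least one of the four sex x genotype groups has
#' `min_detected` or more samples detected at `detection p < alpha`.  Probes
#' never convincingly detected in any group are removed before modelling.
#'
#' @param expr Expression matrix (any scale).
#' @param det Detection p-value matrix on the same axes.
#' @param design Sample design.
#' @param min_detected Minimum detected replicates in some group (default 3).
#' @param alpha Detection p-value threshold (default 0.05).
#' @return List with the filtered `expr`, filtered `det`, and the logical
#'   `mask` over the input probes (TRUE = retained).
#' @export
detection_filter <- function(expr, det, design, min_detected = 3, alpha = 0.05) {
  design <- .check_expr(expr, design)
  stopifnot(identical(dim(expr), dim(det)))
  grp <- .group_of(design)
  if (min_detected > min(table(grp)))
    stop("config error: min_detected exceeds the smallest group size")
  detected <- det < alpha
  counts <- vapply(levels(grp), function(g)
    rowSums(detected[, grp == g, drop = FALSE]), numeric(nrow(expr)))
  counts <- matrix(counts, nrow = nrow(expr))
  mask <- apply(counts >= min_detected, 1L, any)
  names(mask) <- rownames(expr)
  out <- expr[mask, , drop = FALSE]
  attr(out, "scale") <- attr(expr, "scale")
  list(expr = out, det = det[mask, , drop = FALSE], mask = mask)
}

#' Log2-transform a raw-scale matrix
#'
#' @param expr Raw-scale expression matrix (positive values).
#' @param offset Optional additive offset applied before taking logs.
#' @return The log2 matrix with `scale` attribute `"log2"`.
#' @export
log2_transform <- function(expr, offset = 0) {
  .check_expr(expr)
  if (identical(.expr_scale(expr), "log2"))
    stop("matrix is already on the log2 scale")
  v <- expr + offset
  if (any(v <= 0))
    stop("non-positive intensities; supply an offset")
  out <- log2(v)
  .set_scale(out, "log2")
}

#' Cubic-spline quantile normalization
#'
#' Smooth intensity-dependent normalization in the spirit of the BeadChip
#' software's cubic-spline method: the reference profile is the
#' per-quantile mean of the sorted sample columns; for each sample a
#' monotone shape-preserving piecewise-cubic map (Hyman-filtered spline) is
#' fitted through anchor pairs (sample quantile -> reference quantile) at
#' `n_anchors` evenly spaced probabilities and applied to all values.
#' Anchor quantiles are inverse-ECDF (type 1) order statistics, so after
#' mapping each sample's anchor quantiles equal the reference anchors
#' exactly and within-sample rank order is preserved.
#'
#' @param expr Log2-scale expression matrix with at least 2 samples.
#' @param n_anchors Number of anchor probabilities (default 13).
#' @return The normalized log2 matrix.
#' @export
cubic_spline_normalize <- function(expr, n_anchors = 13) {
  .check_expr(expr)
  if (ncol(expr) < 2) stop("need at least 2 samples")
  if (n_anchors < 2) stop("config error: n_anchors must be >= 2")
  if (any(!is.finite(expr))) stop("data error: non-finite values")
  probs <- seq(0, 1, length.out = n_anchors)
  ref <- rowMeans(apply(expr, 2L, sort))
  ref_anchor <- stats::quantile(ref, probs, type = 1, names = FALSE)
  out <- expr
  for (j in seq_len(ncol(expr))) {
    ax <- stats::quantile(expr[, j], probs, type = 1, names = FALSE)
    ay <- ref_anchor
    # a map must be a function: collapse duplicated sample anchors
    if (anyDuplicated(ax)) {
      ay <- as.vector(tapply(ay, match(ax, unique(ax)), mean))
      ax <- unique(ax)
    }
    out[, j] <- if (length(ax) < 2) {
      expr[, j] - mean(expr[, j]) + mean(ref)   # degenerate (constant) column
    } else {
      f <- stats::splinefun(ax, ay, method = "hyman")
      f(expr[, j])
    }
  }
  attr(out, "scale") <- "log2"
  out
}

#' Assess and adjust chip (batch) effects
#'
#' Fits the per-probe three-way model (sex, genotype, batch, sex:genotype)
#' and inspects the batch p-values.  In `auto` mode adjustment triggers when
#' the fraction of probes with batch p < 0.05 exceeds the 99th percentile of
#' the corresponding null binomial fraction; `on`/`off` force the decision.
#' Adjustment subtracts, per probe, each batch's mean deviation from the
#' probe grand mean, which leaves every probe's grand mean untouched.
#'
#' @param expr Log2-scale expression matrix.
#' @param design Sample design with a `batch` column (>= 2 levels).
#' @param force `"auto"`, `"on"` or `"off"`.
#' @param alpha Per-probe batch test level used by the trigger (default 0.05).
#' @return List with `expr` (adjusted or untouched) and `report` (list:
#'   `adjusted`, `fraction`, `threshold`, `mode`, `batch_p`).
#' @export
assess_and_adjust_batch <- function(expr, design, force = c("auto", "on", "off"),
                                    alpha = 0.05) {
  force <- match.arg(force)
  design <- .check_expr(expr, design)
  if (is.null(design$batch) || nlevels(design$batch) < 2)
    stop("design must include a batch with >= 2 levels")
  if (force == "off")
    return(list(expr = expr, report = list(adjusted = FALSE, fraction = NA_real_,
                                           threshold = NA_real_, mode = force,
                                           batch_p = NULL)))
  eng <- .anova_engine(expr, design, include_batch = TRUE)
  batch_p <- eng$p[, "batch"]
  m <- length(batch_p)
  fraction <- mean(batch_p < alpha)
  threshold <- stats::qbinom(0.99, m, alpha) / m
  adjusted <- force == "on" || fraction > threshold
  out <- expr
  if (adjusted) {
    grand <- rowMeans(expr)
    for (b in levels(design$batch)) {
      cols <- design$batch == b
      dev <- rowMeans(expr[, cols, drop = FALSE]) - grand
      out[, cols] <- out[, cols, drop = FALSE] - dev
    }
  }
  attr(out, "scale") <- attr(expr, "scale")
  list(expr = out,
       report = list(adjusted = adjusted, fraction = fraction,
                     threshold = threshold, mode = force, batch_p = batch_p))
}
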