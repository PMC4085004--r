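## Synthetic BeadChip experiment generator.  Emulates the study layout the
## package targets: a replicated (n = 4) 2x2 sex x genotype factorial, 16
## samples split across two chips, log-normal baseline intensities, additive
## log2 group effects, per-chip batch shifts, and a fraction of unexpressed
## probes carrying high detection p-values.

#' Specify a synthetic factorial BeadChip experiment
#'
#' Defaults reproduce the target study conditions: 4 replicates per
#' sex x genotype cell (16 samples) balanced over 2 chips; log-normal
#' baselines (log2 mean 8, sd 1.5); residual noise sd 0.25 on the log2
#' scale; mild probe-specific chip shifts (sd 0.1); and 48% of probes
#' unexpressed, mirroring expressed-transcript fractions on whole-genome
#' expression arrays.
#'
#' @param n_probes Number of probes.
#' @param n_per_group Replicates per sex x genotype cell (>= 2).
#' @param n_batches Number of chips; samples of each cell are dealt across
#'   chips in rotation so the default layout is balanced.
#' @param baseline_log2_mean,baseline_log2_sd Per-probe baseline log2
#'   intensity distribution.
#' @param residual_sd Within-group log2 noise sd.
#' @param residual_sd_range Optional length-2 range; when given, each
#'   probe's noise sd is drawn Uniform over it (BeadChip noise is
#'   probe-dependent), otherwise all probes share `residual_sd`.
#' @param batch_shift_sd Sd of the probe-by-chip additive log2 shift.
#' @param undetected_fraction Proportion of probes simulated as unexpressed
#'   (detection p-values drawn above 0.05 in every sample).
#' @param spikes Data frame of true effects: columns `probe` (index or
#'   probe id), `factor` (`genotype`, `sex` or `interaction`) and `fc`
#'   (signed fold change, |fc| >= 1).  Positive fold changes raise KO over
#'   WT, female over male; interaction effects act only in the (female, KO)
#'   cell.
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(n_probes = 2000, n_per_group = 4, n_batches = 2,
                        baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                        residual_sd = 0.25, residual_sd_range = NULL,
                        batch_shift_sd = 0.1,
                        undetected_fraction = 0.48,
                        spikes = NULL, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (undetected_fraction < 0 || undetected_fraction > 1)
    stop("undetected_fraction must be in [0, 1]")
  if (residual_sd < 0 || batch_shift_sd < 0 || baseline_log2_sd < 0)
    stop("standard deviations must be non-negative")
  if (!is.null(residual_sd_range) &&
      (length(residual_sd_range) != 2 || any(residual_sd_range <= 0) ||
       diff(residual_sd_range) < 0))
    stop("residual_sd_range must be an increasing positive pair")
  if (is.null(spikes))
    spikes <- data.frame(probe = integer(), factor = character(),
                         fc = numeric(), stringsAsFactors = FALSE)
  if (!is.data.frame(spikes))   # e.g. a YAML block of parallel arrays
    spikes <- as.data.frame(spikes, stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "factor", "fc") %in% names(spikes)))
  if (!all(spikes$factor %in% c("genotype", "sex", "interaction")))
    stop("spike factor must be genotype, sex or interaction")
  if (any(abs(spikes$fc) < 1))
    stop("spike |fold change| must be >= 1")
  structure(list(n_probes = n_probes, n_per_group = n_per_group,
                 n_batches = n_batches,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 residual_sd = residual_sd,
                 residual_sd_range = residual_sd_range,
                 batch_shift_sd = batch_shift_sd,
                 undetected_fraction = undetected_fraction,
                 spikes = spikes, seed = as.integer(seed)),
            class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("Synthetic BeadChip experiment spec\n")
  cat(sprintf("  %d probes, %d samples (%d per sex x genotype cell), %d chip(s)\n",
              x$n_probes, 4 * x$n_per_group, x$n_per_group, x$n_batches))
  cat(sprintf("  baseline log2 ~ N(%.2f, %.2f), residual sd %.3f, batch shift sd %.3f\n",
              x$baseline_log2_mean, x$baseline_log2_sd,
              x$residual_sd, x$batch_shift_sd))
  cat(sprintf("  undetected fraction %.2f, %d spike-in effect(s), seed %d\n",
              x$undetected_fraction, nrow(x$spikes), x$seed))
  invisible(x)
}

#' Simulate a factorial BeadChip experiment with known truth
#'
#' Per probe p and sample s the log2 signal is
#' `baseline_p + group effects + batch_shift(p, chip(s)) + N(0, residual_sd)`,
#' where each spiked effect contributes `sign(fc) * log2(|fc|)` to the
#' samples of its high group (KO for genotype, female for sex, the
#' female-KO cell for interaction).  The raw matrix is `2^log2`.  Detection
#' p-values are Uniform(0, 0.049) for expressed probes and
#' Uniform(0.06, 1) for the unexpressed fraction, in every sample.
#'
#' @param spec An [effect_spec()].
#' @return List with `expr` (raw scale), `det`, `design`, `truth` (data
#'   frame `probe_id`, `factor`, `fc`, `detected`), `features` and the
#'   `spec` itself.
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  m <- spec$n_probes
  probes <- sprintf("PROBE%05d", seq_len(m))
  symbols <- sprintf("GENE%05d", seq_len(m))

  cells <- expand.grid(genotype = GENOTYPE_LEVELS, sex = SEX_LEVELS,
                       stringsAsFactors = FALSE)
  design <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(sex = cells$sex[i], genotype = cells$genotype[i],
               rep = seq_len(spec$n_per_group), stringsAsFactors = FALSE)))
  design$sample_id <- sprintf("S%02d", seq_len(nrow(design)))
  # deal replicates of each cell across chips in rotation: balanced layout
  design$batch <- paste0("chip", ((design$rep - 1L) %% spec$n_batches) + 1L)
  design <- .as_design(design[c("sample_id", "sex", "genotype", "batch")])
  n <- nrow(design)

  spikes <- spec$spikes
  if (nrow(spikes)) {
    idx <- if (is.numeric(spikes$probe)) as.integer(spikes$probe)
           else match(as.character(spikes$probe), probes)
    if (anyNA(idx) || any(idx < 1L) || any(idx > m))
      stop("spec error: spike probe index out of range")
    if (anyDuplicated(idx)) stop("spec error: duplicated spike probe")
    spikes$probe <- idx
  }

  set.seed(spec$seed)
  baseline <- stats::rnorm(m, spec$baseline_log2_mean, spec$baseline_log2_sd)
  chips <- levels(design$batch)
  shift <- matrix(stats::rnorm(m * length(chips), 0, spec$batch_shift_sd),
                  m, length(chips), dimnames = list(probes, chips))

  log2mat <- matrix(baseline, m, n) + shift[, as.character(design$batch)]
  if (nrow(spikes)) {
    delta <- sign(spikes$fc) * log2(abs(spikes$fc))
    for (i in seq_len(nrow(spikes))) {
      cols <- switch(spikes$factor[i],
        genotype = design$genotype == "KO",
        sex = design$sex == "female",
        interaction = design$sex == "female" & design$genotype == "KO")
      log2mat[spikes$probe[i], cols] <- log2mat[spikes$probe[i], cols] + delta[i]
    }
  }
  sd_p <- if (is.null(spec$residual_sd_range)) rep(spec$residual_sd, m)
          else stats::runif(m, spec$residual_sd_range[1],
                            spec$residual_sd_range[2])
  log2mat <- log2mat + matrix(stats::rnorm(m * n, 0, sd_p), m, n)
  dimnames(log2mat) <- list(probes, design$sample_id)

  # spiked effects are on expressed probes: draw the unexpressed set from
  # the non-spiked probes
  candidates <- setdiff(seq_len(m), spikes$probe)
  n_undet <- min(round(spec$undetected_fraction * m), length(candidates))
  undet <- sort(sample(candidates, n_undet))
  det <- matrix(stats::runif(m * n, 0, 0.049), m, n,
                dimnames = dimnames(log2mat))
  if (n_undet)
    det[undet, ] <- matrix(stats::runif(n_undet * n, 0.06, 1), n_undet, n)

  truth <- data.frame(probe_id = probes, factor = NA_character_,
                      fc = NA_real_, detected = TRUE,
                      stringsAsFactors = FALSE)
  truth$detected[undet] <- FALSE
  if (nrow(spikes)) {
    truth$factor[spikes$probe] <- spikes$factor
    truth$fc[spikes$probe] <- spikes$fc
  }

  list(expr = .set_scale(2^log2mat, "raw"), det = det, design = design,
       truth = truth,
       features = data.frame(probe_id = probes, symbol = symbols,
                             stringsAsFactors = FALSE),
       spec = spec)
}

#' Destroy group structure by per-probe sample permutation
#'
#' Permutes each probe's values across samples independently, preserving
#' every per-probe marginal distribution while removing all association
#' with the design.  Used to build global-null data for calibration tests.
#'
#' @param expr Expression matrix.
#' @param seed Integer seed.
#' @return A matrix of the same dimensions and dimnames.
#' @export
resample_null <- function(expr, seed = 1L) {
  .check_expr(expr)
  set.seed(seed)
  n <- ncol(expr)
  out <- t(apply(expr, 1L, function(v) v[sample.int(n)]))
  dimnames(out) <- dimnames(expr)
  attr(out, "scale") <- attr(expr, "scale")
  out
}
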