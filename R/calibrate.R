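## Permutation calibration: rerun the whole per-probe analysis on random
## re-combinations of the sex x genotype labels (chip layout fixed), compare
## fold-change histograms between the real and permuted analyses, and sweep
## FDR levels to pick an operating threshold.

#' Random re-combinations of the design labels
#'
#' Shuffles the sex x genotype cell labels jointly across samples,
#' uniformly among assignments that preserve the per-cell group sizes;
#' chip (batch) labels stay attached to their samples.  Draws are without
#' replacement across the `k` outputs and never equal the real design.
#'
#' @param design Sample design.
#' @param k Number of re-combinations (default 20).
#' @param seed Integer seed.
#' @return List of `k` permuted designs.
#' @export
random_combinations <- function(design, k = 20, seed = 1L) {
  design <- .as_design(design)
  if (k < 1) stop("config error: k must be >= 1")
  n <- nrow(design)
  grp <- as.character(.group_of(design))
  counts <- table(grp)
  total <- exp(lgamma(n + 1) - sum(lgamma(counts + 1)))  # multiset perms
  if (k > total - 1)
    stop("config error: k exceeds the number of distinct re-labelings")
  set.seed(seed)
  seen <- character(0); id_key <- paste(grp, collapse = "|")
  out <- vector("list", k); got <- 0L
  while (got < k) {
    lab <- grp[sample.int(n)]
    key <- paste(lab, collapse = "|")
    if (key == id_key || key %in% seen) next
    seen <- c(seen, key)
    d <- design
    sg <- do.call(rbind, strsplit(lab, ".", fixed = TRUE))
    d$sex <- factor(sg[, 1], levels = SEX_LEVELS)
    d$genotype <- factor(sg[, 2], levels = GENOTYPE_LEVELS)
    got <- got + 1L
    out[[got]] <- d
  }
  out
}

#' Fit the analysis on the real design plus K permuted designs
#'
#' @param expr Model-ready log2 expression matrix.
#' @param design Real sample design.
#' @param k Number of permuted designs (default 20).
#' @param seed Integer seed for the label draws.
#' @param features Optional probe/symbol map.
#' @param include_batch Passed to [bead_anova()].
#' @return An object of class `perm_ensemble` holding the real fit, the
#'   long result tables for the real and each permuted design, and the
#'   permuted designs themselves.
#' @export
permutation_ensemble <- function(expr, design, k = 20, seed = 1L,
                                 features = NULL, include_batch = "auto") {
  design <- .check_expr(expr, design)
  perms <- random_combinations(design, k = k, seed = seed)
  fit <- bead_anova(expr, design, features = features,
                    include_batch = include_batch)
  perm_tabs <- lapply(perms, function(d)
    probe_results(bead_anova(expr, d, features = features,
                             include_batch = include_batch)))
  structure(list(fit = fit, real = probe_results(fit), perms = perm_tabs,
                 designs = perms, k = k, seed = seed),
            class = "perm_ensemble")
}

#' @export
print.perm_ensemble <- function(x, ...) {
  cat(sprintf(
    "Permutation ensemble: real design + %d label re-combinations (seed %d)\n",
    x$k, x$seed))
  invisible(x)
}

#' Fold-change histogram, real analysis vs permutation mean
#'
#' Counts probes whose contrast p-value is below `p_cut`, binned by
#' absolute signed fold change into `[e1, e2), [e2, e3), ...` plus an
#' overflow bin, for the real design and (averaged) for the permuted
#' designs.  With real effects present the real counts exceed the
#' permutation mean even in the lowest |FC| bins.
#'
#' @param ensemble A [permutation_ensemble()].
#' @param family `"genotype"` or `"sex"`.
#' @param p_cut Contrast p-value cutoff (default 0.05).
#' @param bin_edges Increasing |FC| bin edges (default 1.0 to 3.0 by 0.1).
#' @return Data frame `bin_lo`, `bin_hi`, `real`, `perm_mean`.
#' @export
fc_histogram <- function(ensemble, family = c("genotype", "sex"),
                         p_cut = 0.05, bin_edges = seq(1, 3, by = 0.1)) {
  stopifnot(inherits(ensemble, "perm_ensemble"))
  family <- match.arg(family)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("config error: bin_edges must be strictly increasing")
  if (bin_edges[1] < 1) stop("config error: |FC| bins start at >= 1")
  nb <- length(bin_edges)
  count_one <- function(tab) {
    tab <- tab[tab$factor == family & tab$p_value < p_cut, , drop = FALSE]
    idx <- findInterval(abs(tab$fold_change), bin_edges)
    tabulate(idx[idx >= 1L], nbins = nb)
  }
  real <- count_one(ensemble$real)
  perm <- vapply(ensemble$perms, count_one, numeric(nb))
  data.frame(bin_lo = bin_edges,
             bin_hi = c(bin_edges[-1], Inf),
             real = real,
             perm_mean = rowMeans(perm))
}

#' Significant-gene counts across an FDR grid
#'
#' For each FDR level the number of unique significant genes is counted in
#' the real analysis and in every permuted analysis, per contrast family.
#' The recommended operating level is the largest grid level at which
#' every permutation yields zero significant genes, capped at the
#' conventional 0.05 when 0.05 itself qualifies.
#'
#' @param ensemble A [permutation_ensemble()].
#' @param grid Increasing FDR levels.
#' @param families Contrast families to sweep.
#' @return Object of class `fdr_sweep`: per family `real` counts (named by
#'   level) and `perm` count matrix (permutation x level), plus
#'   `recommended`.
#' @export
fdr_sweep <- function(ensemble, grid = c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25),
                      families = c("genotype", "sex")) {
  stopifnot(inherits(ensemble, "perm_ensemble"))
  if (!length(grid)) stop("config error: empty FDR grid")
  grid <- sort(grid)
  count_genes <- function(tab, fam, level) {
    sub <- tab[tab$factor == fam, , drop = FALSE]
    sum(.collapse_genes(sub)$q_value < level)
  }
  fam_out <- lapply(families, function(fam) {
    real <- vapply(grid, function(lv) count_genes(ensemble$real, fam, lv), 0)
    perm <- t(vapply(ensemble$perms, function(tb)
      vapply(grid, function(lv) count_genes(tb, fam, lv), 0),
      numeric(length(grid))))
    dimnames(perm) <- list(NULL, as.character(grid))
    list(real = stats::setNames(real, as.character(grid)), perm = perm)
  })
  names(fam_out) <- families
  all_perm <- do.call(cbind, lapply(fam_out, function(f) t(f$perm)))
  qual <- grid[apply(matrix(all_perm, nrow = length(grid)) == 0, 1L, all)]
  recommended <- if (!length(qual)) NA_real_
    else if (0.05 %in% qual) 0.05 else max(qual)
  structure(list(grid = grid, families = fam_out, recommended = recommended),
            class = "fdr_sweep")
}

#' @export
print.fdr_sweep <- function(x, ...) {
  cat("FDR sweep (unique significant genes per level)\n")
  for (fam in names(x$families)) {
    cat(sprintf("  %s: real ", fam))
    cat(paste(sprintf("%g@%s", x$families[[fam]]$real, names(x$families[[fam]]$real)),
              collapse = " "), "\n")
    cat(sprintf("    permutation max: %s\n",
                paste(apply(x$families[[fam]]$perm, 2L, max), collapse = " ")))
  }
  cat(sprintf("  recommended level: %s\n", format(x$recommended)))
  invisible(x)
}
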