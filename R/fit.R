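## Per-probe factorial ANOVA engine: three-way model with interaction
## (sex, genotype, chip batch, sex:genotype), Fisher LSD contrasts on the
## pooled residual variance, signed fold changes and per-family BH FDR.
## All probes are fitted in one pass of matrix least squares because the
## model matrix is shared across probes.

#' @noRd
.anova_engine <- function(expr, design, include_batch = TRUE) {
  design <- .check_expr(expr, design)
  if (nlevels(droplevels(design$sex)) < 2 ||
      nlevels(droplevels(design$genotype)) < 2)
    stop("model error: both sexes and both genotypes must be present")
  has_batch <- include_batch && !is.null(design$batch) &&
    nlevels(droplevels(design$batch)) >= 2
  dat <- design
  if (has_batch) dat$batch <- droplevels(dat$batch)
  fml <- if (has_batch) ~ sex + genotype + batch + sex:genotype
         else ~ sex + genotype + sex:genotype
  ctr <- list(sex = "contr.sum", genotype = "contr.sum")
  if (has_batch) ctr$batch <- "contr.sum"
  X <- stats::model.matrix(fml, dat, contrasts.arg = ctr)
  asgn <- attr(X, "assign")
  labs <- attr(stats::terms(fml), "term.labels")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    alias_cols <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    bad <- unique(labs[asgn[alias_cols]])
    stop("model error: aliased term(s): ", paste(bad, collapse = ", "))
  }
  n <- nrow(X)
  df_res <- n - ncol(X)
  if (df_res < 1) stop("model error: no residual degrees of freedom")

  Yt <- t(expr)                               # samples x probes
  fit <- stats::lm.fit(X, Yt)
  res <- as.matrix(fit$residuals)
  rss_full <- colSums(res^2)
  mse <- rss_full / df_res
  degenerate <- mse <= 1e-12 * pmax(1, colMeans(Yt^2))

  out_labs <- sub("^sex:genotype$", "interaction", labs)
  m <- ncol(Yt)
  SS <- Fv <- P <- matrix(NA_real_, m, length(labs),
                          dimnames = list(colnames(Yt), out_labs))
  df_term <- stats::setNames(integer(length(labs)), out_labs)
  for (ti in seq_along(labs)) {
    Xr <- X[, asgn != ti, drop = FALSE]
    rss_r <- colSums(as.matrix(stats::lm.fit(Xr, Yt)$residuals)^2)
    ss <- pmax(rss_r - rss_full, 0)
    dfi <- sum(asgn == ti)
    f <- (ss / dfi) / mse
    p <- stats::pf(f, dfi, df_res, lower.tail = FALSE)
    p[degenerate] <- 1            # zero residual variance convention
    SS[, ti] <- ss; Fv[, ti] <- f; P[, ti] <- p; df_term[ti] <- dfi
  }

  grp <- .group_of(design)
  cnt <- as.vector(table(grp))
  cellmeans <- t(rowsum(Yt, grp) / cnt)       # probes x 4 cells
  list(ss = SS, f = Fv, p = P, mse = mse, df_res = df_res,
       df_term = df_term, residual_ss = rss_full, residuals = t(res),
       cellmeans = cellmeans, degenerate = degenerate,
       design = design, has_batch = has_batch)
}

## pooled-variance LSD contrast between two sample index sets, vectorized
#' @noRd
.lsd_stats <- function(expr, idx_a, idx_b, mse, df_res) {
  if (!length(idx_a) || !length(idx_b)) stop("contrast error: empty group")
  est <- rowMeans(expr[, idx_a, drop = FALSE]) -
         rowMeans(expr[, idx_b, drop = FALSE])
  se <- sqrt(mse * (1 / length(idx_a) + 1 / length(idx_b)))
  t <- est / se
  t[se == 0 & est == 0] <- 0
  p <- 2 * stats::pt(abs(t), df_res, lower.tail = FALSE)
  p[se == 0 & est == 0] <- 1
  data.frame(estimate = est, t = t, p = p)
}

#' Fit the factorial ANOVA to one probe
#'
#' Single-probe interface to the shared least-squares engine: sums of
#' squares come from effect-coded factors, and for the balanced
#' 2x2(+batch) layout all classical ANOVA types coincide.  A probe with
#' zero residual variance returns p = 1 for every term by convention.
#'
#' @param y Numeric vector of log2 values, one per design row (in design
#'   order, or named by sample).
#' @param design Sample design.
#' @param include_batch Include the chip term when a batch column with
#'   >= 2 levels is present?
#' @return List with per-term `ss`, `f`, `p`, `df`, plus `mse`,
#'   `residual_ss` and `df_res`.
#' @export
fit_probe_anova <- function(y, design, include_batch = TRUE) {
  design <- .as_design(design)
  if (!is.null(names(y))) y <- y[design$sample_id]
  stopifnot(length(y) == nrow(design))
  expr <- matrix(y, 1L, length(y),
                 dimnames = list("y", design$sample_id))
  eng <- .anova_engine(expr, design, include_batch = include_batch)
  list(ss = eng$ss[1L, ], f = eng$f[1L, ], p = eng$p[1L, ],
       df = eng$df_term, mse = unname(eng$mse[1L]),
       residual_ss = unname(eng$residual_ss[1L]), df_res = eng$df_res)
}

#' Signed fold change from a log2 difference
#'
#' The antilog of the log2 ratio, reported with the negative-reciprocal
#' convention: `2^delta` when that is >= 1, else `-2^-delta` (so a halving
#' is -2.0, not 0.5).
#'
#' @param delta_log2 Numeric vector of log2 differences.
#' @return Signed fold changes, `|FC| >= 1`.
#' @export
signed_fold_change <- function(delta_log2) {
  stopifnot(all(is.finite(delta_log2)))
  r <- 2^delta_log2
  ifelse(r >= 1, r, -1 / r)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q(i) = min_{j: rank(j) >= rank(i)} m * p(j) / rank(j)`, capped at 1 and
#' returned in input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("data error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-probe factorial ANOVA differential expression
#'
#' The package's central fit: for every probe a three-way ANOVA with
#' interaction (sex, genotype, chip batch, sex:genotype) on effect-coded
#' factors, followed by Fisher LSD contrasts on the pooled residual
#' variance for the genotype (KO/WT) and sex (female/male) margins, signed
#' fold changes, and Benjamini-Hochberg FDR applied separately within the
#' genotype and sex contrast families.
#'
#' @param expr Log2-scale expression matrix (probes x samples), typically
#'   filtered, normalized and batch-adjusted.
#' @param design Sample design.
#' @param features Optional `probe_id`/`symbol` map; defaults to symbols
#'   equal to probe ids.
#' @param include_batch Include the chip term (`"auto"` uses it whenever a
#'   batch column with >= 2 levels is present; logical forces it).
#' @return An object of class `bead_anova`; see [probe_results()],
#'   [call_significant()] and the `print`/`summary`/`coef`/`residuals`/
#'   `plot`/`simulate` methods.
#' @examples
#' sim <- simulate_experiment(effect_spec(n_probes = 200, seed = 42))
#' fit <- bead_anova(log2_transform(sim$expr), sim$design,
#'                   features = sim$features)
#' fit
#' @export
bead_anova <- function(expr, design, features = NULL, include_batch = "auto") {
  design <- .check_expr(expr, design)
  use_batch <- if (identical(include_batch, "auto"))
    !is.null(design$batch) && nlevels(droplevels(design$batch)) >= 2
  else isTRUE(include_batch)
  eng <- .anova_engine(expr, design, include_batch = use_batch)

  ko <- which(design$genotype == "KO"); wt <- which(design$genotype == "WT")
  fe <- which(design$sex == "female"); ma <- which(design$sex == "male")
  gt <- .lsd_stats(expr, ko, wt, eng$mse, eng$df_res)
  sx <- .lsd_stats(expr, fe, ma, eng$mse, eng$df_res)

  probes <- rownames(expr)
  symbols <- if (is.null(features)) probes else {
    s <- features$symbol[match(probes, features$probe_id)]
    ifelse(is.na(s), probes, s)
  }
  tab <- data.frame(probe_id = probes, symbol = symbols,
                    stringsAsFactors = FALSE)
  for (term in colnames(eng$p)) {
    tab[[paste0("F_", term)]] <- eng$f[, term]
    tab[[paste0("p_", term)]] <- eng$p[, term]
  }
  tab$genotype_log2fc <- gt$estimate
  tab$genotype_t <- gt$t
  tab$genotype_p <- gt$p
  tab$genotype_fc <- signed_fold_change(gt$estimate)
  tab$genotype_q <- bh_fdr(gt$p)
  tab$sex_log2fc <- sx$estimate
  tab$sex_t <- sx$t
  tab$sex_p <- sx$p
  tab$sex_fc <- signed_fold_change(sx$estimate)
  tab$sex_q <- bh_fdr(sx$p)
  rownames(tab) <- NULL

  structure(list(table = tab, expr = expr, mse = eng$mse,
                 df_res = eng$df_res, df_term = eng$df_term,
                 cellmeans = eng$cellmeans, residuals = eng$residuals,
                 design = design, include_batch = eng$has_batch,
                 call = match.call()),
            class = "bead_anova")
}

#' Per-probe results in long (one row per probe and contrast family) form
#'
#' @param fit A [bead_anova()] object.
#' @param family `"genotype"`, `"sex"` or both (default).
#' @return Data frame with columns `probe_id`, `symbol`, `factor`,
#'   `log2fc`, `fold_change`, `t`, `p_value`, `q_value` — the schema
#'   consumed by [write_results()].
#' @export
probe_results <- function(fit, family = c("genotype", "sex")) {
  stopifnot(inherits(fit, "bead_anova"))
  family <- match.arg(family, several.ok = TRUE)
  tab <- fit$table
  do.call(rbind, lapply(family, function(fam)
    data.frame(probe_id = tab$probe_id, symbol = tab$symbol, factor = fam,
               log2fc = tab[[paste0(fam, "_log2fc")]],
               fold_change = tab[[paste0(fam, "_fc")]],
               t = tab[[paste0(fam, "_t")]],
               p_value = tab[[paste0(fam, "_p")]],
               q_value = tab[[paste0(fam, "_q")]],
               stringsAsFactors = FALSE)))
}

#' Fisher LSD contrast between two design cells or margins
#'
#' Groups are named by factor level (`"KO"`, `"WT"`, `"male"`, `"female"`)
#' or cell (`"female.KO"` etc.); the pooled residual variance and degrees
#' of freedom of the full fit are used, with no multiplicity adjustment at
#' this step.
#'
#' @param fit A [bead_anova()] object.
#' @param group_a,group_b Group labels as above.
#' @return Data frame per probe: `estimate` (log2), `t`, `p`.
#' @export
lsd_contrast <- function(fit, group_a, group_b) {
  stopifnot(inherits(fit, "bead_anova"))
  design <- fit$design
  pick <- function(g) {
    grp <- as.character(.group_of(design))
    idx <- if (g %in% SEX_LEVELS) which(design$sex == g)
      else if (g %in% GENOTYPE_LEVELS) which(design$genotype == g)
      else which(grp == g)
    if (!length(idx)) stop("contrast error: empty group '", g, "'")
    idx
  }
  a <- pick(group_a); b <- pick(group_b)
  out <- .lsd_stats(fit$expr, a, b, fit$mse, fit$df_res)
  rownames(out) <- fit$table$probe_id
  out
}

#' Call significant genes within a contrast family
#'
#' Probes with family q-value below `fdr` are collapsed to unique gene
#' symbols: a symbol is significant if any of its probes is, and the
#' reported fold change comes from its most significant probe (ties broken
#' by larger |FC|, then probe id).
#'
#' @param fit A [bead_anova()] object or a long table from
#'   [probe_results()].
#' @param family `"genotype"` or `"sex"`.
#' @param fdr FDR threshold (default 0.05).
#' @return Data frame `symbol`, `fold_change`, `p_value`, `q_value`,
#'   `probe_id`, ordered by p-value.
#' @export
call_significant <- function(fit, family = c("genotype", "sex"), fdr = 0.05) {
  family <- match.arg(family)
  res <- if (inherits(fit, "bead_anova")) probe_results(fit, family)
         else fit[fit$factor == family, , drop = FALSE]
  collapsed <- .collapse_genes(res)
  out <- collapsed[collapsed$q_value < fdr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## one row per symbol: the most significant probe (p, then |FC|, then id)
#' @noRd
.collapse_genes <- function(res) {
  ord <- order(res$p_value, -abs(res$fold_change), res$probe_id)
  res <- res[ord, , drop = FALSE]
  res <- res[!duplicated(res$symbol), , drop = FALSE]
  res[c("symbol", "fold_change", "p_value", "q_value", "probe_id")]
}

#' Sex-stratified KO-vs-WT contrasts
#'
#' Fits the genotype contrast separately within males and within females
#' (each with its own pooled variance, keeping the chip term when it is
#' estimable within the stratum), applies BH within each stratum, and
#' intersects the significant gene symbol sets.
#'
#' @param expr Log2-scale expression matrix.
#' @param design Sample design with both sexes present.
#' @param features Optional probe/symbol map.
#' @param alpha Threshold applied to `measure`.
#' @param measure `"p"` (raw contrast p, the relaxed-threshold pathway
#'   analysis convention) or `"q"` (BH-adjusted).
#' @return List with per-sex result tables (`male`, `female`) and symbol
#'   sets `intersection`, `male_only`, `female_only`.
#' @export
stratified_contrasts <- function(expr, design, features = NULL,
                                 alpha = 0.05, measure = c("p", "q")) {
  measure <- match.arg(measure)
  design <- .check_expr(expr, design)
  if (nlevels(droplevels(design$sex)) < 2)
    stop("design error: both sexes must be present")
  one_sex <- function(sx) {
    keep <- design$sex == sx
    sub <- droplevels(design[keep, , drop = FALSE])
    ex <- expr[, keep, drop = FALSE]
    fml <- ~genotype
    if (!is.null(sub$batch) && nlevels(sub$batch) >= 2) {
      X2 <- stats::model.matrix(~ genotype + batch, sub)
      if (qr(X2)$rank == ncol(X2)) fml <- ~ genotype + batch
    }
    X <- stats::model.matrix(fml, sub)
    f <- stats::lm.fit(X, t(ex))
    df_res <- nrow(X) - ncol(X)
    mse <- colSums(as.matrix(f$residuals)^2) / df_res
    st <- .lsd_stats(ex, which(sub$genotype == "KO"),
                     which(sub$genotype == "WT"), mse, df_res)
    probes <- rownames(ex)
    symbols <- if (is.null(features)) probes else {
      s <- features$symbol[match(probes, features$probe_id)]
      ifelse(is.na(s), probes, s)
    }
    data.frame(probe_id = probes, symbol = symbols, factor = "genotype",
               log2fc = st$estimate,
               fold_change = signed_fold_change(st$estimate),
               t = st$t, p_value = st$p, q_value = bh_fdr(st$p),
               stringsAsFactors = FALSE)
  }
  male <- one_sex("male"); female <- one_sex("female")
  sig <- function(tb) unique(tb$symbol[
    (if (measure == "p") tb$p_value else tb$q_value) < alpha])
  ms <- sig(male); fs <- sig(female)
  list(male = male, female = female,
       intersection = sort(intersect(ms, fs)),
       male_only = sort(setdiff(ms, fs)),
       female_only = sort(setdiff(fs, ms)))
}
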