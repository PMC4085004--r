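## S3 methods for the bead_anova fit object.

#' @export
print.bead_anova <- function(x, ...) {
  tab <- x$table
  cat("Factorial ANOVA differential expression fit\n")
  cat(sprintf("  %d probes, %d samples; batch term: %s; residual df = %d\n",
              nrow(tab), nrow(x$design),
              if (x$include_batch) "yes" else "no", x$df_res))
  for (fam in c("genotype", "sex"))
    cat(sprintf("  %s family: %d probes q < 0.05 (%d unique genes)\n", fam,
                sum(tab[[paste0(fam, "_q")]] < 0.05),
                nrow(call_significant(x, fam, 0.05))))
  invisible(x)
}

#' @export
summary.bead_anova <- function(object, fdr = 0.05, ...) {
  tab <- object$table
  fam_stats <- lapply(c(genotype = "genotype", sex = "sex"), function(fam) {
    sig <- call_significant(object, fam, fdr)
    list(n_probes_sig = sum(tab[[paste0(fam, "_q")]] < fdr),
         n_genes_sig = nrow(sig), top = utils::head(sig, 10L))
  })
  structure(list(n_probes = nrow(tab), n_samples = nrow(object$design),
                 include_batch = object$include_batch,
                 df_res = object$df_res, fdr = fdr, families = fam_stats),
            class = "summary.bead_anova")
}

#' @export
print.summary.bead_anova <- function(x, ...) {
  cat(sprintf("Factorial ANOVA DE summary: %d probes, %d samples (FDR %.2f)\n",
              x$n_probes, x$n_samples, x$fdr))
  for (fam in names(x$families)) {
    fs <- x$families[[fam]]
    cat(sprintf("\n%s contrast: %d significant probe sets, %d unique genes\n",
                fam, fs$n_probes_sig, fs$n_genes_sig))
    if (nrow(fs$top)) {
      cat("top genes:\n")
      print(fs$top, digits = 3)
    }
  }
  invisible(x)
}

#' @export
coef.bead_anova <- function(object, ...) {
  tab <- object$table
  out <- cbind(genotype = tab$genotype_log2fc, sex = tab$sex_log2fc)
  rownames(out) <- tab$probe_id
  out
}

#' @export
residuals.bead_anova <- function(object, ...) object$residuals

#' Diagnostic plots for a factorial DE fit
#'
#' `which = "pvalue"` draws the contrast p-value histograms for both
#' families (flat under the null, spiked near zero with real effects);
#' `which = "volcano"` draws |signed fold change| direction vs
#' -log10 p for one family.
#'
#' @param x A [bead_anova()] object.
#' @param which `"pvalue"` or `"volcano"`.
#' @param family Family for the volcano panel.
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.bead_anova <- function(x, which = c("pvalue", "volcano"),
                            family = c("genotype", "sex"), ...) {
  which <- match.arg(which)
  family <- match.arg(family)
  tab <- x$table
  if (which == "pvalue") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    for (fam in c("genotype", "sex"))
      graphics::hist(tab[[paste0(fam, "_p")]], breaks = 20,
                     main = paste(fam, "contrast"), xlab = "p-value", ...)
  } else {
    p <- tab[[paste0(family, "_p")]]
    lfc <- tab[[paste0(family, "_log2fc")]]
    q <- tab[[paste0(family, "_q")]]
    graphics::plot(lfc, -log10(p), pch = 20,
                   col = ifelse(q < 0.05, "red3", grDevices::grey(0.6)),
                   xlab = "log2 fold change", ylab = "-log10 p",
                   main = paste(family, "volcano"), ...)
  }
  invisible(x)
}

#' Simulate replicate matrices from a fitted model
#'
#' Draws new log2 matrices from the fitted sex x genotype cell means with
#' per-probe residual sd `sqrt(MSE)` (the chip term is not resimulated).
#'
#' @param object A [bead_anova()] object.
#' @param nsim Number of matrices.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` matrices on the fitted axes.
#' @export
simulate.bead_anova <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  grp <- .group_of(object$design)
  mu <- object$cellmeans[, as.integer(grp), drop = FALSE]
  dimnames(mu) <- list(object$table$probe_id, object$design$sample_id)
  sd_p <- sqrt(object$mse)
  lapply(seq_len(nsim), function(i) {
    out <- mu + matrix(stats::rnorm(length(mu), 0, sd_p),
                       nrow(mu), ncol(mu))
    attr(out, "scale") <- "log2"
    out
  })
}
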