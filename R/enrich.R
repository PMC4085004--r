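## Hypergeometric gene-set enrichment and complete-linkage hierarchical
## clustering of z-scored expression profiles.

#' Hypergeometric gene-set enrichment
#'
#' For each set, the upper-tail probability `P(X >= k)` that `k` of the
#' `n` query genes fall in a set of size `K` drawn from a universe of size
#' `N` — the chance that the observed mapping of the experiment to the set
#' arises at random.  Symbols are matched case-insensitively; each set is
#' intersected with the universe before testing, and BH adjustment is
#' applied across the tested sets.  The universe should normally be the
#' genes surviving the detection filter, not the whole genome.
#'
#' @param query Character vector of significant gene symbols.
#' @param sets A [read_gmt()] collection (named list of symbol vectors).
#' @param universe Character vector of background symbols.
#' @return Data frame ranked by p: `set`, `description`, `K` (set size in
#'   universe), `k` (overlap with query), `p`, `q`.  Query symbols absent
#'   from the universe are dropped with a warning; the number dropped is
#'   kept in the `n_dropped` attribute.
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  universe <- unique(.norm_symbol(universe))
  if (!length(universe)) stop("data error: empty universe")
  query <- unique(.norm_symbol(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) absent from universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  desc <- attr(sets, "descriptions")
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(.norm_symbol(sets[[nm]])), universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm,
               description = if (is.null(desc)) nm else unname(desc[nm]),
               K = K, k = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(outside)
  out
}

#' Complete-linkage hierarchical clustering of z-scored profiles
#'
#' Rows (or samples, via `axis`) are shifted to mean zero and sd one, then
#' clustered agglomeratively on Euclidean distances under complete linkage,
#' where the distance between two clusters is the distance between their
#' two furthest members.  Zero-variance rows have no z-score and are
#' excluded with a warning.
#'
#' @param expr Expression (sub)matrix, typically the significant probes.
#' @param axis Cluster `"probes"` (rows, after z-scoring each probe) or
#'   `"samples"` (columns of the row-z-scored matrix).
#' @return List with `hclust` (a [stats::hclust] tree), `order` (leaf
#'   labels in dendrogram order), `zscores` (the z-scored matrix) and
#'   `excluded` (zero-variance row names).
#' @export
hcl_cluster <- function(expr, axis = c("probes", "samples")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (nrow(expr) < 2 || ncol(expr) < 2)
    stop("need at least 2 rows and 2 columns")
  rsd <- apply(expr, 1L, stats::sd)
  excluded <- rownames(expr)[rsd == 0]
  if (length(excluded)) {
    warning("excluding ", length(excluded), " zero-variance row(s)")
    expr <- expr[rsd > 0, , drop = FALSE]
    rsd <- rsd[rsd > 0]
  }
  z <- (expr - rowMeans(expr)) / rsd
  items <- if (axis == "probes") z else t(z)
  if (nrow(items) < 2) stop("fewer than 2 items left to cluster")
  hc <- stats::hclust(stats::dist(items, method = "euclidean"),
                      method = "complete")
  list(hclust = hc, order = hc$labels[hc$order], zscores = z,
       excluded = excluded)
}

#' Serialize a dendrogram as a Newick string
#'
#' Merge heights become branch lengths (each leaf/cluster branch spans the
#' height difference to its parent merge).
#'
#' @param hc A [stats::hclust] object (or [hcl_cluster()] result).
#' @param path Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
hcl_newick <- function(hc, path = NULL) {
  if (is.list(hc) && !inherits(hc, "hclust")) hc <- hc$hclust
  stopifnot(inherits(hc, "hclust"))
  build <- function(i, parent_h) {
    if (i < 0) {   # leaf
      lab <- hc$labels[-i]
      return(sprintf("%s:%.12g", lab, parent_h))
    }
    h <- hc$height[i]
    sprintf("(%s,%s):%.12g", build(hc$merge[i, 1], h),
            build(hc$merge[i, 2], h), parent_h - h)
  }
  k <- length(hc$height)
  nwk <- paste0(sub(":[^:]*$", "",
                    build(k, hc$height[k])), ";")
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}
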