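## Readers and writers for the external formats the pipeline touches:
## Genome-Studio-style sample probe profiles, GEO series matrices, GMT gene
## set collections, SIF-like typed edge lists and TSV result tables.  All
## downstream stages consume only the in-memory objects built here.

#' Read a Genome-Studio-style sample probe profile
#'
#' Parses a tab-delimited probe-profile export: one probe-identifier column
#' (name containing `Probe`), an optional symbol column (name containing
#' `Symbol`), and per sample one signal column (`<sample>.AVG_Signal`) and
#' one detection p-value column (`<sample>.Detection Pval`).  Rows for the
#' same probe (on-array replicates) are averaged on the raw intensity scale
#' when `collapse_replicates` is set, as Genome Studio does before export.
#'
#' @param path Path to the tab-delimited profile.
#' @param collapse_replicates Average duplicated probe rows (raw scale)?
#' @return A list with components `expr` (raw-scale expression matrix,
#'   probes x samples, `scale` attribute `"raw"`), `det` (detection p-value
#'   matrix on the same axes) and `features` (data frame `probe_id`,
#'   `symbol`).
#' @export
read_probe_profile <- function(path, collapse_replicates = TRUE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(tab)
  probe_col <- grep("probe", nm, ignore.case = TRUE, value = TRUE)[1]
  if (is.na(probe_col)) stop("format error: no probe-identifier column")
  sig_cols <- grep("\\.AVG_Signal$", nm, value = TRUE)
  det_cols <- grep("\\.Detection Pval$", nm, value = TRUE)
  if (!length(det_cols))
    stop("format error: no 'Detection Pval' columns in header")
  if (!length(sig_cols))
    stop("format error: no 'AVG_Signal' columns in header")
  sig_samples <- sub("\\.AVG_Signal$", "", sig_cols)
  det_samples <- sub("\\.Detection Pval$", "", det_cols)
  if (!setequal(sig_samples, det_samples))
    stop("format error: signal and detection columns name different samples")
  det_cols <- det_cols[match(sig_samples, det_samples)]

  probes <- as.character(tab[[probe_col]])
  sym_col <- grep("symbol", nm, ignore.case = TRUE, value = TRUE)[1]
  symbols <- if (is.na(sym_col)) probes else as.character(tab[[sym_col]])

  expr <- as.matrix(tab[sig_cols]); det <- as.matrix(tab[det_cols])
  colnames(expr) <- colnames(det) <- sig_samples

  if (anyDuplicated(probes)) {
    if (!collapse_replicates)
      stop("format error: duplicated probe rows; set collapse_replicates")
    sym_by_probe <- tapply(symbols, probes, function(s) length(unique(s)))
    bad <- names(sym_by_probe)[sym_by_probe > 1]
    if (length(bad))
      stop("format error: probe(s) with conflicting symbol: ",
           paste(bad, collapse = ", "))
    idx <- factor(probes, levels = unique(probes))
    expr <- rowsum(expr, idx) / as.vector(table(idx))
    det <- rowsum(det, idx) / as.vector(table(idx))
    symbols <- symbols[!duplicated(probes)]
    probes <- levels(idx)
  }
  rownames(expr) <- rownames(det) <- probes
  list(expr = .set_scale(expr, "raw"), det = det,
       features = data.frame(probe_id = probes, symbol = symbols,
                             stringsAsFactors = FALSE))
}

#' Write a probe profile in Genome-Studio export layout
#'
#' @param expr,det Expression and detection matrices on identical axes.
#' @param features Optional `probe_id`/`symbol` map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_profile <- function(expr, det, path, features = NULL) {
  .check_expr(expr)
  stopifnot(identical(dim(expr), dim(det)))
  symbols <- if (is.null(features)) rownames(expr) else
    features$symbol[match(rownames(expr), features$probe_id)]
  out <- data.frame(ProbeID = rownames(expr), Symbol = symbols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(expr)) {
    out[[paste0(s, ".AVG_Signal")]] <- expr[, s]
    out[[paste0(s, ".Detection Pval")]] <- det[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Reads the `!series_matrix_table_begin` ... `!series_matrix_table_end`
#' block into an expression matrix and recovers whatever sex / genotype /
#' batch annotation is present on `!Sample_characteristics_ch1` lines
#' (`key: value` entries, e.g. `Sex: female`).  Factors that are not
#' annotated are left `NA` for a manifest override.
#'
#' @param path Path to an uncompressed series-matrix text file.
#' @param scale Scale tag to attach; deposited matrices may be raw or
#'   normalized log2, and the file itself does not say which.
#' @return List with `expr` and a partial `design` data frame.
#' @export
read_series_matrix <- function(path, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
    stop("format error: truncated or missing series matrix table block")
  tab <- utils::read.delim(text = lines[(beg + 1):(end - 1)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- as.character(tab[[1]])
  colnames(expr) <- gsub('"', "", colnames(expr))
  expr <- .set_scale(expr, scale)

  design <- data.frame(sample_id = colnames(expr),
                       sex = NA_character_, genotype = NA_character_,
                       batch = NA_character_, stringsAsFactors = FALSE)
  ch <- grep("^!Sample_characteristics_ch1", lines, value = TRUE)
  for (line in ch) {
    fields <- gsub('"', "", strsplit(line, "\t")[[1]][-1])
    if (length(fields) != ncol(expr)) next
    key <- tolower(trimws(sub(":.*$", "", fields)))
    val <- trimws(sub("^[^:]*:", "", fields))
    for (j in seq_along(fields)) {
      if (key[j] %in% "sex") design$sex[j] <- tolower(val[j])
      if (key[j] %in% c("genotype", "genotype/variation"))
        design$genotype[j] <- val[j]
      if (key[j] %in% c("batch", "chip")) design$batch[j] <- val[j]
    }
  }
  list(expr = expr, design = design)
}

#' Write a minimal GEO-style series matrix
#'
#' @param expr Expression matrix.
#' @param path Output path.
#' @param design Optional design; sex/genotype/batch are emitted as
#'   `!Sample_characteristics_ch1` lines.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(expr, path, design = NULL) {
  .check_expr(expr)
  con <- file(path, "w"); on.exit(close(con))
  qt <- function(x) paste0('"', x, '"')
  writeLines(paste(c("!Sample_title", qt(colnames(expr))), collapse = "\t"), con)
  if (!is.null(design)) {
    d <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
    for (key in c("sex", "genotype", "batch")) {
      if (is.null(d[[key]])) next
      writeLines(paste(c("!Sample_characteristics_ch1",
                         qt(paste0(key, ": ", d[[key]]))), collapse = "\t"), con)
    }
  }
  writeLines("!series_matrix_table_begin", con)
  writeLines(paste(c("ID_REF", qt(colnames(expr))), collapse = "\t"), con)
  utils::write.table(
    data.frame(ID_REF = rownames(expr), expr, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Member symbols are matched case-insensitively throughout the package.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member symbols, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stop("format error: GMT line with empty member list: line ",
         which(bad)[1])
  sets <- lapply(parts, function(p) .norm_symbol(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of member character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to the
#'   `descriptions` attribute or the set name.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

EDGE_TYPES <- c("tf_target", "ligand_receptor", "other")
NODE_ROLES <- c("transcription_factor", "receptor", "ligand", "other")

#' Read a SIF-like typed interaction graph
#'
#' Each edge line is `source <TAB> edge_type <TAB> target` with
#' `edge_type` one of `tf_target`, `ligand_receptor`, `other`; any other
#' type is an error rather than being coerced.  Node roles come from a side
#' table (`node <TAB> role`, roles `transcription_factor`, `receptor`,
#' `ligand`, `other`); unlisted nodes get role `other`.  Node names are
#' upper-cased so downstream symbol matching is case-insensitive.
#'
#' @param path Path to the edge list.
#' @param roles A data frame (`node`, `role`) or path to a two-column TSV.
#' @return A directed [igraph::igraph] with vertex attribute `role` and edge
#'   attribute `type`.
#' @export
read_sif <- function(path, roles = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  if (any(vapply(parts, length, 1L) != 3L))
    stop("format error: SIF lines must be 'source type target'")
  el <- do.call(rbind, parts)
  if (!all(el[, 2] %in% EDGE_TYPES))
    stop("format error: unknown edge type(s): ",
         paste(unique(setdiff(el[, 2], EDGE_TYPES)), collapse = ", "))
  edges <- data.frame(from = .norm_symbol(el[, 1]), to = .norm_symbol(el[, 3]),
                      type = el[, 2], stringsAsFactors = FALSE)
  if (is.character(roles) && length(roles) == 1L)
    roles <- utils::read.delim(roles, header = FALSE,
                               col.names = c("node", "role"),
                               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  role <- rep("other", igraph::vcount(g))
  if (!is.null(roles)) {
    if (!all(roles$role %in% NODE_ROLES))
      stop("format error: unknown node role(s): ",
           paste(unique(setdiff(roles$role, NODE_ROLES)), collapse = ", "))
    m <- match(igraph::V(g)$name, .norm_symbol(roles$node))
    role[!is.na(m)] <- roles$role[m[!is.na(m)]]
  }
  igraph::V(g)$role <- role
  g
}

#' Write a typed interaction graph as a SIF-like edge list
#' @param graph Graph from [read_sif()].
#' @param path Output path for edges.
#' @param roles_path Optional output path for the node-role side table.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path, roles_path = NULL) {
  el <- igraph::as_data_frame(graph, what = "edges")
  writeLines(paste(el$from, el$type, el$to, sep = "\t"), path)
  if (!is.null(roles_path))
    utils::write.table(
      data.frame(node = igraph::V(graph)$name, role = igraph::V(graph)$role),
      roles_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read per-probe result tables
#'
#' The TSV schema mirrors the published per-contrast gene tables: columns
#' `symbol`, `fold_change`, `p_value`, `q_value`, `factor`.
#'
#' @param results Data frame carrying at least those columns.
#' @param path File path.
#' @return `write_results`: `path` invisibly; `read_results`: the data frame.
#' @export
write_results <- function(results, path) {
  need <- c("symbol", "fold_change", "p_value", "q_value", "factor")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("results table missing column(s): ", paste(miss, collapse = ", "))
  utils::write.table(results[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a published fold-change gene table
#'
#' Parses the layout of the study's printed differential-expression tables
#' (`Gene Name`, `Symbol`, `FC`, `p.value`), as shipped under
#' `inst/extdata/` for the GSE55936 cardiomyocyte ERalpha-knockout study.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `gene_name`, `symbol`, `fc`, `p_value`.
#' @export
read_fc_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("format error: expected 4 columns")
  out <- data.frame(gene_name = tab[[1]], symbol = tab[[2]],
                    fc = as.numeric(tab[[3]]), p_value = as.numeric(tab[[4]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$fc) || anyNA(out$p_value))
    stop("format error: non-numeric FC or p.value entries")
  out
}
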