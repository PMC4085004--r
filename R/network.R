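## Transcription-factor and receptor subnetwork extraction on a typed,
## directed interaction graph, plus the hypergeometric saturation score.
## Traversal follows edge direction (TF -> target, ligand -> receptor).

#' @noRd
.root_nodes <- function(graph, root) {
  intersect(igraph::V(graph)$name, unique(.norm_symbol(root)))
}

#' Per-transcription-factor shortest-path subnetworks
#'
#' A transcription factor is eligible when it has at least one direct
#' `tf_target` edge into the root gene list; a receptor is eligible when it
#' has at least one direct root-list neighbor.  For each eligible TF the
#' subnetwork is the union of all shortest directed paths from the TF to
#' every eligible receptor at the minimal distance `d*`; ties across
#' receptors at `d*` are all included.  A TF with no reachable eligible
#' receptor is reported as unreachable.  Self-loops never count as paths.
#'
#' @param graph Typed directed graph from [read_sif()] (vertex `role`,
#'   edge `type` attributes required).
#' @param root Character vector of root gene symbols (the significant
#'   gene list seeding the network).
#' @return Named list (one element per eligible TF) of lists with `tf`,
#'   `d` (path length, `NA` if unreachable), `receptors`, `nodes`,
#'   `edges` (data frame `from`, `to`, `type`) and `unreachable`.
#' @export
tf_subnetworks <- function(graph, root) {
  if (is.null(igraph::V(graph)$role))
    stop("data error: graph has no node role flags")
  root <- .root_nodes(graph, root)
  if (!length(root)) return(structure(list(), names = character(0)))
  vnames <- igraph::V(graph)$name
  roles <- igraph::V(graph)$role

  el <- igraph::as_data_frame(graph, what = "edges")
  tf_edges <- el[el$type == "tf_target" & el$to %in% root &
                   el$from != el$to, , drop = FALSE]
  tfs <- intersect(vnames[roles == "transcription_factor"],
                   unique(tf_edges$from))

  receptors <- vnames[roles == "receptor"]
  receptors <- receptors[vapply(receptors, function(r) {
    nb <- unique(c(el$to[el$from == r], el$from[el$to == r]))
    length(intersect(setdiff(nb, r), root)) > 0
  }, logical(1))]

  out <- lapply(tfs, function(tf) {
    targets <- setdiff(receptors, tf)
    if (!length(targets))
      return(list(tf = tf, d = NA_real_, receptors = character(0),
                  nodes = character(0),
                  edges = el[0, c("from", "to", "type")], unreachable = TRUE))
    dm <- igraph::distances(graph, v = tf, to = targets, mode = "out")
    d <- stats::setNames(as.vector(dm[1, ]), colnames(dm))
    if (!any(is.finite(d)))
      return(list(tf = tf, d = NA_real_, receptors = character(0),
                  nodes = character(0),
                  edges = el[0, c("from", "to", "type")], unreachable = TRUE))
    dstar <- min(d[is.finite(d)])
    close_rec <- names(d)[is.finite(d) & d == dstar]
    nodes <- character(0); epairs <- el[0, c("from", "to", "type")]
    for (r in close_rec) {
      paths <- igraph::all_shortest_paths(graph, from = tf, to = r,
                                          mode = "out")$vpaths
      for (pp in paths) {
        pn <- vnames[as.integer(pp)]
        nodes <- union(nodes, pn)
        if (length(pn) > 1) {
          pe <- data.frame(from = pn[-length(pn)], to = pn[-1],
                           stringsAsFactors = FALSE)
          pe$type <- apply(pe, 1L, function(e)
            el$type[el$from == e[["from"]] & el$to == e[["to"]]][1])
          epairs <- rbind(epairs, pe)
        }
      }
    }
    epairs <- unique(epairs)
    rownames(epairs) <- NULL
    list(tf = tf, d = dstar, receptors = close_rec, nodes = nodes,
         edges = epairs, unreachable = FALSE)
  })
  names(out) <- tfs
  out
}

#' Receptor / ligand subgraph of the root list
#'
#' The induced subgraph on root-list nodes flagged `receptor` or `ligand`,
#' keeping the ligand-to-receptor edges among them; every other node is
#' hidden.  When a result table is supplied each node is annotated with
#' its expression direction (up for positive fold change, down for
#' negative).
#'
#' @param graph Typed directed graph from [read_sif()].
#' @param root Root gene symbols.
#' @param results Optional long result table ([probe_results()] or a
#'   `symbol`/`fold_change`-bearing data frame).
#' @return List with `nodes` (data frame `node`, `role`, `regulation`) and
#'   `edges` (data frame `from`, `to`, `type`).
#' @export
receptor_network <- function(graph, root, results = NULL) {
  root <- .root_nodes(graph, root)
  roles <- igraph::V(graph)$role
  keep <- igraph::V(graph)$name[roles %in% c("receptor", "ligand")]
  keep <- intersect(keep, root)
  sub <- igraph::induced_subgraph(graph, keep)
  el <- igraph::as_data_frame(sub, what = "edges")
  if (!nrow(el)) el <- data.frame(from = character(0), to = character(0),
                                  type = character(0))
  el <- el[el$type == "ligand_receptor", c("from", "to", "type"), drop = FALSE]
  rownames(el) <- NULL
  nodes <- data.frame(node = keep,
                      role = roles[match(keep, igraph::V(graph)$name)],
                      regulation = rep(NA_character_, length(keep)),
                      stringsAsFactors = FALSE)
  if (!is.null(results) && nrow(nodes)) {
    fc_col <- if ("fold_change" %in% names(results)) "fold_change" else "fc"
    m <- match(nodes$node, .norm_symbol(results$symbol))
    fc <- results[[fc_col]][m]
    nodes$regulation <- ifelse(is.na(fc), NA_character_,
                               ifelse(fc > 0, "up", "down"))
  }
  list(nodes = nodes, edges = el)
}

#' Hypergeometric saturation score of a subnetwork
#'
#' The upper-tail probability of drawing at least the observed number of
#' root-list nodes when `|subnetwork|` nodes are sampled from the node
#' universe.  A node-only statistic: edge directions do not enter.
#'
#' @param nodes Character vector of subnetwork node names (or a
#'   [tf_subnetworks()] element).
#' @param root Root gene symbols.
#' @param universe All node symbols eligible to appear in subnetworks
#'   (normally every graph node).
#' @return The saturation p-value.
#' @export
score_subnetwork <- function(nodes, root, universe) {
  if (is.list(nodes)) nodes <- nodes$nodes
  nodes <- unique(.norm_symbol(nodes))
  root <- unique(.norm_symbol(root))
  universe <- unique(.norm_symbol(universe))
  if (length(setdiff(nodes, universe)))
    stop("data error: subnetwork nodes outside the universe")
  N <- length(universe)
  K <- length(intersect(root, universe))
  n <- length(nodes)
  k <- length(intersect(nodes, root))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
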