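# Signed correlation graphs, Prim minimum spanning trees, and a transparent
# annotation-category percentage scorer used in place of a commercial pathway
# knowledge base.

#' Build a signed correlation graph over treatment responses
#'
#' Nodes are all candidates plus every partner with at least one qualifying
#' correlation; edges connect any node pair (candidate-partner and
#' partner-partner alike) with `|r| >= r_min`. Edge weight is `1 - |r|`, so
#' the strongest correlation is the shortest edge; the sign of r is kept.
#'
#' @param candidates,partners Response matrices (features x patients) with
#'   shared patient columns. `partners` may be `NULL` for a candidates-only
#'   graph.
#' @param r_min Correlation magnitude threshold for an edge.
#' @param star_only Keep only candidate-incident edges.
#' @return A list of class `corr_graph` with `nodes` (id, role) and `edges`
#'   (from, to, r, weight, sign) data.frames; an empty node set yields an
#'   empty graph.
#' @export
build_graph <- function(candidates, partners = NULL, r_min = 0.7,
                        star_only = FALSE) {
  mats <- list(candidate = candidates, partner = partners)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!length(mats) || !sum(vapply(mats, nrow, integer(1)))) {
    return(structure(list(nodes = data.frame(id = character(0),
                                             role = character(0)),
                          edges = empty_edges()), class = "corr_graph"))
  }
  x <- do.call(rbind, mats)
  role <- rep(names(mats), vapply(mats, nrow, integer(1)))
  ids <- unlist(lapply(mats, rownames), use.names = FALSE)
  r <- suppressWarnings(stats::cor(t(x)))
  r[!is.finite(r)] <- 0
  pairs <- which(upper.tri(r) & abs(r) >= r_min, arr.ind = TRUE)
  edges <- data.frame(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                      r = r[pairs],
                      weight = 1 - abs(r[pairs]),
                      sign = sign(r[pairs]),
                      stringsAsFactors = FALSE)
  if (star_only && nrow(edges)) {
    cand_ids <- ids[role == "candidate"]
    edges <- edges[edges$from %in% cand_ids | edges$to %in% cand_ids, ,
                   drop = FALSE]
  }
  keep <- role == "candidate" | ids %in% c(edges$from, edges$to)
  nodes <- data.frame(id = ids[keep], role = role[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[edges$from %in% nodes$id & edges$to %in% nodes$id, ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "corr_graph")
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0), r = numeric(0),
             weight = numeric(0), sign = numeric(0), stringsAsFactors = FALSE)
}

#' Prim minimum spanning tree (forest on disconnected graphs)
#'
#' Grows a minimum-total-weight spanning tree per connected component with
#' Prim's algorithm. Deterministic: each component is grown from its
#' lexicographically smallest node, and among equal-weight frontier edges the
#' lexicographically smallest (sorted node-id pair) wins.
#'
#' @param graph A [build_graph()] result.
#' @return The graph with an `in_mst` logical edge column, plus
#'   `total_weight` (sum over tree edges) and `n_components`.
#' @export
prim_mst <- function(graph) {
  stopifnot(inherits(graph, "corr_graph"))
  nodes <- graph$nodes$id
  edges <- graph$edges
  in_mst <- logical(nrow(edges))
  if (length(nodes)) {
    nv <- length(nodes)
    ef <- match(edges$from, nodes)
    et <- match(edges$to, nodes)
    ## edge priority precomputed once: weight, then lexicographic node pair
    prio <- integer(nrow(edges))
    prio[order(edges$weight, pmin(edges$from, edges$to),
               pmax(edges$from, edges$to))] <- seq_len(nrow(edges))
    inc <- lapply(seq_len(nv), function(i) integer(0))
    for (e in seq_len(nrow(edges))) {
      inc[[ef[e]]] <- c(inc[[ef[e]]], e)
      inc[[et[e]]] <- c(inc[[et[e]]], e)
    }
    visited <- logical(nv)
    node_rank <- order(nodes) # lexicographic start order
    while (!all(visited)) {
      start <- node_rank[which(!visited[node_rank])[1]]
      visited[start] <- TRUE
      frontier <- inc[[start]]
      repeat {
        frontier <- frontier[xor(visited[ef[frontier]], visited[et[frontier]])]
        if (!length(frontier)) break
        pick <- frontier[which.min(prio[frontier])]
        in_mst[pick] <- TRUE
        new_node <- if (visited[ef[pick]]) et[pick] else ef[pick]
        visited[new_node] <- TRUE
        frontier <- c(frontier, inc[[new_node]])
      }
    }
  }
  graph$edges$in_mst <- in_mst
  graph$total_weight <- sum(edges$weight[in_mst])
  graph$n_components <- length(nodes) - sum(in_mst)
  graph
}

#' Percentage of network nodes per annotation category
#'
#' For each category label, the percentage of network nodes annotated with
#' it: `100 * |annotated nodes in category| / |nodes|`, ranked by decreasing
#' percentage (ties by label).
#'
#' @param nodes Character vector of node ids (or a `corr_graph`).
#' @param categories Named list from [read_categories()].
#' @param top_k Number of categories to keep (default 10).
#' @return Data.frame `category`, `n`, `percent`; empty (with a warning) when
#'   no node is annotated.
#' @export
category_percentage <- function(nodes, categories, top_k = 10) {
  if (inherits(nodes, "corr_graph")) nodes <- nodes$nodes$id
  if (!length(nodes)) contract_error("empty node set")
  labs <- unlist(categories[intersect(nodes, names(categories))],
                 use.names = FALSE)
  if (!length(labs)) {
    warnf("no network node carries a category annotation")
    return(data.frame(category = character(0), n = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  cnt <- table(labs)
  out <- data.frame(category = names(cnt), n = as.integer(cnt),
                    percent = 100 * as.integer(cnt) / length(nodes),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent, out$category), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Export a graph as an edge-list table
#'
#' Edge list (node1, node2, r, weight, sign, in_mst) suitable for Cytoscape
#' import.
#'
#' @param graph A [build_graph()] (optionally after [prim_mst()]) result.
#' @param path Optional TSV path; when given the table is also written.
#' @return The edge-list data.frame.
#' @export
export_edges <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "corr_graph"))
  edges <- graph$edges
  if (is.null(edges$in_mst)) edges$in_mst <- NA
  if (!is.null(path)) write_tsv(edges, path)
  edges
}
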