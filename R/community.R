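## Community structure on the projected simple graph and the
## two-network comparison that nominates structural key genes.

#' Project a logic network onto an undirected simple graph
#'
#' Every relation (A, B) -> C contributes the undirected edges A–C and
#' B–C; duplicates are collapsed and self-loops cannot arise. Isolated
#' nodes of the network are kept as isolated vertices.
#'
#' @param net a [logic_network()].
#' @return an undirected simple [igraph::graph].
#' @export
project_simple_graph <- function(net) {
  stopifnot(inherits(net, "logic_network"))
  r <- net$relations
  if (nrow(r)) {
    edges <- rbind(data.frame(from = r$source_a, to = r$target),
                   data.frame(from = r$source_b, to = r$target))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  } else {
    igraph::make_empty_graph(n = length(net$nodes), directed = FALSE) |>
      igraph::set_vertex_attr("name", value = net$nodes)
  }
}

#' Greedy modularity communities (Newman fast algorithm)
#'
#' Agglomerative modularity maximization starting from isolated nodes,
#' merging at each step the pair of communities with the largest
#' modularity increase, and returning the partition at maximum Q along
#' the merge sequence. Edge weights are ignored (unweighted
#' modularity).
#'
#' @param graph an undirected simple [igraph::graph], e.g. from
#'   [project_simple_graph()].
#' @return list with `membership` (named integer vector), `modularity`
#'   (Q of the returned partition) and `communities`, a data.frame with
#'   per-community `id`, `size`, `n_inside`, `n_crossing` and the
#'   inside-to-outside ratio `alpha` (Inf when no crossing edge).
#' @export
greedy_communities <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::ecount(graph) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(graph)),
                            igraph::V(graph)$name)
    return(list(membership = memb, modularity = 0,
                communities = community_ratio(graph, memb)))
  }
  cl <- igraph::cluster_fast_greedy(graph, weights = NULL)
  ## cut the merge dendrogram at the step with maximum Q (entry i of the
  ## modularity sequence corresponds to vcount - (i - 1) communities)
  best_no <- igraph::vcount(graph) - (which.max(cl$modularity) - 1)
  memb <- igraph::cut_at(cl, no = best_no)
  memb <- stats::setNames(as.integer(memb), igraph::V(graph)$name)
  list(membership = memb,
       modularity = igraph::modularity(graph, memb),
       communities = community_ratio(graph, memb))
}

#' Inside-to-outside edge ratio per community
#'
#' For each community, `n_inside` counts edges with both endpoints in
#' the community, `n_crossing` counts edges with exactly one endpoint
#' inside, and `alpha = n_inside / n_crossing` (Inf when the community
#' has no crossing edge).
#'
#' @param graph an undirected simple [igraph::graph].
#' @param membership named (by vertex name) community assignment.
#' @return data.frame with `id`, `size`, `n_inside`, `n_crossing`,
#'   `alpha`.
#' @export
community_ratio <- function(graph, membership) {
  stopifnot(igraph::is_igraph(graph))
  vn <- igraph::V(graph)$name
  if (!all(vn %in% names(membership))) {
    stop("membership must cover every vertex", call. = FALSE)
  }
  el <- igraph::as_edgelist(graph)
  ids <- sort(unique(as.integer(membership[vn])))
  out <- lapply(ids, function(cid) {
    inside_v <- vn[membership[vn] == cid]
    m1 <- el[, 1] %in% inside_v
    m2 <- el[, 2] %in% inside_v
    n_in <- sum(m1 & m2)
    n_cross <- sum(xor(m1, m2))
    data.frame(id = cid, size = length(inside_v), n_inside = n_in,
               n_crossing = n_cross,
               alpha = if (n_cross == 0) Inf else n_in / n_cross)
  })
  do.call(rbind, out)
}

#' Compare two condition-specific networks and nominate key genes
#'
#' Takes per-node metric tables (see [node_metrics()]) of two networks
#' over the union gene set (a gene absent from one network scores 0
#' there) and, for each of the four structural parameters — total
#' degree (in + out), mean path length, clustering, betweenness —
#' ranks genes by the absolute difference (network 1 minus network 2),
#' descending, ties broken by gene id. The structural key genes are the
#' intersection of the four top-`top_n` lists.
#'
#' @param metrics_1,metrics_2 data.frames from [node_metrics()].
#' @param top_n size of each top-difference list (default 6).
#' @return list with `differences` (per-gene signed differences),
#'   `top_lists` (named list of four character vectors), `key_genes`,
#'   and `degenerate` (TRUE when every difference is zero, in which
#'   case the ranking is tie-break only).
#' @export
compare_networks <- function(metrics_1, metrics_2, top_n = 6) {
  top_n <- assert_count(top_n, "top_n", positive = TRUE)
  genes <- sort(union(metrics_1$gene, metrics_2$gene))
  get <- function(m, col) {
    v <- stats::setNames(rep(0, length(genes)), genes)
    v[m$gene] <- m[[col]]
    v
  }
  params <- list(
    degree = get(metrics_1, "in_degree") + get(metrics_1, "out_degree") -
      get(metrics_2, "in_degree") - get(metrics_2, "out_degree"),
    path_length = get(metrics_1, "mean_path_length") - get(metrics_2, "mean_path_length"),
    clustering = get(metrics_1, "clustering") - get(metrics_2, "clustering"),
    betweenness = get(metrics_1, "betweenness") - get(metrics_2, "betweenness")
  )
  top_lists <- lapply(params, function(diff) {
    ord <- order(-abs(diff), genes)
    genes[ord][seq_len(min(top_n, length(genes)))]
  })
  differences <- data.frame(
    gene = genes,
    D_difference = unname(params$degree),
    L_difference = unname(params$path_length),
    C_difference = unname(params$clustering),
    B_difference = unname(params$betweenness),
    stringsAsFactors = FALSE
  )
  list(differences = differences,
       top_lists = top_lists,
       key_genes = Reduce(intersect, top_lists),
       degenerate = all(vapply(params, function(p) all(p == 0), logical(1))))
}
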