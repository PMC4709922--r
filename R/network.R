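## The logic network: a directed weighted hypergraph whose edges are
## accepted triplet relations (A, B) -> C, plus the four structural
## parameters generalized to it.

#' Construct a logic network
#'
#' @param relations data.frame with columns `source_a`, `source_b`,
#'   `target`, `logic_type`, `u_value` (positive), e.g. the output of
#'   [scan_triplets()]. Optional columns are carried along.
#' @param nodes optional character vector of node ids; the union with
#'   all relation genes is used, so isolated nodes can be represented.
#' @return an object of class `logic_network` with fields `nodes` and
#'   `relations`.
#' @export
logic_network <- function(relations, nodes = NULL) {
  req <- c("source_a", "source_b", "target", "logic_type", "u_value")
  if (!all(req %in% names(relations))) {
    stop("relations must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(relations)) {
    if (!all(relations$logic_type %in% logic_types())) {
      stop("unknown logic_type in relations", call. = FALSE)
    }
    if (any(!is.finite(relations$u_value) | relations$u_value <= 0)) {
      stop("relation with U <= 0: edge length would be infinite", call. = FALSE)
    }
    if (any(relations$target == relations$source_a |
            relations$target == relations$source_b)) {
      stop("self-loop: target appears in its own source pair", call. = FALSE)
    }
    if (any(relations$source_a == relations$source_b)) {
      stop("source pair must be two distinct genes", call. = FALSE)
    }
    key <- paste(pmin(relations$source_a, relations$source_b),
                 pmax(relations$source_a, relations$source_b),
                 relations$target, relations$logic_type)
    if (anyDuplicated(key)) {
      stop("duplicate (source pair, target, type) relation", call. = FALSE)
    }
  }
  all_nodes <- sort(unique(c(nodes, relations$source_a, relations$source_b,
                             relations$target)))
  rownames(relations) <- NULL
  structure(list(nodes = all_nodes, relations = relations),
            class = "logic_network")
}

#' @export
print.logic_network <- function(x, ...) {
  cat("Logic network:", length(x$nodes), "nodes,",
      nrow(x$relations), "relations\n")
  invisible(x)
}

#' Fractional in-/out-degrees
#'
#' Every relation (A, B) -> C adds 1/2 per source to C's in-degree
#' (1 in total) and 1/2 to each source's out-degree, so that the sums of
#' in- and out-degrees over the network are both equal to the number of
#' relations.
#'
#' @param net a [logic_network()].
#' @return data.frame with `gene`, `in_degree`, `out_degree`.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "logic_network"))
  ind <- outd <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  r <- net$relations
  for (i in seq_len(nrow(r))) {
    ind[r$target[i]] <- ind[r$target[i]] + 1
    outd[r$source_a[i]] <- outd[r$source_a[i]] + 0.5
    outd[r$source_b[i]] <- outd[r$source_b[i]] + 0.5
  }
  data.frame(gene = net$nodes, in_degree = unname(ind[net$nodes]),
             out_degree = unname(outd[net$nodes]), stringsAsFactors = FALSE)
}

#' Doublet clustering coefficients
#'
#' A doublet centered on node v is an unordered pair of distinct
#' relations both incident to v (v target in both: "both-in"; v source
#' in both: "both-out"; otherwise "in-out"). The doublet is strong
#' connected when the two relations share at least two nodes (v plus at
#' least one more). The clustering coefficient of v is the fraction of
#' its doublets that are strong connected (0 when v has no doublet).
#'
#' @param net a [logic_network()].
#' @return data.frame with `gene`, `clustering` in \[0, 1\].
#' @export
clustering_coefficients <- function(net) {
  stopifnot(inherits(net, "logic_network"))
  r <- net$relations
  rel_nodes <- lapply(seq_len(nrow(r)), function(i) {
    c(r$source_a[i], r$source_b[i], r$target[i])
  })
  cl <- vapply(net$nodes, function(v) {
    inc <- which(vapply(rel_nodes, function(s) v %in% s, logical(1)))
    m <- length(inc)
    if (m < 2) return(0)
    pairs <- utils::combn(inc, 2)
    strong <- 0L
    for (p in seq_len(ncol(pairs))) {
      shared <- intersect(rel_nodes[[pairs[1, p]]], rel_nodes[[pairs[2, p]]])
      if (length(shared) >= 2) strong <- strong + 1L
    }
    strong / ncol(pairs)
  }, numeric(1))
  data.frame(gene = net$nodes, clustering = unname(cl), stringsAsFactors = FALSE)
}

## ---- shortest hyperpaths ----

## internal relation table with traversal semantics
rel_table <- function(net) {
  r <- net$relations
  list(t1 = r$source_a, t2 = r$source_b, head = r$target,
       cls = relation_semantics(r$logic_type),
       inv = 1 / r$u_value, inv2 = 2 / r$u_value, n = nrow(r))
}

## which nodes are reachable from `source`: least fixpoint over hyperedges.
## AND heads need both tails (the other tail when the source is a tail);
## OR heads need any tail (none when the source is a tail); XOR heads need
## any tail, but the AND rule applies from a tail.
reachable_set <- function(rt, nodes, source) {
  reach <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  reach[source] <- TRUE
  if (rt$n == 0) return(reach)
  repeat {
    changed <- FALSE
    for (i in seq_len(rt$n)) {
      if (reach[[rt$head[i]]]) next
      t1 <- rt$t1[i]; t2 <- rt$t2[i]; cls <- rt$cls[i]
      ok <- if (source == t1 || source == t2) {
        other <- if (source == t1) t2 else t1
        if (cls == "OR") TRUE else reach[[other]]
      } else if (cls == "AND") {
        reach[[t1]] && reach[[t2]]
      } else {
        reach[[t1]] || reach[[t2]]
      }
      if (ok) {
        reach[[rt$head[i]]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  reach
}

## candidate distance to rt$head[i] via relation i, given labels d from
## source. An XOR relation's rule is pinned by the *final* reachability of
## its tails (AND when both reachable, OR when exactly one): the rule must
## not depend on transient labels, otherwise a stale one-tail OR estimate
## could undercut the settled both-tail AND distance.
rel_candidate <- function(rt, i, d, source, reach) {
  t1 <- rt$t1[i]; t2 <- rt$t2[i]; cls <- rt$cls[i]
  if (source == t1 || source == t2) {
    other <- if (source == t1) t2 else t1
    if (cls == "OR") return(rt$inv2[i])
    dov <- d[[other]]
    return(if (is.finite(dov)) dov + rt$inv[i] else Inf)
  }
  if (cls == "XOR") {
    cls <- if (reach[[t1]] && reach[[t2]]) "AND" else "OR"
  }
  dA <- d[[t1]]; dB <- d[[t2]]
  fA <- is.finite(dA); fB <- is.finite(dB)
  if (cls == "AND") {
    if (fA && fB) max(dA, dB) + rt$inv[i] else Inf
  } else {
    if (fA || fB) min(dA, dB) + rt$inv2[i] else Inf
  }
}

#' Shortest logic-path distances and paths from one source
#'
#' Distances through hyperedges follow the traversal semantics of each
#' relation's logic type. AND relations (types 1, 2, 4, 5a, 5b) require
#' both sources reachable and cost `max(tail distances) + 1/U` (when the
#' query source is itself a tail, the path routes through the other
#' tail: `d = d(other tail) + 1/U`). OR relations (types 3, 6a, 6b)
#' split the uncertainty coefficient over the two sources, giving branch
#' length `2/U` from either tail (direct `2/U` when the query source is
#' a tail); the head distance is the minimum over available branches.
#' XOR relations (types 7, 8) use the AND rule when both tails are
#' reachable or the source is a tail, and the OR rule when exactly one
#' tail is reachable. Distances are computed by label-correcting
#' relaxation, which terminates because both aggregation rules are
#' monotone with positive edge lengths.
#'
#' @param net a [logic_network()].
#' @param source node id.
#' @param enumerate_paths if `TRUE` (default) also reconstruct the tied
#'   shortest node sequences per reachable target (at most `cap` each).
#' @param cap maximum number of tied paths kept per pair.
#' @return list with `distances` (named numeric, `Inf` when
#'   unreachable, 0 at the source) and `paths` (named list: for each
#'   finite target, a list of node sequences from source to target).
#' @export
logic_shortest_paths <- function(net, source, enumerate_paths = TRUE, cap = 64) {
  stopifnot(inherits(net, "logic_network"))
  if (!source %in% net$nodes) stop("unknown source node: ", source, call. = FALSE)
  rt <- rel_table(net)
  reach <- reachable_set(rt, net$nodes, source)
  d <- stats::setNames(rep(Inf, length(net$nodes)), net$nodes)
  d[source] <- 0
  if (rt$n > 0) {
    max_iter <- (length(net$nodes) + 2) * (rt$n + 2)
    for (iter in seq_len(max_iter)) {
      changed <- FALSE
      for (i in seq_len(rt$n)) {
        cand <- rel_candidate(rt, i, d, source, reach)
        if (cand < d[[rt$head[i]]] - 1e-12) {
          d[[rt$head[i]]] <- cand
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  paths <- list()
  if (enumerate_paths) {
    paths <- enumerate_shortest(rt, d, source, cap, reach = reach)
  }
  list(distances = d, paths = paths)
}

## all tied shortest node sequences from `source` to every finite target
enumerate_shortest <- function(rt, d, source, cap = 64, tol = 1e-9, reach = NULL) {
  memo <- new.env(parent = emptyenv())
  enum <- function(C) {
    if (C == source) return(list(source))
    if (!is.null(memo[[C]])) return(memo[[C]])
    memo[[C]] <- list() # guard (not reachable via positive-weight cycles)
    res <- list()
    for (i in which(rt$head == C)) {
      if (!is.finite(d[[C]])) next
      cand <- rel_candidate(rt, i, d, source, reach)
      if (!is.finite(cand) || abs(cand - d[[C]]) > tol) next
      t1 <- rt$t1[i]; t2 <- rt$t2[i]; cls <- rt$cls[i]
      if (source == t1 || source == t2) {
        other <- if (source == t1) t2 else t1
        if (cls == "OR") {
          res <- c(res, list(c(source, C)))
        } else {
          res <- c(res, lapply(enum(other), function(sp) c(sp, C)))
        }
      } else {
        dA <- d[[t1]]; dB <- d[[t2]]
        both <- is.finite(dA) && is.finite(dB)
        if (cls == "AND" || (cls == "XOR" && reach[[t1]] && reach[[t2]])) {
          ## visit the nearer tail first, then the farther, then the head
          near <- if (dA < dB || (dA == dB && t1 <= t2)) t1 else t2
          far <- if (near == t1) t2 else t1
          for (spn in enum(near)) {
            for (spf in enum(far)) {
              res <- c(res, list(c(spn, spf[-1], C)))
              if (length(res) >= cap) break
            }
            if (length(res) >= cap) break
          }
        } else {
          for (tail_node in c(t1, t2)) {
            dt <- d[[tail_node]]
            if (is.finite(dt) && abs(dt + rt$inv2[i] - cand) <= tol) {
              res <- c(res, lapply(enum(tail_node), function(sp) c(sp, C)))
            }
          }
        }
      }
      if (length(res) >= cap) break
    }
    ## deduplicate by node sequence, cap the tie set
    if (length(res)) {
      keys <- vapply(res, paste, character(1), collapse = "\r")
      res <- res[!duplicated(keys)]
      if (length(res) > cap) res <- res[seq_len(cap)]
    }
    memo[[C]] <- res
    res
  }
  targets <- names(d)[is.finite(d) & names(d) != source]
  out <- lapply(targets, enum)
  names(out) <- targets
  out
}

#' Average path length of a logic network
#'
#' Mean of the distances over all ordered node pairs with finite,
#' nonzero-source-to-target distance (self pairs and unreachable pairs
#' excluded). Returns 0 with a warning when no finite pair exists.
#'
#' @param net a [logic_network()].
#' @return single numeric value.
#' @export
average_path_length <- function(net) {
  stopifnot(inherits(net, "logic_network"))
  dists <- unlist(lapply(net$nodes, function(s) {
    d <- logic_shortest_paths(net, s, enumerate_paths = FALSE)$distances
    d[is.finite(d) & names(d) != s]
  }))
  if (!length(dists)) {
    warning("no finite node pair: average path length undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  mean(dists)
}

#' Mean outgoing path length of one node
#'
#' Source-role mean of the finite distances from `v` to all other
#' nodes; 0 when no other node is reachable.
#'
#' @param net a [logic_network()].
#' @param v node id.
#' @return single numeric value.
#' @export
node_mean_path_length <- function(net, v) {
  stopifnot(inherits(net, "logic_network"))
  d <- logic_shortest_paths(net, v, enumerate_paths = FALSE)$distances
  fin <- d[is.finite(d) & names(d) != v]
  if (!length(fin)) 0 else mean(fin)
}

#' Standard betweenness on the logic network
#'
#' Let L be the set of all tied shortest paths over all ordered finite
#' node pairs (deduplicated by node sequence). The betweenness of v is
#' the fraction of paths in L that contain v as an intermediate node
#' (endpoints excluded); values lie in \[0, 1\].
#'
#' @param net a [logic_network()].
#' @param cap maximum tied paths per pair (see [logic_shortest_paths()]).
#' @return data.frame with `gene`, `betweenness`.
#' @export
betweenness <- function(net, cap = 64) {
  stopifnot(inherits(net, "logic_network"))
  cnt <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  total <- 0L
  for (s in net$nodes) {
    sp <- logic_shortest_paths(net, s, cap = cap)
    for (tt in names(sp$paths)) {
      plist <- sp$paths[[tt]]
      total <- total + length(plist)
      for (p in plist) {
        ints <- setdiff(unique(p), c(s, tt))
        if (length(ints)) cnt[ints] <- cnt[ints] + 1
      }
    }
  }
  b <- if (total > 0) cnt / total else cnt
  data.frame(gene = net$nodes, betweenness = unname(b[net$nodes]),
             stringsAsFactors = FALSE)
}

#' Per-node structural parameters of a logic network
#'
#' Combines fractional degrees, doublet clustering, source-role mean
#' path length and standard betweenness into one table, computing the
#' all-pairs shortest hyperpaths once.
#'
#' @param net a [logic_network()].
#' @param cap maximum tied paths per pair.
#' @return data.frame with columns `gene`, `in_degree`, `out_degree`,
#'   `clustering`, `mean_path_length`, `betweenness`.
#' @export
node_metrics <- function(net, cap = 64) {
  stopifnot(inherits(net, "logic_network"))
  deg <- degrees(net)
  cl <- clustering_coefficients(net)
  cnt <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  mpl <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  total <- 0L
  for (s in net$nodes) {
    sp <- logic_shortest_paths(net, s, cap = cap)
    fin <- sp$distances[is.finite(sp$distances) & names(sp$distances) != s]
    if (length(fin)) mpl[s] <- mean(fin)
    for (tt in names(sp$paths)) {
      plist <- sp$paths[[tt]]
      total <- total + length(plist)
      for (p in plist) {
        ints <- setdiff(unique(p), c(s, tt))
        if (length(ints)) cnt[ints] <- cnt[ints] + 1
      }
    }
  }
  btw <- if (total > 0) cnt / total else cnt
  data.frame(gene = net$nodes,
             in_degree = deg$in_degree,
             out_degree = deg$out_degree,
             clustering = cl$clustering,
             mean_path_length = unname(mpl[net$nodes]),
             betweenness = unname(btw[net$nodes]),
             stringsAsFactors = FALSE)
}

#' Network-level structural summary
#'
#' @param net a [logic_network()].
#' @param cap maximum tied paths per pair.
#' @return list with `n_nodes`, `n_relations`, `average_degree` (mean
#'   of in+out), `average_clustering`, `average_path_length`,
#'   `average_betweenness`.
#' @export
network_summary <- function(net, cap = 64) {
  m <- node_metrics(net, cap = cap)
  apl <- if (nrow(net$relations)) {
    suppressWarnings(average_path_length(net))
  } else 0
  list(n_nodes = length(net$nodes),
       n_relations = nrow(net$relations),
       average_degree = mean(m$in_degree + m$out_degree),
       average_clustering = mean(m$clustering),
       average_path_length = apl,
       average_betweenness = mean(m$betweenness))
}
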