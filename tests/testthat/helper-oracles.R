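# Independent oracles and shared fixtures for the test suite. Every
# oracle is coded from the definition, not from the package internals.

## ---- Boolean truth-table oracle (k = 1) ----
## logical R operators only; returns 0/1
bool_oracle <- function(type, a, b) {
  a <- as.logical(a); b <- as.logical(b)
  out <- switch(type,
    "1" = a & b,
    "2" = !(a & b),
    "3" = a | b,
    "4" = !(a | b),
    "5a" = (!a) & b,
    "5b" = a & (!b),
    "6a" = (!a) | b,
    "6b" = a | (!b),
    "7" = a == b,
    "8" = xor(a, b))
  as.numeric(out)
}

## ---- uncertainty-coefficient oracle from the contingency table ----
## U(B|A) = (H(A) + H(B) - H(A,B)) / H(B), all from table() counts
u_oracle <- function(a, b) {
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  HA <- ent(table(a))
  HB <- ent(table(b))
  HAB <- ent(table(paste(a, b)))
  (HA + HB - HAB) / HB
}

## ---- hyperpath distance oracle ----
## reachability closure by functional iteration, then exhaustive
## recursion over acyclic derivation chains
oracle_semantics <- function(type) {
  c("1" = "AND", "2" = "AND", "4" = "AND", "5a" = "AND", "5b" = "AND",
    "3" = "OR", "6a" = "OR", "6b" = "OR", "7" = "XOR", "8" = "XOR")[[type]]
}

oracle_reach_set <- function(r, nodes, X) {
  S <- X
  for (rep in seq_len(length(nodes) + 1)) {
    add <- character(0)
    for (i in seq_len(nrow(r))) {
      t1 <- r$source_a[i]; t2 <- r$source_b[i]
      cls <- oracle_semantics(r$logic_type[i])
      ok <- if (X %in% c(t1, t2)) {
        if (cls == "OR") TRUE else setdiff(c(t1, t2), X) %in% S
      } else if (cls == "AND") {
        all(c(t1, t2) %in% S)
      } else {
        any(c(t1, t2) %in% S)
      }
      if (ok) add <- c(add, r$target[i])
    }
    S2 <- union(S, add)
    if (setequal(S2, S)) break
    S <- S2
  }
  S
}

oracle_dist <- function(r, X, target, reach = NULL, blocked = character()) {
  if (is.null(reach)) {
    nodes <- unique(c(r$source_a, r$source_b, r$target, X))
    reach <- oracle_reach_set(r, nodes, X)
  }
  if (target == X) return(0)
  if (target %in% blocked) return(Inf)
  best <- Inf
  for (i in which(r$target == target)) {
    U <- r$u_value[i]
    cls <- oracle_semantics(r$logic_type[i])
    t1 <- r$source_a[i]; t2 <- r$source_b[i]
    if (X == t1 || X == t2) {
      other <- if (X == t1) t2 else t1
      cand <- if (cls == "OR") 2 / U else {
        d <- oracle_dist(r, X, other, reach, c(blocked, target))
        if (is.finite(d)) d + 1 / U else Inf
      }
    } else {
      if (cls == "XOR") cls <- if (all(c(t1, t2) %in% reach)) "AND" else "OR"
      dA <- oracle_dist(r, X, t1, reach, c(blocked, target))
      dB <- oracle_dist(r, X, t2, reach, c(blocked, target))
      cand <- if (cls == "AND") {
        if (is.finite(dA) && is.finite(dB)) max(dA, dB) + 1 / U else Inf
      } else {
        if (is.finite(dA) || is.finite(dB)) min(dA, dB) + 2 / U else Inf
      }
    }
    best <- min(best, cand)
  }
  best
}

## ---- random logic networks ----
random_logic_net <- function(seed, node_range = 4:8, rel_range = 1:6) {
  set.seed(seed)
  nn <- sample(node_range, 1)
  nodes <- LETTERS[seq_len(nn)]
  nr <- sample(rel_range, 1)
  rel <- NULL
  guard <- 0
  while ((is.null(rel) || nrow(rel) < nr) && guard < 200) {
    guard <- guard + 1
    tri <- sample(nodes, 3)
    row <- data.frame(source_a = tri[1], source_b = tri[2], target = tri[3],
                      logic_type = sample(logic_types(), 1),
                      u_value = round(runif(1, 0.2, 1), 3),
                      stringsAsFactors = FALSE)
    if (is.null(rel)) {
      rel <- row
    } else {
      key <- paste(pmin(rel$source_a, rel$source_b),
                   pmax(rel$source_a, rel$source_b), rel$target)
      k2 <- paste(min(tri[1], tri[2]), max(tri[1], tri[2]), tri[3])
      if (!k2 %in% key) rel <- rbind(rel, row)
    }
  }
  logic_network(rel, nodes = nodes)
}

## ---- brute-force modularity oracle ----
## all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxid) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (g in seq_len(maxid + 1)) rec(c(assign, g), max(maxid, g))
  }
  rec(integer(0), 0L)
  out
}

## Q from the definition: sum_c (e_c / m - (deg_c / 2m)^2)
modularity_oracle <- function(edges, membership) {
  m <- nrow(edges)
  q <- 0
  for (cid in unique(membership)) {
    inside <- names(membership)[membership == cid]
    e_c <- sum(edges[, 1] %in% inside & edges[, 2] %in% inside)
    deg_c <- sum(edges[, 1] %in% inside) + sum(edges[, 2] %in% inside)
    q <- q + e_c / m - (deg_c / (2 * m))^2
  }
  q
}

brute_force_best_modularity <- function(edges, nodes) {
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    memb <- stats::setNames(p, nodes)
    best <- max(best, modularity_oracle(edges, memb))
  }
  best
}

## ---- shared fixtures ----

## the worked 5-node network: two OR relations feeding an AND relation
five_node_net <- function() {
  logic_network(data.frame(
    source_a = c("X", "X", "A"), source_b = c("Y", "Y", "B"),
    target = c("A", "B", "C"),
    logic_type = c("3", "3", "1"),
    u_value = c(0.5, 0.25, 0.5), stringsAsFactors = FALSE))
}

## recovery benchmark: 20 decoys + 5 planted triplets of distinct types
recovery_spec <- function(seed, noise = 0.1, n = 60) {
  synthetic_spec(
    n_genes = 35, n_samples_a = n, n_samples_b = 5,
    planted_triplets = list(
      planted_triplet(1, 2, 3, "1", noise),
      planted_triplet(4, 5, 6, "3", noise),
      planted_triplet(7, 8, 9, "5a", noise),
      planted_triplet(10, 11, 12, "5b", noise),
      planted_triplet(13, 14, 15, "7", noise)),
    seed = seed)
}

## scan one condition of a synthetic dataset
scan_condition <- function(ds, t, k = 1, condition = "matrix_a") {
  norm <- t(apply(ds[[condition]], 1, minmax_normalize))
  scan_triplets(discretize_matrix(norm, k), t)
}

## how many of the planted triplets are recovered (pair + target + type
## up to complement/argument-swap equivalence)
count_recovered <- function(rel, truth) {
  hits <- vapply(seq_len(nrow(truth$triplet_records)), function(i) {
    tt <- truth$triplet_records[i, ]
    h <- rel[rel$target == tt$target &
             ((rel$source_a == tt$source_a & rel$source_b == tt$source_b) |
              (rel$source_a == tt$source_b & rel$source_b == tt$source_a)), ]
    nrow(h) > 0 && h$logic_type[1] %in%
      equivalent_logic_types(tt$logic_type,
                             swapped = h$source_a[1] != tt$source_a)
  }, logical(1))
  sum(hits)
}

## two-condition fixture with a condition-specific hub gene g003:
## background relations in both conditions anchor the U normalization;
## the hub's relations exist only in condition a (their target rows are
## scrambled in condition b so both conditions share the value scale)
hub_fixture <- function(seed = 5) {
  bal <- function(n) ifelse(runif(n) < 0.5, 6 + rlnorm(n, 0, 0.25),
                            rlnorm(n, 0, 0.25))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ma <- t(sapply(1:14, function(i) bal(42)))
  mb <- t(sapply(1:14, function(i) bal(52)))
  rownames(ma) <- rownames(mb) <- sprintf("g%03d", 1:14)
  colnames(ma) <- sprintf("a%02d", 1:42)
  colnames(mb) <- sprintf("b%02d", 1:52)
  ## background relations present in both conditions
  ma <- plant_logic_triplet(ma, 8, 9, 10, "3", 0, seed = 101)
  mb <- plant_logic_triplet(mb, 8, 9, 10, "3", 0, seed = 102)
  ma <- plant_logic_triplet(ma, 11, 12, 13, "3", 0, seed = 103)
  mb <- plant_logic_triplet(mb, 11, 12, 13, "3", 0, seed = 104)
  ## hub (g003) relations in condition a only; the in-relation shares
  ## source g004 with the out-relations so the hub's doublets are strong
  plant_pair <- function(ma, mb, a, b, c, type, s) {
    list(plant_logic_triplet(ma, a, b, c, type, 0, seed = s),
         plant_logic_triplet(mb, a, b, c, type, 1, seed = s + 1))
  }
  r <- plant_pair(ma, mb, 1, 4, 3, "3", 11); ma <- r[[1]]; mb <- r[[2]]
  r <- plant_pair(ma, mb, 3, 4, 5, "3", 21); ma <- r[[1]]; mb <- r[[2]]
  r <- plant_pair(ma, mb, 3, 4, 6, "3", 31); ma <- r[[1]]; mb <- r[[2]]
  r <- plant_pair(ma, mb, 3, 4, 7, "3", 41); ma <- r[[1]]; mb <- r[[2]]
  list(matrix_a = ma, matrix_b = mb, hub = "g003")
}
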