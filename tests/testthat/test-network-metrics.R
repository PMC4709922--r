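# Hypergraph structural parameters: degrees, doublet clustering,
# AND/OR/XOR shortest paths, betweenness.

test_that("network construction rejects malformed relation sets", {
  base <- data.frame(source_a = "A", source_b = "B", target = "C",
                     logic_type = "1", u_value = 0.5, stringsAsFactors = FALSE)
  expect_s3_class(logic_network(base), "logic_network")
  bad_loop <- base; bad_loop$target <- "A"
  expect_error(logic_network(bad_loop), "self-loop")
  bad_u <- base; bad_u$u_value <- 0
  expect_error(logic_network(bad_u), "U <= 0")
  bad_type <- base; bad_type$logic_type <- "9"
  expect_error(logic_network(bad_type), "logic_type")
  dup <- rbind(base, data.frame(source_a = "B", source_b = "A", target = "C",
                                logic_type = "1", u_value = 0.7))
  expect_error(logic_network(dup), "duplicate")
})

test_that("degrees follow the half-per-source rule and conserve totals", {
  net <- logic_network(data.frame(source_a = "A", source_b = "B", target = "C",
                                  logic_type = "1", u_value = 0.5))
  d <- degrees(net)
  expect_equal(d$in_degree[d$gene == "C"], 1)
  expect_equal(d$out_degree[d$gene %in% c("A", "B")], c(0.5, 0.5))
  expect_equal(mean(d$in_degree + d$out_degree), 2 / 3)

  empty <- logic_network(data.frame(source_a = character(0), source_b = character(0),
                                    target = character(0), logic_type = character(0),
                                    u_value = numeric(0)), nodes = c("A", "B"))
  expect_true(all(degrees(empty)$in_degree == 0))

  for (s in 1:100) {
    net <- random_logic_net(s)
    d <- degrees(net)
    expect_equal(sum(d$in_degree), nrow(net$relations))
    expect_equal(sum(d$out_degree), nrow(net$relations))
  }
})

test_that("doublet clustering counts strong connected relation pairs", {
  # both-in doublet sharing only the center: not strong
  n1 <- logic_network(data.frame(source_a = c("A", "D"), source_b = c("B", "E"),
                                 target = c("C", "C"),
                                 logic_type = c("1", "1"), u_value = c(0.5, 0.5)))
  cl1 <- clustering_coefficients(n1)
  expect_equal(cl1$clustering[cl1$gene == "C"], 0)
  # two relations sharing both sources: strong for A and B
  n2 <- logic_network(data.frame(source_a = c("A", "A"), source_b = c("B", "B"),
                                 target = c("C", "D"),
                                 logic_type = c("1", "3"), u_value = c(0.5, 0.5)))
  cl2 <- clustering_coefficients(n2)
  expect_equal(cl2$clustering[cl2$gene %in% c("A", "B")], c(1, 1))
  # a single relation yields no doublet anywhere
  n3 <- logic_network(data.frame(source_a = "A", source_b = "B", target = "C",
                                 logic_type = "1", u_value = 0.5))
  expect_true(all(clustering_coefficients(n3)$clustering == 0))
  for (s in 1:30) {
    cl <- clustering_coefficients(random_logic_net(s))$clustering
    expect_true(all(cl >= 0 & cl <= 1))
  }
})

test_that("AND heads are unreachable from a tail without a path to the other tail", {
  net <- logic_network(data.frame(source_a = "A", source_b = "B", target = "C",
                                  logic_type = "1", u_value = 0.5))
  d <- logic_shortest_paths(net, "A")$distances
  expect_equal(unname(d["C"]), Inf)
  expect_equal(unname(d["A"]), 0)
})

test_that("the worked 5-node network reproduces the hand-traced distances and paths", {
  net <- five_node_net()
  sp <- logic_shortest_paths(net, "X")
  expect_equal(unname(sp$distances[c("A", "B", "C")]), c(4, 8, 10))
  expect_equal(unname(sp$distances["Y"]), Inf)
  expect_equal(sp$paths[["C"]], list(c("X", "A", "B", "C")))
  # every node is at distance zero from itself
  for (v in net$nodes) {
    expect_equal(unname(logic_shortest_paths(net, v)$distances[v]), 0)
  }
  expect_equal(suppressWarnings(average_path_length(net)), mean(c(4, 8, 10, 4, 8, 10)))
  expect_equal(node_mean_path_length(net, "X"), mean(c(4, 8, 10)))
  expect_equal(node_mean_path_length(net, "C"), 0)
})

test_that("distances scale homogeneously in 1/U and empty networks warn", {
  net <- five_node_net()
  rel2 <- net$relations
  rel2$u_value <- rel2$u_value * 0.5
  net2 <- logic_network(rel2)
  d1 <- logic_shortest_paths(net, "X", enumerate_paths = FALSE)$distances
  d2 <- logic_shortest_paths(net2, "X", enumerate_paths = FALSE)$distances
  fin <- is.finite(d1)
  expect_equal(d2[fin], 2 * d1[fin])
  expect_equal(suppressWarnings(average_path_length(net2)),
               2 * suppressWarnings(average_path_length(net)))
  empty <- logic_network(data.frame(source_a = character(0), source_b = character(0),
                                    target = character(0), logic_type = character(0),
                                    u_value = numeric(0)), nodes = c("A", "B"))
  expect_warning(apl <- average_path_length(empty), "no finite")
  expect_equal(apl, 0)
})

test_that("betweenness counts intermediates over all tied shortest paths", {
  one <- logic_network(data.frame(source_a = "A", source_b = "B", target = "C",
                                  logic_type = "3", u_value = 0.5))
  expect_true(all(betweenness(one)$betweenness == 0))
  b <- betweenness(five_node_net())
  expect_equal(b$betweenness[b$gene == "A"], 1 / 3)
  expect_equal(b$betweenness[b$gene == "B"], 1 / 3)
  expect_equal(b$betweenness[b$gene == "C"], 0) # sink
  expect_equal(b$betweenness[b$gene == "X"], 0)
  for (s in 1:30) {
    net <- random_logic_net(s)
    bw <- betweenness(net)$betweenness
    expect_true(all(bw >= 0 & bw <= 1))
    sinks <- setdiff(net$nodes, c(net$relations$source_a, net$relations$source_b))
    expect_true(all(bw[match(sinks, betweenness(net)$gene)] == 0))
  }
})

test_that("relaxation distances equal the exhaustive hyperpath oracle on random networks", {
  for (s in 1:40) {
    net <- random_logic_net(s)
    for (src in net$nodes) {
      d <- logic_shortest_paths(net, src, enumerate_paths = FALSE)$distances
      reach <- oracle_reach_set(net$relations, net$nodes, src)
      for (tt in net$nodes) {
        od <- oracle_dist(net$relations, src, tt, reach)
        if (is.infinite(od)) {
          expect_true(is.infinite(d[[tt]]),
                      info = paste("seed", s, src, "->", tt))
        } else {
          expect_equal(unname(d[tt]), od, tolerance = 1e-9,
                       info = paste("seed", s, src, "->", tt))
        }
      }
    }
  }
})

test_that("node_metrics aggregates the four parameters consistently", {
  net <- five_node_net()
  m <- node_metrics(net)
  expect_equal(m$gene, net$nodes)
  expect_equal(m$in_degree, degrees(net)$in_degree)
  expect_equal(m$clustering, clustering_coefficients(net)$clustering)
  expect_equal(m$betweenness, betweenness(net)$betweenness)
  expect_equal(m$mean_path_length[m$gene == "X"], mean(c(4, 8, 10)))
  s <- network_summary(net)
  expect_equal(s$n_relations, 3)
  expect_equal(s$average_degree, mean(m$in_degree + m$out_degree))
})
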