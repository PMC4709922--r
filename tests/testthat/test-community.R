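# Projection, greedy modularity communities, and network comparison.

test_that("projection yields the undirected simple source-target graph", {
  one <- logic_network(data.frame(source_a = "A", source_b = "B", target = "C",
                                  logic_type = "1", u_value = 0.5))
  g1 <- project_simple_graph(one)
  expect_equal(igraph::ecount(g1), 2) # A-C and B-C
  # two relations sharing the source pair: duplicates collapse
  two <- logic_network(data.frame(source_a = c("A", "A"), source_b = c("B", "B"),
                                  target = c("C", "D"),
                                  logic_type = c("1", "1"), u_value = c(0.5, 0.5)))
  expect_lte(igraph::ecount(project_simple_graph(two)), 4)
  empty <- logic_network(data.frame(source_a = character(0), source_b = character(0),
                                    target = character(0), logic_type = character(0),
                                    u_value = numeric(0)), nodes = c("A", "B"))
  ge <- project_simple_graph(empty)
  expect_equal(igraph::ecount(ge), 0)
  expect_equal(igraph::vcount(ge), 2)
})

test_that("greedy modularity matches the brute-force optimum on two bridged cliques", {
  g <- igraph::make_graph(~ a - b, a - c, a - d, b - c, b - d, c - d,
                          e - f, e - g, e - h, f - g, f - h, g - h, d - e)
  com <- greedy_communities(g)
  # the two cliques are recovered
  memb <- com$membership
  expect_length(unique(memb[c("a", "b", "c", "d")]), 1)
  expect_length(unique(memb[c("e", "f", "g", "h")]), 1)
  expect_length(unique(memb), 2)
  # greedy Q equals the exhaustive optimum over all partitions of 8 nodes
  edges <- igraph::as_edgelist(g)
  best <- brute_force_best_modularity(edges, igraph::V(g)$name)
  expect_equal(com$modularity, best, tolerance = 1e-12)
  # and the reported Q agrees with the from-scratch definition
  expect_equal(com$modularity, modularity_oracle(edges, memb), tolerance = 1e-12)
  expect_equal(com$communities$alpha, c(6, 6))
})

test_that("a single clique collapses to one community with Q = 0", {
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- letters[1:5]
  com <- greedy_communities(g)
  expect_length(unique(com$membership), 1)
  expect_equal(com$modularity, 0)
  expect_equal(com$communities$n_crossing, 0)
  expect_equal(com$communities$alpha, Inf)
})

test_that("greedy Q is bounded by the singleton partition below and brute force above", {
  for (s in 1:10) {
    set.seed(s)
    n <- 7
    g <- igraph::sample_gnp(n, 0.45)
    igraph::V(g)$name <- letters[seq_len(n)]
    if (igraph::ecount(g) < 2) next
    com <- greedy_communities(g)
    edges <- igraph::as_edgelist(g)
    singletons <- stats::setNames(seq_len(n), letters[seq_len(n)])
    expect_gte(com$modularity, modularity_oracle(edges, singletons) - 1e-12)
    expect_lte(com$modularity,
               brute_force_best_modularity(edges, letters[seq_len(n)]) + 1e-12)
  }
})

test_that("planted two-block graphs are recovered", {
  skip_if_not_installed("mclust")
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    blocks <- rep(1:2, each = 15)
    g <- igraph::sample_sbm(30, matrix(c(0.6, 0.05, 0.05, 0.6), 2),
                            block.sizes = c(15, 15))
    igraph::V(g)$name <- sprintf("v%02d", 1:30)
    com <- greedy_communities(g)
    mclust::adjustedRandIndex(com$membership, blocks) == 1
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("community ratios count inside and crossing edges", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, c - d, d - e)
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2)
  cr <- community_ratio(g, memb)
  expect_equal(cr$n_inside, c(3, 1))
  expect_equal(cr$n_crossing, c(1, 1))
  expect_equal(cr$alpha, c(3, 1))
  expect_error(community_ratio(g, memb[-1]), "every vertex")
})

test_that("network comparison ranks absolute differences and intersects top lists", {
  m1 <- data.frame(gene = c("a", "b", "c"), in_degree = c(3, 1, 0),
                   out_degree = c(2, 0, 0), clustering = c(0.5, 0, 0),
                   mean_path_length = c(4, 1, 0), betweenness = c(0.4, 0, 0))
  m2 <- data.frame(gene = c("a", "b", "d"), in_degree = c(0, 1, 1),
                   out_degree = c(0, 0, 0.5), clustering = c(0, 0, 0.2),
                   mean_path_length = c(0, 1, 2), betweenness = c(0, 0, 0.1))
  cmp <- compare_networks(m1, m2, top_n = 2)
  expect_equal(cmp$top_lists$degree[1], "a") # |5 - 0| dominates
  expect_true("a" %in% cmp$key_genes)
  expect_false(cmp$degenerate)
  # antisymmetry under input swap
  cmp_rev <- compare_networks(m2, m1, top_n = 2)
  expect_equal(cmp$differences$D_difference, -cmp_rev$differences$D_difference)
  expect_equal(sort(cmp$key_genes), sort(cmp_rev$key_genes))
  # identical inputs: all differences zero, degenerate flag raised
  cmp_id <- compare_networks(m1, m1, top_n = 2)
  expect_true(cmp_id$degenerate)
  expect_true(all(cmp_id$differences$D_difference == 0))
  # vacuous cut keeps every gene
  cmp_all <- compare_networks(m1, m2, top_n = 4)
  expect_setequal(cmp_all$top_lists$degree, c("a", "b", "c", "d"))
})
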