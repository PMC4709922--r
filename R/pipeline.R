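## End-to-end orchestration: screen -> infer (per condition) -> metrics
## -> communities -> comparison, with all artifacts written as TSV/JSON.

#' Build a validated pipeline configuration
#'
#' @param matrix_a,matrix_b input gene-by-sample matrices, or paths to
#'   TSV files readable by [read_expression_matrix()].
#' @param out_dir output directory (created if missing).
#' @param k discretization granularity (positive integer).
#' @param t acceptance threshold, or a vector for a threshold sweep;
#'   communities and the network comparison are computed at the first
#'   element.
#' @param alpha screening significance level.
#' @param top_n key-gene cut per parameter list.
#' @param seed integer seed recorded with the run (the pipeline itself
#'   is deterministic).
#' @param condition_a,condition_b labels used in file names and sidecars.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_a, matrix_b, out_dir,
                            k = 1, t = 0.3, alpha = 1e-5, top_n = 6,
                            seed = 1, condition_a = "condition_a",
                            condition_b = "condition_b") {
  if (!is.numeric(t) || !length(t) || any(t < 0 | t > 1)) {
    stop("field 't' must be threshold(s) in [0, 1]", call. = FALSE)
  }
  structure(list(
    matrix_a = matrix_a, matrix_b = matrix_b, out_dir = out_dir,
    k = assert_count(k, "k", positive = TRUE),
    t = as.numeric(t),
    alpha = assert_prob(alpha, "alpha"),
    top_n = assert_count(top_n, "top_n", positive = TRUE),
    seed = assert_count(seed, "seed"),
    condition_a = as.character(condition_a),
    condition_b = as.character(condition_b)
  ), class = "pipeline_config")
}

resolve_matrix <- function(x, what) {
  if (is.character(x) && length(x) == 1) {
    return(read_expression_matrix(x))
  }
  if (!is.matrix(x) || !is.numeric(x) || is.null(rownames(x))) {
    stop(what, " must be a numeric matrix with gene rownames or a TSV path",
         call. = FALSE)
  }
  x
}

#' Run the full logic-network pipeline
#'
#' Screens candidate genes with the rank-sum test, normalizes them over
#' the pooled samples, discretizes per condition, scans triplets at each
#' threshold, computes per-node and network-level structural parameters,
#' detects communities, and compares the two condition-specific networks
#' to nominate structural key genes. Every stage logs its parameters and
#' counts; artifacts are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with `screen`, per-threshold `networks`,
#'   `metrics` and `summaries`, `communities`, and `comparison`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ma <- resolve_matrix(config$matrix_a, "matrix_a")
  mb <- resolve_matrix(config$matrix_b, "matrix_b")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  message(sprintf("screen: %d genes, alpha = %g", nrow(ma), config$alpha))
  screen <- screen_candidates(ma, mb, config$alpha)
  cand <- screen$gene_id[screen$is_candidate]
  message(sprintf("screen: %d candidate gene(s)", length(cand)))
  utils::write.table(screen, file.path(config$out_dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(cand) < 3) {
    stop("fewer than 3 candidate genes; cannot scan triplets", call. = FALSE)
  }

  norm <- normalize_pooled(ma[cand, , drop = FALSE], mb[cand, , drop = FALSE])
  disc_a <- discretize_matrix(norm$matrix_a, config$k)
  disc_b <- discretize_matrix(norm$matrix_b, config$k)

  conds <- list(a = list(label = config$condition_a, disc = disc_a),
                b = list(label = config$condition_b, disc = disc_b))
  networks <- list()
  metrics <- list()
  summaries <- list()
  for (tt in config$t) {
    for (cn in names(conds)) {
      lab <- conds[[cn]]$label
      rel <- scan_triplets(conds[[cn]]$disc, tt)
      message(sprintf(
        "infer [%s, t = %.2f]: %d triplets evaluated, %d accepted, %d gene(s) skipped (H = 0)",
        lab, tt, attr(rel, "n_triplets_evaluated"), attr(rel, "n_accepted"),
        attr(rel, "n_skipped_zero_entropy")))
      net <- logic_network(rel, nodes = names(conds[[cn]]$disc))
      key <- sprintf("%s_t%s", lab, format(tt))
      networks[[key]] <- net
      write_network(net, file.path(config$out_dir, paste0("network_", key, ".tsv")),
                    k = config$k, t = tt, condition = lab)
      m <- node_metrics(net)
      metrics[[key]] <- m
      utils::write.table(m, file.path(config$out_dir, paste0("metrics_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summaries[[key]] <- c(list(condition = lab, t = tt), network_summary(net))
    }
  }
  jsonlite::write_json(summaries,
                       file.path(config$out_dir, "network_summaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## communities and comparison at the primary threshold
  t0 <- config$t[1]
  key_a <- sprintf("%s_t%s", config$condition_a, format(t0))
  key_b <- sprintf("%s_t%s", config$condition_b, format(t0))
  communities <- lapply(stats::setNames(c(key_a, key_b), c(key_a, key_b)),
                        function(key) {
    g <- project_simple_graph(networks[[key]])
    com <- greedy_communities(g)
    utils::write.table(
      data.frame(gene = names(com$membership),
                 community = unname(com$membership)),
      file.path(config$out_dir, paste0("community_", key, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    com
  })
  jsonlite::write_json(
    lapply(communities, function(com) {
      list(modularity = com$modularity,
           communities = lapply(seq_len(nrow(com$communities)), function(i) {
             as.list(com$communities[i, ])
           }))
    }),
    file.path(config$out_dir, "community_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  comparison <- compare_networks(metrics[[key_a]], metrics[[key_b]],
                                 top_n = config$top_n)
  utils::write.table(comparison$differences,
                     file.path(config$out_dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(comparison$key_genes,
             file.path(config$out_dir, "key_genes.txt"))
  message(sprintf("compare [t = %.2f]: key gene(s): %s", t0,
                  if (length(comparison$key_genes))
                    paste(comparison$key_genes, collapse = ", ")
                  else "(none)"))

  invisible(list(screen = screen, networks = networks, metrics = metrics,
                 summaries = summaries, communities = communities,
                 comparison = comparison))
}
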