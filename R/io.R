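## Plain-text file formats: TSV expression matrices, triplet TSV with a
## JSON sidecar, and a write-only Pajek export.

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column holds gene ids, the header row sample ids. Duplicate
#' gene ids and non-numeric cells are rejected with informative errors.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression TSV needs a gene column plus samples",
                          call. = FALSE)
  genes <- raw[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  samples <- colnames(raw)[-1]
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) & !is.na(col))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1]], genes[bad[1]], samples[j]), call. = FALSE)
    }
    mat[, j] <- val
  }
  mat
}

#' Write a gene-by-sample expression matrix to TSV
#'
#' Values are written with full double precision so a write/read cycle
#' is bit-identical.
#'
#' @param mat numeric matrix with gene rownames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  if (is.null(rownames(mat))) stop("matrix must have gene rownames", call. = FALSE)
  header <- paste(c("gene", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a logic network as triplet TSV plus JSON sidecar
#'
#' The TSV holds one relation per line (`source_a`, `source_b`,
#' `target`, `logic_type`, `u_value`, `u_first_a`, `u_first_b`); the
#' sidecar `<path>.json` records the inference parameters.
#'
#' @param net a [logic_network()].
#' @param path output TSV path (sidecar written next to it).
#' @param k,t,condition parameters recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, k = NA, t = NA, condition = NA) {
  stopifnot(inherits(net, "logic_network"))
  r <- net$relations
  for (col in c("u_first_a", "u_first_b")) {
    if (is.null(r[[col]])) r[[col]] <- rep(NA_real_, nrow(r))
  }
  cols <- c("source_a", "source_b", "target", "logic_type",
            "u_value", "u_first_a", "u_first_b")
  utils::write.table(r[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(k = k, t = t, condition = condition,
               nodes = net$nodes, n_relations = nrow(r))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a logic network written by [write_network()]
#'
#' @param path triplet TSV path; the JSON sidecar is read when present
#'   (restoring isolated nodes and parameters).
#' @return a [logic_network()]; sidecar parameters are attached as
#'   attribute `"meta"`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  r <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(source_a = "character",
                                        source_b = "character",
                                        target = "character",
                                        logic_type = "character"))
  if (nrow(r) && !all(r$logic_type %in% logic_types())) {
    bad <- setdiff(unique(r$logic_type), logic_types())
    stop("unknown logic_type in file: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  meta <- NULL
  nodes <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    nodes <- meta$nodes
  }
  net <- logic_network(r, nodes = nodes)
  attr(net, "meta") <- meta
  net
}

#' Export a logic network in Pajek .net format (write-only)
#'
#' Writes the projected arcs source -> target of every relation; a
#' convenience for external visualization, never read back.
#'
#' @param net a [logic_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(net, path) {
  stopifnot(inherits(net, "logic_network"))
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  lines <- c(sprintf("*Vertices %d", length(net$nodes)),
             sprintf('%d "%s"', idx, net$nodes),
             "*Arcs")
  r <- net$relations
  for (i in seq_len(nrow(r))) {
    lines <- c(lines,
               sprintf("%d %d %.6f", idx[[r$source_a[i]]], idx[[r$target[i]]],
                       r$u_value[i]),
               sprintf("%d %d %.6f", idx[[r$source_b[i]]], idx[[r$target[i]]],
                       r$u_value[i]))
  }
  writeLines(lines, path)
  invisible(path)
}
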