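## Synthetic two-condition expression data with known ground truth.
##
## Emulates the study layout: two conditions with unequal sample counts,
## nonnegative continuous expression, a subset of genes shifted in
## location between conditions, and planted second-order logic relations
## C = f2(A, B) corrupted by noise, among independent decoy genes.

#' Describe one planted logic triplet
#'
#' @param a,b,c gene indices (1-based, distinct) of the two sources and
#'   the target.
#' @param type one of [logic_types()].
#' @param noise_prob fraction of samples whose planted target level is
#'   randomized, in \[0, 1\].
#' @return a `planted_triplet` list.
#' @export
planted_triplet <- function(a, b, c, type, noise_prob = 0) {
  out <- list(
    a = assert_count(a, "a", positive = TRUE),
    b = assert_count(b, "b", positive = TRUE),
    c = assert_count(c, "c", positive = TRUE),
    type = match.arg(as.character(type), logic_types()),
    noise_prob = assert_prob(noise_prob, "noise_prob")
  )
  if (anyDuplicated(c(out$a, out$b, out$c))) {
    stop("field 'a/b/c' must be three distinct gene indices", call. = FALSE)
  }
  structure(out, class = "planted_triplet")
}

#' Specification of a synthetic two-condition dataset
#'
#' Defaults mirror the study conditions the generator emulates: two
#' conditions with 42 and 52 samples and a location shift of 5
#' expression units for differential genes.
#'
#' @param n_genes number of genes.
#' @param n_samples_a,n_samples_b sample counts for conditions a and b.
#' @param n_differential number of genes whose location is shifted in
#'   condition b (direction alternates to cover both tails).
#' @param shift location shift, in expression units.
#' @param planted_triplets list of [planted_triplet()]s.
#' @param seed integer RNG seed; identical specs give bit-identical data.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes, n_samples_a = 42, n_samples_b = 52,
                           n_differential = 0, shift = 5,
                           planted_triplets = list(), seed = 1) {
  n_genes <- assert_count(n_genes, "n_genes", positive = TRUE)
  spec <- list(
    n_genes = n_genes,
    n_samples_a = assert_count(n_samples_a, "n_samples_a", positive = TRUE),
    n_samples_b = assert_count(n_samples_b, "n_samples_b", positive = TRUE),
    n_differential = assert_count(n_differential, "n_differential"),
    shift = shift,
    planted_triplets = planted_triplets,
    seed = assert_count(seed, "seed")
  )
  if (!is.numeric(shift) || length(shift) != 1 || is.na(shift)) {
    stop("field 'shift' must be a single number", call. = FALSE)
  }
  if (spec$n_differential > n_genes) {
    stop("field 'n_differential' exceeds n_genes", call. = FALSE)
  }
  for (tr in planted_triplets) {
    if (!inherits(tr, "planted_triplet")) {
      stop("field 'planted_triplets' must contain planted_triplet objects",
           call. = FALSE)
    }
    if (max(tr$a, tr$b, tr$c) > n_genes) {
      stop("field 'planted_triplets' refers to a gene index beyond n_genes",
           call. = FALSE)
    }
  }
  planted_ids <- unique(unlist(lapply(planted_triplets, function(t) c(t$a, t$b, t$c))))
  if (spec$n_differential > n_genes - length(planted_ids)) {
    stop("field 'n_differential' leaves no room outside planted triplet genes",
         call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

## balanced bimodal draw for planted source rows: 50/50 low/high lognormal
## components well separated so min-max discretization is ~balanced
rbimodal <- function(n) {
  hi <- stats::runif(n) < 0.5
  ifelse(hi, 6 + stats::rlnorm(n, 0, 0.25), stats::rlnorm(n, 0, 0.25))
}

#' Generate a synthetic two-condition expression dataset
#'
#' Decoy genes are i.i.d. lognormal(0, 1) in both conditions. Source
#' genes of planted triplets are drawn from a balanced bimodal mixture
#' so their discretized levels are roughly equiprobable. Differential
#' genes are location-shifted in condition b only (up-shifts add
#' `shift`; down-shifts subtract and truncate at zero to keep values
#' nonnegative). Planted target rows are overwritten by
#' [plant_logic_triplet()] in each condition independently.
#'
#' @param spec a [synthetic_spec()].
#' @param k discretization granularity used when planting triplets.
#' @return list with `matrix_a`, `matrix_b` (gene-by-sample, rownames
#'   `g001`, ...) and `truth` (differential gene ids, planted triplet
#'   records, and the spec).
#' @export
generate_expression_dataset <- function(spec, k = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- assert_count(k, "k", positive = TRUE)
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  with_seed(spec$seed, {
    ma <- matrix(stats::rlnorm(spec$n_genes * spec$n_samples_a),
                 nrow = spec$n_genes,
                 dimnames = list(genes, sprintf("a%02d", seq_len(spec$n_samples_a))))
    mb <- matrix(stats::rlnorm(spec$n_genes * spec$n_samples_b),
                 nrow = spec$n_genes,
                 dimnames = list(genes, sprintf("b%02d", seq_len(spec$n_samples_b))))

    planted_src <- unique(unlist(lapply(spec$planted_triplets, function(t) c(t$a, t$b))))
    for (g in planted_src) {
      ma[g, ] <- rbimodal(spec$n_samples_a)
      mb[g, ] <- rbimodal(spec$n_samples_b)
    }

    planted_all <- unique(unlist(lapply(spec$planted_triplets,
                                        function(t) c(t$a, t$b, t$c))))
    eligible <- setdiff(seq_len(spec$n_genes), planted_all)
    diff_idx <- if (spec$n_differential > 0) {
      sort(sample(eligible, spec$n_differential))
    } else integer(0)
    for (i in seq_along(diff_idx)) {
      g <- diff_idx[i]
      mb[g, ] <- if (i %% 2 == 1) mb[g, ] + spec$shift
                 else pmax(mb[g, ] - spec$shift, 0)
    }

    plant_seeds <- if (length(spec$planted_triplets)) {
      sample.int(.Machine$integer.max - 1L, 2 * length(spec$planted_triplets))
    } else integer(0)
    for (i in seq_along(spec$planted_triplets)) {
      tr <- spec$planted_triplets[[i]]
      ma <- plant_logic_triplet(ma, tr$a, tr$b, tr$c, tr$type, tr$noise_prob,
                                k = k, seed = plant_seeds[2 * i - 1])
      mb <- plant_logic_triplet(mb, tr$a, tr$b, tr$c, tr$type, tr$noise_prob,
                                k = k, seed = plant_seeds[2 * i])
    }

    truth <- list(
      differential_gene_ids = genes[diff_idx],
      triplet_records = if (length(spec$planted_triplets)) {
        do.call(rbind, lapply(spec$planted_triplets, function(t) {
          data.frame(source_a = genes[t$a], source_b = genes[t$b],
                     target = genes[t$c], logic_type = t$type,
                     noise_prob = t$noise_prob, stringsAsFactors = FALSE)
        }))
      } else {
        data.frame(source_a = character(0), source_b = character(0),
                   target = character(0), logic_type = character(0),
                   noise_prob = numeric(0))
      },
      spec = spec
    )
    list(matrix_a = ma, matrix_b = mb, truth = truth)
  })
}

#' Plant a second-order logic relation into an expression matrix
#'
#' Overwrites row `c` so that, after min-max normalization and
#' discretization at granularity `k`, the target equals the chosen
#' proper function of the discretized source rows in a fraction
#' `>= 1 - noise_prob` of samples; the remaining samples get a level
#' drawn uniformly at random. Planting happens in discretized space and
#' level codes are mapped back to the midpoint of each level's interval,
#' so the ground truth survives normalization exactly whenever the
#' planted row spans both extreme levels (always the case at `k = 1` for
#' non-degenerate rows).
#'
#' @param matrix numeric gene-by-sample matrix.
#' @param a,b,c distinct row indices: sources and target.
#' @param logic_type one of [logic_types()].
#' @param noise_prob corruption probability in \[0, 1\].
#' @param k discretization granularity.
#' @param seed integer seed; output is deterministic given the seed.
#' @return the matrix with row `c` replaced.
#' @export
plant_logic_triplet <- function(matrix, a, b, c, logic_type, noise_prob,
                                k = 1, seed = 1) {
  k <- assert_count(k, "k", positive = TRUE)
  noise_prob <- assert_prob(noise_prob, "noise_prob")
  logic_type <- match.arg(as.character(logic_type), logic_types())
  ids <- c(a, b, c)
  if (any(ids < 1 | ids > nrow(matrix))) {
    stop("gene index out of range", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("a, b, c must be distinct gene indices", call. = FALSE)
  norm_row <- function(i) {
    v <- withCallingHandlers(minmax_normalize(matrix[i, ]),
                             warning = function(w) invokeRestart("muffleWarning"))
    if (isTRUE(attr(v, "degenerate"))) {
      stop("plant_logic_triplet(): source row ", i, " is constant", call. = FALSE)
    }
    v
  }
  ca <- value_to_code(norm_row(a), k)
  cb <- value_to_code(norm_row(b), k)
  out <- apply_logic_codes(logic_type, ca, cb, k)
  with_seed(seed, {
    flip <- stats::runif(length(out)) < noise_prob
    if (any(flip)) out[flip] <- sample.int(2L * k, sum(flip), replace = TRUE)
  })
  matrix[c, ] <- (out - 0.5) / (2 * k)
  matrix
}
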