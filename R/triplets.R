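## Scanning gene triplets for second-order logic relations.

#' Discretize every row of a normalized expression matrix
#'
#' @param mat numeric matrix with values in \[0, 1\] (see
#'   [normalize_pooled()]), genes in rows.
#' @param k granularity.
#' @return named list of `disc_vector`s, one per gene.
#' @export
discretize_matrix <- function(mat, k = 1) {
  if (is.null(rownames(mat))) stop("matrix must have gene rownames", call. = FALSE)
  out <- lapply(rownames(mat), function(g) discretize(mat[g, ], k, gene_id = g))
  names(out) <- rownames(mat)
  out
}

#' First-order uncertainty U(C | f1(A))
#'
#' The best first-order prediction of target `C` from source `A`: the
#' maximum of `U(C|A)` over the two unary proper functions, identity and
#' negation. (Negating the predictor relabels its levels bijectively, so
#' the two candidates coincide; both are computed nonetheless.)
#'
#' @param A source `disc_vector`.
#' @param C target `disc_vector` with positive entropy.
#' @return U value in \[0, 1\].
#' @export
first_order_u <- function(A, C) {
  max(uncertainty(A, C)$value, uncertainty(negate_disc(A), C)$value)
}

#' Best second-order logic function for a triplet
#'
#' Evaluates `U(C | f2(A, B))` for all ten proper functions and returns
#' the maximizer. Ties are broken by the canonical order of
#' [logic_types()] (lowest type id, then the `a` before the `b`
#' variant); note each function ties exactly with its complement (see
#' [equivalent_logic_types()]).
#'
#' @param A,B source `disc_vector`s.
#' @param C target `disc_vector` with positive entropy.
#' @return list with `logic_type` and raw `u` value.
#' @export
best_second_order <- function(A, B, C) {
  check_same_system(A, B, "best_second_order()")
  check_same_system(A, C, "best_second_order()")
  k <- A$k
  H_t <- H_codes(C$codes, k)
  if (H_t <= 0) stop("best_second_order(): target has zero entropy", call. = FALSE)
  best_u <- -Inf
  best_type <- NA_character_
  for (type in logic_types()) {
    f <- apply_logic_codes(type, A$codes, B$codes, k)
    u <- u_codes(f, C$codes, k, H_t)
    if (u > best_u + 1e-12) {
      best_u <- u
      best_type <- type
    }
  }
  list(logic_type = best_type, u = best_u)
}

#' Scan all gene triplets and apply the acceptance filter
#'
#' For every unordered source pair \{A, B\} and every other target C
#' with positive entropy, the best proper function and its raw U value
#' are computed. All raw U values — second-order and first-order — are
#' then normalized by the dataset-wide maximum raw U value ("U / max U"
#' over the database), and a relation is kept iff
#' \deqn{U(C|f_2(A,B)) \ge \max\{U(C|A) + t,\; U(C|B) + t\}}
#' in normalized units: the pair must predict the target better than
#' either source alone by margin `t`. Genes with zero entropy are
#' skipped.
#'
#' @param disc_list named list of `disc_vector`s (see
#'   [discretize_matrix()]), at least 3 non-degenerate genes.
#' @param t acceptance threshold in \[0, 1\].
#' @return data.frame of accepted relations with columns `source_a`,
#'   `source_b`, `target`, `logic_type`, `u_value`, `u_first_a`,
#'   `u_first_b` (all U values normalized). Attributes report
#'   `n_triplets_evaluated`, `n_accepted`, `n_skipped_zero_entropy` and
#'   the raw normalization constant `u_max`.
#' @export
scan_triplets <- function(disc_list, t) {
  t <- assert_prob(t, "t")
  if (!length(disc_list) || is.null(names(disc_list))) {
    stop("scan_triplets(): need a named list of disc_vectors", call. = FALSE)
  }
  k <- disc_list[[1]]$k
  n <- length(disc_list[[1]]$codes)
  for (d in disc_list) check_same_system(disc_list[[1]], d, "scan_triplets()")

  H <- vapply(disc_list, function(d) H_codes(d$codes, k), numeric(1))
  skipped <- sum(H <= 0)
  keep <- names(disc_list)[H > 0]
  if (length(keep) < 3) {
    stop("scan_triplets(): need >= 3 genes with positive entropy", call. = FALSE)
  }
  codes <- do.call(rbind, lapply(disc_list[keep], function(d) d$codes))
  rownames(codes) <- keep
  H <- H[keep]
  ng <- length(keep)

  types <- logic_types()
  n_trip <- ng * (ng - 1) / 2 * (ng - 2)
  rec_a <- rec_b <- rec_c <- rec_type <- character(n_trip)
  rec_u <- numeric(n_trip)
  pos <- 0L
  two_k <- 2L * k

  if (k == 1) {
    ## fast path: Boolean levels; joint counts for all targets at once via
    ## a matrix-vector product over the 0/1 indicator rows
    up <- (codes == 2L) * 1
    n_up <- rowSums(up)
    plogp <- function(x) {
      out <- numeric(length(x))
      pos <- x > 0
      out[pos] <- x[pos] * log2(x[pos])
      out
    }
    u_against_all <- function(fb) {
      nf <- sum(fb)
      Hf <- -(plogp(nf / n) + plogp(1 - nf / n))
      n11 <- as.numeric(up %*% fb)
      n10 <- nf - n11
      n01 <- n_up - n11
      n00 <- n - n11 - n10 - n01
      Hj <- -(plogp(n11 / n) + plogp(n10 / n) + plogp(n01 / n) + plogp(n00 / n))
      pmin(pmax((H + Hf - Hj) / H, 0), 1)
    }
    ## first-order (predictor negation permutes the joint cells, so the
    ## identity and negation candidates coincide exactly)
    u1 <- matrix(NA_real_, ng, ng, dimnames = list(keep, keep))
    for (s in seq_len(ng)) {
      u1[s, ] <- pmax(u_against_all(up[s, ]), u_against_all(1 - up[s, ]))
      u1[s, s] <- NA_real_
    }
    for (i in seq_len(ng - 1)) {
      fi <- up[i, ]
      for (j in seq((i + 1), ng)) {
        fj <- up[j, ]
        fand <- fi * fj
        fs <- list("1" = fand, "2" = 1 - fand,
                   "3" = fi + fj - fand, "4" = 1 - fi - fj + fand,
                   "5a" = fj - fand, "5b" = fi - fand,
                   "6a" = 1 - fi + fand, "6b" = 1 - fj + fand,
                   "7" = 1 - fi - fj + 2 * fand, "8" = fi + fj - 2 * fand)
        targets <- setdiff(seq_len(ng), c(i, j))
        best_u <- rep(-Inf, ng)
        best_type <- rep(NA_character_, ng)
        for (type in types) {
          u <- u_against_all(fs[[type]])
          imp <- u > best_u + 1e-12
          best_u[imp] <- u[imp]
          best_type[imp] <- type
        }
        idx <- pos + seq_along(targets)
        rec_a[idx] <- keep[i]
        rec_b[idx] <- keep[j]
        rec_c[idx] <- keep[targets]
        rec_type[idx] <- best_type[targets]
        rec_u[idx] <- best_u[targets]
        pos <- pos + length(targets)
      }
    }
  } else {
    ## general multi-valued path
    u1 <- matrix(NA_real_, ng, ng, dimnames = list(keep, keep))
    for (s in seq_len(ng)) {
      neg_s <- negate_codes(codes[s, ], k)
      for (tt in seq_len(ng)) {
        if (s == tt) next
        u1[s, tt] <- max(u_codes(codes[s, ], codes[tt, ], k, H[tt]),
                         u_codes(neg_s, codes[tt, ], k, H[tt]))
      }
    }
    for (i in seq_len(ng - 1)) {
      ci <- codes[i, ]
      for (j in seq((i + 1), ng)) {
        cj <- codes[j, ]
        targets <- setdiff(seq_len(ng), c(i, j))
        best_u <- rep(-Inf, length(targets))
        best_type <- rep(NA_character_, length(targets))
        for (type in types) {
          f <- apply_logic_codes(type, ci, cj, k)
          Hf <- H_codes(f, k)
          base <- (f - 1L) * two_k
          for (m in seq_along(targets)) {
            ct <- codes[targets[m], ]
            Hj <- ent_bits(tabulate(base + ct, nbins = 4L * k * k))
            u <- min(max((H[targets[m]] + Hf - Hj) / H[targets[m]], 0), 1)
            if (u > best_u[m] + 1e-12) {
              best_u[m] <- u
              best_type[m] <- type
            }
          }
        }
        idx <- pos + seq_along(targets)
        rec_a[idx] <- keep[i]
        rec_b[idx] <- keep[j]
        rec_c[idx] <- keep[targets]
        rec_type[idx] <- best_type
        rec_u[idx] <- best_u
        pos <- pos + length(targets)
      }
    }
  }

  ## normalize every U value by the dataset-wide maximum raw U
  u_max <- max(c(rec_u, u1[!is.na(u1)]))
  if (u_max <= 0) {
    rel <- data.frame(source_a = character(0), source_b = character(0),
                      target = character(0), logic_type = character(0),
                      u_value = numeric(0), u_first_a = numeric(0),
                      u_first_b = numeric(0), stringsAsFactors = FALSE)
  } else {
    u2n <- rec_u / u_max
    u1a <- u1[cbind(rec_a, rec_c)] / u_max
    u1b <- u1[cbind(rec_b, rec_c)] / u_max
    acc <- u2n >= pmax(u1a, u1b) + t
    rel <- data.frame(source_a = rec_a[acc], source_b = rec_b[acc],
                      target = rec_c[acc], logic_type = rec_type[acc],
                      u_value = u2n[acc], u_first_a = u1a[acc],
                      u_first_b = u1b[acc], stringsAsFactors = FALSE)
  }
  rownames(rel) <- NULL
  structure(rel,
            n_triplets_evaluated = n_trip,
            n_accepted = nrow(rel),
            n_skipped_zero_entropy = skipped,
            u_max = if (is.finite(u_max)) u_max else 0)
}
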