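## Normalization and Wilcoxon rank-sum candidate screening.

#' Min-max normalize an expression row to [0, 1]
#'
#' Affine map `(x - min) / (max - min)`. A constant row has no scale and
#' is flagged degenerate: the function warns and returns an all-`NA`
#' vector carrying `attr(, "degenerate") = TRUE`; such genes are
#' excluded from triplet scanning.
#'
#' @param row numeric vector with at least 2 entries.
#' @return numeric vector in \[0, 1\], or flagged `NA` vector if degenerate.
#' @examples
#' minmax_normalize(c(2, 4, 6)) # 0 0.5 1
#' @export
minmax_normalize <- function(row) {
  if (length(row) < 2 || anyNA(row)) {
    stop("minmax_normalize(): need >= 2 non-missing values", call. = FALSE)
  }
  rng <- range(row)
  if (rng[1] == rng[2]) {
    warning("constant expression row: flagged degenerate, excluded from scanning",
            call. = FALSE)
    return(structure(rep(NA_real_, length(row)), degenerate = TRUE))
  }
  (row - rng[1]) / (rng[2] - rng[1])
}

#' Rank-sum screening statistic for one gene
#'
#' Pools the two samples, ranks them (midranks for ties), and forms the
#' per-sample mean rank difference `T0/n0 - T1/n1`, where `T0`, `T1` are
#' the rank sums of the two conditions. Under the null of identical
#' distributions the statistic has expectation zero. The two-sided
#' p-value uses the normal approximation to the rank sum with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y numeric expression vectors for the two conditions.
#' @return list with `T0`, `T1`, `statistic`, `p_value`.
#' @examples
#' rank_sum_statistic(c(1, 2, 3), c(4, 5, 6))$statistic # -3
#' @export
rank_sum_statistic <- function(x, y) {
  n0 <- length(x); n1 <- length(y)
  if (n0 < 1 || n1 < 1) stop("rank_sum_statistic(): empty sample", call. = FALSE)
  z <- c(x, y)
  r <- rank(z)
  T0 <- sum(r[seq_len(n0)])
  T1 <- sum(r[n0 + seq_len(n1)])
  N <- n0 + n1
  mu <- n0 * (N + 1) / 2
  ties <- table(z)
  sigma2 <- n0 * n1 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    p <- 1
  } else {
    dev <- T0 - mu
    zstat <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(zstat)))
  }
  list(T0 = T0, T1 = T1, statistic = T0 / n0 - T1 / n1, p_value = p)
}

#' Screen candidate genes by the rank-sum test
#'
#' Applies [rank_sum_statistic()] to each shared gene of two
#' gene-by-sample matrices and marks genes with `p_value <= alpha` as
#' candidates.
#'
#' @param matrix_a,matrix_b numeric matrices (genes in rows, identical
#'   rownames; sample counts may differ).
#' @param alpha significance level in \[0, 1\].
#' @return data.frame with columns `gene_id`, `T0`, `T1`, `statistic`,
#'   `p_value`, `is_candidate`, sorted by increasing p-value (ties by
#'   gene id).
#' @export
screen_candidates <- function(matrix_a, matrix_b, alpha) {
  alpha <- assert_prob(alpha, "alpha")
  if (is.null(rownames(matrix_a)) || is.null(rownames(matrix_b)) ||
      !setequal(rownames(matrix_a), rownames(matrix_b))) {
    stop("screen_candidates(): matrices must share an identical gene id set",
         call. = FALSE)
  }
  genes <- rownames(matrix_a)
  res <- lapply(genes, function(g) {
    s <- rank_sum_statistic(matrix_a[g, ], matrix_b[g, ])
    data.frame(gene_id = g, T0 = s$T0, T1 = s$T1, statistic = s$statistic,
               p_value = s$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$is_candidate <- out$p_value <= alpha
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled min-max normalization of two condition matrices
#'
#' Normalizes each gene over the pooled samples of both conditions so
#' the two networks share one discretization scale, then splits the
#' result back into per-condition matrices. Degenerate (constant) genes
#' are dropped with a warning.
#'
#' @param matrix_a,matrix_b numeric gene-by-sample matrices with the
#'   same rownames.
#' @return list with normalized `matrix_a`, `matrix_b` and character
#'   vector `dropped` of degenerate gene ids.
#' @export
normalize_pooled <- function(matrix_a, matrix_b) {
  if (!identical(rownames(matrix_a), rownames(matrix_b))) {
    stop("normalize_pooled(): row order/ids must match", call. = FALSE)
  }
  na <- ncol(matrix_a)
  pooled <- cbind(matrix_a, matrix_b)
  dropped <- character(0)
  for (g in rownames(pooled)) {
    v <- withCallingHandlers(
      minmax_normalize(pooled[g, ]),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (isTRUE(attr(v, "degenerate"))) dropped <- c(dropped, g)
    pooled[g, ] <- as.numeric(v)
  }
  if (length(dropped)) {
    warning(sprintf("%d constant gene(s) dropped: %s", length(dropped),
                    paste(dropped, collapse = ", ")), call. = FALSE)
    pooled <- pooled[setdiff(rownames(pooled), dropped), , drop = FALSE]
  }
  list(
    matrix_a = pooled[, seq_len(na), drop = FALSE],
    matrix_b = pooled[, na + seq_len(ncol(matrix_b)), drop = FALSE],
    dropped = dropped
  )
}
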