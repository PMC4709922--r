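## Entropy and uncertainty-coefficient machinery.
##
## All entropies are in bits (log base 2) and use maximum-likelihood
## plug-in frequencies without smoothing; 0 * log 0 = 0 by convention.

ent_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Down-/up-regulation self-entropy of a discretized vector
#'
#' Splits the Shannon entropy of the level distribution into the
#' contribution of the `k` down levels (values below 1/2) and the `k` up
#' levels. The two parts sum exactly to the total self-entropy.
#'
#' @param D a `disc_vector` (see [discretize()]).
#' @return list with `H_down`, `H_up`, `H` (bits).
#' @examples
#' self_entropy(discretize(c(0, 0, 1, 1), k = 1)) # 0.5 + 0.5 = 1 bit
#' @export
self_entropy <- function(D) {
  stopifnot(inherits(D, "disc_vector"))
  if (length(D$codes) == 0) stop("self_entropy(): empty vector", call. = FALSE)
  k <- D$k
  n <- length(D$codes)
  tab <- tabulate(D$codes, nbins = 2L * k)
  ## partial entropies share the full-sample denominator
  p <- tab / n
  h_part <- function(idx) {
    pp <- p[idx][p[idx] > 0]
    if (!length(pp)) 0 else -sum(pp * log2(pp))
  }
  H_down <- h_part(seq_len(k))
  H_up <- h_part(k + seq_len(k))
  list(H_down = H_down, H_up = H_up, H = H_down + H_up)
}

## total self-entropy from raw codes (fast path)
H_codes <- function(codes, k) ent_bits(tabulate(codes, nbins = 2L * k))

#' Joint entropy of two discretized vectors, split by sign quadrant
#'
#' The joint empirical distribution of level pairs is split into four
#' sign quadrants — both down (`H_dd`), both up (`H_uu`), up in `D` /
#' down in `B` (`H_ud`), down in `D` / up in `B` (`H_du`) — whose
#' entropy contributions sum to the total joint entropy `H_joint`.
#'
#' @param D,B `disc_vector`s of equal length on the same level system.
#' @return list with `H_dd`, `H_uu`, `H_ud`, `H_du`, `H_joint` (bits).
#' @export
joint_entropy <- function(D, B) {
  check_same_system(D, B, "joint_entropy()")
  k <- D$k
  n <- length(D$codes)
  idx <- (D$codes - 1L) * 2L * k + B$codes
  tab <- tabulate(idx, nbins = 4L * k * k)
  p <- tab / n
  ## quadrant membership of joint cell (d, b): row-major by D code
  dcode <- rep(seq_len(2L * k), each = 2L * k)
  bcode <- rep(seq_len(2L * k), times = 2L * k)
  h_part <- function(sel) {
    pp <- p[sel][p[sel] > 0]
    if (!length(pp)) 0 else -sum(pp * log2(pp))
  }
  H_dd <- h_part(dcode <= k & bcode <= k)
  H_uu <- h_part(dcode > k & bcode > k)
  H_ud <- h_part(dcode > k & bcode <= k)
  H_du <- h_part(dcode <= k & bcode > k)
  list(H_dd = H_dd, H_uu = H_uu, H_ud = H_ud, H_du = H_du,
       H_joint = H_dd + H_uu + H_ud + H_du)
}

H_joint_codes <- function(codes_a, codes_b, k) {
  ent_bits(tabulate((codes_a - 1L) * 2L * k + codes_b, nbins = 4L * k * k))
}

#' Uncertainty coefficient U(B|A)
#'
#' The normalized mutual information
#' \deqn{U(B|A) = \frac{H(B) + H(A) - H(A,B)}{H(B)},}
#' read as the probability that predictor `A` determines target `B`.
#' Defined only when `H(B) > 0`; the value is clamped to \[0, 1\] to
#' absorb floating-point negatives near independence.
#'
#' @param A predictor `disc_vector`.
#' @param B target `disc_vector`.
#' @return list with `value` (in \[0, 1\]) and `target_entropy` (bits).
#' @examples
#' A <- discretize(c(0, 0, 1, 1), k = 1)
#' uncertainty(A, A)$value # 1
#' @export
uncertainty <- function(A, B) {
  check_same_system(A, B, "uncertainty()")
  k <- A$k
  HB <- H_codes(B$codes, k)
  if (HB <= 0) {
    stop("uncertainty(): target has zero entropy (constant vector); U undefined",
         call. = FALSE)
  }
  HA <- H_codes(A$codes, k)
  HAB <- H_joint_codes(A$codes, B$codes, k)
  val <- (HB + HA - HAB) / HB
  list(value = min(max(val, 0), 1), target_entropy = HB)
}

## fast path: U(target | predictor codes) given precomputed H(target)
u_codes <- function(pred, targ, k, H_targ) {
  Hp <- H_codes(pred, k)
  Hj <- H_joint_codes(pred, targ, k)
  min(max((H_targ + Hp - Hj) / H_targ, 0), 1)
}
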