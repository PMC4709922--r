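#' Multi-valued level system
#'
#' The discretization scale used throughout the package. A granularity
#' parameter `k` splits the unit interval into `2k` symbolic levels:
#' `k` "down" levels \eqn{x_i = (i-1)/2k} (all below 1/2) and `k` "up"
#' levels \eqn{x^i = 1 - (i-1)/2k} (all at or above 1/2), for
#' \eqn{i = 1, \dots, k}. At `k = 1` the system reduces to Boolean
#' \{0, 1\}. Negation pairs \eqn{x_i} with \eqn{x^i}; logical AND and OR
#' are min and max on the level values.
#'
#' Internally levels are stored as integer codes `1..2k` ordered by value
#' (code `c <= k` is the down level with value `(c-1)/2k`; code `c > k` is
#' the up level with value `c/2k`), so all comparisons are exact.
#'
#' @param k positive integer granularity.
#' @return An object of class `level_system` with fields `k`,
#'   `down_levels`, `up_levels`.
#' @examples
#' level_system(2)
#' @export
level_system <- function(k) {
  k <- assert_count(k, "k", positive = TRUE)
  ## one canonical formula for every level value (x^i = 1 - (i-1)/2k is
  ## computed as (2k+1-i)/2k so equal levels are bit-identical doubles)
  structure(
    list(
      k = k,
      down_levels = (seq_len(k) - 1) / (2 * k),
      up_levels = (2 * k + 1 - seq_len(k)) / (2 * k)
    ),
    class = "level_system"
  )
}

#' @export
print.level_system <- function(x, ...) {
  cat("Level system, k =", x$k, "\n")
  cat("  down:", paste(format(x$down_levels), collapse = " "), "\n")
  cat("  up:  ", paste(format(rev(x$up_levels)), collapse = " "), "\n")
  invisible(x)
}

## code <-> value maps (codes 1..2k ascending by level value)
code_to_value <- function(code, k) {
  ifelse(code <= k, (code - 1) / (2 * k), code / (2 * k))
}

value_to_code <- function(v, k) {
  code <- pmin(as.integer(floor(v * 2 * k + 1e-9)) + 1L, 2L * k)
  code
}

negate_codes <- function(codes, k) 2L * k + 1L - codes

#' Discretize a normalized expression vector
#'
#' Maps values in \[0, 1\] onto the `2k` levels of [level_system()].
#' Intervals are half-open `[lo, hi)`: the value `(i-1)/2k <= d < i/2k`
#' becomes down level \eqn{x_i}, `1 - i/2k <= d < 1 - (i-1)/2k` becomes up
#' level \eqn{x^i}, the midpoint 1/2 falls on the up side (\eqn{x^k}) and
#' `d = 1` maps to \eqn{x^1 = 1}.
#'
#' @param x numeric vector with all entries in \[0, 1\].
#' @param k positive integer granularity.
#' @param gene_id optional identifier carried along.
#' @return A `disc_vector`: integer level codes plus the level system.
#' @examples
#' discretize(c(0.10, 0.30, 0.60, 0.95), k = 2)
#' @export
discretize <- function(x, k = 1, gene_id = NULL) {
  k <- assert_count(k, "k", positive = TRUE)
  if (anyNA(x) || any(x < 0 | x > 1)) {
    stop("discretize(): values must lie in [0, 1] and be non-missing", call. = FALSE)
  }
  new_disc_vector(value_to_code(x, k), k, gene_id)
}

new_disc_vector <- function(codes, k, gene_id = NULL) {
  structure(
    list(codes = as.integer(codes), k = as.integer(k), gene_id = gene_id),
    class = "disc_vector"
  )
}

#' @export
print.disc_vector <- function(x, ...) {
  id <- if (is.null(x$gene_id)) "" else paste0(" [", x$gene_id, "]")
  cat("Discretized vector", id, " (k = ", x$k, ", n = ", length(x$codes), ")\n", sep = "")
  print(code_to_value(x$codes, x$k))
  invisible(x)
}

#' @export
length.disc_vector <- function(x) length(x$codes)

#' Level values of a discretized vector
#' @param x a `disc_vector`.
#' @param ... unused.
#' @return numeric vector of level values in \[0, 1\].
#' @export
as.double.disc_vector <- function(x, ...) code_to_value(x$codes, x$k)

check_same_system <- function(a, b, what) {
  if (!inherits(a, "disc_vector") || !inherits(b, "disc_vector")) {
    stop(what, ": inputs must be disc_vector objects", call. = FALSE)
  }
  if (a$k != b$k) stop(what, ": level systems differ (k mismatch)", call. = FALSE)
  if (length(a$codes) != length(b$codes)) stop(what, ": lengths differ", call. = FALSE)
  invisible(TRUE)
}

#' Negate a level value
#'
#' The multi-valued NOT swaps \eqn{x_i} with \eqn{x^i}; it is an
#' involution on the level set.
#'
#' @param level a level value belonging to `system`.
#' @param system a [level_system()].
#' @return the negated level value.
#' @examples
#' negate_level(0.25, level_system(2)) # 0.75
#' @export
negate_level <- function(level, system) {
  stopifnot(inherits(system, "level_system"))
  k <- system$k
  all_values <- code_to_value(seq_len(2 * k), k)
  code <- vapply(level, function(v) {
    hit <- which(abs(all_values - v) < 1e-9)
    if (length(hit) != 1) {
      stop("negate_level(): value is not a level of this system", call. = FALSE)
    }
    hit
  }, integer(1))
  code_to_value(negate_codes(code, k), k)
}

#' Negate a discretized vector componentwise
#' @param x a `disc_vector`.
#' @return a `disc_vector` with every level negated.
#' @export
negate_disc <- function(x) {
  stopifnot(inherits(x, "disc_vector"))
  new_disc_vector(negate_codes(x$codes, x$k), x$k, x$gene_id)
}

#' Basic multi-valued AND / OR
#'
#' AND is the componentwise minimum of level values, OR the maximum.
#'
#' @param op `"AND"` or `"OR"`.
#' @param a,b level values (vectors allowed) from the same system.
#' @return level values.
#' @export
apply_basic <- function(op, a, b) {
  op <- match.arg(op, c("AND", "OR"))
  if (op == "AND") pmin(a, b) else pmax(a, b)
}

#' The ten two-argument proper logic functions
#'
#' Identifiers of the ten second-order logic functions: AND (`"1"`),
#' NAND (`"2"`), OR (`"3"`), NOR (`"4"`), the two asymmetric
#' conjunctions \eqn{\neg A \wedge B} (`"5a"`) / \eqn{A \wedge \neg B}
#' (`"5b"`), the two implications (`"6a"`, `"6b"`), XNOR (`"7"`) and
#' XOR (`"8"`). All are compositions of min, max and level negation, so
#' at `k = 1` they reproduce the Boolean truth tables.
#'
#' @return character vector of the ten type ids, in canonical order.
#' @export
logic_types <- function() c("1", "2", "3", "4", "5a", "5b", "6a", "6b", "7", "8")

## componentwise application on integer codes
apply_logic_codes <- function(type, a, b, k) {
  ng <- function(z) 2L * k + 1L - z
  switch(type,
    "1"  = pmin(a, b),
    "2"  = pmax(ng(a), ng(b)),
    "3"  = pmax(a, b),
    "4"  = pmin(ng(a), ng(b)),
    "5a" = pmin(ng(a), b),
    "5b" = pmin(a, ng(b)),
    "6a" = pmax(ng(a), b),
    "6b" = pmax(a, ng(b)),
    "7"  = pmin(pmax(ng(a), b), pmax(a, ng(b))),
    "8"  = pmax(pmin(ng(a), b), pmin(a, ng(b))),
    stop("unknown logic type: ", type, call. = FALSE)
  )
}

#' Apply a proper logic function to two discretized vectors
#'
#' @param type one of [logic_types()].
#' @param A,B `disc_vector`s of equal length on the same level system.
#' @return a `disc_vector` with the componentwise function value.
#' @examples
#' A <- discretize(c(0, 0, 1, 1), k = 1)
#' B <- discretize(c(0, 1, 0, 1), k = 1)
#' as.numeric(apply_proper_function("8", A, B)) # XOR: 0 1 1 0
#' @export
apply_proper_function <- function(type, A, B) {
  type <- match.arg(as.character(type), logic_types())
  check_same_system(A, B, "apply_proper_function()")
  new_disc_vector(apply_logic_codes(type, A$codes, B$codes, A$k), A$k)
}

#' Logic types equivalent to a given type under the U score
#'
#' The uncertainty coefficient is invariant under negation of the
#' predictor (negation is a bijective recoding of the levels), so each
#' proper function scores identically to its complement: 1~2, 3~4,
#' 5a~6b, 5b~6a, 7~8. Swapping the two source arguments additionally
#' exchanges the `a`/`b` variants of types 5 and 6. This helper returns
#' every type id that is indistinguishable from `type` by U, which is
#' what "recovering the planted logic type" can mean at best.
#'
#' @param type one of [logic_types()].
#' @param swapped if `TRUE`, return the equivalents for the triplet with
#'   its two sources swapped.
#' @return character vector of equivalent type ids.
#' @export
equivalent_logic_types <- function(type, swapped = FALSE) {
  type <- match.arg(as.character(type), logic_types())
  comp <- c("1" = "2", "2" = "1", "3" = "4", "4" = "3",
            "5a" = "6b", "6b" = "5a", "5b" = "6a", "6a" = "5b",
            "7" = "8", "8" = "7")
  swap <- c("1" = "1", "2" = "2", "3" = "3", "4" = "4",
            "5a" = "5b", "5b" = "5a", "6a" = "6b", "6b" = "6a",
            "7" = "7", "8" = "8")
  base <- if (swapped) unname(swap[type]) else type
  sort(unique(c(base, unname(comp[base]))))
}

## AND / OR / XOR traversal class of each logic type
relation_semantics <- function(type) {
  cls <- c("1" = "AND", "2" = "AND", "4" = "AND", "5a" = "AND", "5b" = "AND",
           "3" = "OR", "6a" = "OR", "6b" = "OR",
           "7" = "XOR", "8" = "XOR")
  out <- unname(cls[as.character(type)])
  if (anyNA(out)) stop("unknown logic type(s)", call. = FALSE)
  out
}

## ---- small shared validators ----
assert_count <- function(x, name, positive = FALSE, allow_zero = !positive) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != floor(x) ||
      x < if (allow_zero) 0 else 1) {
    stop(sprintf("field '%s' must be a %s integer", name,
                 if (allow_zero) "nonnegative" else "positive"), call. = FALSE)
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("field '%s' must lie in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

## evaluate code with a private RNG stream, restoring global state after
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
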