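# Exact enumeration of binary phylogenetic trees, forests, and snowflake
# (central-vertex) counts.  Everything here is exact integer or rational
# arithmetic; floating point (log-Gamma) appears only in the asymptotic
# evaluators meant for very large n.
#
# Notation: B(n) unrooted binary phylogenetic trees on n labelled leaves;
# R(n) rooted ones; N(n, k) forests of k rooted binary trees whose leaf sets
# partition {1..n}; S(n) ordered pairs (T, v) with v the central vertex of a
# snowflake of T; W(n) ordered triples (T, v1, v2) with both vertices
# snowflake centres at distance >= 5.

#' Count unrooted and rooted binary phylogenetic trees
#'
#' `count_unrooted_binary(n)` is `B(n) = (2n-4)!/((n-2)! 2^(n-2)) = (2n-5)!!`
#' (both forms are evaluated and must agree); `count_rooted_binary(n)` is
#' `R(n) = B(n+1)`.  With the convention `B(2) = 1`.
#'
#' @param n number of leaves (`n >= 2`, resp. `n >= 1`).
#' @return `xint`.
#' @examples
#' count_unrooted_binary(6)   # 105
#' @export
count_unrooted_binary <- function(n) {
  n <- as.numeric(n)
  if (n < 2 || n != trunc(n)) stop("need an integer n >= 2")
  f1 <- xi_divexact(xi_factorial(2 * n - 4),
                    xi_factorial(n - 2) * xi_pow(xint(2), n - 2))
  f2 <- xi_double_factorial(2 * n - 5)
  if (!(f1 == f2)) stop("internal error: the two closed forms of B(n) disagree")
  f1
}

#' @rdname count_unrooted_binary
#' @export
count_rooted_binary <- function(n) {
  n <- as.numeric(n)
  if (n < 1 || n != trunc(n)) stop("need an integer n >= 1")
  count_unrooted_binary(n + 1)
}

#' Count forests of rooted binary phylogenetic trees
#'
#' `N(n, k) = (2n-k-1)! / ((n-k)! (k-1)! 2^(n-k))` for `n >= k >= 1`, and 0
#' for `k > n`: the number of forests of `k` rooted binary trees on disjoint
#' leaf sets partitioning `{1..n}`.  Satisfies `N(n,1) = N(n,2) = R(n)` and
#' `N(n,n) = 1`.
#'
#' @param n,k positive integers.
#' @return `xint`.
#' @export
count_forests <- function(n, k) {
  n <- as.numeric(n); k <- as.numeric(k)
  if (n < 1 || k < 1 || n != trunc(n) || k != trunc(k)) stop("need integers n, k >= 1")
  if (k > n) return(xint(0))
  xi_divexact(xi_factorial(2 * n - k - 1),
              xi_factorial(n - k) * xi_factorial(k - 1) * xi_pow(xint(2), n - k))
}

#' Check the path-decomposition identity for B(n+2)
#'
#' Decomposing a tree on `n + 2` leaves along the path between the last two
#' leaves gives `B(n+2) = sum_{k=1}^{n} k! N(n, k)` (the ordered forests
#' hanging off the path).  Both sides are evaluated exactly.
#'
#' @param n integer `>= 1`.
#' @return list with `holds`, `lhs`, `rhs` (`xint`).
#' @export
verify_forest_decomposition <- function(n) {
  n <- as.numeric(n)
  lhs <- count_unrooted_binary(n + 2)
  rhs <- xint(0)
  for (k in seq_len(n)) rhs <- rhs + xi_factorial(k) * count_forests(n, k)
  list(holds = lhs == rhs, lhs = lhs, rhs = rhs)
}

# symmetry count of the snowflake attachment: 12 rooted subtrees arranged
# around the centre; orbit-stabilizer gives 12!/(2^9 * 3!)
snowflake_symmetry_factor <- function() {
  xi_divexact(xi_factorial(12), xi_pow(xint(2), 9) * xi_factorial(3))
}

# same for the double-snowflake backbone: 22 subtrees, 22!/2^16
double_snowflake_symmetry_factor <- function() {
  xi_divexact(xi_factorial(22), xi_pow(xint(2), 16))
}

#' Count (tree, snowflake-centre) pairs
#'
#' `|S(n)| = N(n, 12) * 12!/(2^9 3!)`: a snowflake centred at `v` determines a
#' forest of 12 hanging rooted subtrees plus an arrangement counted by the
#' orbit-stabilizer factor (computed, not hard-coded).  Zero for `n < 12`.
#'
#' @param n integer `>= 1`.
#' @return `xint`.
#' @export
snowflake_pairs <- function(n) {
  n <- as.numeric(n)
  if (n < 1 || n != trunc(n)) stop("need an integer n >= 1")
  if (n < 12) return(xint(0))
  count_forests(n, 12) * snowflake_symmetry_factor()
}

#' Expected number of snowflake centres, exactly
#'
#' `snowflake_density(n)` is the exact rational `|S(n)|/B(n)`, which equals
#' `E(X_n)`, the expected number of snowflake central vertices of a uniform
#' binary tree on `n` leaves.  It also equals the closed form
#' `4 (2n-13)!/(2n-4)! (n-2)!/(n-12)!` (cross-checked exactly), and behaves
#' like `n / 128` for large n.  `snowflake_density_float(n)` evaluates the
#' closed form in floating point via log-Gamma, usable at n = 1e6 and beyond.
#'
#' @param n integer; the exact form needs `n >= 12` (below that the density
#'   is 0).
#' @return `xrat` (or double for the `_float` variant).
#' @export
snowflake_density <- function(n) {
  n <- as.numeric(n)
  if (n < 12) return(xrat(0, 1))
  ratio <- xrat(snowflake_pairs(n), count_unrooted_binary(n))
  closed <- xrat(xint(4) * xi_factorial(2 * n - 13) * xi_factorial(n - 2),
                 xi_factorial(2 * n - 4) * xi_factorial(n - 12))
  if (!(ratio == closed)) stop("internal error: |S(n)|/B(n) disagrees with the closed form")
  ratio
}

#' @rdname snowflake_density
#' @export
snowflake_density_float <- function(n) {
  4 * exp(lgamma(2 * n - 12) - lgamma(2 * n - 3) + lgamma(n - 1) - lgamma(n - 11))
}

#' Count (tree, centre, centre) triples with well-separated centres
#'
#' `W(n)` counts ordered triples `(T, v1, v2)` where both vertices are
#' snowflake centres of `T` at distance at least 5.  `W_by_summation`
#' evaluates the decomposition along the path between the two centres:
#' `W(n) = sum_{i=0}^{n-22} B(i+2) C(n,i) N(n-i, 22) 22!/2^16`.
#' `W_identity` evaluates the generating-function consequence
#' `W(n) = (22!/2^16) N(n+1, 23)`; the two agree exactly.
#'
#' @param n integer (`W(n) = 0` below 22).
#' @return `xint`.
#' @export
W_by_summation <- function(n) {
  n <- as.numeric(n)
  if (n < 22) return(xint(0))
  sym <- double_snowflake_symmetry_factor()
  acc <- xint(0)
  for (i in 0:(n - 22)) {
    acc <- acc + count_unrooted_binary(i + 2) * xi_binomial(n, i) *
      count_forests(n - i, 22) * sym
  }
  acc
}

#' @rdname W_by_summation
#' @export
W_identity <- function(n) {
  n <- as.numeric(n)
  if (n < 22) return(xint(0))
  double_snowflake_symmetry_factor() * count_forests(n + 1, 23)
}

#' Second-moment density W(n)/B(n), exactly and asymptotically
#'
#' The closed form `W(n)/B(n) = 16 (2n-22)!/(2n-4)! (n-2)!/(n-22)!`, an exact
#' rational that behaves like `n^2 / 2^14`.  Cross-checked against
#' `W_by_summation(n) / B(n)` exactly.
#'
#' @inheritParams W_by_summation
#' @return `xrat` (double for the `_float` variant).
#' @export
W_density_closed_form <- function(n) {
  n <- as.numeric(n)
  if (n < 22) return(xrat(0, 1))
  xrat(xint(16) * xi_factorial(2 * n - 22) * xi_factorial(n - 2),
       xi_factorial(2 * n - 4) * xi_factorial(n - 22))
}

#' @rdname W_density_closed_form
#' @export
W_density_float <- function(n) {
  16 * exp(lgamma(2 * n - 21) - lgamma(2 * n - 3) + lgamma(n - 1) - lgamma(n - 21))
}

#' Ordered/unordered counting identity for d-ary trees
#'
#' For `n = d i + 1`, the number of ordered d-ary trees on `n - 1` leaves
#' times `n!` equals the number of leaf-labelled unrooted d-ary trees on `n`
#' leaves times `n (d!)^((n-2)/(d-1))` (rooting at a leaf and ordering each
#' internal vertex).  For `d = 2` the two counts are the Catalan number
#' `C_{n-2}` and `(2n-5)!!`; for `d > 2` the ordered count comes from the
#' exhaustive generator and the unrooted count is solved from the identity
#' (and, for small `n`, cross-checked against exhaustive enumeration).
#'
#' @param d arity (`>= 2`).
#' @param n leaf count with `n = d i + 1` for some `i >= 1`.
#' @param cross_check for `d > 2`, also enumerate the unrooted trees
#'   exhaustively and compare (small `n` only).
#' @return list with `holds`, `lhs`, `rhs`, `n_ordered`, `n_unrooted` (`xint`).
#' @export
remark9_identity <- function(d, n, cross_check = FALSE) {
  d <- as.integer(d); n <- as.integer(n)
  if (d < 2L || n < d + 1L || (n - 1L) %% d != 0L)
    stop("need n = d*i + 1 for some i >= 1")
  ex <- (n - 2L) %/% (d - 1L)
  if (d == 2L) {
    n_ord <- xi_catalan(n - 2L)
    n_unr <- count_unrooted_binary(n)
  } else {
    n_ord <- xint(length(enumerate_all_ordered(n - 1L, d)))
    n_unr <- xi_divexact(n_ord * xi_factorial(n),
                         xint(n) * xi_pow(xi_factorial(d), ex))
    if (cross_check) {
      got <- length(enumerate_all_unrooted(n, d))
      if (!(xint(got) == n_unr)) stop("exhaustive unrooted count disagrees with the identity")
    }
  }
  lhs <- n_ord * xi_factorial(n)
  rhs <- n_unr * xint(n) * xi_pow(xi_factorial(d), ex)
  list(holds = lhs == rhs, lhs = lhs, rhs = rhs,
       n_ordered = n_ord, n_unrooted = n_unr)
}

#' Series coefficients of r(x) = 1 - sqrt(1 - 2x)
#'
#' The exponential generating function of rooted binary phylogenetic tree
#' counts: `[x^n] r(x) = R(n)/n!`.  Coefficients are computed from the
#' functional equation `r = x + r^2/2` by the exact convolution recurrence
#' `r_1 = 1`, `r_n = (1/2) sum_{i=1}^{n-1} r_i r_{n-i}` -- an oracle
#' independent of the factorial formula for `R(n)`.
#'
#' @param nmax highest order.
#' @return list of `xrat`, entry `i` being `[x^i] r(x)`.
#' @export
r_series_coeffs <- function(nmax) {
  r <- vector("list", nmax)
  r[[1L]] <- xrat(1, 1)
  if (nmax >= 2L) for (n in 2:nmax) {
    acc <- xrat(0, 1)
    for (i in 1:(n - 1L)) acc <- acc + r[[i]] * r[[n - i]]
    r[[n]] <- acc * xrat(1, 2)
  }
  r
}
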