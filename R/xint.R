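# Exact arbitrary-precision integers and rationals.
#
# Counting formulas for phylogenetic trees involve factorials far beyond the
# 2^53 exact range of doubles (B(200) has over 350 decimal digits), and the
# identities implemented in this package must be checked exactly, not in
# floating point.  Numbers are stored sign + magnitude, the magnitude being a
# little-endian vector of base-1e6 limbs held in doubles: limb products stay
# below 1e12 and all intermediate sums below 2^53, so every operation is exact.

.XI_BASE <- 1e6

xi_trim <- function(m) {
  n <- length(m)
  while (n > 0L && m[n] == 0) n <- n - 1L
  m[seq_len(n)]
}

# carry-normalise a limb vector that may hold values >= base (all >= 0)
xi_norm <- function(v) {
  repeat {
    carry <- v %/% .XI_BASE
    if (!any(carry > 0)) break
    v <- v - carry * .XI_BASE
    v <- c(v, 0) + c(0, carry)
  }
  xi_trim(v)
}

xi_mag_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la < lb) -1L else 1L)
  if (la == 0L) return(0L)
  for (i in la:1) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

xi_mag_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  xi_norm(a + b)
}

# a - b, requires a >= b
xi_mag_sub <- function(a, b) {
  b <- c(b, numeric(length(a) - length(b)))
  d <- a - b
  while (any(d < 0)) {
    i <- which(d < 0)
    d[i] <- d[i] + .XI_BASE
    d[i + 1L] <- d[i + 1L] - 1
  }
  xi_trim(d)
}

xi_mag_mul_small <- function(a, k) {
  if (k == 0 || length(a) == 0L) return(numeric(0))
  xi_norm(a * k)
}

xi_mag_mul <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(numeric(0))
  if (length(b) > length(a)) { tmp <- a; a <- b; b <- tmp }
  acc <- numeric(0)
  for (i in seq_along(b)) {
    if (b[i] == 0) next
    term <- c(numeric(i - 1L), a * b[i])
    acc <- xi_norm(c(acc, numeric(max(0L, length(term) - length(acc)))) +
                   c(term, numeric(max(0L, length(acc) - length(term)))))
  }
  acc
}

# short division by a single limb 0 < m < base; returns list(q, r)
xi_mag_divmod_small <- function(a, m) {
  la <- length(a)
  if (la == 0L) return(list(q = numeric(0), r = 0))
  q <- numeric(la); r <- 0
  for (i in la:1) {
    cur <- r * .XI_BASE + a[i]
    q[i] <- cur %/% m
    r <- cur %% m
  }
  list(q = xi_trim(q), r = if (r == 0) numeric(0) else r)
}

# leading three limbs as a double (value / base^(length - 3))
xi_mag_top3 <- function(a) {
  la <- length(a)
  v <- 0
  for (i in la:max(1L, la - 2L)) v <- v * .XI_BASE + a[i]
  if (la < 3L) v <- v * .XI_BASE^(3L - la)
  v
}

# schoolbook long division; returns list(q, r) with a = q*b + r, 0 <= r < b
xi_mag_divmod <- function(a, b) {
  lb <- length(b)
  if (lb == 0L) stop("division by zero")
  if (xi_mag_cmp(a, b) < 0) return(list(q = numeric(0), r = a))
  if (lb == 1L) return(xi_mag_divmod_small(a, b[1]))
  la <- length(a)
  q <- numeric(la)
  r <- numeric(0)
  for (i in la:1) {
    r <- xi_trim(c(a[i], r))   # r <- r*base + a[i]
    if (xi_mag_cmp(r, b) < 0) next
    # estimate the quotient limb from the leading limbs; r < base * b, so
    # the limb-length gap is at most 1 and the scale factor stays finite
    qi <- floor(xi_mag_top3(r) / xi_mag_top3(b) * .XI_BASE^(length(r) - length(b)))
    qi <- max(0, min(.XI_BASE - 1, qi))
    t <- xi_mag_mul_small(b, qi)
    while (xi_mag_cmp(t, r) > 0) { qi <- qi - 1; t <- xi_mag_sub(t, b) }
    repeat {
      t2 <- xi_mag_add(t, b)
      if (xi_mag_cmp(t2, r) > 0) break
      qi <- qi + 1; t <- t2
    }
    r <- xi_mag_sub(r, t)
    q[i] <- qi
  }
  list(q = xi_trim(q), r = r)
}

new_xint <- function(sign, mag) {
  mag <- xi_trim(mag)
  if (length(mag) == 0L) sign <- 0L
  structure(list(sign = as.integer(sign), mag = mag), class = "xint")
}

#' Exact arbitrary-precision integers
#'
#' `xint(x)` converts an R number (exact below 2^53) or a decimal string to an
#' exact integer.  Arithmetic (`+`, `-`, `*`, `^`, `%/%`, `%%`) and comparisons
#' work through the usual operators and are exact at any size; mixed
#' `xint`/numeric expressions promote the numeric operand.
#'
#' @param x integer-valued numeric scalar, decimal string, or an `xint`.
#' @return An object of class `xint`.
#' @examples
#' xint("123456789012345678901234567890") + xint(1)
#' xi_factorial(50)
#' @export
xint <- function(x) {
  if (inherits(x, "xint")) return(x)
  if (is.character(x)) {
    s <- trimws(x)
    sign <- 1L
    if (startsWith(s, "-")) { sign <- -1L; s <- substring(s, 2L) }
    if (!grepl("^[0-9]+$", s)) stop("not a decimal integer string: ", x)
    nd <- nchar(s)
    starts <- rev(seq(nd, 1L, by = -6L))
    mag <- as.numeric(vapply(starts, function(p) substr(s, max(1L, p - 5L), p), ""))
    mag <- rev(mag)
    return(new_xint(sign, mag))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x))
    stop("xint() needs a single integer-valued number or string")
  if (abs(x) > 2^53) stop("numeric input too large to be exact; pass a string")
  sign <- if (x > 0) 1L else if (x < 0) -1L else 0L
  x <- abs(x); mag <- numeric(0)
  while (x > 0) { mag <- c(mag, x %% .XI_BASE); x <- x %/% .XI_BASE }
  new_xint(sign, mag)
}

#' @export
is_xint <- function(x) inherits(x, "xint")

#' @export
as.character.xint <- function(x, ...) {
  if (x$sign == 0L) return("0")
  m <- rev(x$mag)
  body <- paste0(m[1], paste(sprintf("%06d", m[-1]), collapse = ""))
  paste0(if (x$sign < 0L) "-" else "", body)
}

#' @export
format.xint <- function(x, ...) as.character(x)

#' @export
print.xint <- function(x, ...) { cat(as.character(x), "\n"); invisible(x) }

#' @export
as.double.xint <- function(x, ...) {
  v <- 0
  for (i in rev(seq_along(x$mag))) v <- v * .XI_BASE + x$mag[i]
  v * x$sign
}

#' Natural log of the absolute value of an exact integer
#' @param x an `xint` (nonzero).
#' @return double.
#' @export
xi_log <- function(x) {
  x <- xint(x)
  if (x$sign == 0L) stop("log of zero")
  la <- length(x$mag)
  top <- 0
  lo <- max(1L, la - 2L)
  for (i in la:lo) top <- top * .XI_BASE + x$mag[i]
  log(top) + (lo - 1L) * log(.XI_BASE)
}

xi_add2 <- function(a, b) {
  if (a$sign == 0L) return(b)
  if (b$sign == 0L) return(a)
  if (a$sign == b$sign) return(new_xint(a$sign, xi_mag_add(a$mag, b$mag)))
  cmp <- xi_mag_cmp(a$mag, b$mag)
  if (cmp == 0L) return(new_xint(0L, numeric(0)))
  if (cmp > 0L) new_xint(a$sign, xi_mag_sub(a$mag, b$mag))
  else          new_xint(b$sign, xi_mag_sub(b$mag, a$mag))
}

xi_neg <- function(a) new_xint(-a$sign, a$mag)

xi_cmp <- function(a, b) {
  d <- xi_add2(a, xi_neg(b))
  d$sign
}

#' @export
Ops.xint <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(xi_neg(e1))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for xint")
  }
  if (.Generic == "^") {
    return(xi_pow(e1, e2))
  }
  a <- xint(e1); b <- xint(e2)
  switch(.Generic,
    "+" = xi_add2(a, b),
    "-" = xi_add2(a, xi_neg(b)),
    "*" = new_xint(a$sign * b$sign, xi_mag_mul(a$mag, b$mag)),
    "%/%" = xi_divq(a, b),
    "%%" = xi_divr(a, b),
    "==" = xi_cmp(a, b) == 0L,
    "!=" = xi_cmp(a, b) != 0L,
    "<"  = xi_cmp(a, b) < 0L,
    ">"  = xi_cmp(a, b) > 0L,
    "<=" = xi_cmp(a, b) <= 0L,
    ">=" = xi_cmp(a, b) >= 0L,
    stop(.Generic, " not defined for xint")
  )
}

xi_divq <- function(a, b) {
  if (a$sign < 0L || b$sign < 0L) stop("division implemented for non-negative xint")
  new_xint(1L, xi_mag_divmod(a$mag, b$mag)$q)
}

xi_divr <- function(a, b) {
  if (a$sign < 0L || b$sign < 0L) stop("division implemented for non-negative xint")
  new_xint(1L, xi_mag_divmod(a$mag, b$mag)$r)
}

#' Exact division, failing loudly on a nonzero remainder
#'
#' Used by every counting formula of the package: the formulas are integers by
#' construction, so a remainder indicates a programming error, never a rounding
#' issue.
#' @param a,b non-negative `xint` (or coercible); `b != 0`.
#' @return `xint` quotient with `a = q * b` exactly.
#' @export
xi_divexact <- function(a, b) {
  a <- xint(a); b <- xint(b)
  dm <- xi_mag_divmod(a$mag, b$mag)
  if (length(dm$r) != 0L) stop("xi_divexact: division is not exact")
  new_xint(a$sign * b$sign, dm$q)
}

#' @export
xi_pow <- function(a, e) {
  a <- xint(a)
  e <- as.numeric(e)
  if (e < 0 || e != trunc(e)) stop("exponent must be a non-negative integer")
  r <- xint(1)
  while (e > 0) {
    if (e %% 2 == 1) r <- r * a
    a <- a * a
    e <- e %/% 2
  }
  r
}

#' Exact factorial, double factorial, binomial and Catalan numbers
#'
#' `xi_factorial(n)` is `n!`; `xi_double_factorial(n)` is `n!!` with the
#' conventions `(-1)!! = 0!! = 1`; `xi_binomial(n, k)` is `choose(n, k)`;
#' `xi_catalan(k)` is the k-th Catalan number `choose(2k, k)/(k+1)`.
#' All are exact at any size.
#' @param n,k non-negative integers (`n = -1` allowed for the double factorial).
#' @return `xint`.
#' @export
xi_factorial <- function(n) {
  n <- as.numeric(n)
  if (n < 0 || n != trunc(n)) stop("factorial needs n >= 0")
  r <- xint(1)
  if (n >= 2) for (i in 2:n) r <- new_xint(1L, xi_mag_mul_small(r$mag, i))
  r
}

#' @rdname xi_factorial
#' @export
xi_double_factorial <- function(n) {
  n <- as.numeric(n)
  if (n < -1 || n != trunc(n)) stop("double factorial needs n >= -1")
  r <- xint(1)
  while (n >= 2) { r <- new_xint(1L, xi_mag_mul_small(r$mag, n)); n <- n - 2 }
  r
}

#' @rdname xi_factorial
#' @export
xi_binomial <- function(n, k) {
  n <- as.numeric(n); k <- as.numeric(k)
  if (k < 0 || k > n) return(xint(0))
  xi_divexact(xi_factorial(n), xi_factorial(k) * xi_factorial(n - k))
}

#' @rdname xi_factorial
#' @export
xi_catalan <- function(k) xi_divexact(xi_binomial(2 * k, k), xint(k + 1))

#' Greatest common divisor of two exact integers
#' @param a,b `xint` (or coercible).
#' @return non-negative `xint`.
#' @export
xi_gcd <- function(a, b) {
  a <- new_xint(1L, xint(a)$mag); b <- new_xint(1L, xint(b)$mag)
  while (b$sign != 0L) {
    r <- xi_divr(a, b)
    a <- b; b <- r
  }
  a
}

# ---------------------------------------------------------------------------
# Exact rationals

#' Exact rationals in lowest terms
#'
#' `xrat(num, den)` stores an exact fraction, reduced, with a positive
#' denominator; the sign lives on the numerator.  Arithmetic and comparisons
#' go through the usual operators.
#'
#' @param num,den `xint` or anything `xint()` accepts; `den != 0`.
#' @return An object of class `xrat` with fields `num` and `den`.
#' @examples
#' xrat(155925, "654729075")
#' @export
xrat <- function(num, den = 1) {
  if (inherits(num, "xrat") && missing(den)) return(num)
  num <- xint(num); den <- xint(den)
  if (den$sign == 0L) stop("zero denominator")
  if (den$sign < 0L) { num <- xi_neg(num); den <- xi_neg(den) }
  if (num$sign == 0L) return(structure(list(num = xint(0), den = xint(1)), class = "xrat"))
  g <- xi_gcd(num, den)
  structure(list(num = new_xint(num$sign, xi_divq(new_xint(1L, num$mag), g)$mag),
                 den = xi_divq(den, g)),
            class = "xrat")
}

#' @export
is_xrat <- function(x) inherits(x, "xrat")

as_xrat <- function(x) {
  if (inherits(x, "xrat")) return(x)
  xrat(xint(x), xint(1))
}

#' @export
as.character.xrat <- function(x, ...) paste0(as.character(x$num), "/", as.character(x$den))

#' @export
format.xrat <- function(x, ...) as.character(x)

#' @export
print.xrat <- function(x, ...) { cat(as.character(x), "\n"); invisible(x) }

#' @export
as.double.xrat <- function(x, ...) {
  if (x$num$sign == 0L) return(0)
  x$num$sign * exp(xi_log(x$num) - xi_log(x$den))
}

#' @export
Ops.xrat <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") { e1$num <- xi_neg(e1$num); return(e1) }
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for xrat")
  }
  a <- as_xrat(e1); b <- as_xrat(e2)
  switch(.Generic,
    "+" = xrat(a$num * b$den + b$num * a$den, a$den * b$den),
    "-" = xrat(a$num * b$den - b$num * a$den, a$den * b$den),
    "*" = xrat(a$num * b$num, a$den * b$den),
    "/" = xrat(a$num * b$den, a$den * b$num),
    "==" = (a$num == b$num) && (a$den == b$den),
    "!=" = !((a$num == b$num) && (a$den == b$den)),
    "<"  = xi_cmp(a$num * b$den, b$num * a$den) < 0L,
    ">"  = xi_cmp(a$num * b$den, b$num * a$den) > 0L,
    "<=" = xi_cmp(a$num * b$den, b$num * a$den) <= 0L,
    ">=" = xi_cmp(a$num * b$den, b$num * a$den) >= 0L,
    stop(.Generic, " not defined for xrat")
  )
}
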