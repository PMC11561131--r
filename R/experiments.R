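# Seeded Monte-Carlo experiments tying the samplers to the exact enumeration:
# moment checks for the snowflake-centre count X_n, occurrence (0-1 law)
# curves, local-limit diagnostics, and the Yule-Harding root-split test.
# Every driver takes an explicit seed and is reproducible bit for bit.

new_mc_estimate <- function(x, seed) {
  structure(list(estimate = mean(x), se = stats::sd(x) / sqrt(length(x)),
                 reps = length(x), seed = seed),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("MC estimate %.6g (SE %.3g, %d replicates, seed %d)\n",
              x$estimate, x$se, x$reps, x$seed))
  invisible(x)
}

# internal: edge list + vertex count of a uniform unrooted binary tree shape.
# Labels are a uniform permutation independent of the shape, and the
# snowflake-centre count ignores them, so the Monte-Carlo drivers work on the
# shape alone.
sample_uniform_shape_edges <- function(n) {
  if (n == 2L) return(list(edges = matrix(c(1L, 2L), 1L), V = 2L))
  deg <- sample_dary_degseq(n - 1L, 2L)
  V <- length(deg)
  par <- rotree_parent(structure(list(deg = deg), class = "rotree"))
  edges <- cbind(c(par[-1L], 1L), c(seq_len(V)[-1L], V + 1L))
  list(edges = edges, V = V + 1L)
}

# internal: edge list of a Yule-Harding shape (root suppressed)
sample_yule_shape_edges <- function(n) {
  g <- yule_grow(n)
  nv <- g$nv
  keepv <- 2:nv
  edges <- cbind(g$parent[keepv] - 1L, keepv - 1L)
  edges <- edges[edges[, 1L] != 0L, , drop = FALSE]
  edges <- rbind(edges, c(g$childA[1L] - 1L, g$childB[1L] - 1L))
  list(edges = edges, V = nv - 1L)
}

#' Monte-Carlo mean of the snowflake-centre count
#'
#' Estimates `E(X_n)`, the mean number of snowflake central vertices of a
#' uniform binary tree on `n` leaves; the exact value is
#' [snowflake_density()]`(n)`.
#'
#' @param n leaf count.
#' @param reps replicates (`>= 2`).
#' @param seed integer seed.
#' @return an `mc_estimate`.
#' @export
mc_mean_snowflake_centers <- function(n, reps, seed) {
  set.seed(seed)
  x <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- sample_uniform_shape_edges(n)
    x[r] <- count_centers_edges(s$edges, s$V)
  }
  new_mc_estimate(x, seed)
}

#' @rdname mc_mean_snowflake_centers
#' @description `mc_second_moment_snowflake_centers` estimates `E(X_n^2)`,
#'   whose dominant part is the exact [W_density_closed_form()]`(n)` (pairs
#'   of centres at distance >= 5); near pairs add only O(n)/B-type terms.
#' @export
mc_second_moment_snowflake_centers <- function(n, reps, seed) {
  set.seed(seed)
  x <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- sample_uniform_shape_edges(n)
    x[r] <- count_centers_edges(s$edges, s$V)^2
  }
  new_mc_estimate(x, seed)
}

#' Monte-Carlo probability that a tree has no snowflake
#'
#' Estimates `P(X_n = 0)` over uniform binary trees on `n` leaves.  The
#' limit is 0 (the 0-1 law); for all n the limit superior is bounded by
#' `1 - 2^-7` via `E(X_n)/n`.
#'
#' @inheritParams mc_mean_snowflake_centers
#' @return an `mc_estimate`.
#' @export
mc_zero_probability <- function(n, reps, seed) {
  set.seed(seed)
  x <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- sample_uniform_shape_edges(n)
    x[r] <- as.numeric(count_centers_edges(s$edges, s$V) == 0L)
  }
  new_mc_estimate(x, seed)
}

#' Occurrence-probability curve for a pattern
#'
#' Estimates `P(T_n contains tau)` on a grid of leaf counts, for uniform
#' binary trees (`model = "uniform"`) or Yule-Harding trees
#' (`model = "yule"`).  When `tau` is the snowflake the distance-to-leaf
#' criterion is used (fast); otherwise the embedding engine runs on each
#' sampled tree.  Realizability of the pattern under the binary offspring
#' law is recorded in the result: a non-realizable pattern never occurs, at
#' any n, and the curve is identically zero.
#'
#' @param model `"uniform"` or `"yule"`.
#' @param tau a `ptree`.
#' @param n_grid strictly increasing leaf counts.
#' @param reps replicates per grid point.
#' @param seed master seed; each grid point uses a derived child seed.
#' @return a data frame of class `curve_result` with columns `n`, `estimate`,
#'   `se`, `reps`, `seed`; attributes `model`, `pattern_code`, `realizable`.
#' @export
mc_pattern_curve <- function(model = c("uniform", "yule"), tau, n_grid, reps, seed) {
  model <- match.arg(model)
  stopifnot(is_ptree(tau), all(diff(n_grid) > 0))
  real <- is_realizable(tau, offspring_dary(2L))
  is_snow <- identical(pattern_code(tau), pattern_code(snowflake_pattern()))
  rows <- lapply(seq_along(n_grid), function(i) {
    n <- n_grid[i]
    s <- child_seed(seed, i)
    set.seed(s)
    x <- numeric(reps)
    for (r in seq_len(reps)) {
      if (is_snow) {
        sh <- if (model == "uniform") sample_uniform_shape_edges(n)
              else sample_yule_shape_edges(n)
        x[r] <- as.numeric(count_centers_edges(sh$edges, sh$V) > 0L)
      } else {
        T <- if (model == "uniform") sample_uniform_leaf_labelled(n)
             else sample_yule_harding(n)
        x[r] <- as.numeric(occurs(T, tau))
      }
    }
    data.frame(n = n, estimate = mean(x), se = stats::sd(x) / sqrt(reps),
               reps = reps, seed = s)
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  attr(out, "pattern_code") <- pattern_code(tau)
  attr(out, "realizable") <- real
  class(out) <- c("curve_result", class(out))
  out
}

# role-aware canonical code of a pattern (AHU over the centroid rootings)
pattern_code <- function(tau) {
  adj <- tau$adj
  V <- length(adj)
  rec <- function(v, from) {
    sub <- sort(vapply(setdiff(adj[[v]], from), function(u) rec(u, v), ""), method = "radix")
    paste0(if (tau$role[v] == "free") "f" else "i",
           "(", paste(sub, collapse = ","), ")")
  }
  # root at every vertex and take the lexicographic minimum: size is small
  min(vapply(seq_len(V), function(v) rec(v, 0L), ""))
}

#' Total-variation distance between conditioned-GW and Kesten balls
#'
#' Draws `reps` size-conditioned `GW(X)` trees with `n_vertices` vertices and
#' `reps` truncated Kesten trees, reduces both to their radius-`radius` root
#' balls, and returns the empirical total-variation distance between the two
#' ball laws (frequencies of the ordered ball codes, on the union of their
#' supports).  The local-limit theorem says this tends to 0 as `n_vertices`
#' grows, for fixed radius.
#'
#' @param X a critical `offspring` with `P(X = 0) > 0`.
#' @param n_vertices size of the conditioned trees.
#' @param radius ball radius (small: the ball space must stay modest).
#' @param reps replicates per law.
#' @param seed integer seed.
#' @return double in `[0, 1]`.
#' @export
ball_tv_distance <- function(X, n_vertices, radius, reps, seed) {
  stopifnot(radius >= 0)
  if (radius == 0) return(0)
  set.seed(seed)
  two_point <- identical(sort(X$support), c(0L, max(X$support))) && max(X$support) > 0L
  codes_gw <- character(reps)
  for (r in seq_len(reps)) {
    if (two_point) {
      d <- max(X$support)
      i <- (n_vertices - 1L) %/% d
      deg <- integer(n_vertices)
      deg[sample.int(n_vertices, i)] <- d
      deg <- cycle_lemma_rotate(deg)
      codes_gw[r] <- paste(ball_deg_prefix(deg, radius), collapse = ",")
    } else {
      t <- sample_conditioned_gw(X, n_vertices)
      codes_gw[r] <- paste(ball(t, radius)$deg, collapse = ",")
    }
  }
  codes_k <- character(reps)
  for (r in seq_len(reps)) {
    kb <- sample_kesten_ball(X, radius)
    codes_k[r] <- paste(kb$tree$deg, collapse = ",")
  }
  lev <- union(unique(codes_gw), unique(codes_k))
  p <- tabulate(match(codes_gw, lev), length(lev)) / reps
  q <- tabulate(match(codes_k, lev), length(lev)) / reps
  0.5 * sum(abs(p - q))
}

# ball of radius k from a preorder degree sequence, without building the
# full tree: subtree ends are located on the Lukasiewicz walk
ball_deg_prefix <- function(deg, k) {
  n <- length(deg)
  s <- cumsum(deg - 1L)
  sub_end <- function(i) {
    if (deg[i] == 0L) return(i)
    target <- if (i == 1L) -1L else s[i - 1L] - 1L
    i - 1L + which(s[i:n] == target)[1L]
  }
  out <- integer(0)
  rec <- function(i, b) {
    x <- if (b == 0L) 0L else deg[i]
    out[length(out) + 1L] <<- x
    if (x > 0L) {
      c1 <- i + 1L
      for (ch in seq_len(x)) {
        rec(c1, b - 1L)
        c1 <- sub_end(c1) + 1L
      }
    }
  }
  rec(1L, k)
  out
}

#' Chi-square test of Yule-Harding root-split uniformity
#'
#' For the rooted Yule-Harding tree, the leaf count `n1` of the first root
#' subtree is uniform on `{1, ..., n-1}`.  Samples `reps` trees and tests the
#' observed `n1` counts against uniformity.
#'
#' @param n leaf count (`n >= 3`).
#' @param reps replicates.
#' @param seed integer seed.
#' @return list with `statistic`, `p.value`, `counts`.
#' @export
yule_split_test <- function(n, reps, seed) {
  n <- as.integer(n)
  if (n < 3L) stop("the root split is degenerate below n = 3")
  set.seed(seed)
  n1 <- integer(reps)
  for (r in seq_len(reps)) n1[r] <- yule_root_split(n)
  counts <- tabulate(n1, n - 1L)
  ct <- stats::chisq.test(counts)
  list(statistic = unname(ct$statistic), p.value = ct$p.value, counts = counts)
}
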