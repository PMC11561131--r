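# Random tree generators.
#
# All samplers draw from R's global RNG: call set.seed() (or use the seed
# arguments of the experiment drivers, which derive one child seed per
# replicate) for reproducibility.

# ---------------------------------------------------------------------------
# offspring distributions

#' Finite-support offspring distributions
#'
#' Probabilities are stored as exact fractions `num[i]/den`, so the mean, the
#' second moment and the criticality test (mean exactly 1) are exact.
#'
#' @param support non-negative integers (distinct).
#' @param num positive integer weights.
#' @param den common denominator, `sum(num) == den`.
#' @return An object of class `offspring`, with fields `support`, `num`,
#'   `den`, `prob` (doubles), and exact accessors via [offspring_mean()].
#' @examples
#' offspring_dary(2)          # 2 * Bernoulli(1/2): the binary offspring law
#' @export
offspring <- function(support, num, den) {
  support <- as.integer(support); num <- as.numeric(num); den <- as.numeric(den)
  if (any(support < 0L) || anyDuplicated(support)) stop("support must be distinct non-negative integers")
  if (any(num <= 0) || sum(num) != den) stop("weights must be positive and sum to the denominator")
  structure(list(support = support, num = num, den = den, prob = num / den),
            class = "offspring")
}

#' @rdname offspring
#' @param d arity.
#' @export
offspring_dary <- function(d) offspring(c(0L, as.integer(d)), c(d - 1, 1), d)

#' @export
print.offspring <- function(x, ...) {
  cat("offspring law: P(X = k) for k in {", paste(x$support, collapse = ", "),
      "} = {", paste(x$num, "/", x$den, sep = "", collapse = ", "), "}",
      if (offspring_is_critical(x)) " (critical)" else "", "\n", sep = "")
  invisible(x)
}

#' Exact moments of an offspring law
#' @param X an `offspring`.
#' @return `xrat` for the mean and second moment; logical for criticality.
#' @export
offspring_mean <- function(X) xrat(sum(X$support * X$num), X$den)

#' @rdname offspring_mean
#' @export
offspring_second_moment <- function(X) xrat(sum(X$support^2 * X$num), X$den)

#' @rdname offspring_mean
#' @export
offspring_is_critical <- function(X) sum(X$support * X$num) == X$den

#' Size-biased version of an offspring law
#'
#' `P(X* = k) = k P(X = k) / E(X)`, computed with exact weights.  The value 0
#' leaves the support, so `X* >= 1` whenever `P(X = 0) < 1`.
#'
#' @param X an `offspring` with positive mean.
#' @return an `offspring`.
#' @export
size_biased <- function(X) {
  m <- sum(X$support * X$num)
  if (m == 0) stop("size-biasing needs a positive mean")
  keep <- X$support > 0L
  offspring(X$support[keep], X$support[keep] * X$num[keep], m)
}

draw_offspring <- function(X, n) {
  if (length(X$support) == 1L) return(rep(X$support, n))
  X$support[sample.int(length(X$support), n, replace = TRUE, prob = X$prob)]
}

# ---------------------------------------------------------------------------
# Galton-Watson trees

#' Sample an unconditioned Galton-Watson tree
#'
#' Generates the preorder out-degree sequence vertex by vertex.  A critical
#' tree is finite almost surely but has heavy tails, so generation aborts once
#' `max_vertices` is exceeded, returning an object of class `gw_truncated`
#' (distinct from a successful draw).
#'
#' @param X an `offspring`.
#' @param max_vertices abort threshold.
#' @return a `rotree`, or a `gw_truncated` object.
#' @export
sample_gw <- function(X, max_vertices = 1e5) {
  deg <- integer(256L); nv <- 0L; open <- 1L
  buf <- draw_offspring(X, 64L); bi <- 0L
  while (open > 0L) {
    nv <- nv + 1L
    if (nv > max_vertices)
      return(structure(list(max_vertices = max_vertices), class = "gw_truncated"))
    if (nv > length(deg)) deg <- c(deg, integer(length(deg)))
    bi <- bi + 1L
    if (bi > length(buf)) { buf <- draw_offspring(X, 2L * length(buf)); bi <- 1L }
    x <- buf[bi]
    deg[nv] <- x
    open <- open + x - 1L
  }
  rotree(deg[seq_len(nv)])
}

#' @export
is_gw_truncated <- function(x) inherits(x, "gw_truncated")

# cycle-lemma rotation: given degrees summing to n-1, the unique cyclic shift
# that is a valid preorder sequence starts right after the first minimum of
# the walk cumsum(deg - 1)
cycle_lemma_rotate <- function(deg) {
  s <- cumsum(deg - 1L)
  j <- which.min(s)
  if (j == length(deg)) return(deg)
  c(deg[(j + 1L):length(deg)], deg[seq_len(j)])
}

#' Sample a size-conditioned Galton-Watson tree, exactly
#'
#' Draws a tree with the law of `GW(X)` conditioned on having `n_vertices`
#' vertices.  An exchangeable out-degree sequence with the right sum is drawn
#' and rotated into a valid preorder sequence (cycle lemma), which is exact
#' and linear-time.  For the d-ary law `X = d Bernoulli(1/d)` the conditioned
#' tree is uniform over ordered d-ary trees with `n_vertices` vertices, and
#' the multiset of degrees is deterministic (a fast path); for a general law
#' the iid sequence is drawn by rejection on its sum.
#'
#' @param X an `offspring`.
#' @param n_vertices target vertex count (must be attainable: for the d-ary
#'   law, `n_vertices` must be 1 mod d).
#' @param max_tries rejection guard for non-two-point laws.
#' @return a `rotree`.
#' @export
sample_conditioned_gw <- function(X, n_vertices, max_tries = 1e6) {
  n <- as.integer(n_vertices)
  if (n < 1L) stop("need n_vertices >= 1")
  if (n == 1L) {
    if (!0L %in% X$support) stop("P(X = 0) = 0: no finite tree")
    return(rotree(0L))
  }
  two_point <- identical(sort(X$support), c(0L, max(X$support))) && max(X$support) > 0L
  if (two_point) {
    d <- max(X$support)
    if ((n - 1L) %% d != 0L)
      stop("impossible size: for this law n_vertices must be congruent to 1 mod ", d)
    i <- (n - 1L) %/% d
    deg <- integer(n)
    deg[sample.int(n, i)] <- d
    return(rotree(cycle_lemma_rotate(deg)))
  }
  for (try in seq_len(max_tries)) {
    deg <- draw_offspring(X, n)
    if (sum(deg) == n - 1L) return(rotree(cycle_lemma_rotate(deg)))
  }
  stop("no degree sequence with the required sum found in ", max_tries,
       " tries; is the size attainable for this offspring law?")
}

# internal: degree sequence of a uniform ordered d-ary tree with m leaves
sample_dary_degseq <- function(m, d) {
  if (m == 1L) return(0L)
  k <- (m - 1L) %/% (d - 1L)       # internal vertices
  n <- k + m
  deg <- integer(n)
  deg[sample.int(n, k)] <- d
  cycle_lemma_rotate(deg)
}

#' Sample a uniform unrooted leaf-labelled d-ary tree
#'
#' Pipeline: a uniform ordered d-ary tree with `n - 1` leaves (size-conditioned
#' Galton-Watson draw), a leaf grafted at its root, a uniform label
#' permutation, ordering and rooting discarded.  For `d = 2` the result is
#' uniform over the `(2n-5)!!` binary phylogenetic trees on `n` leaves.
#'
#' @param n number of leaves (`n >= 2`; for `n > 2`, `(n - 2)` must be
#'   divisible by `(d - 1)`).
#' @param d arity.
#' @return an `lltree`.
#' @export
sample_uniform_leaf_labelled <- function(n, d = 2L) {
  n <- as.integer(n); d <- as.integer(d)
  if (n < 2L) stop("need n >= 2")
  if (n == 2L) return(lltree_from_edges(matrix(c(1L, 2L), 1L), 1:2, d))
  if ((n - 2L) %% (d - 1L) != 0L)
    stop("no d-ary tree with this leaf count: (n - 2) must be divisible by (d - 1)")
  deg <- sample_dary_degseq(n - 1L, d)
  graft_root_leaf_and_label(rotree(deg), sample.int(n), d)
}

# ---------------------------------------------------------------------------
# Yule-Harding

# internal: grow the rooted Yule-Harding tree; returns parent/child arrays
yule_grow <- function(n) {
  maxv <- 2L * n
  childA <- integer(maxv); childB <- integer(maxv); parent <- integer(maxv)
  side <- integer(maxv)            # which root subtree a leaf belongs to
  childA[1L] <- 2L; childB[1L] <- 3L
  parent[2L] <- 1L; parent[3L] <- 1L
  side[2L] <- 1L; side[3L] <- 2L
  leaves <- integer(n); leaves[1:2] <- c(2L, 3L)
  nl <- 2L; nv <- 3L
  label <- integer(maxv); label[2L] <- 1L; label[3L] <- 2L
  while (nl < n) {
    x <- leaves[sample.int(nl, 1L)]       # pendant edge above leaf x
    w <- nv + 1L; u <- nv + 2L; nv <- nv + 2L
    p <- parent[x]
    if (childA[p] == x) childA[p] <- w else childB[p] <- w
    parent[w] <- p; childA[w] <- x; childB[w] <- u
    parent[x] <- w; parent[u] <- w
    side[u] <- side[x]; side[w] <- side[x]
    nl <- nl + 1L
    leaves[nl] <- u
    label[u] <- nl
  }
  list(childA = childA[1:nv], childB = childB[1:nv], parent = parent[1:nv],
       side = side[1:nv], label = label[1:nv], nv = nv, leaves = leaves)
}

#' Sample a Yule-Harding tree
#'
#' Iterative construction: start with the two-leaf tree, then repeatedly pick
#' a pendant edge uniformly at random and attach the next leaf to its
#' subdivision point.  This is the shape distribution induced by constant-rate
#' birth-death models.  With `keep_root = TRUE` the rooted tree is returned
#' (as a `rotree`); otherwise the root is suppressed and the unrooted
#' leaf-labelled tree is returned, leaves labelled in order of attachment.
#'
#' @param n number of leaves (`n >= 2`).
#' @param keep_root return the rooted ordered tree.
#' @return an `lltree`, or a `rotree` when `keep_root = TRUE`.
#' @details Leaf labels are a uniform random permutation, independent of the
#'   shape: the Yule-Harding labelled distribution is exchangeable, which the
#'   raw attachment order is not.
#' @export
sample_yule_harding <- function(n, keep_root = FALSE) {
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2")
  g <- yule_grow(n)
  g$label[g$label > 0L] <- sample.int(n)[g$label[g$label > 0L]]
  if (keep_root) {
    deg <- integer(g$nv); i <- 0L
    st <- integer(g$nv); top <- 1L; st[1L] <- 1L
    while (top > 0L) {
      v <- st[top]; top <- top - 1L
      i <- i + 1L
      if (g$childA[v] > 0L) {
        deg[i] <- 2L
        st[top + 1L] <- g$childB[v]; st[top + 2L] <- g$childA[v]; top <- top + 2L
      }
    }
    return(rotree(deg))
  }
  # suppress the root: edge between its two children
  nv <- g$nv
  keepv <- 2:nv
  newid <- integer(nv); newid[keepv] <- seq_along(keepv)
  edges <- cbind(newid[g$parent[keepv]], newid[keepv])
  edges <- edges[edges[, 1L] != 0L, , drop = FALSE]
  edges <- rbind(edges, c(newid[g$childA[1L]], newid[g$childB[1L]]))
  leaf <- rep(NA_integer_, nv - 1L)
  leaf[newid[keepv]] <- ifelse(g$label[keepv] > 0L, g$label[keepv], NA_integer_)
  lltree_from_edges(edges, leaf, 2L)
}

# internal: leaf count of the first root subtree of a rooted Yule-Harding draw
yule_root_split <- function(n) {
  g <- yule_grow(n)
  sum(g$side[g$leaves[seq_len(n)]] == 1L)
}

# ---------------------------------------------------------------------------
# Kesten's size-biased tree, truncated to a ball

# GW(X) tree truncated at depth `budget`: preorder degrees (vertices at the
# truncation depth appear with out-degree 0)
gw_depth_truncated_deg <- function(X, budget) {
  if (budget == 0L) return(0L)
  x <- draw_offspring(X, 1L)
  if (x == 0L) return(0L)
  out <- x
  for (i in seq_len(x)) out <- c(out, gw_depth_truncated_deg(X, budget - 1L))
  out
}

#' Sample a truncated Kesten tree (the local limit of conditioned GW trees)
#'
#' Builds `[T*]_k`: a spine of vertices at depths `0..k`; spine vertex at
#' depth `j < k` gets `X*_j` children of which one, at a uniformly random
#' position, continues the spine, and the remaining `X*_j - 1` are roots of
#' independent `GW(X)` trees truncated at depth `k - j - 1`.  `X*` is the
#' size-biased version of `X`.  The ball is exact in distribution.
#'
#' @param X a critical `offspring` with `P(X = 0) > 0`.
#' @param radius ball radius `k >= 0`.
#' @return An object of class `kesten_ball`: a list with `tree` (`rotree`),
#'   `spine` (preorder indices of the spine vertices, root first), `radius`,
#'   `spine_out` (the draws of `X*` along the spine) and `S` (the running
#'   off-spine edge counts `S_i = sum_{j<=i} (X*_j - 1)`).
#' @export
sample_kesten_ball <- function(X, radius) {
  k <- as.integer(radius)
  if (k < 0L) stop("need radius >= 0")
  if (!offspring_is_critical(X)) stop("offspring law must be critical (mean exactly 1)")
  if (!0L %in% X$support) stop("need P(X = 0) > 0")
  Xs <- size_biased(X)
  spine_out <- if (k > 0L) draw_offspring(Xs, k) else integer(0)
  deg <- integer(0)
  spine_pos <- integer(k + 1L)
  build <- function(j) {   # spine vertex at depth j
    spine_pos[j + 1L] <<- length(deg) + 1L
    if (j == k) { deg <<- c(deg, 0L); return(invisible(NULL)) }
    x <- spine_out[j + 1L]
    deg <<- c(deg, x)
    pos <- sample.int(x, 1L)
    for (s in seq_len(x)) {
      if (s == pos) build(j + 1L)
      else deg <<- c(deg, gw_depth_truncated_deg(X, k - j - 1L))
    }
  }
  build(0L)
  structure(list(tree = rotree(deg), spine = spine_pos, radius = k,
                 spine_out = spine_out,
                 S = if (k > 0L) cumsum(spine_out - 1L) else integer(0)),
            class = "kesten_ball")
}

#' @export
print.kesten_ball <- function(x, ...) {
  cat("Kesten ball of radius", x$radius, "with", length(x$tree$deg),
      "vertices; off-spine edge counts S =", paste(x$S, collapse = " "), "\n")
  invisible(x)
}

#' Derive a child seed for a replicate stream
#'
#' Deterministic map from (master seed, replicate index) to a child seed in
#' `[1, 2^31 - 2]`, so replicate streams are reproducible individually.
#' @param master,i integers.
#' @return integer.
#' @export
child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 16807) %% 2147483646) + 1L
}
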