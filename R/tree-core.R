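# Core tree structures.
#
# Two views of a tree are used throughout:
#   * `rotree`  -- rooted ordered (plane) tree, stored as its preorder
#     out-degree sequence (a Lukasiewicz word).  This is the natural house for
#     Galton-Watson realisations, balls around the root, and Ulam-Harris
#     addresses.
#   * `lltree`  -- unrooted leaf-labelled d-ary tree (every vertex has degree 1
#     or d+1), stored as an adjacency list plus the leaf labelling.  This is
#     the phylogenetic object: leaves carry labels 1..n, interior vertices are
#     anonymous.
# Newick reading/writing goes through ape.

# ---------------------------------------------------------------------------
# rooted ordered trees

#' Rooted ordered trees from a preorder out-degree sequence
#'
#' An ordered (plane) rooted tree is stored as the sequence of vertex
#' out-degrees in depth-first preorder.  A vector `deg` encodes a single tree
#' exactly when the walk `cumsum(deg - 1)` first reaches -1 at the last
#' position.
#'
#' @param deg integer vector of out-degrees in preorder.
#' @return An object of class `rotree`.
#' @examples
#' rotree(c(2, 0, 0))        # root with two leaf children ("cherry")
#' @export
rotree <- function(deg) {
  deg <- as.integer(deg)
  if (length(deg) == 0L) stop("empty degree sequence")
  if (any(deg < 0L)) stop("negative out-degree")
  s <- cumsum(deg - 1L)
  if (s[length(s)] != -1L || any(s[-length(s)] < 0L))
    stop("degree sequence does not encode a single ordered tree")
  structure(list(deg = deg), class = "rotree")
}

#' @export
is_rotree <- function(x) inherits(x, "rotree")

#' @export
print.rotree <- function(x, ...) {
  cat("rooted ordered tree:", length(x$deg), "vertices,",
      sum(x$deg == 0L), "leaves, height", rotree_height(x), "\n")
  invisible(x)
}

# parent vector (root's parent = 0), preorder indices
rotree_parent <- function(t) {
  deg <- t$deg; n <- length(deg)
  par <- integer(n)
  st <- integer(n); rem <- integer(n); top <- 0L
  for (v in seq_len(n)) {
    if (top > 0L) {
      p <- st[top]
      par[v] <- p
      rem[top] <- rem[top] - 1L
      if (rem[top] == 0L) top <- top - 1L
    }
    if (deg[v] > 0L) {
      top <- top + 1L
      st[top] <- v
      rem[top] <- deg[v]
    }
  }
  par
}

# ordered children lists
rotree_kids <- function(t) {
  par <- rotree_parent(t)
  n <- length(par)
  kids <- vector("list", n)
  for (v in seq_len(n)) kids[[v]] <- integer(0)
  for (v in seq_len(n)[-1]) kids[[par[v]]] <- c(kids[[par[v]]], v)
  kids
}

rotree_depth <- function(t) {
  par <- rotree_parent(t)
  depth <- integer(length(par))
  for (v in seq_along(par)[-1]) depth[v] <- depth[par[v]] + 1L
  depth
}

#' @export
rotree_height <- function(t) max(rotree_depth(t))

#' Ulam-Harris addresses of a rooted ordered tree
#'
#' The root is the empty word `""`; the k-th child of a vertex with address
#' `w` has address `paste0(w, ".", k)` (a dot separates letters so that
#' multi-digit child indices stay unambiguous).
#'
#' @param t a `rotree`.
#' @return character vector of addresses in preorder.
#' @export
ulam_harris <- function(t) {
  par <- rotree_parent(t)
  n <- length(par)
  addr <- character(n)
  child_idx <- integer(n)   # running count of children seen per vertex
  for (v in seq_len(n)[-1]) {
    p <- par[v]
    child_idx[p] <- child_idx[p] + 1L
    addr[v] <- if (p == 1L) as.character(child_idx[p])
               else paste0(addr[p], ".", child_idx[p])
  }
  addr
}

#' Ball of radius k around the root
#'
#' Restricts a rooted ordered tree to the vertices within graph distance `k`
#' of the root, keeping the original child order.  Vertices at depth exactly
#' `k` appear with out-degree 0.
#'
#' @param t a `rotree`.
#' @param k radius, in edges (`k >= 0`).
#' @return a `rotree`.
#' @export
ball <- function(t, k) {
  stopifnot(is_rotree(t), k >= 0)
  depth <- rotree_depth(t)
  keep <- depth <= k
  deg <- t$deg[keep]
  deg[depth[keep] == k] <- 0L
  rotree(deg)
}

# ---------------------------------------------------------------------------
# unrooted leaf-labelled d-ary trees

new_lltree <- function(adj, leaf, d, validate = TRUE) {
  t <- structure(list(adj = adj, leaf = as.integer(leaf), d = as.integer(d)),
                 class = "lltree")
  if (validate) validate_lltree(t)
  t
}

validate_lltree <- function(t) {
  V <- length(t$adj)
  degs <- lengths(t$adj)
  edges2 <- sum(degs)                       # twice the edge count
  if (edges2 != 2L * (V - 1L)) stop("not a tree: edge count mismatch")
  # connectivity
  if (V > 1L) {
    seen <- logical(V); seen[1L] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- t$adj[[v]]; new <- nb[!seen[nb]]
      seen[new] <- TRUE; queue <- c(queue, new)
    }
    if (!all(seen)) stop("not a tree: disconnected")
  }
  is_leaf <- !is.na(t$leaf)
  bad <- which(!(degs == 1L | degs == t$d + 1L))
  if (V == 2L) bad <- which(degs != 1L)
  if (V == 1L) bad <- integer(0)
  if (length(bad))
    stop("degree violation at vertex ", bad[1L], ": degree ", degs[bad[1L]],
         " (expected 1 or ", t$d + 1L, ")")
  if (V >= 2L && !identical(which(degs == 1L), which(is_leaf)))
    stop("leaves and labels disagree")
  labs <- sort(t$leaf[is_leaf])
  if (!identical(labs, seq_len(t$n_leaves))) stop("leaf labels are not 1..n")
  invisible(t)
}

#' @export
is_lltree <- function(x) inherits(x, "lltree")

#' @export
print.lltree <- function(x, ...) {
  cat("unrooted leaf-labelled tree: n =", x$n_leaves, "leaves, arity d =",
      x$d, "\n  ", write_newick(x), "\n")
  invisible(x)
}

# number of leaves, computed on demand
#' @export
`$.lltree` <- function(x, name) {
  if (name == "n_leaves") return(sum(!is.na(unclass(x)$leaf)))
  unclass(x)[[name]]
}

lltree_degrees <- function(t) lengths(t$adj)

# build from an edge matrix (two columns of vertex ids) and a label vector
lltree_from_edges <- function(edges, leaf, d = 2L, validate = TRUE) {
  V <- length(leaf)
  adj <- vector("list", V)
  for (v in seq_len(V)) adj[[v]] <- integer(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  new_lltree(adj, leaf, d, validate = validate)
}

# ---------------------------------------------------------------------------
# Newick I/O (via ape)

#' Read a tree from a Newick string
#'
#' Branch lengths, if present, are parsed and discarded with a warning: all
#' the combinatorics here is purely topological.  With `rooted = FALSE` the
#' result is an unrooted leaf-labelled `lltree` whose tip names must be the
#' integers `1..n`; a binary root (the usual rooted-Newick artefact) is
#' accepted only for the two-leaf tree `"(1,2);"`, and any other degree-2
#' vertex raises a validation error.  With `rooted = TRUE` the result is a
#' `rotree` that keeps the child order of the string (tip names ignored).
#'
#' @param text a Newick string terminated by `;`.
#' @param rooted return a rooted ordered tree instead of an unrooted one.
#' @param d expected arity of the unrooted tree (internal degree `d + 1`).
#' @return an `lltree` or a `rotree`.
#' @examples
#' parse_newick("(1,2,(3,4));")
#' parse_newick("((,),);", rooted = TRUE)
#' @export
parse_newick <- function(text, rooted = FALSE, d = 2L) {
  if (rooted) {
    # tips may be nameless: give them names so ape accepts the string
    text2 <- gsub("\\(,", "(t,", gsub(",,", ",t,", gsub(",\\)", ",t)", text)))
    text2 <- gsub("\\(\\)", "(t)", text2)
    phy <- tryCatch(suppressWarnings(ape::read.tree(text = text2)),
                    error = function(e) stop("Newick parse error: ", conditionMessage(e)))
    if (is.null(phy)) stop("Newick parse error")
    if (!is.null(phy$edge.length)) warning("branch lengths parsed and discarded")
    return(rotree_from_phylo(phy))
  }
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error")
  if (!is.null(phy$edge.length)) warning("branch lengths parsed and discarded")
  labs <- suppressWarnings(as.integer(phy$tip.label))
  if (any(is.na(labs))) stop("unrooted trees need integer leaf labels 1..n")
  ntip <- length(labs)
  V <- ntip + phy$Nnode
  leaf <- rep(NA_integer_, V); leaf[seq_len(ntip)] <- labs
  root <- ntip + 1L
  deg <- tabulate(c(phy$edge[, 1L], phy$edge[, 2L]), V)
  if (ntip == 2L && deg[root] == 2L) {
    # "(1,2);" -- collapse the artificial binary root into a single edge
    return(lltree_from_edges(matrix(c(1L, 2L), 1L), leaf[1:2], d))
  }
  lltree_from_edges(phy$edge, leaf, d)
}

# ape phylo -> rotree, preserving child order as written
rotree_from_phylo <- function(phy) {
  ntip <- length(phy$tip.label)
  V <- ntip + phy$Nnode
  kids <- vector("list", V)
  for (v in seq_len(V)) kids[[v]] <- integer(0)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    kids[[p]] <- c(kids[[p]], c)     # ape keeps edges in input (preorder) order
  }
  root <- ntip + 1L
  deg <- integer(0)
  rec <- function(v) {
    deg <<- c(deg, length(kids[[v]]))
    for (c in kids[[v]]) rec(c)
  }
  rec(root)
  rotree(deg)
}

#' Write a tree as a Newick string
#'
#' Output is deterministic: for an `lltree` the tree is rooted at the interior
#' vertex adjacent to leaf 1 and children are emitted in canonical (sorted)
#' order; for a `rotree` the stored child order is kept and leaves are named
#' by their preorder leaf index.  No branch lengths are written.
#'
#' @param t an `lltree` or `rotree`.
#' @return a Newick string ending in `;`.
#' @export
write_newick <- function(t) {
  if (is_rotree(t)) {
    kids <- rotree_kids(t)
    leafno <- cumsum(t$deg == 0L)
    rec <- function(v) {
      if (length(kids[[v]]) == 0L) return(paste0("t", leafno[v]))
      paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","), ")")
    }
    return(paste0(rec(1L), ";"))
  }
  stopifnot(is_lltree(t))
  if (t$n_leaves == 2L) return("(1,2);")
  rec <- function(v, from) {
    if (!is.na(t$leaf[v])) return(as.character(t$leaf[v]))
    sub <- vapply(setdiff(t$adj[[v]], from), function(u) rec(u, v), "")
    paste0("(", paste(sort(sub, method = "radix"), collapse = ","), ")")
  }
  root <- t$adj[[which(t$leaf == 1L)]][1L]
  sub <- vapply(setdiff(t$adj[[root]], integer(0)), function(u) rec(u, root), "")
  paste0("(", paste(sort(sub, method = "radix"), collapse = ","), ");")
}

# ---------------------------------------------------------------------------
# canonical codes

#' Canonical code of a tree
#'
#' Two trees receive equal codes exactly when they are isomorphic: for
#' `lltree`, isomorphism respects leaf labels (the code roots the tree at the
#' interior vertex next to leaf 1 and sorts child codes); for `rotree`, the
#' default ignores child order (AHU-style sorted-subtree code) and
#' `ordered = TRUE` gives the plane-tree code, i.e. the preorder degree
#' sequence itself.
#'
#' @param t an `lltree` or `rotree`.
#' @param ordered for `rotree` only: respect child order.
#' @return a character scalar.
#' @export
canonical_code <- function(t, ordered = FALSE) {
  if (is_rotree(t)) {
    if (ordered) return(paste(t$deg, collapse = ","))
    kids <- rotree_kids(t)
    rec <- function(v) {
      if (length(kids[[v]]) == 0L) return("()")
      paste0("(", paste(sort(vapply(kids[[v]], rec, ""), method = "radix"), collapse = ""), ")")
    }
    return(rec(1L))
  }
  stopifnot(is_lltree(t))
  if (t$n_leaves == 2L) return("[L1,L2]")
  rec <- function(v, from) {
    if (!is.na(t$leaf[v])) return(paste0("L", t$leaf[v]))
    sub <- vapply(setdiff(t$adj[[v]], from), function(u) rec(u, v), "")
    paste0("[", paste(sort(sub, method = "radix"), collapse = ","), "]")
  }
  root <- t$adj[[which(t$leaf == 1L)]][1L]
  sub <- vapply(t$adj[[root]], function(u) rec(u, root), "")
  paste0("[", paste(sort(sub, method = "radix"), collapse = ","), "]")
}

# ---------------------------------------------------------------------------
# grafting: ordered d-ary tree -> unrooted leaf-labelled tree

#' Graft a root leaf and label the leaves
#'
#' Turns an ordered d-ary tree with `n - 1` leaves into an unrooted
#' leaf-labelled d-ary tree with `n` leaves: a new pendant edge is attached at
#' the old root (which thereby becomes an interior vertex of degree `d + 1`),
#' the ordering and rooting are discarded, and the given label permutation is
#' assigned to the leaves (preorder leaves first, the grafted leaf last).
#' Applied to a uniform ordered d-ary tree with a uniform permutation this
#' yields a uniform leaf-labelled d-ary tree.
#'
#' @param t a `rotree` whose out-degrees are all 0 or `d`.
#' @param labels a permutation of `1..n` where `n` = (leaves of `t`) + 1.
#' @param d arity.
#' @return an `lltree`.
#' @export
graft_root_leaf_and_label <- function(t, labels, d = 2L) {
  stopifnot(is_rotree(t))
  if (!all(t$deg %in% c(0L, d))) stop("tree is not d-ary for d = ", d)
  V <- length(t$deg)
  n <- sum(t$deg == 0L) + 1L
  labels <- as.integer(labels)
  if (!identical(sort(labels), seq_len(n))) stop("labels must be a permutation of 1..n")
  par <- rotree_parent(t)
  edges <- cbind(par[-1L], seq_len(V)[-1L])
  edges <- rbind(edges, c(1L, V + 1L))           # pendant edge at the old root
  leaf <- rep(NA_integer_, V + 1L)
  leaf_vertices <- c(which(t$deg == 0L), V + 1L)
  leaf[leaf_vertices] <- labels
  lltree_from_edges(edges, leaf, d)
}

# ---------------------------------------------------------------------------
# exhaustive generators (test oracles)

#' Enumerate all ordered d-ary trees with a given number of leaves
#'
#' @param n_leaves number of leaves (`>= 1`).
#' @param d arity.
#' @return list of `rotree` (for `d = 2` there are Catalan(n_leaves - 1) of them).
#' @export
enumerate_all_ordered <- function(n_leaves, d = 2L) {
  gen <- function(m) {
    if (m == 1L) return(list(0L))
    # compositions of m into d parts >= 1
    out <- list()
    comp <- function(parts, left, slots) {
      if (slots == 1L) {
        subs <- lapply(c(parts, left), gen)
        grids <- expand_grid_list(subs)
        for (g in grids) out[[length(out) + 1L]] <<- c(d, unlist(g))
        return(invisible(NULL))
      }
      for (p in seq_len(left - slots + 1L)) comp(c(parts, p), left - p, slots - 1L)
    }
    comp(integer(0), m, d)
    out
  }
  lapply(gen(as.integer(n_leaves)), rotree)
}

# cartesian product of lists of choices
expand_grid_list <- function(lists) {
  res <- list(list())
  for (l in lists) {
    res <- unlist(lapply(res, function(pref) {
      lapply(l, function(x) c(pref, list(x)))
    }), recursive = FALSE)
  }
  res
}

#' Enumerate all unrooted leaf-labelled d-ary trees
#'
#' For `d = 2` the classic leaf-insertion recursion is used (attach leaf `m`
#' to every edge of every tree on `m - 1` leaves), producing each of the
#' `(2n-5)!!` trees exactly once.  For `d > 2` all ordered d-ary trees on
#' `n - 1` leaves are grafted and labelled in all ways and the results
#' de-duplicated by canonical code (feasible only for small `n`).
#'
#' @param n number of leaves.
#' @param d arity.
#' @param force allow `n` beyond the 1e6-tree guard.
#' @return list of `lltree`.
#' @export
enumerate_all_unrooted <- function(n, d = 2L, force = FALSE) {
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2")
  if (d == 2L) {
    count <- if (n < 4L) 1 else prod(seq(2L * n - 5L, 1L, by = -2L))
    if (n >= 5L && count > 1e6 && !force) stop("would enumerate ", count, " trees; set force = TRUE")
    trees <- list(list(edges = matrix(c(1L, 2L), 1L), nv = 2L))
    if (n > 2L) for (m in 3L:n) {
      nxt <- vector("list", 0L)
      for (tr in trees) {
        for (e in seq_len(nrow(tr$edges))) {
          a <- tr$edges[e, 1L]; b <- tr$edges[e, 2L]
          w <- tr$nv + 1L   # new internal vertex (will carry no label)
          u <- tr$nv + 2L   # new leaf
          edges <- rbind(tr$edges[-e, , drop = FALSE],
                         c(a, w), c(w, b), c(w, u))
          nxt[[length(nxt) + 1L]] <- list(edges = edges, nv = tr$nv + 2L)
        }
      }
      trees <- nxt
    }
    return(lapply(trees, function(tr) {
      leaf <- rep(NA_integer_, tr$nv)
      leaf[seq_len(min(2L, n))] <- seq_len(min(2L, n))
      if (n > 2L) {
        # leaves added as vertices 2m for m = 3..n carry label m; 1,2 fixed
        leaf[] <- NA_integer_
        leaf[1L] <- 1L; leaf[2L] <- 2L
        if (n >= 3L) for (m in 3L:n) leaf[2L * (m - 2L) + 2L] <- m
      }
      lltree_from_edges(tr$edges, leaf, 2L)
    }))
  }
  # general d: brute force + dedupe
  ord <- enumerate_all_ordered(n - 1L, d)
  perms <- perms_all(n)
  seen <- character(0); out <- list()
  for (t in ord) for (i in seq_len(nrow(perms))) {
    ll <- graft_root_leaf_and_label(t, perms[i, ], d)
    cc <- canonical_code(ll)
    if (!(cc %in% seen)) { seen <- c(seen, cc); out[[length(out) + 1L]] <- ll }
  }
  out
}

# all permutations of 1..n as rows (n small)
perms_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L))
  sub <- perms_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
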