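# Pattern trees and occurrence testing.
#
# A pattern is a finite tree whose vertices are split into "internal"
# vertices and "free leaves".  A pattern occurs in a host tree T if there is
# an injective, adjacency-preserving map of pattern vertices into T under
# which every internal pattern vertex keeps its exact degree (so all of its
# host neighbours are images of pattern neighbours), while free leaves are
# unconstrained -- each free leaf stands for an arbitrary hanging rooted
# subtree of the host.  This is the semantics under which the snowflake
# (central vertex + six interior vertices at distance 2, twelve hanging
# subtrees) is detected by the distance-to-leaf criterion.

#' Build a pattern tree
#'
#' @param edges two-column matrix of vertex pairs (vertices `1..V`).
#' @param role character vector of length `V`, `"internal"` or `"free"`.
#'   Vertices of degree >= 2 must be internal; a degree-1 (or isolated)
#'   vertex may take either role -- an internal vertex of degree 1 matches
#'   only an actual host leaf, a free leaf matches any hanging subtree.
#' @return An object of class `ptree`.
#' @examples
#' # a cherry: one internal vertex carrying two free subtrees
#' pattern_tree(rbind(c(1, 2), c(1, 3)), c("internal", "free", "free"))
#' @export
pattern_tree <- function(edges, role) {
  V <- length(role)
  if (!all(role %in% c("internal", "free"))) stop("roles must be 'internal' or 'free'")
  adj <- vector("list", V)
  for (v in seq_len(V)) adj[[v]] <- integer(0)
  if (V > 1L) {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (nrow(edges) != V - 1L) stop("a tree on V vertices needs V - 1 edges")
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  degs <- lengths(adj)
  if (any(degs >= 2L & role == "free")) stop("a vertex of degree >= 2 cannot be a free leaf")
  # connectivity check via reached count
  if (V > 1L) {
    seen <- logical(V); seen[1L] <- TRUE; stack <- 1L
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE; stack <- c(stack, nb)
    }
    if (!all(seen)) stop("pattern is not connected")
  }
  structure(list(adj = adj, role = role), class = "ptree")
}

#' @export
is_ptree <- function(x) inherits(x, "ptree")

#' @export
print.ptree <- function(x, ...) {
  cat("pattern tree:", length(x$adj), "vertices (",
      sum(x$role == "internal"), "internal,", sum(x$role == "free"),
      "free leaves ), diameter", pattern_diameter(x), "\n")
  invisible(x)
}

#' The snowflake pattern
#'
#' A central internal vertex of degree 3, its three internal neighbours, six
#' internal vertices at distance 2 from the centre, and twelve free leaves
#' (the hanging rooted subtrees): 22 vertices, diameter 6.  A binary
#' phylogenetic tree contains a snowflake centred at `v` exactly when every
#' leaf is at distance at least 3 from `v`.
#'
#' @return a `ptree`.
#' @export
snowflake_pattern <- function() {
  edges <- rbind(
    cbind(1L, 2:4),                 # centre -- three neighbours
    cbind(rep(2:4, each = 2L), 5:10),  # neighbours -- six distance-2 vertices
    cbind(rep(5:10, each = 2L), 11:22) # twelve hanging subtrees
  )
  pattern_tree(edges, c(rep("internal", 10L), rep("free", 12L)))
}

#' Diameter of a pattern tree
#' @param tau a `ptree` (or any object with an `adj` field).
#' @return maximal pairwise edge distance.
#' @export
pattern_diameter <- function(tau) {
  adj <- tau$adj; V <- length(adj)
  if (V == 1L) return(0L)
  ecc <- function(s) {
    dist <- rep(NA_integer_, V); dist[s] <- 0L; queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]][is.na(dist[adj[[v]]])]
      dist[nb] <- dist[v] + 1L
      queue <- c(queue, nb)
    }
    max(dist)
  }
  max(vapply(seq_len(V), ecc, 0L))
}

# ---------------------------------------------------------------------------
# host graphs

# adjacency-list view of a host tree (lltree kept as is; rotree converted to
# its underlying undirected graph)
host_adj <- function(T) {
  if (is_lltree(T)) return(T$adj)
  if (is_rotree(T)) {
    par <- rotree_parent(T)
    V <- length(par)
    adj <- vector("list", V)
    for (v in seq_len(V)) adj[[v]] <- integer(0)
    for (v in seq_len(V)[-1]) {
      adj[[par[v]]] <- c(adj[[par[v]]], v)
      adj[[v]] <- c(adj[[v]], par[v])
    }
    return(adj)
  }
  if (is.list(T) && !is.null(T$adj)) return(T$adj)
  stop("not a tree object")
}

# ---------------------------------------------------------------------------
# snowflake central vertices

#' Snowflake central vertices of a binary tree
#'
#' Returns the interior vertices whose edge distance to every leaf is at
#' least 3; these are exactly the vertices that are the central vertex of at
#' least one snowflake.  `count_snowflake_centers` returns their number,
#' the tree statistic whose mean over uniform trees is `|S(n)|/B(n)`.
#'
#' @param T an `lltree` (binary, `d = 2`) or a `rotree`.
#' @return integer vertex ids; for the count, a single integer.
#' @export
snowflake_central_vertices <- function(T) {
  adj <- host_adj(T)
  degs <- lengths(adj)
  V <- length(adj)
  if (V <= 2L) return(integer(0))
  # vertices within distance 2 of a leaf, by two rounds of neighbour marking
  near <- degs == 1L
  for (round in 1:2) {
    nxt <- near
    for (v in which(near)) nxt[adj[[v]]] <- TRUE
    near <- nxt
  }
  which(!near & degs > 1L)
}

#' @rdname snowflake_central_vertices
#' @export
count_snowflake_centers <- function(T) length(snowflake_central_vertices(T))

# fast path used by the Monte-Carlo drivers: count centers directly from an
# edge list (vectorised two-round leaf propagation)
count_centers_edges <- function(edges, V) {
  degs <- tabulate(c(edges[, 1L], edges[, 2L]), V)
  near <- degs == 1L
  for (round in 1:2) {
    a <- edges[, 1L]; b <- edges[, 2L]
    hit <- c(b[near[a]], a[near[b]])
    near[hit] <- TRUE
  }
  sum(!near & degs > 1L)
}

# ---------------------------------------------------------------------------
# occurrence testing (polynomial DP with bipartite matching)

# Kuhn's augmenting-path bipartite matching; M is a logical matrix
# (rows = pattern children, cols = host children); returns the match vector
# (host index per row) or NULL if no perfect matching exists
perfect_matching <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  if (nr != nc) return(NULL)
  if (nr == 0L) return(integer(0))
  match_col <- integer(nc)       # 0 = unmatched
  for (r in seq_len(nr)) {
    seen <- logical(nc)
    try_kuhn <- function(r) {
      for (c in which(M[r, ] & !seen)) {
        seen[c] <<- TRUE
        if (match_col[c] == 0L || try_kuhn(match_col[c])) {
          match_col[c] <<- r
          return(TRUE)
        }
      }
      FALSE
    }
    if (!try_kuhn(r)) return(NULL)
  }
  res <- integer(nr)
  for (c in seq_len(nc)) if (match_col[c] > 0L) res[match_col[c]] <- c
  res
}

#' Does a pattern occur in a host tree?
#'
#' Degree-exact embedding test (see [pattern_tree()] for the semantics), by
#' dynamic programming: the pattern is rooted at an internal vertex and, for
#' every host vertex, feasibility of each pattern subtree against each host
#' subtree is decided via bipartite matching of children.  Runs in polynomial
#' time; `brute_force_occurs` is the independent exhaustive oracle for small
#' hosts.
#'
#' @param T host tree (`lltree` or `rotree`), viewed as its underlying
#'   unrooted graph.
#' @param tau a `ptree`.
#' @param witness also return an embedding (pattern vertex -> host vertex).
#' @return logical; with `witness = TRUE`, a list `(occurs, map)`.
#' @export
occurs <- function(T, tau, witness = FALSE) {
  hadj <- host_adj(T)
  res <- occurs_impl(hadj, tau, at_host = NULL, witness = witness)
  res
}

#' @rdname occurs
#' @param v host vertex at which the pattern root (its first internal vertex,
#'   for the snowflake: the centre) must be placed.
#' @export
occurs_at <- function(T, tau, v) {
  hadj <- host_adj(T)
  isTRUE(occurs_impl(hadj, tau, at_host = v, witness = FALSE))
}

occurs_impl <- function(hadj, tau, at_host = NULL, witness = FALSE) {
  V <- length(hadj)
  padj <- tau$adj
  pV <- length(padj)
  internal <- which(tau$role == "internal")
  hdegs <- lengths(hadj)
  pdegs <- lengths(padj)
  if (length(internal) == 0L) {
    if (pV == 1L) {
      ok <- V >= 1L
      if (!witness) return(ok)
      return(list(occurs = ok, map = if (ok) 1L else NULL))
    }
    if (pV == 2L) {
      ok <- V >= 2L
      if (!witness) return(ok)
      return(list(occurs = ok, map = if (ok) c(1L, hadj[[1L]][1L]) else NULL))
    }
    stop("pattern with more than 2 vertices needs at least one internal vertex")
  }
  pr <- internal[1L]
  memo <- new.env(hash = TRUE, parent = emptyenv())

  embed <- function(pv, pp, hv, hp) {
    key <- paste(pv, pp, hv, hp)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- if (tau$role[pv] == "free") TRUE else {
      if (hdegs[hv] != pdegs[pv]) FALSE
      else {
        pch <- setdiff(padj[[pv]], pp)
        hch <- setdiff(hadj[[hv]], hp)
        if (length(pch) != length(hch)) FALSE
        else if (length(pch) == 0L) TRUE
        else {
          M <- matrix(FALSE, length(pch), length(hch))
          for (i in seq_along(pch)) for (j in seq_along(hch))
            M[i, j] <- embed(pch[i], pv, hch[j], hv)
          !is.null(perfect_matching(M))
        }
      }
    }
    memo[[key]] <- res
    res
  }

  hosts <- if (is.null(at_host)) seq_len(V) else as.integer(at_host)
  hit <- NA_integer_
  for (hv in hosts) {
    if (embed(pr, 0L, hv, 0L)) { hit <- hv; break }
  }
  if (!witness) return(!is.na(hit))
  if (is.na(hit)) return(list(occurs = FALSE, map = NULL))
  # reconstruct a deterministic embedding: pattern children in order, host
  # children tried in increasing id, with feasibility from the memoised DP;
  # distinct host subtrees are vertex-disjoint, so fragments concatenate
  build_map <- function(pv, pp, hv, hp) {
    base <- stats::setNames(hv, pv)
    if (tau$role[pv] == "free") return(base)
    pch <- setdiff(padj[[pv]], pp)
    hch <- sort(setdiff(hadj[[hv]], hp))
    place <- function(i, avail, acc) {
      if (i > length(pch)) return(acc)
      for (hc in avail) {
        if (embed(pch[i], pv, hc, hv)) {
          sub <- build_map(pch[i], pv, hc, hv)
          if (!is.null(sub)) {
            r <- place(i + 1L, setdiff(avail, hc), c(acc, sub))
            if (!is.null(r)) return(r)
          }
        }
      }
      NULL
    }
    place(1L, hch, base)
  }
  frag <- build_map(pr, 0L, hit, 0L)
  map <- integer(pV)
  map[as.integer(names(frag))] <- unname(frag)
  list(occurs = TRUE, map = map)
}

#' Exhaustive occurrence oracle
#'
#' Checks the same degree-exact containment as [occurs()] by backtracking
#' over injective vertex maps; exponential, guarded to small hosts, and
#' implemented independently of the matching DP so the two can cross-check
#' each other.
#'
#' @inheritParams occurs
#' @param max_host_vertices refusal guard.
#' @return logical.
#' @export
brute_force_occurs <- function(T, tau, max_host_vertices = 16L) {
  hadj <- host_adj(T)
  if (length(hadj) > max_host_vertices)
    stop("host too large for the exhaustive oracle (", length(hadj), " vertices)")
  bf_search(hadj, tau, exact_degree = TRUE)
}

#' Plain-subgraph containment (no degree constraints)
#'
#' An exploratory relation: an injective adjacency-preserving map of the
#' pattern's vertices into the host, ignoring the internal/free distinction.
#' Exhaustive; use on small hosts only.
#'
#' @inheritParams brute_force_occurs
#' @return logical.
#' @export
occurs_subgraph <- function(T, tau, max_host_vertices = 16L) {
  hadj <- host_adj(T)
  if (length(hadj) > max_host_vertices)
    stop("host too large for the exhaustive search (", length(hadj), " vertices)")
  bf_search(hadj, tau, exact_degree = FALSE)
}

bf_search <- function(hadj, tau, exact_degree) {
  padj <- tau$adj
  pV <- length(padj)
  V <- length(hadj)
  if (pV > V) return(FALSE)
  hdegs <- lengths(hadj)
  pdegs <- lengths(padj)
  need_exact <- exact_degree & (tau$role == "internal")
  # order pattern vertices so that each one (after the first) has an earlier
  # neighbour; start from an internal vertex when there is one
  start <- if (any(tau$role == "internal")) which(tau$role == "internal")[1L] else 1L
  ord <- integer(pV); ord[1L] <- start
  placed <- logical(pV); placed[start] <- TRUE
  for (i in seq_len(pV)[-1]) {
    nxt <- 0L
    for (v in seq_len(pV)) {
      if (!placed[v] && any(placed[padj[[v]]])) { nxt <- v; break }
    }
    ord[i] <- nxt; placed[nxt] <- TRUE
  }
  map <- integer(pV); used <- logical(V)
  try_place <- function(i) {
    if (i > pV) return(TRUE)
    pv <- ord[i]
    prev <- padj[[pv]][map[padj[[pv]]] != 0L]
    cand <- if (i == 1L) seq_len(V) else {
      base <- hadj[[map[prev[1L]]]]
      base[!used[base]]
    }
    for (hv in cand) {
      if (used[hv]) next
      if (need_exact[pv] && hdegs[hv] != pdegs[pv]) next
      if (!need_exact[pv] && hdegs[hv] < pdegs[pv]) next
      ok <- TRUE
      for (pn in prev) {
        if (!(map[pn] %in% hadj[[hv]])) { ok <- FALSE; break }
      }
      if (!ok) next
      map[pv] <<- hv; used[hv] <<- TRUE
      if (try_place(i + 1L)) return(TRUE)
      map[pv] <<- 0L; used[hv] <<- FALSE
    }
    FALSE
  }
  try_place(1L)
}

# ---------------------------------------------------------------------------
# realizability

#' Is a pattern realizable under an offspring law?
#'
#' A tree is X-realizable when it can be rooted so that every out-degree lies
#' in the support of X.  Two rooting conventions are checked and reported
#' separately: rooting at a vertex, and rooting at an edge midpoint (the
#' phylogenetic convention: the edge is subdivided and the new degree-2
#' vertex becomes the root, acquiring out-degree 2).
#'
#' @param tau a `ptree` (roles are irrelevant here: all vertices count).
#' @param X an `offspring`.
#' @return list with logical fields `vertex`, `edge`, `any`.
#' @export
is_realizable <- function(tau, X) {
  adj <- tau$adj
  degs <- lengths(adj)
  S <- X$support
  ok_nonroot <- (degs - 1L) %in% S
  vertex_ok <- any(vapply(seq_along(degs), function(v) {
    degs[v] %in% S && all(ok_nonroot[-v])
  }, TRUE))
  edge_ok <- length(adj) >= 2L && (2L %in% S) && all(ok_nonroot)
  list(vertex = vertex_ok, edge = edge_ok, any = vertex_ok || edge_ok)
}
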