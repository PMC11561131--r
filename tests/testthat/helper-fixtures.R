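# Fixtures built in code: explicit hosts, exhaustive small-tree grids, and
# independent little oracles used across the test files.

# caterpillar on n leaves: interior vertices form a path, X_T = 0 for all n
make_caterpillar <- function(n) {
  stopifnot(n >= 4)
  # internals 1..n-2, leaves n-1..2n-2
  edges <- cbind(seq_len(n - 3L), seq_len(n - 3L) + 1L)
  edges <- rbind(edges, c(1L, n - 1L), c(1L, n))
  if (n >= 5L) for (i in 2:(n - 3L)) edges <- rbind(edges, c(i, n + i - 1L))
  edges <- rbind(edges, c(n - 2L, 2L * n - 3L), c(n - 2L, 2L * n - 2L))
  leaf <- rep(NA_integer_, 2L * n - 2L)
  leaf[(n - 1L):(2L * n - 2L)] <- seq_len(n)
  treepatterns:::lltree_from_edges(edges, leaf, 2L)
}

# the 12-leaf tree that is exactly one snowflake (centre + 3 + 6 + 12 leaves)
perfect_snowflake_host <- function() {
  parse_newick("(((1,2),(3,4)),((5,6),(7,8)),((9,10),(11,12)));")
}

# complete balanced tree on 16 leaves: both central-edge endpoints are centres
balanced16_host <- function() {
  parse_newick(paste0("(((1,2),(3,4)),((5,6),(7,8)),",
                      "(((9,10),(11,12)),((13,14),(15,16))));"))
}

# unlabeled-tree canonical code of an edge matrix (min AHU over rootings)
unlabeled_code <- function(edges, V) {
  adj <- vector("list", V)
  for (v in seq_len(V)) adj[[v]] <- integer(0)
  if (V > 1L) for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  rec <- function(v, from) {
    sub <- sort(vapply(setdiff(adj[[v]], from), function(u) rec(u, v), ""),
                method = "radix")
    paste0("(", paste(sub, collapse = ""), ")")
  }
  min(vapply(seq_len(V), function(v) rec(v, 0L), ""))
}

# all unlabeled free trees on V vertices, via Prufer sequences + dedupe
all_free_trees <- function(V) {
  if (V == 1L) return(list(matrix(integer(0), 0L, 2L)))
  if (V == 2L) return(list(matrix(c(1L, 2L), 1L)))
  decode_prufer <- function(p) {
    degree <- rep(1L, V)
    for (x in p) degree[x] <- degree[x] + 1L
    edges <- matrix(0L, V - 1L, 2L)
    k <- 0L
    for (x in p) {
      leafv <- which(degree == 1L)[1L]
      k <- k + 1L
      edges[k, ] <- c(leafv, x)
      degree[leafv] <- degree[leafv] - 1L
      degree[x] <- degree[x] - 1L
    }
    last <- which(degree == 1L)
    edges[V - 1L, ] <- last
    edges
  }
  seqs <- as.matrix(do.call(expand.grid, rep(list(seq_len(V)), V - 2L)))
  seen <- character(0); out <- list()
  for (i in seq_len(nrow(seqs))) {
    edges <- decode_prufer(as.integer(seqs[i, ]))
    code <- unlabeled_code(edges, V)
    if (!(code %in% seen)) {
      seen <- c(seen, code)
      out[[length(out) + 1L]] <- edges
    }
  }
  out
}

# every pattern on <= maxV vertices with every admissible role assignment
# (degree >= 2 forces "internal"; degree <= 1 may be either), de-duplicated
# by the role-aware canonical code; assignments with no internal vertex are
# kept only for patterns of 1 or 2 vertices
all_patterns_upto <- function(maxV) {
  out <- list(); seen <- character(0)
  for (V in seq_len(maxV)) {
    for (edges in all_free_trees(V)) {
      degs <- tabulate(as.integer(edges), V)
      flex <- which(degs <= 1L)
      forced <- rep("internal", V)
      combos <- expand.grid(rep(list(c("internal", "free")), length(flex)),
                            stringsAsFactors = FALSE)
      for (ci in seq_len(nrow(combos))) {
        role <- forced
        role[flex] <- as.character(combos[ci, ])
        if (!any(role == "internal") && V > 2L) next
        tau <- pattern_tree(edges, role)
        code <- treepatterns:::pattern_code(tau)
        if (!(code %in% seen)) {
          seen <- c(seen, code)
          out[[length(out) + 1L]] <- tau
        }
      }
    }
  }
  out
}

# the exhaustive host grid: all unrooted binary trees up to n leaves, and all
# ordered binary trees up to max_ord vertices
grid_hosts <- function(max_leaves = 6L, max_ord = 11L) {
  hosts <- list()
  for (n in 2L:max_leaves) hosts <- c(hosts, enumerate_all_unrooted(n))
  for (v in seq(1L, max_ord, by = 2L)) {
    hosts <- c(hosts, enumerate_all_ordered((v + 1L) %/% 2L, 2L))
  }
  hosts
}

# independent forest-count oracle: sum over set partitions of {1..n} into k
# blocks of the product of rooted-tree counts R(|block|), with R from the
# exhaustive generator
forests_count_oracle <- function(n, k) {
  R <- function(m) length(enumerate_all_unrooted(m + 1L))
  parts <- function(items, k) {
    # all partitions of items into exactly k non-empty blocks
    if (length(items) == 0L) return(if (k == 0L) list(list()) else list())
    if (k == 0L) return(list())
    first <- items[1L]; rest <- items[-1L]
    out <- list()
    for (p in parts(rest, k)) {
      for (b in seq_along(p)) {
        q <- p; q[[b]] <- c(first, q[[b]])
        out[[length(out) + 1L]] <- q
      }
    }
    for (p in parts(rest, k - 1L)) {
      out[[length(out) + 1L]] <- c(list(first), p)
    }
    out
  }
  total <- 0
  for (p in parts(seq_len(n), k)) total <- total + prod(vapply(p, function(b) R(length(b)), 0))
  total
}
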