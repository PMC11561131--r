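# Pattern trees, snowflake detection, the embedding engine and its oracle,
# realizability.

test_that("the snowflake pattern has the right shape", {
  sf <- snowflake_pattern()
  expect_length(sf$adj, 22L)
  expect_equal(sum(sf$role == "free"), 12L)
  expect_equal(pattern_diameter(sf), 6L)
  degs <- lengths(sf$adj)
  expect_equal(degs[1], 3L)                       # centre
  expect_equal(sum(degs == 3L), 10L)              # centre + 3 + 6
})

test_that("pattern constructor enforces roles and connectivity", {
  expect_error(pattern_tree(rbind(c(1, 2), c(1, 3)), c("free", "free", "free")),
               "degree >= 2")
  expect_error(pattern_tree(rbind(c(1, 2)), c("internal", "free", "free")),
               "edges")
  expect_equal(pattern_diameter(pattern_tree(matrix(integer(0), 0, 2), "free")), 0L)
  p5 <- pattern_tree(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
                     c("free", "internal", "internal", "internal", "free"))
  expect_equal(pattern_diameter(p5), 4L)
})

test_that("snowflake central vertices match an independent distance check", {
  bfs_leaf_dist <- function(t) {
    adj <- t$adj; V <- length(adj)
    dist <- rep(NA_integer_, V)
    queue <- which(lengths(adj) == 1L); dist[queue] <- 0L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]][is.na(dist[adj[[v]]])]
      dist[nb] <- dist[v] + 1L
      queue <- c(queue, nb)
    }
    dist
  }
  hosts <- list(make_caterpillar(20), perfect_snowflake_host(), balanced16_host())
  expected <- list(integer(0), NULL, NULL)
  for (i in seq_along(hosts)) {
    t <- hosts[[i]]
    d <- bfs_leaf_dist(t)
    want <- which(d >= 3L & lengths(t$adj) > 1L)
    expect_identical(snowflake_central_vertices(t), want)
  }
  expect_equal(count_snowflake_centers(make_caterpillar(20)), 0L)
  expect_equal(count_snowflake_centers(perfect_snowflake_host()), 1L)
  expect_equal(count_snowflake_centers(balanced16_host()), 2L)
})

test_that("no tree below 12 leaves has a snowflake centre", {
  for (t in enumerate_all_unrooted(6)) expect_equal(count_snowflake_centers(t), 0L)
  set.seed(21)
  for (i in 1:50) expect_equal(count_snowflake_centers(sample_uniform_leaf_labelled(11)), 0L)
})

test_that("occurrence basics: free leaf, star, path, snowflake", {
  star3 <- pattern_tree(rbind(c(1, 2), c(1, 3), c(1, 4)),
                        c("internal", "free", "free", "free"))
  single <- pattern_tree(matrix(integer(0), 0, 2), "free")
  path4 <- pattern_tree(rbind(c(1, 2), c(2, 3), c(3, 4)),
                        c("free", "internal", "internal", "free"))
  sf <- snowflake_pattern()

  expect_true(occurs(parse_newick("(1,2);"), single))
  expect_false(occurs(parse_newick("(1,2);"), star3))
  for (n in 3:5) for (t in enumerate_all_unrooted(n)) expect_true(occurs(t, star3))

  expect_true(occurs(perfect_snowflake_host(), sf))
  expect_false(occurs(make_caterpillar(20), sf))
  w <- occurs(perfect_snowflake_host(), sf, witness = TRUE)
  expect_true(w$occurs)
  expect_identical(w$map[1], snowflake_central_vertices(perfect_snowflake_host()))

  # a path with two adjacent degree-2 internals fits no binary phylogenetic
  # tree and no rooted binary GW realization (only one degree-2 vertex there)
  for (t in enumerate_all_unrooted(5)) expect_false(occurs(t, path4))
  for (t in enumerate_all_ordered(4)) {
    expect_false(occurs(t, path4))
    expect_false(brute_force_occurs(t, path4))
  }
  # a free-internal-free path does match across a rooted GW root
  path3 <- pattern_tree(rbind(c(1, 2), c(2, 3)), c("free", "internal", "free"))
  for (t in enumerate_all_ordered(4)) expect_true(occurs(t, path3))

  expect_error(occurs(parse_newick("(1,2);"),
                      pattern_tree(rbind(c(1, 2), c(2, 3)), c("free", "free", "free"))),
               "degree >= 2")
})

test_that("witness embeddings are genuine degree-exact embeddings", {
  set.seed(22)
  sf <- snowflake_pattern()
  for (i in 1:10) {
    t <- sample_uniform_leaf_labelled(30)
    w <- occurs(t, sf, witness = TRUE)
    if (!w$occurs) next
    map <- w$map
    expect_equal(anyDuplicated(map), 0L)
    for (pv in seq_along(sf$adj)) {
      for (pu in sf$adj[[pv]]) expect_true(map[pu] %in% t$adj[[map[pv]]])
      if (sf$role[pv] == "internal")
        expect_equal(length(t$adj[[map[pv]]]), length(sf$adj[[pv]]))
    }
  }
})

test_that("DP engine agrees with the exhaustive oracle on a small grid", {
  pats <- all_patterns_upto(6)
  hosts <- grid_hosts(max_leaves = 5L, max_ord = 9L)
  for (h in hosts) for (p in pats) {
    expect_identical(occurs(h, p), brute_force_occurs(h, p))
  }
})

test_that("subgraph containment is weaker than degree-exact containment", {
  path4 <- pattern_tree(rbind(c(1, 2), c(2, 3), c(3, 4)),
                        c("free", "internal", "internal", "free"))
  t5 <- enumerate_all_unrooted(5)[[1]]
  expect_false(occurs(t5, path4))
  expect_true(occurs_subgraph(t5, path4))   # a 4-vertex path exists as a subgraph
  for (h in grid_hosts(4L, 7L)) for (p in all_patterns_upto(4)) {
    if (occurs(h, p)) expect_true(occurs_subgraph(h, p))
  }
})

test_that("central-vertex criterion coincides with pattern embedding at n = 30", {
  set.seed(23)
  sf <- snowflake_pattern()
  for (i in 1:20) {
    t <- sample_uniform_leaf_labelled(30)
    centres <- snowflake_central_vertices(t)
    via_embed <- which(vapply(seq_along(t$adj), function(v) occurs_at(t, sf, v), TRUE))
    expect_identical(via_embed, centres)
  }
})

test_that("realizability under vertex- and edge-rooting conventions", {
  X <- offspring_dary(2)
  path3 <- pattern_tree(rbind(c(1, 2), c(2, 3)), c("free", "internal", "free"))
  star3 <- pattern_tree(rbind(c(1, 2), c(1, 3), c(1, 4)),
                        c("internal", "free", "free", "free"))
  path4 <- pattern_tree(rbind(c(1, 2), c(2, 3), c(3, 4)),
                        c("free", "internal", "internal", "free"))
  r3 <- is_realizable(path3, X)
  expect_true(r3$vertex); expect_true(r3$any)
  rs <- is_realizable(star3, X)
  expect_false(rs$vertex); expect_true(rs$edge)
  r4 <- is_realizable(path4, X)
  expect_false(r4$vertex); expect_false(r4$edge); expect_false(r4$any)
  rsf <- is_realizable(snowflake_pattern(), X)
  expect_false(rsf$vertex); expect_true(rsf$edge)
})

test_that("non-realizable patterns never occur in conditioned GW trees", {
  X <- offspring_dary(2)
  pats <- all_patterns_upto(6)
  non_real <- Filter(function(p) !is_realizable(p, X)$any, pats)
  expect_gt(length(non_real), 0L)
  set.seed(24)
  for (i in 1:100) {
    t <- sample_conditioned_gw(X, 201)
    for (p in non_real) expect_false(occurs(t, p))
  }
})

test_that("occurrence is monotone under free-leaf deletion (freed neighbour)", {
  # delete a free leaf whose internal neighbour thereby drops to degree 1 and
  # becomes free itself; the reduced pattern must still occur
  pats <- all_patterns_upto(6)
  hosts_all <- grid_hosts(5L, 9L)
  hosts <- hosts_all[seq(1, length(hosts_all), by = 4)]
  checked <- 0L
  for (p in pats) {
    V <- length(p$adj)
    if (V < 3L) next
    for (f in which(p$role == "free")) {
      nb <- p$adj[[f]][1]
      if (length(p$adj[[nb]]) != 2L) next
      keep <- setdiff(seq_len(V), f)
      remap <- match(seq_len(V), keep)
      edges <- NULL
      for (v in keep) for (u in p$adj[[v]]) {
        if (u > v || u == f) next
        edges <- rbind(edges, c(remap[u], remap[v]))
      }
      role <- p$role[keep]
      role[remap[nb]] <- "free"
      if (!any(role == "internal") && length(keep) > 2L) next
      p2 <- pattern_tree(edges, role)
      for (h in hosts) {
        if (occurs(h, p)) {
          expect_true(occurs(h, p2))
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 10L)
})
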