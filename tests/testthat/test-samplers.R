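# Random tree generators: exact uniformity, product-formula checks,
# size-biasing, Kesten balls, determinism.

test_that("size-biased distributions are exact", {
  expect_identical(size_biased(offspring_dary(2))$support, 2L)
  expect_identical(size_biased(offspring_dary(5))$support, 5L)
  u <- offspring(0:2, c(1, 1, 1), 3)   # uniform on {0,1,2}, critical
  sb <- size_biased(u)
  expect_identical(sb$support, 1:2)
  expect_equal(sb$num / sb$den, c(1/3, 2/3))
  expect_true(offspring_is_critical(u))
  expect_true(offspring_second_moment(u) == xrat(5, 3))
  expect_error(size_biased(offspring(0L, 1, 1)), "positive mean")
})

test_that("offspring constructor validates its weights", {
  expect_error(offspring(c(0, 2), c(1, 1), 3), "sum")
  expect_error(offspring(c(0, 0), c(1, 1), 2), "distinct")
  expect_true(offspring_mean(offspring_dary(3)) == xrat(1, 1))
})

test_that("cycle-lemma rotation is a 5-to-1 map onto valid preorder words", {
  # all 10 arrangements of {2,2,0,0,0}: each of the 2 ordered trees with 5
  # vertices must be reached from exactly 5 arrangements
  pos <- utils::combn(5, 2)
  hits <- character(0)
  for (j in seq_len(ncol(pos))) {
    deg <- integer(5); deg[pos[, j]] <- 2L
    rot <- treepatterns:::cycle_lemma_rotate(deg)
    hits <- c(hits, paste(rot, collapse = ""))
    expect_s3_class(rotree(rot), "rotree")   # valid word
  }
  tab <- table(hits)
  expect_length(tab, 2L)
  expect_true(all(tab == 5L))
})

test_that("conditioned GW draws: degenerate cases and congruence errors", {
  expect_identical(sample_conditioned_gw(offspring_dary(2), 1)$deg, 0L)
  expect_identical(sample_conditioned_gw(offspring_dary(3), 4)$deg[1], 3L)
  expect_error(sample_conditioned_gw(offspring_dary(2), 4), "congruent to 1 mod 2")
  expect_error(sample_conditioned_gw(offspring_dary(3), 6), "congruent to 1 mod 3")
})

test_that("conditioned GW at 7 vertices is uniform over the 5 ordered trees", {
  set.seed(101)
  X <- offspring_dary(2)
  codes <- vapply(1:20000, function(i) paste(sample_conditioned_gw(X, 7)$deg, collapse = ""), "")
  tab <- table(codes)
  expect_length(tab, 5L)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("conditioned GW agrees with the rejection-sampling oracle", {
  set.seed(103)
  X <- offspring_dary(2)
  reject_draw <- function() {
    repeat {
      t <- sample_gw(X, max_vertices = 1000)
      if (!is_gw_truncated(t) && length(t$deg) == 7L) return(t)
    }
  }
  c_fast <- vapply(1:3000, function(i) paste(sample_conditioned_gw(X, 7)$deg, collapse = ""), "")
  c_rej  <- vapply(1:3000, function(i) paste(reject_draw()$deg, collapse = ""), "")
  lev <- sort(unique(c(c_fast, c_rej)))
  m <- rbind(tabulate(match(c_fast, lev), length(lev)),
             tabulate(match(c_rej, lev), length(lev)))
  expect_gt(stats::chisq.test(m)$p.value, 1e-3)
})

test_that("general-support conditioned GW works by rejection on the sum", {
  set.seed(104)
  u <- offspring(0:2, c(1, 1, 1), 3)
  t <- sample_conditioned_gw(u, 10)
  expect_length(t$deg, 10L)
  expect_true(all(t$deg %in% 0:2))
})

test_that("uniform leaf-labelled sampler hits every class; n = 4 frequencies", {
  set.seed(105)
  expect_equal(sample_uniform_leaf_labelled(2)$n_leaves, 2L)
  expect_identical(canonical_code(sample_uniform_leaf_labelled(3)),
                   canonical_code(enumerate_all_unrooted(3)[[1]]))
  codes <- vapply(1:6000, function(i) canonical_code(sample_uniform_leaf_labelled(4)), "")
  tab <- table(codes)
  expect_length(tab, 3L)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
  expect_error(sample_uniform_leaf_labelled(5, d = 3), "divisible")
})

test_that("unconditioned GW realizations follow the product formula", {
  set.seed(106)
  X <- offspring_dary(2)
  reps <- 4000
  sizes <- integer(reps); cherries <- 0L
  for (r in seq_len(reps)) {
    t <- sample_gw(X, max_vertices = 5000)
    if (is_gw_truncated(t)) { sizes[r] <- NA_integer_; next }
    sizes[r] <- length(t$deg)
    expect_true(all(t$deg %in% X$support))
    if (identical(t$deg, c(2L, 0L, 0L))) cherries <- cherries + 1L
  }
  p1 <- mean(sizes == 1L, na.rm = TRUE)    # P(single vertex) = P(X=0) = 1/2
  se1 <- sqrt(0.5 * 0.5 / reps)
  expect_lt(abs(p1 - 0.5), 3 * se1)
  pc <- cherries / reps                    # P(cherry) = (1/2)^3 = 1/8
  sec <- sqrt(0.125 * 0.875 / reps)
  expect_lt(abs(pc - 0.125), 3 * sec)
})

test_that("every ordered binary tree with 7 vertices has GW probability (1/2)^7", {
  X <- offspring_dary(2)
  for (t in enumerate_all_ordered(4)) {
    p <- xrat(1, 1)
    for (dg in t$deg) {
      i <- match(dg, X$support)
      p <- p * xrat(X$num[i], X$den)
    }
    expect_true(p == xrat(1, 128))
  }
})

test_that("Yule-Harding trees: validity, exchangeable labels, root split", {
  set.seed(107)
  expect_equal(sample_yule_harding(2)$n_leaves, 2L)
  t <- sample_yule_harding(40)
  expect_s3_class(t, "lltree")
  r <- sample_yule_harding(40, keep_root = TRUE)
  expect_length(r$deg, 79L)
  # on 4 leaves the three labelled quartet topologies are equally likely
  codes <- vapply(1:6000, function(i) canonical_code(sample_yule_harding(4)), "")
  expect_gt(stats::chisq.test(table(codes))$p.value, 1e-3)
  # root split uniform on {1..n-1}
  ys <- yule_split_test(10, 5000, seed = 108)
  expect_gt(ys$p.value, 1e-3)
  # n = 3: two cells, each about 1/2
  ys3 <- yule_split_test(3, 5000, seed = 109)
  f <- ys3$counts / sum(ys3$counts)
  expect_lt(abs(f[1] - 0.5), 3 * sqrt(0.25 / 5000))
  expect_error(yule_split_test(2, 10, 1), "degenerate")
})

test_that("Kesten balls have the prescribed spine structure", {
  X <- offspring_dary(2)
  set.seed(110)
  k0 <- sample_kesten_ball(X, 0)
  expect_identical(k0$tree$deg, 0L)
  expect_identical(k0$spine, 1L)
  for (k in c(1, 3, 6)) {
    kb <- sample_kesten_ball(X, k)
    expect_identical(kb$spine_out, rep(2L, k))     # X* is a point mass at 2
    expect_identical(kb$S, seq_len(k))             # S_k = k(d-1) exactly
    expect_identical(treepatterns:::rotree_depth(kb$tree)[kb$spine], 0:k)
    expect_true(all(diff(kb$S) >= 0))
  }
  # non-critical law is refused
  expect_error(sample_kesten_ball(offspring(c(0L, 2L), c(1, 2), 3), 2), "critical")
  # general critical law: spine degrees drawn from the size-biased law
  u <- offspring(0:2, c(1, 1, 1), 3)
  kb <- sample_kesten_ball(u, 4)
  expect_true(all(kb$spine_out %in% 1:2))
})

test_that("identical seeds give identical draws", {
  set.seed(314); a1 <- sample_uniform_leaf_labelled(50)
  set.seed(314); a2 <- sample_uniform_leaf_labelled(50)
  expect_identical(canonical_code(a1), canonical_code(a2))
  set.seed(315); y1 <- sample_yule_harding(50, keep_root = TRUE)
  set.seed(315); y2 <- sample_yule_harding(50, keep_root = TRUE)
  expect_identical(y1$deg, y2$deg)
  set.seed(316); k1 <- sample_kesten_ball(offspring_dary(2), 4)
  set.seed(316); k2 <- sample_kesten_ball(offspring_dary(2), 4)
  expect_identical(k1$tree$deg, k2$tree$deg)
  expect_identical(child_seed(1, 1), child_seed(1, 1))
})
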