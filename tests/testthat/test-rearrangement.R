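# Signed circular permutation algebra and reversal distances.

test_that("canonicalization normalizes rotation and reflection and is idempotent", {
  expect_equal(as.integer(canonicalize(scperm(c(2, 3, 1)))), c(1L, 2L, 3L))
  expect_equal(as.integer(canonicalize(scperm(c(-3, -2, -1)))), c(1L, 2L, 3L))
  set.seed(11)
  for (t in 1:25) {
    p <- rand_scperm(sample(4:9, 1))
    c1 <- canonicalize(p)
    expect_identical(as.integer(canonicalize(c1)), as.integer(c1))
    # rotations and the reflection are all circularly equal to p
    v <- as.integer(p)
    k <- sample(length(v), 1)
    rot <- scperm(c(v[k:length(v)], v[seq_len(k - 1)][seq_len(k - 1) > 0]))
    expect_identical(as.integer(canonicalize(rot)), as.integer(c1))
    expect_identical(as.integer(canonicalize(scperm(rev(-v)))), as.integer(c1))
  }
  expect_error(scperm(c(1, 2, -2)), "duplicate")
  expect_error(scperm(c(1, 0, 2)), "non-zero")
})

test_that("an inversion is an involution and respects junction bounds", {
  set.seed(12)
  for (t in 1:25) {
    n <- sample(4:9, 1)
    p <- rand_scperm(n)
    ij <- rand_inversion(n)
    q <- apply_inversion(p, ij[1], ij[2])
    expect_identical(as.integer(apply_inversion(q, ij[1], ij[2])),
                     as.integer(p))
  }
  expect_error(apply_inversion(scperm(1:4), 2, 2))
  expect_error(apply_inversion(scperm(1:4), 0, 4))
})

test_that("reversal distance matches the BFS oracle exhaustively at n <= 4", {
  for (n in 3:4) {
    tab <- plastrearr:::oracle_table(n)
    for (k in ls(tab)) {
      p <- scperm(as.integer(strsplit(k, " ")[[1]]))
      expect_identical(reversal_distance(p, scperm(seq_len(n))), tab[[k]])
    }
  }
})

test_that("reversal distance handles the trivial and single-inversion cases", {
  p <- scperm(c(5, -2, 8, 1, -7, 3))
  expect_identical(reversal_distance(p, p), 0L)
  set.seed(13)
  for (t in 1:20) {
    n <- sample(4:10, 1)
    p <- rand_scperm(n)
    ij <- rand_inversion(n)
    expect_identical(reversal_distance(p, apply_inversion(p, ij[1], ij[2])), 1L)
  }
})

test_that("reversal distance is a metric on seeded random samples", {
  set.seed(14)
  for (t in 1:60) {
    n <- sample(4:8, 1)
    p <- rand_scperm(n); q <- rand_scperm(n); r <- rand_scperm(n)
    dpq <- reversal_distance(p, q)
    expect_identical(dpq, reversal_distance(q, p))
    expect_identical(reversal_distance(p, p), 0L)
    expect_gte(reversal_distance(p, r) + reversal_distance(r, q), dpq)
  }
})

test_that("BFS oracle is symmetric and refuses oversized inputs", {
  set.seed(15)
  for (t in 1:20) {
    p <- rand_scperm(5); q <- rand_scperm(5)
    expect_identical(bfs_distance_oracle(p, q), bfs_distance_oracle(q, p))
  }
  expect_error(bfs_distance_oracle(rand_scperm(9), rand_scperm(9)), "n <= ")
})

test_that("sorting scenarios are optimal and replay to the target", {
  set.seed(16)
  for (t in 1:40) {
    n <- sample(4:6, 1)
    p <- rand_scperm(n); q <- rand_scperm(n)
    sc <- sort_by_reversals(p, q)
    expect_identical(length(sc), as.integer(bfs_distance_oracle(p, q)))
    expect_identical(as.integer(canonicalize(apply_scenario(p, sc))),
                     as.integer(canonicalize(q)))
  }
  p <- scperm(c(3, 1, -2, 4))
  expect_length(sort_by_reversals(p, p), 0)
})

test_that("distance matrices are symmetric metrics with zero diagonal", {
  set.seed(17)
  src <- rand_scperm(8)
  perms <- list(a = apply_inversion(src, 1, 3),
                b = apply_inversion(src, 4, 6),
                c = apply_inversion(src, 2, 7))
  D <- distance_matrix(perms)
  expect_true(all(diag(D) == 0))
  expect_identical(D, t(D))
  expect_true(all(D[upper.tri(D)] <= 2))   # each leaf 1 step from src
  for (t in 1:40) {
    tri <- distance_matrix(list(rand_scperm(6), rand_scperm(6), rand_scperm(6)))
    expect_gte(tri[1, 2] + tri[2, 3], tri[1, 3])
  }
})

test_that("GRIMM permutation files round-trip", {
  perms <- list(alpha = scperm(c(1, -3, 2, 5, -4)),
                beta = scperm(c(-2, 1, 4, 3, 5)))
  path <- tempfile(fileext = ".txt")
  write_grimm(perms, path)
  back <- read_grimm(path)
  expect_identical(names(back), names(perms))
  expect_identical(lapply(back, as.integer), lapply(perms, as.integer))
})

test_that("mgr_tree recovers a planted star ancestor and honors topologies", {
  p <- scperm(1:6)
  star <- mgr_tree(list(a = p, b = p, c = p))
  expect_identical(star$total, 0L)

  set.seed(18)
  anc <- rand_scperm(10)
  leaves <- list(x = apply_inversion(anc, 1, 3),
                 y = apply_inversion(anc, 4, 6),
                 z = apply_inversion(anc, 7, 9))
  tr <- mgr_tree(leaves)
  expect_identical(tr$total, 3L)
  anc_nodes <- setdiff(names(tr$labels), tr$leaf_names)
  expect_true(any(vapply(anc_nodes, function(a)
    reversal_distance(tr$labels[[a]], anc) == 0L, logical(1))))

  # fixed topology on a quartet: total never exceeds the planted count,
  # nor the distance sum along any spanning path of the leaves
  q <- list(x = apply_inversion(anc, 1, 2), y = apply_inversion(anc, 3, 5),
            z = apply_inversion(anc, 6, 8), w = apply_inversion(anc, 2, 9))
  top <- ape::unroot(ape::read.tree(text = "((x,y),(z,w));"))
  tq <- mgr_tree(q, topology = top)
  expect_lte(tq$total, 4L)
  D <- distance_matrix(q)
  for (perm_order in list(1:4, c(2, 1, 3, 4), c(1, 3, 2, 4))) {
    path_len <- sum(D[cbind(perm_order[-4], perm_order[-1])])
    expect_lte(tq$total, path_len)
  }
  expect_identical(tq$edges$count,
                   vapply(seq_len(nrow(tq$edges)), function(r)
                     reversal_distance(tq$labels[[tq$edges$from[r]]],
                                       tq$labels[[tq$edges$to[r]]]),
                     integer(1)))
  expect_error(mgr_tree(list(p, p)), "at least 3")
})

test_that("newick export carries edge counts as branch lengths", {
  set.seed(19)
  anc <- rand_scperm(8)
  tr <- mgr_tree(list(a = apply_inversion(anc, 1, 3),
                      b = apply_inversion(anc, 4, 6),
                      c = apply_inversion(anc, 2, 7)))
  nwk <- write_rearr_newick(tr, tempfile(fileext = ".nwk"))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
  expect_identical(sum(phy$edge.length), as.numeric(tr$total))
})
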