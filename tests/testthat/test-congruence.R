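test_that("identical trees agree on every leaf", {
  set.seed(701)
  for (n in c(6, 10, 14)) {
    tr <- rtree_uniform(n)
    m <- mast(tr, tr)
    expect_equal(attr(m, "size"), n)
    expect_setequal(as.character(m), tr$tip.label)
  }
})

test_that("conflicting quartets agree on three leaves", {
  t1 <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  t2 <- ape::unroot(ape::read.tree(text = "((A,C),(B,D));"))
  expect_equal(mast_size(t1, t2), 3L)
  expect_equal(brute_mast_size(t1, t2), 3L)
})

test_that("DP size equals exhaustive subset enumeration on random pairs", {
  set.seed(702)
  for (i in 1:30) {
    n <- sample(5:8, 1)
    t1 <- rtree_uniform(n)
    t2 <- rtree_uniform(n)
    expect_equal(mast_size(t1, t2), brute_mast_size(t1, t2),
                 label = paste("pair", i, "n =", n))
  }
})

test_that("rooted MAST agrees with the marker-leaf construction", {
  # rooted agreement of (T1, T2) equals unrooted agreement of the trees
  # with an extra leaf attached at the root, minus that leaf
  set.seed(703)
  for (i in 1:10) {
    p <- random_tree_pair(8, seed = 700 + i, rooted = TRUE)
    # make the marker leaf sister to the whole rooted tree, i.e. attach
    # it on the root edge
    add_marker <- function(t) ape::read.tree(text = paste0(
      "(", sub(";$", "", ape::write.tree(t)), ",ZZROOT);"))
    a <- add_marker(p[[1]])
    b <- add_marker(p[[2]])
    um <- mast(ape::unroot(a), ape::unroot(b))
    rm <- mast_size(p[[1]], p[[2]])
    # the marked unrooted MAST restricted to sets containing the marker is
    # rm + 1; the unrestricted unrooted MAST can only be larger
    expect_gte(attr(um, "size"), rm + 1L)
    if ("ZZROOT" %in% as.character(um))
      expect_equal(attr(um, "size"), rm + 1L)
  }
})

test_that("mast is symmetric and invariant to joint relabelling", {
  set.seed(704)
  t1 <- rtree_uniform(10)
  t2 <- rtree_uniform(10)
  expect_equal(mast_size(t1, t2), mast_size(t2, t1))
  perm <- sample(paste0("x", 1:10))
  relab <- function(t) {
    t$tip.label <- perm[as.integer(sub("t", "", t$tip.label))]
    t
  }
  expect_equal(mast_size(relab(t1), relab(t2)), mast_size(t1, t2))
})

test_that("expected MAST is calibrated, monotone and below n", {
  expect_equal(expected_mast(14), 5.42, tolerance = 0.01)
  em <- expected_mast(4:64)
  expect_true(all(diff(em) > 0))
  expect_true(all(em < 4:64))
  expect_error(expected_mast(3), "n >= 4")
})

test_that("null calibration: mean MAST of random rooted pairs", {
  set.seed(705)
  sizes <- vapply(1:400, function(i) {
    p <- random_tree_pair(14, seed = 70000 + i, rooted = TRUE)
    mast_size(p[[1]], p[[2]])
  }, integer(1))
  expect_lt(abs(mean(sizes) - expected_mast(14)), 0.3)
})

test_that("icong increases and p decreases with MAST size", {
  em <- expected_mast(14)
  ic <- (5:14) / em
  expect_true(all(diff(ic) > 0))
  lp <- vapply(5:14, function(m)
    madevol:::.mast_null_log_p(m, 14), numeric(1))
  expect_true(all(diff(lp) < 0))
})

test_that("icong_test reports the shared-leaf restriction and inputs", {
  set.seed(706)
  t1 <- rtree_uniform(14)
  t2 <- rtree_uniform(14)
  res <- icong_test(t1, t2, labels = c("gene", "reference"))
  expect_equal(res$tree1, "gene")
  expect_equal(res$n, 14L)
  expect_equal(res$icong, res$mast_size / expected_mast(14))
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_equal(sort(res$mast_leaves[[1]]),
               sort(as.character(mast(t1, t2))))
})

test_that("self-congruence of a 14-leaf tree is maximally significant", {
  set.seed(707)
  tr <- rtree_uniform(14)
  res <- icong_test(tr, tr)
  expect_equal(res$mast_size, 14L)
  expect_equal(res$icong, 14 / expected_mast(14))
  expect_equal(res$icong, 2.58, tolerance = 0.01)
  expect_lt(res$p_value, 1.66e-6)
})

test_that("trees sharing too few leaves are rejected", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,B),(X,Y));")
  expect_error(suppressMessages(mast(t1, t2)), "fewer than 3")
})
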