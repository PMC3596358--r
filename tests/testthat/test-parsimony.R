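quartet <- function(newick) ape::read.tree(text = newick)

aln4 <- function(...) {
  seqs <- c(...)
  as_char_matrix(stats::setNames(seqs, c("t1", "t2", "t3", "t4")))
}

test_that("hand-checked Fitch scores on a quartet", {
  # pattern (A,A,C,C): 1 change on the matching split, 2 on the other
  d <- aln4("A", "A", "C", "C")
  expect_equal(fitch_score(quartet("((t1,t2),(t3,t4));"), d), 1L)
  expect_equal(fitch_score(quartet("((t1,t3),(t2,t4));"), d), 2L)
  # invariant site contributes 0
  d2 <- aln4("AG", "AG", "CG", "CG")
  expect_equal(fitch_score(quartet("((t1,t2),(t3,t4));"), d2), 1L)
})

test_that("Fitch score is invariant to rooting and taxon order", {
  set.seed(601)
  seqs <- stats::setNames(replicate(6, paste(
    sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")),
    paste0("t", 1:6))
  d <- as_char_matrix(seqs)
  tr <- rtree_uniform(6)
  s0 <- fitch_score(tr, d)
  for (tip in c("t1", "t4")) {
    rooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_score(rooted, d), s0)
  }
  d_perm <- as_char_matrix(seqs[sample(6)])
  expect_equal(fitch_score(tr, d_perm), s0)
})

test_that("leaf/taxa mismatch errors", {
  d <- aln4("A", "A", "C", "C")
  expect_error(fitch_score(quartet("((t1,t2),(t3,t9));"), d), "differ")
})

test_that("mp_search equals exhaustive search on small matrices", {
  set.seed(602)
  for (rep in 1:6) {
    n <- sample(5:6, 1)
    seqs <- stats::setNames(replicate(n, paste(
      sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")),
      paste0("t", 1:n))
    d <- as_char_matrix(seqs)
    res <- suppressWarnings(mp_search(d, n_starts = 5, seed = rep))
    all_tr <- phangorn::allTrees(n, rooted = FALSE,
                            tip.label = paste0("t", 1:n))
    best <- min(vapply(all_tr, fitch_score, integer(1), data = d))
    expect_equal(res$score, best)
  }
})

test_that("mp_search is deterministic under a seed and rejects tiny trees", {
  set.seed(603)
  seqs <- stats::setNames(replicate(6, paste(
    sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")),
    paste0("t", 1:6))
  d <- as_char_matrix(seqs)
  r1 <- suppressWarnings(mp_search(d, n_starts = 4, seed = 9))
  r2 <- suppressWarnings(mp_search(d, n_starts = 4, seed = 9))
  expect_equal(r1$score, r2$score)
  expect_equal(ape::write.tree(r1$best), ape::write.tree(r2$best))
  expect_error(mp_search(as_char_matrix(seqs[1:3]), seed = 1), "4 taxa")
})

test_that("clean clade signal bootstraps to 100 percent support", {
  # sites are perfect clade indicators -> every bipartition certain
  blocks <- c(a1 = "AAAA", a2 = "AAAA", b1 = "CCCC", b2 = "CCCC")
  sig1 <- c(a1 = "GGGG", a2 = "GGGG", b1 = "GGGG", b2 = "TTTT")
  seqs <- paste0(blocks, sig1,
                 c(a1 = "TTTT", a2 = "AAAA", b1 = "AAAA", b2 = "AAAA"))
  names(seqs) <- names(blocks)
  d <- as_char_matrix(seqs)
  bs <- suppressWarnings(mp_bootstrap(d, n_reps = 20, seed = 2))
  sup <- bs$tree$node.label
  expect_true(all(sup[!is.na(sup) & sup != ""] == 100))
})

test_that("consensus is compatible with majority clades of replicates", {
  sim <- simulate_dataset(sim_config_mad1(seed = 77, orf_codons = 120L))
  d <- as_char_matrix(subset(sim$aligned, region == "orf"))
  bs <- suppressWarnings(mp_bootstrap(d, n_reps = 15, seed = 3))
  cons <- bs$consensus
  # every clade in the majority-rule consensus appears in > 50% of reps
  freqs <- ape::prop.clades(cons, bs$replicates, rooted = FALSE)
  freqs[is.na(freqs)] <- 0
  expect_true(all(freqs / length(bs$replicates) > 0.5 - 1e-9))
})

test_that("gap policies differ when gaps are informative", {
  seqs <- c(t1 = "A---A", t2 = "A---A", t3 = "AGGGA", t4 = "AGGGA")
  d_missing <- as_char_matrix(seqs, gap_policy = "missing")
  d_fifth <- as_char_matrix(seqs, gap_policy = "fifth")
  tr <- quartet("((t1,t2),(t3,t4));")
  expect_lte(fitch_score(tr, d_missing), fitch_score(tr, d_fifth))
  expect_equal(fitch_score(tr, d_fifth), 3L)
})

test_that("protein matrices score under Fitch as unordered states", {
  seqs <- c(t1 = "MKLV", t2 = "MKLV", t3 = "MRLV", t4 = "MRLV")
  d <- as_char_matrix(seqs, type = "aa")
  expect_equal(fitch_score(quartet("((t1,t2),(t3,t4));"), d), 1L)
})
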