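test_that("the generator is fully deterministic under a seed", {
  s1 <- simulate_dataset(sim_config(seed = 1001, orf_codons = 80L))
  s2 <- simulate_dataset(sim_config(seed = 1001, orf_codons = 80L))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$aligned, s2$aligned)
  s3 <- simulate_dataset(sim_config(seed = 1002, orf_codons = 80L))
  expect_false(identical(s1$records$sequence, s3$records$sequence))
})

test_that("zero-length branches give identical isolates", {
  tr <- sim_default_tree()
  tr$edge.length[] <- 0
  sim <- simulate_dataset(sim_config(seed = 1003, tree = tr,
                                     orf_codons = 60L,
                                     motif_events = list(),
                                     repeat_counts = c(default = 4L)))
  orfs <- sim$records[sim$records$region == "orf", ]
  expect_equal(length(unique(orfs$sequence)), 1L)
  m <- build_divergence_matrix(orfs)
  expect_true(all(m$values == 0))
})

test_that("omega = 0 produces exclusively synonymous ORF divergence", {
  sim <- simulate_dataset(sim_config(seed = 1004, omega = 0,
                                     orf_codons = 150L,
                                     motif_events = list()))
  orfs <- sim$records[sim$records$region == "orf", ]
  # all proteins of equal repeat count are identical
  by_count <- split(orfs$sequence,
                    sim$truth$repeat_counts[orfs$species])
  for (grp in by_count) {
    ps <- unique(vapply(grp, translate_orf, ""))
    expect_equal(length(ps), 1L)
  }
})

test_that("divergence grows monotonically with branch scaling", {
  base <- sim_default_tree()
  means <- vapply(c(0.5, 1, 2), function(sc) {
    tr <- base
    tr$edge.length <- tr$edge.length * sc
    sim <- simulate_dataset(sim_config(seed = 1005, tree = tr,
                                       orf_codons = 100L,
                                       motif_events = list()))
    orfs <- sim$records[sim$records$region == "orf", ]
    overall_interspecies_mean(build_divergence_matrix(orfs))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("inconsistent motif events are rejected", {
  ev <- list(list(species = "M. majus", element = "PDS", action = "loss",
                  upstream_pos = -109L))
  expect_error(simulate_dataset(sim_config(seed = 1, motif_events = ev)),
               "absent element")
  ev2 <- list(list(species = "M. nonesuch", element = "STRE",
                   action = "loss", upstream_pos = -109L))
  expect_error(simulate_dataset(sim_config(seed = 1, motif_events = ev2)),
               "unknown species")
})

test_that("random unrooted quartets are uniform over the 3 topologies", {
  set.seed(1006)
  refs <- c("((t1,t2),(t3,t4));", "((t1,t3),(t2,t4));",
            "((t1,t4),(t2,t3));")
  ref_trees <- lapply(refs, function(x) ape::read.tree(text = x))
  counts <- integer(3)
  for (i in 1:1500) {
    tr <- rtree_uniform(4)
    k <- which(vapply(ref_trees, function(r)
      suppressWarnings(phangorn::RF.dist(ape::unroot(r), tr)) == 0,
      logical(1)))
    counts[k] <- counts[k] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("random_tree_pair is seed-reproducible and independent-ish", {
  p1 <- random_tree_pair(14, seed = 7)
  p2 <- random_tree_pair(14, seed = 7)
  expect_equal(ape::write.tree(p1[[1]]), ape::write.tree(p2[[1]]))
  expect_equal(ape::write.tree(p1[[2]]), ape::write.tree(p2[[2]]))
  expect_error(random_tree_pair(3, seed = 1), "n >= 4")
})

test_that("a clean simulated alignment recovers the generating topology", {
  cfg <- sim_config(seed = 1007, tree = recovery_tree(),
                    species_map = recovery_species_map(),
                    orf_codons = 400L, omega = 0.31,
                    motif_events = list(),
                    repeat_counts = c(default = 4L))
  sim <- simulate_dataset(cfg)
  d <- as_char_matrix(sim$aligned[sim$aligned$region == "orf", ])
  mp <- suppressWarnings(mp_search(d, n_starts = 5, seed = 1))
  expect_equal(suppressWarnings(
    phangorn::RF.dist(mp$best, ape::unroot(recovery_tree()))), 0)
})

test_that("two loci on the same tree are significantly congruent", {
  cfg1 <- sim_config(seed = 1008, tree = recovery_tree(),
                     species_map = recovery_species_map(),
                     orf_codons = 300L, motif_events = list(),
                     repeat_counts = c(default = 4L))
  cfg2 <- sim_config(seed = 1009, tree = recovery_tree(),
                     species_map = recovery_species_map(),
                     orf_codons = 300L, motif_events = list(),
                     repeat_counts = c(default = 4L))
  al1 <- simulate_dataset(cfg1)$aligned
  al2 <- simulate_dataset(cfg2)$aligned
  t1 <- suppressWarnings(mp_search(
    as_char_matrix(al1[al1$region == "orf", ]), seed = 1)$best)
  t2 <- suppressWarnings(mp_search(
    as_char_matrix(al2[al2$region == "orf", ]), seed = 2)$best)
  res <- suppressWarnings(icong_test(t1, t2))
  expect_gt(res$icong, 1.5)
  expect_lt(res$p_value, 0.01)
})
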