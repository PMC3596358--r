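make_records <- function(seqs, species = NULL) {
  tibble::tibble(
    isolate = names(seqs),
    species = if (is.null(species)) names(seqs) else species,
    locus = "Mad2", region = "orf",
    sequence = unname(seqs))
}

test_that("identical sequences give an all-zero matrix", {
  s <- strrep("ACGT", 25)
  m <- build_divergence_matrix(make_records(c(a = s, b = s, c = s)))
  expect_true(all(m$values == 0))
})

test_that("one substitution in 100 sites gives 1.0 percent", {
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 99), "C")
  m <- build_divergence_matrix(make_records(c(x = a, y = b)))
  expect_equal(m$values["x", "y"], 1.0)
})

test_that("matrix entries equal independent per-pair recomputation", {
  set.seed(401)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                             collapse = ""))
  names(seqs) <- paste0("i", 1:5)
  m <- build_divergence_matrix(make_records(seqs))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m$values[i, j],
                 pairwise_divergence(seqs[i], seqs[j]))
    expect_equal(m$values[i, j], m$values[j, i])
  }
  expect_true(all(diag(m$values) == 0))
})

test_that("duplicate isolates and mixed regions are rejected", {
  r <- make_records(c(a = "ACGT", b = "ACGT"))
  r$isolate <- c("a", "a")
  expect_error(build_divergence_matrix(r), "duplicate")
  r2 <- make_records(c(a = "ACGT", b = "ACGT"))
  r2$region <- c("orf", "promoter")
  expect_error(build_divergence_matrix(r2), "mix")
})

# a divergence matrix with hand-set values for the summary operations
hand_matrix <- function() {
  v <- matrix(0, 3, 3, dimnames = list(c("a1", "a2", "b1"),
                                       c("a1", "a2", "b1")))
  v["a1", "b1"] <- v["b1", "a1"] <- 2
  v["a2", "b1"] <- v["b1", "a2"] <- 4
  v["a1", "a2"] <- v["a2", "a1"] <- 1
  structure(list(values = v, isolates = rownames(v),
                 species = c(a1 = "A", a2 = "A", b1 = "B"),
                 locus = "Mad1", region = "orf", mode = "include_gaps"),
            class = "divergence_matrix")
}

test_that("interspecies mean averages cross-species pairs", {
  m <- hand_matrix()
  expect_equal(interspecies_mean(m, "A", "B"), 3)
  expect_error(interspecies_mean(m, "A", "C"), "not in matrix")
  expect_error(interspecies_mean(m, "A", "A"), "intraspecies")
})

test_that("overall interspecies mean has both aggregation modes", {
  m <- hand_matrix()
  # two species: both modes agree with the single species-pair mean
  expect_equal(overall_interspecies_mean(m), 3)
  expect_equal(overall_interspecies_mean(m, "isolate_pairs"), 3)

  # three species with pair means 2, 4, 6 average to 4
  v <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  v["x", "y"] <- v["y", "x"] <- 2
  v["x", "z"] <- v["z", "x"] <- 4
  v["y", "z"] <- v["z", "y"] <- 6
  m3 <- structure(list(values = v, isolates = rownames(v),
                       species = c(x = "X", y = "Y", z = "Z"),
                       locus = "Mad1", region = "orf",
                       mode = "include_gaps"),
                  class = "divergence_matrix")
  expect_equal(overall_interspecies_mean(m3), 4)
})

test_that("intraspecies mean handles singleton species with a flag", {
  m <- hand_matrix()
  expect_equal(intraspecies_mean(m, "A"), 1)
  expect_warning(v <- intraspecies_mean(m, "B"), "fewer than 2")
  expect_true(is.na(v))
})

test_that("extreme pair is the argmax with lexicographic tie-break", {
  m <- hand_matrix()
  ex <- extreme_pair(m)
  expect_equal(ex$isolate_a, "a2")
  expect_equal(ex$isolate_b, "b1")
  expect_equal(ex$divergence, 4)
  exi <- extreme_pair(m, "intraspecies")
  expect_equal(exi$divergence, 1)
})

test_that("overall mean lies within the range of species-pair means", {
  set.seed(402)
  for (rep in 1:5) {
    n <- 8
    sp <- sample(c("A", "B", "C"), n, TRUE)
    while (length(unique(sp)) < 3) sp <- sample(c("A", "B", "C"), n, TRUE)
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- runif(n * (n - 1) / 2, 0, 30)
    v <- v + t(v)
    ids <- paste0("i", 1:n)
    dimnames(v) <- list(ids, ids)
    m <- structure(list(values = v, isolates = ids,
                        species = stats::setNames(sp, ids),
                        locus = "L", region = "orf",
                        mode = "include_gaps"),
                   class = "divergence_matrix")
    pairs <- utils::combn(c("A", "B", "C"), 2, simplify = FALSE)
    pm <- vapply(pairs, function(p) interspecies_mean(m, p[1], p[2]),
                 numeric(1))
    ov <- overall_interspecies_mean(m)
    expect_gte(ov, min(pm) - 1e-12)
    expect_lte(ov, max(pm) + 1e-12)
    # exhaustive enumeration oracle for each species-pair mean
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      vals <- c()
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if ((sp[i] == p[1] && sp[j] == p[2]) ||
            (sp[i] == p[2] && sp[j] == p[1]))
          vals <- c(vals, v[i, j])
      }
      expect_equal(pm[k], mean(vals))
    }
  }
})

test_that("tidy() returns one row per unordered pair", {
  m <- hand_matrix()
  td <- tidy(m)
  expect_equal(nrow(td), 3L)
  expect_setequal(td$comparison, c("intraspecies", "interspecies"))
})
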