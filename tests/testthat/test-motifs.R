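test_that("coordinates count upstream from the base before the ATG", {
  p <- paste0("AGGGG", strrep("N", 100))
  h <- scan_promoter(p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$element, "STRE")
  expect_equal(h$upstream_pos, -105L)
})

test_that("maximal TATG runs merge into one hit with a repeat count", {
  p <- paste0(strrep("C", 50), strrep("TATG", 5), strrep("C", 50))
  h <- scan_promoter(p)
  h <- h[h$element == "TATG_repeat", ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$repeat_count, 5L)
  # run starts at base 51 of a 120 bp promoter -> upstream position -70
  expect_equal(h$upstream_pos, -70L)
})

test_that("all four elements are found with exact positions", {
  L <- 800L
  x <- rep("C", L)
  put <- function(x, up, txt) {
    s <- L + up + 1L
    x[s:(s + nchar(txt) - 1L)] <- strsplit(txt, "")[[1]]
    x
  }
  x <- put(x, -604L, strrep("TATG", 5))
  x <- put(x, -300L, "AGGGG")
  x <- put(x, -266L, "TACATA")
  x <- put(x, -109L, "AAGGGA")
  h <- scan_promoter(paste(x, collapse = ""))
  expect_equal(h$upstream_pos[h$element == "TATG_repeat"], -604L)
  expect_equal(h$repeat_count[h$element == "TATG_repeat"], 5L)
  expect_equal(h$upstream_pos[h$element == "STRE"], -300L)
  expect_equal(h$upstream_pos[h$element == "TATA_like"], -266L)
  expect_equal(h$upstream_pos[h$element == "PDS"], -109L)
})

test_that("prepending sequence shifts every coordinate by its length", {
  set.seed(801)
  base <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  base <- paste0(substr(base, 1, 120), "AAGGGA", "AGGGG", "TACATA",
                 substr(base, 133, 300))
  h0 <- scan_promoter(base)
  h1 <- scan_promoter(paste0(strrep("C", 37), base))
  expect_equal(nrow(h0), nrow(h1))
  expect_equal(h1$upstream_pos, h0$upstream_pos)
  expect_equal(h1$start, h0$start + 37L)
})

test_that("re-scanning is deterministic and region is enforced", {
  p <- paste0(strrep("AGGGGG", 3), strrep("C", 30))
  expect_identical(scan_promoter(p), scan_promoter(p))
  rec <- tibble::tibble(isolate = "x", species = "s", locus = "Mad2",
                        region = "orf", sequence = p)
  expect_error(scan_promoter(rec), "promoter")
})

test_that("overlapping same-element matches collapse to the 5'-most", {
  # AGGGGG contains AGGGG at two offsets; one hit survives, at the first
  p <- paste0(strrep("C", 20), "AGGGGG", strrep("C", 20))
  h <- scan_promoter(p)
  h <- h[h$element == "STRE", ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 21L)
})

test_that("species motif table separates conservation from variation", {
  sm <- tibble::tibble(isolate = c("r1", "r2", "b1", "b2"),
                       species = c("R", "R", "B", "B"))
  mk <- function(with_tacata) {
    base <- strrep("C", 200)
    if (with_tacata)
      paste0(substr(base, 1, 100), "TACATA", substr(base, 107, 200))
    else base
  }
  recs <- tibble::tibble(
    isolate = sm$isolate, species = sm$species, locus = "Mad2",
    region = "promoter",
    sequence = c(mk(TRUE), mk(TRUE), mk(FALSE), mk(FALSE)))
  hits <- scan_promoters(recs)
  tab <- compare_motif_tables(hits, sm, isolates = sm$isolate)
  r <- tab[tab$species == "R" & tab$element == "TATA_like", ]
  b <- tab[tab$species == "B" & tab$element == "TATA_like", ]
  expect_equal(r$n_with_element, 2L)
  expect_equal(b$n_with_element, 0L)
  expect_true(all(tab$conserved))

  # intraspecies variation is flagged as not conserved
  recs$sequence[2] <- mk(FALSE)
  tab2 <- compare_motif_tables(scan_promoters(recs), sm,
                               isolates = sm$isolate)
  r2 <- tab2[tab2$species == "R" & tab2$element == "TATA_like", ]
  expect_false(r2$conserved)
})

test_that("simulated motif layouts are recovered exactly", {
  sim <- simulate_dataset(sim_config(seed = 802))
  proms <- sim$records[sim$records$region == "promoter", ]
  hits <- scan_promoters(proms)
  layouts <- sim$truth$motif_layouts
  for (iso in proms$isolate) {
    sp <- proms$species[proms$isolate == iso]
    lay <- layouts[[sp]]
    h <- hits[hits$isolate == iso, ]
    for (k in seq_len(nrow(lay))) {
      hk <- h[h$element == lay$element[k] &
                h$upstream_pos == lay$upstream_pos[k], ]
      expect_equal(nrow(hk), 1L,
                   label = paste(iso, lay$element[k], lay$upstream_pos[k]))
      if (lay$element[k] == "TATG_repeat")
        expect_equal(hk$repeat_count, lay$count[k])
    }
  }
})
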