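# Maximum-parsimony inference: Fitch scoring, random-addition starts with
# SPR hill climbing, nonparametric bootstrap and majority-rule consensus.
# The heavy lifting is delegated to phangorn (the R counterpart of the
# PHYLIP dnapars/protpars family); this module fixes the search protocol
# (10 random-addition replicates, SPR swapping, seeded reproducibility)
# and the gap policy.

#' Build a parsimony character matrix
#'
#' @param x aligned sequences: a record tibble (equal-length `sequence`
#'   strings) or a named character vector.
#' @param type `"dna"` or `"aa"`.
#' @param gap_policy `"missing"` (gaps treated as missing data, the
#'   dnapars-style default) or `"fifth"` (gap as an extra character
#'   state).
#' @return a `phangorn::phyDat` object.
#' @export
as_char_matrix <- function(x, type = c("dna", "aa"),
                           gap_policy = c("missing", "fifth")) {
  type <- match.arg(type)
  gap_policy <- match.arg(gap_policy)
  if (is.data.frame(x)) x <- stats::setNames(x$sequence, x$isolate)
  stopifnot(length(x) >= 2L, !anyDuplicated(names(x)))
  lens <- nchar(x)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned (unequal lengths: ",
         paste(range(lens), collapse = "-"), ")")
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  if (gap_policy == "missing") {
    if (type == "dna") {
      m[m == "-"] <- "N"
      phangorn::phyDat(m, type = "DNA")
    } else {
      m[m == "-"] <- "X"
      phangorn::phyDat(m, type = "AA")
    }
  } else {
    levels <- if (type == "dna") c("A", "C", "G", "T", "-")
      else c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
    amb <- if (type == "dna") "N" else "X"
    m[!m %in% levels] <- amb
    phangorn::phyDat(m, type = "USER", levels = levels, ambiguity = amb)
  }
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of character changes the tree requires, summed over
#' sites (weighted by site pattern weights); invariant to rooting and
#' taxon order.
#'
#' @param tree an `ape::phylo`.
#' @param data a `phyDat` from [as_char_matrix()].
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, data) {
  taxa <- names(data)
  if (!setequal(tree$tip.label, taxa))
    stop("tree leaves and matrix taxa differ: ",
         paste(c(setdiff(tree$tip.label, taxa),
                 setdiff(taxa, tree$tip.label)), collapse = ", "))
  as.integer(phangorn::parsimony(tree, data, method = "fitch"))
}

#' Maximum-parsimony search
#'
#' For each random-addition start, stepwise addition builds a tree which
#' is then hill-climbed with subtree-pruning-and-regrafting (SPR) until no
#' rearrangement improves the score; all distinct equally-best trees found
#' across starts are returned.  Reproducible for a given seed.
#'
#' @param data a `phyDat` from [as_char_matrix()].
#' @param n_starts number of random-addition replicates (default 10).
#' @param seed integer seed.
#' @return list of class `mp_result`: `trees` (a `multiPhylo` of the
#'   equally-best trees, unrooted), `best` (first best tree), `score`.
#' @export
mp_search <- function(data, n_starts = 10L, seed = 1L) {
  if (length(data) < 4L) stop("need at least 4 taxa")
  set.seed(seed)
  best_trees <- list()
  best_score <- Inf
  for (i in seq_len(n_starts)) {
    t0 <- phangorn::random.addition(data)
    tr <- suppressMessages(
      phangorn::optim.parsimony(t0, data, method = "fitch",
                                rearrangements = "SPR", trace = 0))
    sc <- phangorn::parsimony(tr, data, method = "fitch")
    tr <- ape::unroot(tr)
    if (sc < best_score) {
      best_score <- sc
      best_trees <- list(tr)
    } else if (sc == best_score) {
      dup <- any(vapply(best_trees, function(b)
        suppressWarnings(phangorn::RF.dist(b, tr)) == 0, logical(1)))
      if (!dup) best_trees <- c(best_trees, list(tr))
    }
  }
  trees <- best_trees
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, best = best_trees[[1]],
                 score = as.integer(best_score)),
            class = "mp_result")
}

#' @export
print.mp_result <- function(x, ...) {
  cat("Maximum parsimony:", length(x$trees), "best tree(s), score",
      x$score, "\n")
  invisible(x)
}

#' Nonparametric parsimony bootstrap
#'
#' Resamples alignment columns with replacement `n_reps` times, runs
#' [mp_search()] on each pseudoreplicate, and maps bipartition support
#' percentages onto the best tree from the full data; also returns the
#' majority-rule consensus of the replicate trees.
#'
#' @param data a `phyDat`.
#' @param n_reps bootstrap pseudoreplicates (the reference protocol uses
#'   1000; reduced runs trade support precision for time roughly as a
#'   binomial standard error).
#' @param seed integer seed.
#' @param n_starts random-addition starts per replicate (fewer than the
#'   full search is customary).
#' @return list of class `mp_bootstrap`: `tree` (best full-data tree with
#'   `node.label` percent supports), `consensus` (majority rule),
#'   `replicates` (`multiPhylo`), `score`.
#' @export
mp_bootstrap <- function(data, n_reps = 100L, seed = 1L, n_starts = 2L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (length(data) < 4L) stop("need at least 4 taxa")
  full <- mp_search(data, n_starts = max(10L, n_starts), seed = seed)
  m <- as.character(data)
  nsite <- ncol(m)
  set.seed(seed + 1L)
  reps <- purrr::map(seq_len(n_reps), function(r) {
    cols <- sample.int(nsite, nsite, replace = TRUE)
    md <- m[, cols, drop = FALSE]
    pd <- phangorn::phyDat(md, type = attr(data, "type") %||% "DNA",
                           levels = attr(data, "levels"))
    mp_search(pd, n_starts = n_starts, seed = seed + r)$best
  })
  class(reps) <- "multiPhylo"
  best <- full$best
  counts <- ape::prop.clades(best, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  best$node.label <- round(100 * counts / n_reps)
  cons <- ape::consensus(reps, p = 0.5)
  structure(list(tree = best, consensus = cons, replicates = reps,
                 score = full$score),
            class = "mp_bootstrap")
}

#' @export
print.mp_bootstrap <- function(x, ...) {
  cat("MP bootstrap:", length(x$replicates), "replicates; score",
      x$score, "\n")
  invisible(x)
}
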