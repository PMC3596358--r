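# Independent brute-force oracles used to validate the dynamic programmes.
# These deliberately avoid the package's own algorithms: subsets are
# enumerated, pathways permuted, and alignments recursed explicitly.

# exhaustive MAST of two unrooted trees: largest leaf subset on which the
# restricted topologies coincide (RF distance 0; any 3-leaf unrooted
# topology is trivially shared)
brute_mast_size <- function(t1, t2) {
  labs <- t1$tip.label
  n <- length(labs)
  for (k in n:4) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      a <- ape::keep.tip(t1, labs[s])
      b <- ape::keep.tip(t2, labs[s])
      if (suppressWarnings(phangorn::RF.dist(ape::unroot(a),
                                             ape::unroot(b))) == 0)
        return(k)
    }
  }
  3L
}

# exhaustive Nei-Gojobori difference counts for one codon pair: enumerate
# every ordering of the differing positions, step through intermediates,
# drop orderings that visit a stop codon, average the rest
brute_ng_diffs <- function(ca, cb) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  perm <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm(v[-i]), function(r) c(v[i], r))))
  }
  res <- list()
  for (ord in perm(pos)) {
    cur <- ca; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) res[[length(res) + 1L]] <- c(sd = sd, nd = nd)
  }
  if (length(res) == 0L) return(NULL)  # caller decides on the fallback
  colMeans(do.call(rbind, res))
}

# brute-force optimal global alignment score with affine gaps (penalty for
# a gap of length L is open + L * extend), by recursion over edit moves
brute_nw_score <- function(a, b, match = 5, mismatch = -4, open = 10,
                           extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {
      pen <- if (prev == "u") extend else open + extend
      best <- max(best, -pen + rec(i + 1, j, "u"))
    }
    if (j <= length(cb)) {
      pen <- if (prev == "l") extend else open + extend
      best <- max(best, -pen + rec(i, j + 1, "l"))
    }
    best
  }
  rec(1, 1, "m")
}

# random sense-codon sequence (no stops)
random_orf <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# a clean 8-taxon tree with informative internal branches, for
# topology-recovery checks
recovery_tree <- function() {
  ape::read.tree(text = paste0(
    "(((a1:0.02,a2:0.02):0.04,(b1:0.02,b2:0.02):0.04):0.04,",
    "((c1:0.02,c2:0.02):0.04,(d1:0.02,d2:0.02):0.04):0.04);"))
}

recovery_species_map <- function() {
  tibble::tibble(
    isolate = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    species = rep(c("sp. a", "sp. b", "sp. c", "sp. d"), each = 2),
    clade = "other")
}
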