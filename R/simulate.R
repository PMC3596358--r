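# Seeded synthetic-data generator emulating a 14-isolate, 7-species
# Metarhizium adhesin dataset: a known isolate tree, an in-frame ORF
# partition with controllable dN/dS, a faster-evolving promoter partition
# carrying transcriptional elements, and species-specific tandem-repeat
# arrays in the "domain B" region of the protein.

#' Default isolate tree for the simulated panel
#'
#' Fourteen isolates in seven species arranged as in the *Metarhizium*
#' species complex: a PARB clade (*M. robertsii*, *M. pingshaense*,
#' *M. brunneum*), an MGT clade (*M. guizhouense*, *M. majus*), and the
#' more distant *M. lepidiotae* and *M. acridum* lineages.  Branch lengths
#' are expected neutral substitutions per site, chosen so that realized
#' open-reading-frame divergences fall in the few-percent range within
#' clades and around 15% against *M. acridum*.
#'
#' @return an `ape::phylo` with 14 tips.
#' @export
sim_default_tree <- function() {
  rob5 <- paste0("((HKB1-1b:0.002,B18-ai:0.002):0.001,(M31-ai:0.002,",
                 "(G90-bi:0.0015,ARSEF_2575:0.0015):0.0008):0.001)")
  parb <- paste0("((", rob5, ":0.017,ARSEF_439:0.022):0.008,",
                 "(43a-2i:0.002,G55-ai:0.002):0.028)")
  mgt <- paste0("(((B34-aiii:0.002,B77-ai:0.002):0.030,ARSEF_6238:0.032)",
                ":0.012,ARSEF_1914:0.030)")
  core <- paste0("((", parb, ":0.022,", mgt, ":0.022):0.025,",
                 "ARSEF_7488:0.085)")
  ape::read.tree(text = paste0("(", core, ":0.040,ARSEF_7486:0.240);"))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults emulate a
#' *Mad2*-like locus: omega 0.31 (purifying selection), a promoter evolving
#' 1.3x faster than the synonymous rate so promoter divergence exceeds ORF
#' divergence for every species pair, a Thr-rich 12-mer tandem-repeat array
#' with eight copies in *M. acridum* versus six elsewhere, and a
#' species-structured promoter element layout (STRE/PDS/TACATA/TATG
#' arrays).  `sim_config_mad1()` and `sim_config_ef1a()` derive the
#' *Mad1*-like (omega 0.20, uniform promoter elements) and neutral
#' reference-locus variants.
#'
#' @param seed integer seed; fully determines the dataset.
#' @param tree isolate tree (`phylo`, branch lengths in expected neutral
#'   substitutions/site).
#' @param species_map species map tibble covering the tree's tips.
#' @param locus locus label stamped on the records.
#' @param orf_codons ORF length in codons including start and stop but
#'   excluding the repeat array.
#' @param promoter_len promoter length in bp (about 800 in the emulated
#'   data).
#' @param omega target dN/dS of the ORF.
#' @param kappa transition/transversion rate ratio of the proposal process.
#' @param promoter_rate_mult promoter rate relative to the synonymous
#'   (neutral) rate.
#' @param repeat_unit amino-acid repeat unit inserted in the ORF.
#' @param repeat_counts named integer vector of repeat copies per species;
#'   unnamed default applies to species not listed.
#' @param repeat_at codon index at which the repeat array is inserted;
#'   `NULL` places it mid-ORF.
#' @param motif_ancestral ancestral promoter element layout (tibble with
#'   `element`, `upstream_pos`, `count`).
#' @param motif_events list of per-species element events; each entry is a
#'   list with `species` (species name or clade label), `element`, `action`
#'   (`"gain"`, `"loss"`, `"replace"`, `"set_count"`), and optionally
#'   `with`, `upstream_pos`, `count`.
#' @param coding if `FALSE`, simulate a single neutral nucleotide region
#'   (used for the EF-1alpha-like reference locus) instead of
#'   promoter + ORF.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tree = sim_default_tree(),
                       species_map = metarhizium_species_map(),
                       locus = "Mad2",
                       orf_codons = 300L,
                       promoter_len = 800L,
                       omega = 0.31,
                       kappa = 1,
                       promoter_rate_mult = 1.3,
                       repeat_unit = "GKETTPAQQTTP",
                       repeat_counts = c("M. acridum" = 8L, default = 6L),
                       repeat_at = NULL,
                       motif_ancestral = sim_default_motifs(),
                       motif_events = sim_default_motif_events(),
                       coding = TRUE) {
  stopifnot(is.numeric(seed), orf_codons >= 10L || !coding,
            promoter_len > 50L, omega >= 0, kappa > 0,
            promoter_rate_mult > 0)
  if (is.null(repeat_at)) repeat_at <- max(2L, orf_codons %/% 2L)
  if (coding && (repeat_at < 2L || repeat_at > orf_codons - 2L))
    stop("repeat_at must lie inside the ORF (2..orf_codons-2)")
  if (!all(tree$tip.label %in% species_map$isolate))
    stop("tree tips missing from species map: ",
         paste(setdiff(tree$tip.label, species_map$isolate), collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  structure(list(seed = as.integer(seed), tree = tree,
                 species_map = species_map, locus = locus,
                 orf_codons = as.integer(orf_codons),
                 promoter_len = as.integer(promoter_len),
                 omega = omega, kappa = kappa,
                 promoter_rate_mult = promoter_rate_mult,
                 repeat_unit = repeat_unit,
                 repeat_counts = repeat_counts,
                 repeat_at = as.integer(repeat_at),
                 motif_ancestral = motif_ancestral,
                 motif_events = motif_events,
                 coding = coding),
            class = "sim_config")
}

#' @rdname sim_config
#' @param ... overrides passed on to [sim_config()].
#' @export
sim_config_mad1 <- function(seed = 1L, orf_codons = 500L, omega = 0.20,
                            promoter_rate_mult = 1.1,
                            motif_events = list(), ...) {
  sim_config(seed = seed, locus = "Mad1", orf_codons = orf_codons,
             omega = omega, promoter_rate_mult = promoter_rate_mult,
             motif_events = motif_events, ...)
}

#' @rdname sim_config
#' @export
sim_config_ef1a <- function(seed = 1L, promoter_len = 1000L,
                            promoter_rate_mult = 1, ...) {
  sim_config(seed = seed, locus = "EF1a", coding = FALSE,
             promoter_len = promoter_len,
             promoter_rate_mult = promoter_rate_mult,
             motif_ancestral = sim_empty_motifs(), motif_events = list(),
             ...)
}

#' @rdname sim_config
#' @export
sim_default_motifs <- function() {
  tibble::tribble(
    ~element,      ~upstream_pos, ~count,
    "TATG_repeat", -604L,         1L,
    "STRE",        -300L,         1L,
    "TATA_like",   -266L,         1L,
    "STRE",        -109L,         1L
  )
}

#' @rdname sim_config
#' @export
sim_empty_motifs <- function() {
  tibble::tibble(element = character(), upstream_pos = integer(),
                 count = integer())
}

#' @rdname sim_config
#' @export
sim_default_motif_events <- function() {
  list(
    list(species = "M. robertsii", element = "STRE", action = "replace",
         upstream_pos = -109L, with = "PDS"),
    list(species = "M. acridum", element = "STRE", action = "replace",
         upstream_pos = -109L, with = "PDS"),
    list(species = "M. robertsii", element = "TATG_repeat",
         action = "set_count", upstream_pos = -604L, count = 5L),
    list(species = "M. pingshaense", element = "TATG_repeat",
         action = "set_count", upstream_pos = -604L, count = 3L),
    list(species = "M. lepidiotae", element = "TATG_repeat",
         action = "set_count", upstream_pos = -604L, count = 2L),
    list(species = "M. brunneum", element = "TATG_repeat", action = "loss",
         upstream_pos = -604L),
    list(species = "M. acridum", element = "TATA_like", action = "loss",
         upstream_pos = -266L),
    list(species = "M. lepidiotae", element = "TATA_like", action = "loss",
         upstream_pos = -266L)
  )
}

# motif pattern definitions shared with the scanner
.motif_patterns <- c(STRE = "AGGGG", PDS = "AAGGGA", TATA_like = "TACATA",
                     TATG_repeat = "TATG")

.codon_table <- function() {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc
}

.random_codons <- function(n, gc) {
  sense <- names(gc)[gc != "*"]
  sample(sense, n, replace = TRUE)
}

# one proposal-thinning pass along a branch of length t (expected neutral
# substitutions/site); x is a character vector of single bases
.evolve_nt <- function(x, t, kappa, accept, protected = integer()) {
  L <- length(x)
  n_ev <- stats::rpois(1L, L * t)
  if (n_ev == 0L) return(x)
  nts <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n_ev)) {
    pos <- sample.int(L, 1L)
    if (pos %in% protected) next
    cur <- x[pos]
    if (!cur %in% nts) next
    alts <- setdiff(nts, cur)
    w <- ifelse(alts == transition[[cur]], kappa, 1)
    alt <- sample(alts, 1L, prob = w)
    if (accept(x, pos, cur, alt)) x[pos] <- alt
  }
  x
}

.evolve_orf <- function(x, t, omega, kappa, gc, protected = integer()) {
  accept <- function(cur_seq, pos, cur, alt) {
    ci <- (pos - 1L) %/% 3L
    idx <- ci * 3L + 1:3
    old_cod <- paste(cur_seq[idx], collapse = "")
    new <- cur_seq[idx]
    new[pos - ci * 3L] <- alt
    new_cod <- paste(new, collapse = "")
    if (gc[[new_cod]] == "*") return(FALSE)
    if (gc[[new_cod]] == gc[[old_cod]]) return(TRUE)
    stats::runif(1L) < omega
  }
  .evolve_nt(x, t, kappa, accept, protected)
}

.evolve_neutral <- function(x, t, kappa, protected = integer()) {
  .evolve_nt(x, t, kappa, function(cur_seq, pos, cur, alt) TRUE, protected)
}

# apply motif events down the species tree: returns per-species layout
.species_motif_layouts <- function(cfg) {
  species <- unique(cfg$species_map$species[
    cfg$species_map$isolate %in% cfg$tree$tip.label])
  base <- cfg$motif_ancestral
  layouts <- stats::setNames(rep(list(base), length(species)), species)
  clade_of <- stats::setNames(metarhizium_clade(species), species)
  for (ev in cfg$motif_events) {
    targets <- if (ev$species %in% species) ev$species
      else species[clade_of == ev$species]
    if (length(targets) == 0L)
      stop("motif event names unknown species/clade: ", ev$species)
    for (sp in targets) {
      lay <- layouts[[sp]]
      hit <- which(lay$element == ev$element &
                     lay$upstream_pos == ev$upstream_pos)
      if (ev$action == "gain") {
        if (length(hit) > 0L)
          stop("gain of element already present: ", ev$element, " at ",
               ev$upstream_pos, " in ", sp)
        lay <- dplyr::bind_rows(lay, tibble::tibble(
          element = ev$element, upstream_pos = as.integer(ev$upstream_pos),
          count = as.integer(ev$count %||% 1L)))
      } else if (length(hit) == 0L) {
        stop("event '", ev$action, "' on absent element ", ev$element,
             " at ", ev$upstream_pos, " in ", sp)
      } else if (ev$action == "loss") {
        lay <- lay[-hit, ]
      } else if (ev$action == "replace") {
        lay$element[hit] <- ev$with
      } else if (ev$action == "set_count") {
        lay$count[hit] <- as.integer(ev$count)
      } else stop("unknown motif action: ", ev$action)
      layouts[[sp]] <- lay
    }
  }
  layouts
}

# write a species' element layout into a promoter sequence (character
# vector); returns list(seq, windows = protected positions)
.stamp_motifs <- function(x, layout) {
  L <- length(x)
  windows <- integer()
  if (nrow(layout) == 0L) return(list(seq = x, windows = windows))
  for (i in seq_len(nrow(layout))) {
    el <- layout$element[i]
    pat <- .motif_patterns[[el]]
    txt <- if (el == "TATG_repeat")
      strrep(pat, layout$count[i]) else pat
    start <- L + layout$upstream_pos[i] + 1L
    idx <- start:(start + nchar(txt) - 1L)
    if (start < 1L || max(idx) > L)
      stop("motif ", el, " at ", layout$upstream_pos[i],
           " falls outside the promoter")
    x[idx] <- strsplit(txt, "")[[1]]
    # guard flanks so a TATG array cannot extend into background sequence
    if (el == "TATG_repeat") {
      if (start > 4L &&
          paste(x[(start - 4L):(start - 1L)], collapse = "") == "TATG") {
        x[start - 1L] <- "C"
        windows <- c(windows, start - 1L)
      }
      after <- max(idx) + 1L
      if (after + 3L <= L && paste(x[after:(after + 3L)], collapse = "") ==
            "TATG") { x[after] <- "C"; windows <- c(windows, after) }
    }
    windows <- c(windows, idx)
  }
  list(seq = x, windows = windows)
}

# remove chance occurrences of the scanned motifs from a background
# sequence so planted layouts are the only signal
.scrub_motifs <- function(x) {
  s <- paste(x, collapse = "")
  for (pat in unique(c(.motif_patterns, "TATG"))) {
    repeat {
      m <- regexpr(pat, s, fixed = TRUE)
      if (m < 0L) break
      pos <- as.integer(m) + 2L
      substr(s, pos, pos) <- if (substr(s, pos, pos) == "C") "G" else "C"
    }
  }
  strsplit(s, "")[[1]]
}

#' Simulate a full adhesin-locus dataset along a known tree
#'
#' Evolves an in-frame ORF (codon-wise proposal thinning: proposals are
#' HKY-like single-base changes; synonymous changes are always accepted,
#' nonsynonymous changes with probability omega, changes creating stop
#' codons never) and a promoter (neutral, at `promoter_rate_mult` times the
#' synonymous rate) down the configured isolate tree.  Species-specific
#' promoter element layouts and domain-B tandem-repeat arrays are stamped
#' per species; the stamped windows, the start/stop codons and the repeat
#' array are excluded from point substitution so that the generating truth
#' is exactly recoverable.
#'
#' @param cfg a [sim_config()].
#' @return a list with `records` (tidy record tibble: promoter, orf and
#'   full region per isolate for coding loci; one full region per isolate
#'   otherwise), `aligned` (the generating-truth multiple alignment of the
#'   same records, plus a `protein` region -- the only indels are the
#'   repeat copy-number differences, so the true alignment is known), and
#'   `truth` (generating tree, per-species motif layouts, repeat counts,
#'   and config).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  gc <- .codon_table()
  sp_of <- stats::setNames(cfg$species_map$species, cfg$species_map$isolate)

  if (!cfg$coding) {
    anc <- sample(c("A", "C", "G", "T"), cfg$promoter_len, replace = TRUE)
    seqs <- .evolve_tree(tree, anc, function(x, t)
      .evolve_neutral(x, t * cfg$promoter_rate_mult, cfg$kappa))
    records <- tibble::tibble(
      isolate = names(seqs),
      species = unname(sp_of[names(seqs)]),
      locus = cfg$locus, region = "full",
      sequence = vapply(seqs, paste, "", collapse = ""))
    return(list(records = records, aligned = records,
                truth = list(tree = tree, config = cfg)))
  }

  layouts <- .species_motif_layouts(cfg)
  rep_nt <- .aa_to_codons(cfg$repeat_unit, gc)
  base_count <- .repeat_count_for(cfg$repeat_counts, NULL)

  # ancestral promoter: scrubbed background, ancestral layout stamped
  anc_prom <- .scrub_motifs(sample(c("A", "C", "G", "T"), cfg$promoter_len,
                                   replace = TRUE))
  # ancestral ORF: ATG + random sense codons + repeat array + stop
  body <- .random_codons(cfg$orf_codons - 2L, gc)
  rep_block <- rep(rep_nt, base_count)
  codons <- c("ATG", body[seq_len(cfg$repeat_at - 2L)],
              rep_block,
              body[(cfg$repeat_at - 1L):length(body)], "TAA")
  anc_orf <- strsplit(paste(codons, collapse = ""), "")[[1]]
  rep_start_nt <- (cfg$repeat_at - 1L) * 3L + 1L
  rep_idx <- rep_start_nt:(rep_start_nt + length(rep_block) * 3L - 1L)
  prot_orf <- c(1:3, rep_idx, (length(anc_orf) - 2L):length(anc_orf))

  orf_seqs <- .evolve_tree(tree, anc_orf, function(x, t)
    .evolve_orf(x, t, cfg$omega, cfg$kappa, gc, protected = prot_orf))
  prom_seqs <- .evolve_tree(tree, anc_prom, function(x, t)
    .evolve_neutral(x, t * cfg$promoter_rate_mult, cfg$kappa))

  unit_nt_len <- length(rep_nt) * 3L
  k_of <- vapply(tree$tip.label, function(iso)
    .repeat_count_for(cfg$repeat_counts, sp_of[[iso]]), integer(1))
  k_max <- max(k_of)
  recs <- purrr::map(tree$tip.label, function(iso) {
    sp <- sp_of[[iso]]
    st <- .stamp_motifs(.scrub_motifs(prom_seqs[[iso]]), layouts[[sp]])
    prom <- paste(st$seq, collapse = "")
    orf <- orf_seqs[[iso]]
    k <- k_of[[iso]]
    if (k != base_count) {
      unit_nt <- orf[rep_start_nt:(rep_start_nt + unit_nt_len - 1L)]
      if (k > base_count) {
        extra <- rep(unit_nt, k - base_count)
        orf <- append(orf, extra, after = rep_start_nt - 1L)
      } else {
        drop_n <- (base_count - k) * unit_nt_len
        orf <- orf[-(rep_start_nt:(rep_start_nt + drop_n - 1L))]
      }
    }
    orf <- paste(orf, collapse = "")
    # true alignment: the only indel is the repeat copy-number difference,
    # so pad each ORF with gap columns after its repeat block
    rep_end <- rep_start_nt - 1L + k * unit_nt_len
    pad <- strrep("-", (k_max - k) * unit_nt_len)
    orf_al <- paste0(substr(orf, 1L, rep_end), pad,
                     substr(orf, rep_end + 1L, nchar(orf)))
    prot <- translate_orf(orf)
    prot_end <- cfg$repeat_at - 1L + k * length(rep_nt)
    prot_al <- paste0(substr(prot, 1L, prot_end),
                      strrep("-", (k_max - k) * length(rep_nt)),
                      substr(prot, prot_end + 1L, nchar(prot)))
    base <- tibble::tibble(
      isolate = iso, species = sp, locus = cfg$locus,
      region = c("promoter", "orf", "full"),
      sequence = c(prom, orf, paste0(prom, orf)))
    al <- tibble::tibble(
      isolate = iso, species = sp, locus = cfg$locus,
      region = c("promoter", "orf", "full", "protein"),
      sequence = c(prom, orf_al, paste0(prom, orf_al), prot_al))
    list(base = base, al = al)
  })
  records <- dplyr::bind_rows(purrr::map(recs, "base"))
  aligned <- dplyr::bind_rows(purrr::map(recs, "al"))
  truth <- list(
    tree = tree,
    motif_layouts = layouts,
    repeat_counts = stats::setNames(
      vapply(unique(unname(sp_of[tree$tip.label])),
             function(sp) .repeat_count_for(cfg$repeat_counts, sp),
             integer(1)),
      unique(unname(sp_of[tree$tip.label]))),
    repeat_unit = cfg$repeat_unit,
    omega = cfg$omega,
    config = cfg)
  list(records = records, aligned = aligned, truth = truth)
}

.repeat_count_for <- function(counts, species) {
  if (is.null(species) || !length(counts)) {
    if ("default" %in% names(counts)) return(as.integer(counts[["default"]]))
    return(if (length(counts)) as.integer(counts[[1]]) else 6L)
  }
  if (species %in% names(counts)) return(as.integer(counts[[species]]))
  if ("default" %in% names(counts)) return(as.integer(counts[["default"]]))
  6L
}

# reverse-translate an amino-acid unit deterministically (first codon in
# the standard-code table for each residue)
.aa_to_codons <- function(aa, gc) {
  res <- strsplit(aa, "")[[1]]
  vapply(res, function(a) {
    cands <- names(gc)[gc == a]
    if (length(cands) == 0L) stop("no codon for residue ", a)
    sort(cands)[1]
  }, "")
}

# evolve a root sequence down a phylo; branch_fun(x, t) -> x'
.evolve_tree <- function(tree, root_seq, branch_fun) {
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- vector("list", n + nnode)
  root <- n + 1L
  seqs[[root]] <- root_seq
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1]; child <- eo$edge[i, 2]
    seqs[[child]] <- branch_fun(seqs[[par]], eo$edge.length[i])
  }
  out <- seqs[seq_len(n)]
  names(out) <- tree$tip.label
  out
}

#' Simulate an aligned codon pair with known omega
#'
#' Two sequences diverged from a random ancestor by total branch length
#' `t` (expected neutral substitutions per site), used for estimator
#' parameter-recovery checks.
#'
#' @param n_codons number of codons.
#' @param t total divergence between the pair, neutral scale.
#' @param omega dN/dS of the generating process.
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed.
#' @return list with `a` and `b`, in-frame ORF strings without stop codons.
#' @export
simulate_codon_pair <- function(n_codons, t, omega, kappa = 1, seed = 1L) {
  set.seed(seed)
  gc <- .codon_table()
  anc <- strsplit(paste(.random_codons(n_codons, gc), collapse = ""), "")[[1]]
  a <- .evolve_orf(anc, t / 2, omega, kappa, gc)
  b <- .evolve_orf(anc, t / 2, omega, kappa, gc)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

#' Uniform random binary trees
#'
#' `rtree_uniform()` draws a topology uniformly at random (every labelled
#' binary topology equally likely) by sequential attachment of each new
#' leaf to a uniformly chosen edge.  `random_tree_pair()` draws two
#' independent such trees on the same labels; it feeds the congruence null
#' calibration.
#'
#' @param n number of leaves (>= 4).
#' @param rooted draw a rooted topology (uniform over rooted binary
#'   topologies) instead of an unrooted one.
#' @param labels tip labels; default `t1..tn`.
#' @return an `ape::phylo` (`rtree_uniform`) or list of two
#'   (`random_tree_pair`).
#' @export
rtree_uniform <- function(n, rooted = FALSE, labels = paste0("t", seq_len(n))) {
  if (n < 4L) stop("need n >= 4 leaves")
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  m <- if (rooted) n + 1L else n
  edges <- matrix(c(m + 1L, 1L, m + 1L, 2L, m + 1L, 3L), ncol = 2,
                  byrow = TRUE)
  nextint <- m + 2L
  if (m >= 4L) for (k in 4:m) {
    e <- sample.int(nrow(edges), 1L)
    b <- edges[e, 2L]
    newi <- nextint; nextint <- nextint + 1L
    edges[e, 2L] <- newi
    edges <- rbind(edges, c(newi, b), c(newi, k))
  }
  kids <- split(edges[, 2L], edges[, 1L])
  lab <- function(v) if (rooted && v == m) "@ROOT@" else labels[v]
  rec <- function(v) {
    if (v <= m) return(lab(v))
    paste0("(", paste(vapply(kids[[as.character(v)]], rec, ""),
                      collapse = ","), ")")
  }
  tr <- ape::read.tree(text = paste0(rec(m + 1L), ";"))
  if (rooted) {
    tr <- ape::root(tr, outgroup = "@ROOT@", resolve.root = TRUE)
    tr <- ape::drop.tip(tr, "@ROOT@")
  }
  tr$node.label <- NULL
  tr
}

#' @rdname rtree_uniform
#' @param seed integer seed.
#' @export
random_tree_pair <- function(n, seed = 1L, rooted = FALSE) {
  if (n < 4L) stop("need n >= 4 leaves")
  set.seed(seed)
  list(rtree_uniform(n, rooted = rooted),
       rtree_uniform(n, rooted = rooted))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
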