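# Optional reproduction suite for the deposited isolate panel.  The
# deposited sequences (GenBank accessions KC484624-KC484651 plus the
# EF-1alpha records) cannot be fetched by this package -- there is no
# network access by design -- so these helpers run against a local
# directory the user populates, and compare the recomputed quantities with
# the published reference values at stated tolerances.

#' Published reference values for the deposited panel
#'
#' The headline quantities reported for the 14-isolate *Metarhizium*
#' panel: overall and extreme divergence percentages per locus and
#' region, mean dN/dS per locus, MAST sizes and Icong values against the
#' 5' EF-1alpha tree, protein lengths, and domain-B repeat counts.
#' Tolerances: +/-0.3 percentage points for divergences, +/-0.05 for
#' dN/dS, exact for lengths, repeat counts and MAST sizes (given
#' re-inferred trees), +/-0.01 for Icong.
#'
#' @return tibble: `quantity`, `locus`, `region`, `subject`, `target`,
#'   `tolerance`.
#' @export
repro_targets <- function() {
  tibble::tribble(
    ~quantity,              ~locus,  ~region,    ~subject,                      ~target, ~tolerance,
    "overall_interspecies", "Mad1",  "orf",      "all species",                 6.7,     0.3,
    "overall_interspecies", "Mad1",  "promoter", "all species",                 7.1,     0.3,
    "overall_interspecies", "Mad2",  "orf",      "all species",                 7.4,     0.3,
    "overall_interspecies", "Mad2",  "promoter", "all species",                 9.9,     0.3,
    "extreme_pair",         "Mad1",  "orf",      "ARSEF_7486/ARSEF_6238",       14.2,    0.3,
    "extreme_pair",         "Mad2",  "orf",      "ARSEF_7486/HKB1-1b",          15.9,    0.3,
    "mean_omega",           "Mad1",  "orf",      "all pairs",                   0.20,    0.05,
    "mean_omega",           "Mad2",  "orf",      "all pairs",                   0.31,    0.05,
    "mast_size",            "Mad1",  "promoter", "vs EF1a",                     11,      0,
    "mast_size",            "Mad2",  "promoter", "vs EF1a",                     11,      0,
    "mast_size",            "Mad1",  "orf",      "vs EF1a",                     9,       0,
    "mast_size",            "Mad2",  "orf",      "vs EF1a",                     10,      0,
    "icong",                "Mad1",  "promoter", "vs EF1a",                     2.03,    0.01,
    "icong",                "Mad2",  "promoter", "vs EF1a",                     2.03,    0.01,
    "icong",                "Mad1",  "orf",      "vs EF1a",                     1.66,    0.01,
    "icong",                "Mad2",  "orf",      "vs EF1a",                     1.84,    0.01,
    "protein_length",       "Mad1",  "protein",  "M. robertsii",                717,     0,
    "protein_length",       "Mad1",  "protein",  "M. acridum",                  723,     0,
    "protein_length",       "Mad2",  "protein",  "M. acridum",                  295,     0,
    "protein_length",       "Mad2",  "protein",  "PARB clade",                  306,     0,
    "repeat_count",         "Mad1",  "protein",  "M. acridum",                  8,       0,
    "repeat_count",         "Mad1",  "protein",  "other species",               6,       0
  )
}

#' Recompute the reported quantities from local sequence files
#'
#' Expects `seq_dir` to contain FASTA files named
#' `<locus>_<region>.fasta` (`Mad1_promoter`, `Mad1_orf`, `Mad2_promoter`,
#' `Mad2_orf`, `EF1a_full`) with headers resolvable by [read_sequences()]
#' (pipe-delimited or isolate-first with `species_map`), plus optional
#' pre-aligned `<locus>_<region>_aligned.fasta` files used for tree
#' inference.  Computes each quantity of [repro_targets()] that its
#' inputs allow, and reports the deviation from the published value.
#'
#' @param seq_dir directory of local sequence files.
#' @param species_map species map tibble.
#' @param boot_reps bootstrap replicates for tree inference.
#' @param seed integer seed.
#' @return tibble: [repro_targets()] columns plus `value`, `delta`,
#'   `within_tolerance` (`NA` where inputs were unavailable).
#' @export
repro_report <- function(seq_dir, species_map = metarhizium_species_map(),
                         boot_reps = 100L, seed = 1L) {
  targets <- repro_targets()
  rd <- function(locus, region, aligned = FALSE) {
    suffix <- if (aligned) "_aligned.fasta" else ".fasta"
    f <- file.path(seq_dir, paste0(locus, "_", region, suffix))
    if (!file.exists(f)) return(NULL)
    read_sequences(f, locus = locus, region = region,
                   species_map = species_map, aligned = aligned)
  }
  value <- rep(NA_real_, nrow(targets))
  matrices <- list()
  trees <- list()
  for (i in seq_len(nrow(targets))) {
    t <- targets[i, ]
    value[i] <- tryCatch({
      if (t$quantity %in% c("overall_interspecies", "extreme_pair")) {
        key <- paste0(t$locus, "_", t$region)
        if (is.null(matrices[[key]])) {
          recs <- rd(t$locus, t$region)
          if (is.null(recs)) stop("missing input")
          matrices[[key]] <- build_divergence_matrix(recs)
        }
        m <- matrices[[key]]
        if (t$quantity == "overall_interspecies")
          overall_interspecies_mean(m)
        else extreme_pair(m)$divergence
      } else if (t$quantity == "mean_omega") {
        recs <- rd(t$locus, "orf")
        if (is.null(recs)) stop("missing input")
        mean_omega(recs)
      } else if (t$quantity %in% c("mast_size", "icong")) {
        for (key in c(paste0(t$locus, "_", t$region), "EF1a_full")) {
          if (is.null(trees[[key]])) {
            parts <- strsplit(key, "_")[[1]]
            al <- rd(parts[1], parts[2], aligned = TRUE)
            if (is.null(al)) al <- rd(parts[1], parts[2])
            if (is.null(al)) stop("missing input")
            d <- as_char_matrix(al)
            trees[[key]] <- suppressWarnings(
              mp_search(d, seed = seed)$best)
          }
        }
        res <- suppressWarnings(icong_test(
          trees[[paste0(t$locus, "_", t$region)]], trees[["EF1a_full"]]))
        if (t$quantity == "mast_size") res$mast_size else res$icong
      } else if (t$quantity %in% c("protein_length", "repeat_count")) {
        recs <- rd(t$locus, "orf")
        if (is.null(recs)) stop("missing input")
        pr <- protein_report(recs)
        sub <- switch(t$subject,
          "PARB clade" = pr[metarhizium_clade(pr$species) == "PARB", ],
          "other species" = pr[pr$species != "M. acridum", ],
          pr[pr$species == t$subject, ])
        if (nrow(sub) == 0L) stop("missing subject")
        col <- if (t$quantity == "protein_length") "protein_length"
          else "repeat_count"
        as.numeric(names(sort(table(sub[[col]]), decreasing = TRUE))[1])
      } else NA_real_
    }, error = function(e) NA_real_)
  }
  out <- targets
  out$value <- value
  out$delta <- out$value - out$target
  out$within_tolerance <- ifelse(is.na(out$value), NA,
                                 abs(out$delta) <= out$tolerance + 1e-9)
  out
}
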