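#' Build a pairwise percent-divergence matrix
#'
#' Runs [global_align()] + [percent_divergence()] on every unordered pair
#' of records (same locus and region) and assembles the symmetric
#' divergence matrix used for inter-/intraspecies summaries.
#'
#' @param records record tibble (one locus/region; see [read_sequences()]).
#' @param mode divergence mode, see [percent_divergence()].
#' @param scoring an [align_scoring()] configuration.
#' @return an object of class `divergence_matrix`: list with `values`
#'   (symmetric matrix, percent), `isolates`, `species` (named vector),
#'   `locus`, `region`, `mode`.
#' @export
build_divergence_matrix <- function(records, mode = "include_gaps",
                                    scoring = align_scoring()) {
  stopifnot(nrow(records) >= 2L)
  if (anyDuplicated(records$isolate))
    stop("duplicate isolate ids: ",
         paste(unique(records$isolate[duplicated(records$isolate)]),
               collapse = ", "))
  if (dplyr::n_distinct(records$locus) > 1L ||
      dplyr::n_distinct(records$region) > 1L)
    stop("records mix loci or regions; filter first")
  n <- nrow(records)
  v <- matrix(0, n, n, dimnames = list(records$isolate, records$isolate))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- pairwise_divergence(records$sequence[i], records$sequence[j],
                             mode = mode, scoring = scoring)
    v[i, j] <- v[j, i] <- d
  }
  structure(list(values = v, isolates = records$isolate,
                 species = stats::setNames(records$species,
                                           records$isolate),
                 locus = records$locus[1], region = records$region[1],
                 mode = mode),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat("Divergence matrix:", length(x$isolates), "isolates |",
      x$locus, x$region, "|", x$mode, "\n")
  print(round(x$values, 1))
  invisible(x)
}

#' @describeIn build_divergence_matrix long-format tidy view (one row per
#'   unordered pair, with both species labels and a within/between flag).
#' @param x a `divergence_matrix`.
#' @param ... unused.
#' @export
tidy.divergence_matrix <- function(x, ...) {
  n <- length(x$isolates)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    isolate_a = x$isolates[idx[, 1]],
    isolate_b = x$isolates[idx[, 2]],
    species_a = unname(x$species[idx[, 1]]),
    species_b = unname(x$species[idx[, 2]]),
    divergence = x$values[idx],
    comparison = ifelse(x$species[idx[, 1]] == x$species[idx[, 2]],
                        "intraspecies", "interspecies"))
}

.check_species <- function(m, sp) {
  missing <- setdiff(sp, unique(m$species))
  if (length(missing))
    stop("species not in matrix: ", paste(missing, collapse = ", "))
}

#' Interspecies and intraspecies divergence summaries
#'
#' `interspecies_mean()` averages all cross-species isolate pairs between
#' two species.  `overall_interspecies_mean()` aggregates across species:
#' the default mode averages the species-pair means (each species pair
#' weighted equally); the alternative averages over all cross-species
#' isolate pairs.  `intraspecies_mean()` averages within-species pairs and
#' returns `NA` (with a warning) for species represented by a single
#' isolate.
#'
#' @param m a `divergence_matrix`.
#' @param sp1,sp2,sp species names.
#' @return percent divergence (scalar).
#' @export
interspecies_mean <- function(m, sp1, sp2) {
  .check_species(m, c(sp1, sp2))
  if (sp1 == sp2) stop("use intraspecies_mean() for within-species pairs")
  a <- which(m$species == sp1)
  b <- which(m$species == sp2)
  mean(m$values[a, b, drop = FALSE])
}

#' @rdname interspecies_mean
#' @param mode `"species_pairs"` (mean of species-pair means, default) or
#'   `"isolate_pairs"` (mean over all cross-species isolate pairs).
#' @export
overall_interspecies_mean <- function(m,
                                      mode = c("species_pairs",
                                               "isolate_pairs")) {
  mode <- match.arg(mode)
  sps <- unique(m$species)
  if (length(sps) < 2L) stop("need at least two species")
  if (mode == "species_pairs") {
    pairs <- utils::combn(sort(sps), 2L, simplify = FALSE)
    mean(vapply(pairs, function(p) interspecies_mean(m, p[1], p[2]),
                numeric(1)))
  } else {
    td <- tidy(m)
    mean(td$divergence[td$comparison == "interspecies"])
  }
}

#' @rdname interspecies_mean
#' @export
intraspecies_mean <- function(m, sp) {
  .check_species(m, sp)
  idx <- which(m$species == sp)
  if (length(idx) < 2L) {
    warning("species ", sp, " has fewer than 2 isolates; ",
            "intraspecies divergence undefined")
    return(NA_real_)
  }
  v <- m$values[idx, idx, drop = FALSE]
  mean(v[upper.tri(v)])
}

#' Most divergent pair in a divergence matrix
#'
#' Returns the argmax pair for the requested scope with deterministic
#' lexicographic tie-breaking on (isolate_a, isolate_b).
#'
#' @param m a `divergence_matrix`.
#' @param scope `"all"`, `"interspecies"` or `"intraspecies"`.
#' @return one-row tibble: `isolate_a`, `isolate_b`, `species_a`,
#'   `species_b`, `divergence`.
#' @export
extreme_pair <- function(m, scope = c("all", "interspecies",
                                      "intraspecies")) {
  scope <- match.arg(scope)
  td <- tidy(m)
  if (scope != "all") td <- td[td$comparison == scope, ]
  if (nrow(td) == 0L) stop("no qualifying pair for scope ", scope)
  td <- td[order(-td$divergence, td$isolate_a, td$isolate_b), ]
  td[1, c("isolate_a", "isolate_b", "species_a", "species_b", "divergence")]
}

#' Summary table mirroring the per-locus divergence results
#'
#' One call producing, per divergence matrix: the overall interspecies
#' mean (both aggregation modes), all species-pair means, all defined
#' intraspecies means, and the most divergent isolate pair.
#'
#' @param m a `divergence_matrix`.
#' @return a tibble with columns `statistic`, `species_a`, `species_b`,
#'   `value` (percent, 1 decimal shown by the report writer).
#' @export
divergence_summary <- function(m) {
  sps <- sort(unique(m$species))
  rows <- list(
    tibble::tibble(statistic = "overall_interspecies_mean",
                   species_a = NA, species_b = NA,
                   value = overall_interspecies_mean(m)),
    tibble::tibble(statistic = "overall_interspecies_mean_isolate_pairs",
                   species_a = NA, species_b = NA,
                   value = overall_interspecies_mean(m, "isolate_pairs")))
  if (length(sps) >= 2L) {
    pr <- utils::combn(sps, 2L, simplify = FALSE)
    rows <- c(rows, list(dplyr::bind_rows(purrr::map(pr, function(p)
      tibble::tibble(statistic = "interspecies_mean", species_a = p[1],
                     species_b = p[2],
                     value = interspecies_mean(m, p[1], p[2]))))))
  }
  intra <- purrr::map(sps, function(sp) {
    v <- suppressWarnings(intraspecies_mean(m, sp))
    tibble::tibble(statistic = "intraspecies_mean", species_a = sp,
                   species_b = sp, value = v)
  })
  ex <- extreme_pair(m)
  rows <- c(rows, list(dplyr::bind_rows(intra),
                       tibble::tibble(statistic = "extreme_pair",
                                      species_a = ex$isolate_a,
                                      species_b = ex$isolate_b,
                                      value = ex$divergence)))
  out <- dplyr::bind_rows(rows)
  out$locus <- m$locus
  out$region <- m$region
  out
}

#' @export
autoplot.divergence_matrix <- function(object, ...) {
  td <- tidy(object)
  both <- dplyr::bind_rows(
    td,
    dplyr::rename(td, isolate_a = "isolate_b", isolate_b = "isolate_a"))
  ggplot2::ggplot(both, ggplot2::aes(.data$isolate_a, .data$isolate_b,
                                     fill = .data$divergence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% divergence") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste(object$locus, object$region,
                                "pairwise divergence")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
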