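# Promoter transcriptional-element scanning.  Elements are exact-match
# literals on the coding strand: the stress-responsive element STRE
# (AGGGG), the post-diauxic-shift element PDS (AAGGGA), the TATA-box-like
# sequence TACATA, and degenerate-TATA (TATG) repeat arrays, with maximal
# TATG runs merged into one hit carrying a repeat count.

#' Scan a promoter for transcriptional elements
#'
#' Coordinates follow the upstream convention: position -1 is the base
#' immediately 5' of the ORF start (the promoter is supplied 5'->3' and
#' ends right before the ATG), and a hit's position is the coordinate of
#' its 5'-most base.  All exact matches on the given strand are reported;
#' overlapping matches of the same element collapse to the 5'-most;
#' maximal `TATG` runs are merged into a single `TATG_repeat` hit whose
#' `repeat_count` is the run length divided by 4.
#'
#' @param x promoter sequence string, or a one-row record tibble with
#'   `region == "promoter"` (any other region is an error).
#' @param elements subset of elements to scan.
#' @return tibble: `element`, `pattern`, `upstream_pos`, `repeat_count`
#'   (`NA` except for TATG arrays), `start` (1-based position in the
#'   supplied sequence).
#' @export
scan_promoter <- function(x, elements = names(.motif_patterns)) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    if (!identical(x$region, "promoter"))
      stop("scan_promoter() needs a promoter record, got region = ",
           x$region)
    x <- x$sequence
  }
  s <- toupper(x)
  L <- nchar(s)
  hits <- list()
  for (el in elements) {
    pat <- .motif_patterns[[el]]
    if (el == "TATG_repeat") {
      m <- gregexpr("(?:TATG)+", s)[[1]]
      if (m[1] != -1L) {
        len <- attr(m, "match.length")
        hits[[el]] <- tibble::tibble(
          element = el, pattern = substring(s, m, m + len - 1L),
          start = as.integer(m), repeat_count = as.integer(len %/% 4L))
      }
    } else {
      # lookahead finds overlapping occurrences; same-element overlaps are
      # then collapsed to the 5'-most
      m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
      if (m[1] != -1L) {
        pos <- as.integer(m)
        keep <- logical(length(pos))
        last_end <- -1L
        for (i in seq_along(pos)) {
          if (pos[i] > last_end) {
            keep[i] <- TRUE
            last_end <- pos[i] + nchar(pat) - 1L
          }
        }
        pos <- pos[keep]
        hits[[el]] <- tibble::tibble(
          element = el, pattern = pat, start = pos,
          repeat_count = NA_integer_)
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L)
    return(tibble::tibble(element = character(), pattern = character(),
                          upstream_pos = integer(),
                          repeat_count = integer(), start = integer()))
  out$upstream_pos <- out$start - L - 1L
  dplyr::arrange(out[, c("element", "pattern", "upstream_pos",
                         "repeat_count", "start")],
                 .data$start, .data$element)
}

#' Scan many promoter records
#'
#' @param records record tibble with `region == "promoter"` rows.
#' @return tibble of per-isolate hits ([scan_promoter()] columns plus
#'   `isolate`, `species`).
#' @export
scan_promoters <- function(records) {
  proms <- records[records$region == "promoter", ]
  stopifnot(nrow(proms) >= 1L)
  dplyr::bind_rows(purrr::map(seq_len(nrow(proms)), function(i) {
    h <- scan_promoter(proms$sequence[i])
    if (nrow(h) == 0L) return(h)
    h$isolate <- proms$isolate[i]
    h$species <- proms$species[i]
    h
  }))
}

#' Species-level comparative motif table
#'
#' Summarises per-isolate promoter hits into a per-species x element
#' table: how many isolates carry the element, total hit count, TATG
#' repeat counts, and whether the pattern is conserved across the
#' species' isolates (same number of hits and repeat structure) --
#' distinguishing species-level variation from intra-species variation.
#'
#' @param hits per-isolate hit table from [scan_promoters()].
#' @param species_map species map providing the species of each isolate.
#' @param isolates isolates that were scanned (defaults to those with at
#'   least one hit; pass the full panel so hit-less isolates are counted
#'   as absences).
#' @return tibble: `species`, `element`, `n_isolates`, `n_with_element`,
#'   `hits_per_isolate`, `repeat_counts`, `conserved`.
#' @export
compare_motif_tables <- function(hits, species_map,
                                 isolates = unique(hits$isolate)) {
  if (length(isolates) < 2L)
    stop("need at least 2 scanned isolates")
  els <- sort(unique(hits$element))
  grid <- tidyr::expand_grid(isolate = isolates, element = els)
  per_iso <- grid |>
    dplyr::left_join(
      hits |>
        dplyr::group_by(.data$isolate, .data$element) |>
        dplyr::summarise(
          n_hits = dplyr::n(),
          reps = paste(sort(.data$repeat_count), collapse = ","),
          .groups = "drop"),
      by = c("isolate", "element")) |>
    dplyr::mutate(n_hits = dplyr::coalesce(.data$n_hits, 0L),
                  reps = dplyr::coalesce(.data$reps, "")) |>
    dplyr::left_join(species_map[, c("isolate", "species")], by = "isolate")
  per_iso |>
    dplyr::group_by(.data$species, .data$element) |>
    dplyr::summarise(
      n_isolates = dplyr::n(),
      n_with_element = sum(.data$n_hits > 0L),
      hits_per_isolate = paste(.data$n_hits, collapse = "/"),
      repeat_counts = paste(unique(.data$reps[.data$reps != ""]),
                            collapse = ";"),
      conserved = dplyr::n_distinct(paste(.data$n_hits, .data$reps)) == 1L,
      .groups = "drop")
}

#' @export
autoplot.motif_hits <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$upstream_pos, y = .data$isolate,
                               colour = .data$element)) +
    ggplot2::geom_point(size = 3, shape = 124) +
    ggplot2::labs(x = "position upstream of ATG (bp)", y = NULL,
                  colour = "element") +
    ggplot2::theme_minimal()
}

#' Plot per-isolate promoter element maps
#'
#' @param hits per-isolate hit table from [scan_promoters()].
#' @return a ggplot object.
#' @export
plot_motif_map <- function(hits) {
  class(hits) <- c("motif_hits", class(hits))
  autoplot(hits)
}
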