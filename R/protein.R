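#' Translate an in-frame ORF to protein
#'
#' Standard nuclear genetic code.  A terminal stop codon is removed (so an
#' ORF of 3L nucleotides with terminal stop yields L - 1 residues); an
#' internal stop is an error naming the codon index; a length not
#' divisible by 3 is an error.  Codons containing non-ACGT bases translate
#' to `X`.
#'
#' @param orf ORF nucleotide string, or a one-row record tibble whose
#'   `sequence` is used (and whose metadata is propagated).
#' @return protein string, or a record tibble row with
#'   `region = "protein"` when a record was supplied.
#' @export
translate_orf <- function(orf) {
  if (is.data.frame(orf)) {
    stopifnot(nrow(orf) == 1L)
    out <- orf
    out$region <- "protein"
    out$sequence <- translate_orf(orf$sequence)
    return(out)
  }
  gc <- .codon_table()
  cod <- .split_codons(orf)
  aa <- vapply(cod, .translate_codon, "", gc = gc)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  internal <- which(aa == "*")
  if (length(internal))
    stop("internal stop codon at codon ", internal[1])
  paste(aa, collapse = "")
}

#' Translate every ORF record in a tibble
#'
#' @param records record tibble with `region == "orf"` rows.
#' @return record tibble of the corresponding `region == "protein"` rows.
#' @export
translate_records <- function(records) {
  orfs <- records[records$region == "orf", ]
  stopifnot(nrow(orfs) >= 1L)
  dplyr::bind_rows(purrr::map(seq_len(nrow(orfs)), function(i)
    translate_orf(orfs[i, ])))
}

.hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Count tandem repeats of a unit in a protein
#'
#' Finds the longest run of consecutive copies of `unit`, each copy within
#' `max_mismatch` substitutions of the unit, scanning every start
#' position; ties resolve to the leftmost run (leftmost-longest rule).
#' The domain-B Thr-rich arrays of the adhesins (e.g. `GKETTPAQQTTP`) are
#' the motivating case.
#'
#' @param protein protein string.
#' @param unit amino-acid repeat unit (length >= 3).
#' @param max_mismatch allowed substitutions per unit copy (default 2 per
#'   12-mer; repeats in real data drift, so exact matching is optional,
#'   not assumed).
#' @return one-row tibble: `unit`, `start` (1-based residue index of the
#'   run; `NA` when count is 0), `count`, `max_mismatch`.
#' @export
count_tandem_repeats <- function(protein, unit, max_mismatch = 2L) {
  stopifnot(nzchar(unit), nchar(unit) >= 2L)
  L <- nchar(protein); u <- nchar(unit)
  best_count <- 0L; best_start <- NA_integer_
  if (u <= L) {
    for (i in seq_len(L - u + 1L)) {
      k <- 0L
      while (TRUE) {
        s <- i + k * u
        if (s + u - 1L > L) break
        if (.hamming(substr(protein, s, s + u - 1L), unit) > max_mismatch)
          break
        k <- k + 1L
      }
      if (k > best_count) { best_count <- k; best_start <- i }
    }
  }
  tibble::tibble(unit = unit, start = best_start, count = best_count,
                 max_mismatch = as.integer(max_mismatch))
}

#' Protein length and repeat report per isolate
#'
#' Translates each ORF record and annotates the configured tandem-repeat
#' unit, mirroring the per-species protein-length / repeat-count
#' comparisons of the adhesin analysis.
#'
#' @param records record tibble with `region == "orf"` rows.
#' @param unit repeat unit (default the domain-B 12-mer).
#' @param max_mismatch allowed substitutions per copy.
#' @return tibble: `isolate`, `species`, `locus`, `protein_length`,
#'   `repeat_unit`, `repeat_start`, `repeat_count`.
#' @export
protein_report <- function(records, unit = "GKETTPAQQTTP",
                           max_mismatch = 2L) {
  prots <- translate_records(records)
  dplyr::bind_rows(purrr::map(seq_len(nrow(prots)), function(i) {
    rep <- count_tandem_repeats(prots$sequence[i], unit, max_mismatch)
    tibble::tibble(isolate = prots$isolate[i], species = prots$species[i],
                   locus = prots$locus[i],
                   protein_length = nchar(prots$sequence[i]),
                   repeat_unit = unit, repeat_start = rep$start,
                   repeat_count = rep$count)
  }))
}
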