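#' Read sequence records from a multi-FASTA file
#'
#' Parses a FASTA file into the tidy record format used throughout the
#' package: one row per sequence with columns `isolate`, `species`, `locus`,
#' `region`, `sequence`.
#'
#' Header grammar: a pipe-delimited header `>isolate|species|locus|region`
#' fills all four fields directly (species may be written with underscores,
#' e.g. `M_robertsii`, which are converted to spaces after the genus
#' initial).  Any other header falls back to `isolate` = first whitespace
#' token; `species` is then looked up in `species_map` and `locus`/`region`
#' are taken from the arguments.
#'
#' @param path path to a FASTA file.
#' @param locus locus label used when the header does not carry one
#'   (`"Mad1"`, `"Mad2"`, `"EF1a"`, or any label).
#' @param region region label used when the header does not carry one
#'   (`"promoter"`, `"orf"`, `"full"` or `"protein"`).
#' @param species_map optional species map tibble (see [read_species_map()])
#'   used to attach species for free-form headers.
#' @param aligned if `TRUE` the file is pre-aligned and gap characters `-`
#'   are retained; if `FALSE` (default) gaps in the input are an error.
#' @return a tibble with columns `isolate`, `species`, `locus`, `region`,
#'   `sequence`.
#' @export
read_sequences <- function(path, locus = NA_character_, region = NA_character_,
                           species_map = NULL, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (!aligned && any(grepl("-", seqs, fixed = TRUE)))
    stop("gap characters found but `aligned = FALSE`; ",
         "pass `aligned = TRUE` for pre-aligned input")
  recs <- purrr::imap(headers, function(h, i) {
    if (grepl("|", h, fixed = TRUE)) {
      parts <- strsplit(h, "|", fixed = TRUE)[[1]]
      if (length(parts) != 4L)
        stop("malformed pipe-delimited header (need 4 fields): >", h)
      tibble::tibble(
        isolate = trimws(parts[1]),
        species = gsub("_", " ", trimws(parts[2])),
        locus = trimws(parts[3]),
        region = trimws(parts[4])
      )
    } else {
      iso <- strsplit(trimws(h), "\\s+")[[1]][1]
      if (is.na(iso) || !nzchar(iso))
        stop("malformed header at entry ", i, ": >", h)
      tibble::tibble(isolate = iso, species = NA_character_,
                     locus = locus, region = region)
    }
  })
  out <- dplyr::bind_rows(recs)
  out$sequence <- unname(seqs)
  if (!is.null(species_map)) {
    idx <- match(out$isolate, species_map$isolate)
    out$species <- dplyr::coalesce(out$species, species_map$species[idx])
  }
  stopifnot(nrow(out) == length(set))
  out
}

#' Write sequence records to FASTA
#'
#' Headers use the pipe-delimited grammar `isolate|species|locus|region`
#' (spaces in species become underscores) so that [read_sequences()] round
#' trips all fields.
#'
#' @param records record tibble as returned by [read_sequences()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path) {
  hdr <- paste(records$isolate,
               gsub(" ", "_", records$species),
               records$locus, records$region, sep = "|")
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read one or more records from a local GenBank flat file
#'
#' Supports offline use of deposited records: entries are split on `//`,
#' sequence text is taken from the ORIGIN block, and the length declared on
#' each LOCUS line is checked against the parsed sequence.
#'
#' @param path path to a GenBank flat file.
#' @inheritParams read_sequences
#' @return a record tibble; `isolate` holds the accession (LOCUS name).
#' @export
read_genbank <- function(path, locus = NA_character_, region = NA_character_,
                         species_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines))) stop("not a GenBank flat file: ", path)
  starts <- grep("^LOCUS", lines)
  ends <- grep("^//", lines)
  if (length(ends) < length(starts))
    ends <- c(ends, length(lines))
  recs <- purrr::map2(starts, ends[seq_along(starts)], function(s, e) {
    block <- lines[s:e]
    loc <- strsplit(trimws(block[1]), "\\s+")[[1]]
    acc <- loc[2]
    declared <- suppressWarnings(as.integer(loc[3]))
    o <- grep("^ORIGIN", block)
    if (length(o) != 1L) stop("no ORIGIN block in entry ", acc)
    seqlines <- block[(o + 1L):(length(block) - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
    if (!is.na(declared) && nchar(seq) != declared)
      stop("entry ", acc, ": LOCUS declares ", declared,
           " bp but ORIGIN has ", nchar(seq))
    tibble::tibble(isolate = acc, species = NA_character_,
                   locus = locus, region = region, sequence = seq)
  })
  out <- dplyr::bind_rows(recs)
  if (!is.null(species_map)) {
    idx <- match(out$isolate, species_map$isolate)
    out$species <- dplyr::coalesce(out$species, species_map$species[idx])
  }
  out
}

#' Species map utilities
#'
#' A species map is a tibble with columns `isolate`, `species` and `clade`.
#' Clades follow the *Metarhizium* species-complex convention: the PARB
#' clade groups *M. pingshaense*, *M. anisopliae*, *M. robertsii* and
#' *M. brunneum*; the MGT clade groups *M. majus* and *M. guizhouense*;
#' everything else is labelled `other`.
#'
#' `read_species_map()` accepts a two/three-column TSV
#' (`isolate<TAB>species[<TAB>clade]`) or a YAML mapping of species to
#' isolate lists.  `metarhizium_clade()` applies the clade rule to species
#' names.
#'
#' @param path path to a TSV or YAML species map.
#' @return a tibble with columns `isolate`, `species`, `clade`.
#' @export
read_species_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    out <- purrr::imap(y, function(isos, sp)
      tibble::tibble(isolate = as.character(unlist(isos)), species = sp)) |>
      dplyr::bind_rows()
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 2L) stop("species map TSV needs >= 2 columns")
    out <- tibble::tibble(isolate = as.character(df[[1]]),
                          species = as.character(df[[2]]))
    if (ncol(df) >= 3L) out$clade <- as.character(df[[3]])
  }
  if (anyDuplicated(out$isolate))
    stop("duplicate isolate in species map: ",
         paste(unique(out$isolate[duplicated(out$isolate)]), collapse = ", "))
  if (!"clade" %in% names(out)) out$clade <- metarhizium_clade(out$species)
  out
}

#' @rdname read_species_map
#' @param species character vector of species names (e.g. `"M. robertsii"`).
#' @export
metarhizium_clade <- function(species) {
  sp <- tolower(gsub("^M\\.?\\s*|^Metarhizium\\s+", "", species,
                     ignore.case = TRUE))
  dplyr::case_when(
    sp %in% c("pingshaense", "anisopliae", "robertsii", "brunneum") ~ "PARB",
    sp %in% c("majus", "guizhouense") ~ "MGT",
    TRUE ~ "other"
  )
}

#' The 14-isolate study panel
#'
#' Species map for the fourteen *Metarhizium* isolates (seven species)
#' analysed throughout the package and emulated by the simulator: five
#' *M. robertsii*, two *M. brunneum*, three *M. guizhouense*, and one each
#' of *M. pingshaense*, *M. lepidiotae*, *M. acridum* and *M. majus*.
#'
#' @return a species-map tibble (`isolate`, `species`, `clade`).
#' @export
metarhizium_species_map <- function() {
  m <- tibble::tribble(
    ~isolate,      ~species,
    "HKB1-1b",     "M. robertsii",
    "B18-ai",      "M. robertsii",
    "M31-ai",      "M. robertsii",
    "G90-bi",      "M. robertsii",
    "ARSEF_2575",  "M. robertsii",
    "43a-2i",      "M. brunneum",
    "G55-ai",      "M. brunneum",
    "B34-aiii",    "M. guizhouense",
    "B77-ai",      "M. guizhouense",
    "ARSEF_6238",  "M. guizhouense",
    "ARSEF_439",   "M. pingshaense",
    "ARSEF_7488",  "M. lepidiotae",
    "ARSEF_7486",  "M. acridum",
    "ARSEF_1914",  "M. majus"
  )
  m$clade <- metarhizium_clade(m$species)
  m
}

#' Read and write trees in newick format
#'
#' Thin validated wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Reading rejects duplicate leaf labels and malformed newick; writing
#' round-trips topology exactly.
#'
#' @param path newick file path.
#' @return `read_tree()` returns an `ape::phylo`; `write_tree()` returns
#'   `path` invisibly.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (nchar(gsub("[^(]", "", txt)) != nchar(gsub("[^)]", "", txt)))
    stop("unbalanced parentheses in newick: ", path)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' @rdname read_tree
#' @param tree an `ape::phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
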