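#' Alignment scoring configuration
#'
#' Defaults mimic the EMBOSS Needle DNA defaults (EDNAFULL-like match +5 /
#' mismatch -4, gap open 10, gap extend 0.5).  For protein input a
#' BLOSUM62-style matrix is used instead of match/mismatch.  IUPAC
#' ambiguity codes score as a match only when one code subsumes the other,
#' otherwise as a mismatch.
#'
#' @param match,mismatch DNA match/mismatch scores.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param protein_matrix name of the substitution matrix for protein input.
#' @return a list of class `align_scoring`.
#' @export
align_scoring <- function(match = 5, mismatch = -4, gap_open = 10,
                          gap_extend = 0.5, protein_matrix = "BLOSUM62") {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, protein_matrix = protein_matrix),
            class = "align_scoring")
}

# IUPAC-aware DNA substitution matrix: match score when one code's base set
# contains the other's, mismatch otherwise
.dna_submat <- function(match, mismatch) {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  m <- matrix(mismatch, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (i in seq_along(codes)) for (j in seq_along(codes)) {
    if (all(sets[[i]] %in% sets[[j]]) || all(sets[[j]] %in% sets[[i]]))
      m[i, j] <- match
  }
  m
}

.guess_alphabet <- function(x) {
  ch <- strsplit(toupper(gsub("-", "", x)), "")[[1]]
  if (length(ch) == 0L) stop("empty sequence")
  # ambiguity codes are rare in practice, so classify on the ACGTUN share
  if (mean(ch %in% c("A", "C", "G", "T", "U", "N")) >= 0.9) "dna"
  else "protein"
}

#' Needleman-Wunsch global pairwise alignment
#'
#' Optimal global alignment with affine gap penalties, as used for the
#' pairwise divergence comparisons.  The dynamic programme is delegated to
#' [Biostrings::pairwiseAlignment()]; this wrapper fixes Needle-style
#' scoring and returns a tidy result with identity and gap counts.
#'
#' @param a,b sequences (character scalars), both DNA or both protein.
#' @param scoring an [align_scoring()] configuration.
#' @return an object of class `pairwise_alignment`: list with `a_aligned`,
#'   `b_aligned`, `score`, `identities`, `gaps` (gap columns), `length`.
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  alph <- c(.guess_alphabet(a), .guess_alphabet(b))
  if (alph[1] != alph[2])
    stop("mixed alphabets: one sequence looks like ", alph[1],
         ", the other like ", alph[2])
  if (alph[1] == "dna") {
    mat <- .dna_submat(scoring$match, scoring$mismatch)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = scoring$protein_matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  }
  a_al <- as.character(Biostrings::alignedPattern(pa))
  b_al <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(a_al, "")[[1]]
  cb <- strsplit(b_al, "")[[1]]
  gaps <- sum(ca == "-" | cb == "-")
  idents <- sum(ca == cb & ca != "-")
  out <- structure(list(a_aligned = a_al, b_aligned = b_al,
                        score = Biostrings::score(pa),
                        identities = idents, gaps = gaps,
                        length = length(ca)),
                   class = "pairwise_alignment")
  stopifnot(nchar(out$a_aligned) == nchar(out$b_aligned),
            gsub("-", "", out$a_aligned) == a,
            gsub("-", "", out$b_aligned) == b)
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment: length", x$length, "| identities", x$identities,
      "| gap columns", x$gaps, "| score", format(x$score), "\n")
  invisible(x)
}

#' Percent divergence of a pairwise alignment
#'
#' `include_gaps` (default) treats every non-identical alignment column,
#' including gap columns, as a difference: `100 * (1 - identities/length)`
#' -- the complement of the Needle "Identity" percentage.  `exclude_gaps`
#' restricts to gap-free columns: `100 * (1 - identities/(length - gaps))`.
#'
#' @param aln a `pairwise_alignment` from [global_align()].
#' @param mode `"include_gaps"` or `"exclude_gaps"`.
#' @return percent divergence in `[0, 100]`.
#' @export
percent_divergence <- function(aln, mode = c("include_gaps", "exclude_gaps")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "pairwise_alignment"))
  denom <- if (mode == "include_gaps") aln$length else aln$length - aln$gaps
  if (denom <= 0) stop("all-gap alignment: divergence undefined")
  100 * (1 - aln$identities / denom)
}

#' One-call pairwise divergence between two sequences
#'
#' The pair is aligned in a canonical order (lexicographically smaller
#' sequence first) so the result is exactly symmetric even when tie-broken
#' optimal alignments differ between orders.
#'
#' @inheritParams global_align
#' @inheritParams percent_divergence
#' @return percent divergence.
#' @export
pairwise_divergence <- function(a, b, mode = "include_gaps",
                                scoring = align_scoring()) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  percent_divergence(global_align(a, b, scoring), mode)
}
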