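# Nei-Gojobori (1986) counting estimator of synonymous and nonsynonymous
# substitution rates: per-codon potential-site fractions from the standard
# genetic code, equal-weight averaging over minimal substitution pathways
# for multi-hit codons (pathways through stop codons excluded), and the
# Jukes-Cantor multiple-hit correction d = -3/4 * log(1 - 4p/3).

.split_codons <- function(x) {
  x <- toupper(gsub("-", "", x))
  if (nchar(x) %% 3L != 0L)
    stop("ORF length ", nchar(x), " not divisible by 3")
  substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
}

# synonymous potential-site count of one codon: sum over the 3 positions of
# the fraction of the 3 possible single-base changes that preserve the
# amino acid
.syn_sites <- function(codon, gc) {
  nts <- c("A", "C", "G", "T")
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    cur <- substr(codon, pos, pos)
    for (alt in setdiff(nts, cur)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (gc[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# pathway-averaged (Sd, Nd) contribution of one codon pair
.codon_pair_diffs <- function(ca, cb, gc) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  paths <- .perms(pos)
  tallies <- purrr::map(paths, function(ord) {
    cur <- ca
    sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] == "*") return(NULL)  # pathway through a stop codon
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  })
  ok <- purrr::compact(tallies)
  if (length(ok) == 0L) {
    # all pathways blocked by stops (possible only if an endpoint-adjacent
    # intermediate is a stop in every order); fall back to counting every
    # pathway, scoring stop intermediates as nonsynonymous steps
    ok <- purrr::map(paths, function(ord) {
      cur <- ca
      sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        syn <- gc[[nxt]] != "*" && gc[[cur]] != "*" &&
          gc[[nxt]] == gc[[cur]]
        if (syn) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, ok))
}

#' Codon alignment of two in-frame ORFs via their proteins
#'
#' Translates both ORFs, aligns the proteins globally, back-propagates the
#' protein gaps to codons, and drops codon columns containing a gap or a
#' non-ACGT base in either sequence (pairwise deletion).  A terminal stop
#' codon on either ORF is removed before translation; an internal stop is
#' an error naming the codon.
#'
#' @param orf_a,orf_b in-frame ORF nucleotide strings.
#' @param scoring an [align_scoring()] configuration (protein matrix used).
#' @return list with `codons_a` and `codons_b`, equal-length character
#'   vectors of retained codon columns.
#' @export
codon_align <- function(orf_a, orf_b, scoring = align_scoring()) {
  gc <- .codon_table()
  prep <- function(x) {
    cod <- .split_codons(x)
    if (gc[[cod[length(cod)]]] == "*") cod <- cod[-length(cod)]
    stops <- which(vapply(cod, function(c)
      all(strsplit(c, "")[[1]] %in% c("A", "C", "G", "T")) &&
        gc[[c]] == "*", logical(1)))
    if (length(stops))
      stop("internal stop codon at codon ", stops[1])
    cod
  }
  ca <- prep(orf_a); cb <- prep(orf_b)
  pa <- vapply(ca, function(c) .translate_codon(c, gc), "")
  pb <- vapply(cb, function(c) .translate_codon(c, gc), "")
  aln <- global_align(paste(pa, collapse = ""), paste(pb, collapse = ""),
                      scoring)
  ga <- strsplit(aln$a_aligned, "")[[1]]
  gb <- strsplit(aln$b_aligned, "")[[1]]
  ia <- cumsum(ga != "-")
  ib <- cumsum(gb != "-")
  keep <- which(ga != "-" & gb != "-")
  kca <- ca[ia[keep]]
  kcb <- cb[ib[keep]]
  clean <- vapply(seq_along(kca), function(i)
    all(strsplit(paste0(kca[i], kcb[i]), "")[[1]] %in%
          c("A", "C", "G", "T")), logical(1))
  list(codons_a = unname(kca[clean]), codons_b = unname(kcb[clean]))
}

.translate_codon <- function(codon, gc) {
  if (!all(strsplit(codon, "")[[1]] %in% c("A", "C", "G", "T")))
    return("X")
  gc[[codon]]
}

#' Nei-Gojobori pairwise dN/dS
#'
#' Computes the counting estimator on a paired codon alignment (see
#' [codon_align()]): potential synonymous/nonsynonymous sites `S`/`N`
#' (averaged over the two sequences), observed pathway-averaged differences
#' `Sd`/`Nd`, proportions `pS`/`pN`, Jukes-Cantor corrected rates
#' `dS`/`dN`, and their ratio `omega`.  The correction is undefined at
#' p >= 3/4 and `omega` is undefined when `dS` is 0 or undefined; such
#' values are returned as `NA` and flagged, never clamped.
#'
#' @param pair list with `codons_a`, `codons_b` (from [codon_align()]), or
#'   two ORF strings via `orf_a`/`orf_b` convenience arguments.
#' @param orf_a,orf_b optional raw ORFs, aligned internally when `pair` is
#'   missing.
#' @return a one-row tibble of class `codon_pair_stats` with columns
#'   `codons`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`,
#'   `flag`.
#' @export
nei_gojobori <- function(pair = NULL, orf_a = NULL, orf_b = NULL) {
  if (is.null(pair)) pair <- codon_align(orf_a, orf_b)
  ca <- pair$codons_a; cb <- pair$codons_b
  stopifnot(length(ca) == length(cb))
  if (length(ca) < 1L) stop("no retained codon columns")
  gc <- .codon_table()
  s_a <- sum(vapply(ca, .syn_sites, numeric(1), gc = gc))
  s_b <- sum(vapply(cb, .syn_sites, numeric(1), gc = gc))
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i)
    .codon_pair_diffs(ca[i], cb[i], gc), numeric(2))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  flag <- dplyr::case_when(
    is.na(dS) || is.na(dN) ~ "jc_undefined",
    dS == 0 ~ "omega_undefined",
    TRUE ~ "ok")
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  out <- tibble::tibble(codons = length(ca), S = S, N = N, Sd = Sd,
                        Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
                        omega = omega, flag = flag)
  class(out) <- c("codon_pair_stats", class(out))
  out
}

#' All-pairs dN/dS table for a set of ORF records
#'
#' @param records record tibble with `region == "orf"`.
#' @param scoring an [align_scoring()] configuration.
#' @return tibble with one row per unordered isolate pair: both isolate
#'   and species labels plus the [nei_gojobori()] columns.
#' @export
pairwise_dnds <- function(records, scoring = align_scoring()) {
  stopifnot(nrow(records) >= 2L)
  n <- nrow(records)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    st <- nei_gojobori(codon_align(records$sequence[i],
                                   records$sequence[j], scoring))
    st$isolate_a <- records$isolate[i]
    st$isolate_b <- records$isolate[j]
    st$species_a <- records$species[i]
    st$species_b <- records$species[j]
    rows[[length(rows) + 1L]] <- st
  }
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "isolate_a", "isolate_b", "species_a", "species_b")
}

#' Average dN/dS over sequence pairs
#'
#' Default aggregation is the mean of per-pair omega over pairs where the
#' ratio is defined (`dS > 0`); the alternative is the ratio of mean dN to
#' mean dS.  Scope restricts to interspecies pairs when species labels are
#' available.
#'
#' @param x a record tibble (`region == "orf"`) or a [pairwise_dnds()]
#'   table.
#' @param mode `"pair_mean"` or `"ratio_of_means"`.
#' @param scope `"all"` or `"interspecies"`.
#' @param scoring an [align_scoring()] configuration (record input only).
#' @return mean omega (scalar).
#' @export
mean_omega <- function(x, mode = c("pair_mean", "ratio_of_means"),
                       scope = c("all", "interspecies"),
                       scoring = align_scoring()) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  tab <- if ("sequence" %in% names(x)) pairwise_dnds(x, scoring) else x
  if (scope == "interspecies") {
    if (!"species_a" %in% names(tab)) stop("no species labels for scope")
    tab <- tab[!is.na(tab$species_a) & !is.na(tab$species_b) &
                 tab$species_a != tab$species_b, ]
  }
  if (mode == "pair_mean") {
    ok <- tab$omega[!is.na(tab$omega)]
    if (length(ok) == 0L) stop("no pair with defined omega")
    mean(ok)
  } else {
    ok <- !is.na(tab$dS) & !is.na(tab$dN)
    if (!any(ok) || mean(tab$dS[ok]) == 0) stop("mean dS is 0 or undefined")
    mean(tab$dN[ok]) / mean(tab$dS[ok])
  }
}
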