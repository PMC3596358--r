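---
title: "Methods: divergence, selection and tree congruence in fungal adhesin genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence, selection and tree congruence in fungal adhesin genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madevol)
```

## The scientific question

*Metarhizium* species are insect pathogens and plant-root symbionts.  Two
adhesin genes mediate these two lifestyles: *Mad1* attaches the fungus to
insect cuticle, *Mad2* to plant surfaces.  If plant association has been
the stronger force in the divergence of the genus, *Mad2* should vary more
across species than *Mad1* and its gene tree should track the species
phylogeny (proxied by the 5′ EF-1α locus used for species identification)
more closely.  madevol implements the full comparative workflow needed to
ask that question of any such three-locus panel: pairwise divergence
summaries, counting-based dN/dS, maximum-parsimony trees with bootstrap,
maximum-agreement-subtree (MAST) congruence with the Icong index, promoter
element scanning, and protein tandem-repeat annotation — plus a simulator
that generates panels with known truth so every stage is testable without
sequence downloads.

## Pairwise divergence

Pairwise comparisons use optimal global (Needleman–Wunsch) alignment with
affine gaps, delegated to `Biostrings::pairwiseAlignment()` under
Needle-style DNA defaults: match +5, mismatch −4, gap open 10, gap extend
0.5.  IUPAC ambiguity codes count as a match only when one code's base set
contains the other's; anything else is a mismatch.  Percent divergence is
`100 * (1 - identities / length)` over all alignment columns
(`include_gaps`, the complement of the Needle "Identity" percentage) or
over gap-free columns (`exclude_gaps`).  Which convention produced a given
published percentage is rarely stated, so both are provided;
`include_gaps` is the default.  Because tie-broken optimal alignments can
differ between argument orders, `pairwise_divergence()` canonicalises the
pair order so the divergence matrix is exactly symmetric.

Species-level summaries aggregate the isolate-pair matrix.  "Overall
interspecies variation" is ambiguous between (a) the mean of species-pair
means and (b) the mean over all cross-species isolate pairs; both are
implemented and (a) — which weights every species pair equally regardless
of sampling depth — is the default.

## Nei–Gojobori dN/dS

The counting estimator works per codon pair on a protein-guided codon
alignment (proteins aligned globally under BLOSUM62, gaps back-propagated
to codons, codon columns with a gap or ambiguity in either sequence
dropped).  Potential synonymous sites per codon are the sum over its three
positions of the fraction of the three possible base changes that preserve
the amino acid; S is averaged between the two sequences and N = 3·(codons)
− S.  Codons differing at d positions contribute differences averaged over
all d! substitution orderings, excluding orderings that pass through a
stop codon (if every ordering is blocked — possible only for rare
codon pairs — all orderings are counted with stop-crossing steps scored
nonsynonymous, and this fallback is deterministic).  Proportions are
corrected for multiple hits with Jukes–Cantor, d = −(3/4)·ln(1 − 4p/3),
which is undefined at p ≥ 3/4: such pairs are flagged, never clamped.
ω = dN/dS is undefined when dS = 0.

"Average dN/dS" over a panel again has two readings: the mean of per-pair
ω over pairs where it is defined (default) or the ratio of mean dN to mean
dS.  Both are available and the choice is recorded in pipeline output.

## Maximum parsimony

Tree inference follows the PHYLIP-style protocol: per search, 10
random-addition starts each refined by SPR branch swapping until no
rearrangement improves the Fitch score, keeping all distinct equally-best
trees; nonparametric bootstrap resamples alignment columns (the reference
protocol uses 1000 pseudoreplicates; reduced runs trade support precision
roughly as a binomial standard error, and the test suite uses 10–30
replicates at its reduced problem sizes).  Scoring and search are
delegated to phangorn, the R implementation of this algorithm family; the
package fixes the protocol, seeding, and the gap policy — gaps as missing
data by default (the dnapars convention), or as a fifth (21st) state by
flag.  Protein trees use unordered Fitch states over the 20-letter
alphabet.  Trees are reported unrooted; published figure rootings are
presentational.

## MAST and the Icong index

The MAST of two trees is the largest leaf subset on which their restricted
topologies are identical.  The rooted MAST is computed by the classical
dynamic programme over node pairs (implemented in C++); the unrooted MAST
uses the identity that any unrooted agreement set containing leaf *x*
corresponds to a rooted agreement of the two trees re-rooted at *x*, so it
equals the maximum over shared leaves of 1 + the rooted MAST of the
re-rooted, *x*-deleted trees.  Ties among equally large agreement sets are
broken deterministically (lexicographically smallest of the per-rooting
optima).  Multifurcating inputs (e.g. consensus trees) are resolved
deterministically with `multi2di` and flagged; soft-polytomy semantics are
not implemented.

Icong divides the observed MAST size by the expected MAST size of two
independent random binary trees with the same leaf count.  That
expectation was calibrated here by simulation: uniform random tree pairs
(sequential uniform edge attachment, which is exact for both the rooted
and unrooted uniform distributions) at each leaf count n = 4…64, 6,000
pairs per n, give a mean MAST that follows a power law in n.  Two facts
emerged from the calibration and drive a design decision:

* the null of **rooted** MAST over uniform random **rooted** pairs has
  mean 5.46 ± 0.01 at n = 14 and power-law fit `1.4194 · n^0.5083`
  (5.429 at n = 14), matching the reference tool's internal anchor
  (11/2.03 ≈ 10/1.84 ≈ 9/1.66 ≈ 5.42);
* the unrooted-maximised null is systematically larger (mean 6.59 at
  n = 14) and does not match that anchor.

`expected_mast()` therefore uses the rooted-null power law, the convention
of the published index.  `mast()` compares rooted inputs as rooted and
maximises over rootings for unrooted inputs (the `rooted` argument
overrides the auto-detection), so users comparing unrooted inference
output should know the index is mildly anti-conservative in that case —
the same situation as feeding arbitrarily rooted program output to the
original tool.

The p-value models the null tail as log-linear in the MAST size m with
leaf-count-dependent intercept and slope,
`log P(MAST ≥ m) = (a0 + a1·log n) + (b0 + b1·log n)·m`.  The n-scaling
(a1 = 3.2119, b1 = 0.66753) is fitted to the simulated null tails
(300,000–1,500,000 pairs per n; per-n log-linear fits have r² ≥ 0.98), and
the n = 14 anchor is set to the reference tool's three published
(m, p) pairs, which lie exactly on a log-linear tail of slope −2.468.  The
simulated tail independently agrees with those anchors to within a factor
of about two — the accuracy limit of this approximation.  p-values are
capped at 1 and are comparative statistics, not exact tail probabilities.

## Promoter elements

The scanner reports exact matches, on the coding strand, of the
stress-responsive element STRE (AGGGG), the post-diauxic-shift element PDS
(AAGGGA), the TATA-box-like TACATA, and degenerate-TATA (TATG) repeat
arrays, with maximal TATG runs merged into a single hit carrying a repeat
count.  Coordinates follow the −1-before-ATG convention: the promoter is
supplied 5′→3′ ending immediately before the ORF start, and a hit's
position is the upstream coordinate of its 5′-most base.  Overlapping hits
of different elements are both reported; overlapping matches of the same
element collapse to the 5′-most.  Reverse-strand scanning is deliberately
off by default, as the elements are defined on the coding strand.

## Protein features

Translation uses the standard nuclear code, removes the terminal stop (an
ORF of 3L nt yields L − 1 residues), and reports internal stops as errors
with their codon index.  Tandem repeats are counted as the longest run of
consecutive unit copies, each within `max_mismatch` substitutions of the
unit (default 2 per 12-mer — Thr-rich adhesin repeats drift, so exact
matching is optional), with leftmost-longest tie-breaking.

## The synthetic-data generator

`simulate_dataset()` evolves a promoter + ORF locus down a known isolate
tree.  The default tree carries 14 isolates in 7 species with the clade
structure of the *Metarhizium* complex (a PARB clade, an MGT clade, and
distant *M. lepidiotae* / *M. acridum* lineages); branch lengths are
expected neutral substitutions per site, chosen so realized ORF
divergences span ~0.1% within species to ~15–18% against *M. acridum*.

The ORF evolves by proposal thinning: single-base proposals (uniform
across sites; transitions weighted by κ) are accepted always if
synonymous, with probability ω if nonsynonymous, and never if they create
a stop codon.  This makes the realized dN/dS equal ω on the scale the
Nei–Gojobori estimator measures.  κ defaults to 1 because the estimator of
record assumes no transition bias; raising κ is supported but biases the
counting estimator, as it does on real data.  The promoter evolves
neutrally at `promoter_rate_mult` × the synonymous rate, default 1.3, so
promoter divergence exceeds ORF divergence for every species pair — the
qualitative contrast of interest.  (Quantitatively, a published
promoter/ORF divergence ratio of ~1.34 with ω ≈ 0.31 would imply a
promoter rate *below* the synonymous rate, since purifying selection slows
the ORF; the default favours the qualitative regime.)

Species-specific features are stamped rather than mutated: promoter
element layouts (an ancestral layout modified by per-species gain / loss /
replace / set-count events, with inconsistent events rejected) and
domain-B repeat arrays (default: eight copies of GKETTPAQQTTP in
*M. acridum*, six elsewhere, inserted mid-ORF).  Stamped windows, the
start/stop codons and the repeat array are excluded from point
substitution so the generating truth is exactly recoverable; this is a
deliberate idealisation.  Because the only indels are repeat copy-number
differences, the generator also emits the true multiple alignment
(`aligned`, including a translated protein region), which is what the tree
stages consume — multiple-alignment heuristics are outside the package's
scope, and real data should arrive pre-aligned.

What passing tests on this generator do **not** show about real data:
there is no rate heterogeneity among sites beyond the ω partition, no
recombination or gene conversion, no indel process beyond the repeat
arrays, motif windows cannot degrade by point mutation, and promoters are
length-conserved.  Estimator behaviour under those violations is untested
here.

## Reproducing the published panel

The deposited sequences of the original 14-isolate panel live in GenBank
(KC484624–KC484651 plus EF-1α records); the package performs no network
access, so `repro_report()` runs the full computation on a local directory
of FASTA files and compares against `repro_targets()` — the published
divergences (±0.3 points), mean dN/dS (±0.05), MAST/Icong grid (exact /
±0.01), protein lengths and repeat counts (exact).  The test suite
exercises this machinery on simulated stand-ins only.

## Problem sizes and determinism

Every stochastic step takes an explicit integer seed and is fully
reproducible (byte-identical simulator output, identical search and
bootstrap results).  The test and acceptance runs use desk-scale sizes
chosen to finish in minutes on one core: 200 random tree pairs at n ≤ 8
for the MAST oracle, 50 five/six-taxon matrices for the parsimony oracle,
2,000-codon pairs for ω recovery, 400 random rooted 14-leaf pairs for the
null-mean check, and 10–30 bootstrap replicates in pipeline smoke tests.
The calibration constants baked into `expected_mast()` and the p-value
model were fitted once from the larger simulations described above and are
fixed; they are not refitted at run time.

## Known limitations

* The Icong null calibration assumes uniformly random binary topologies;
  trees with strong shape signal (very unbalanced true trees) depart from
  it.
* p-values are a log-linear tail approximation anchored at n = 14;
  far from the calibrated range (n ≫ 64) they extrapolate.
* The Nei–Gojobori estimator underestimates selection strength under
  transition bias and saturates near p = 3/4; no maximum-likelihood codon
  model is provided, by design.
* `mp_search()` is a heuristic; equality with the global optimum is
  guaranteed only where the exhaustive oracle can check it (≤ ~7 taxa),
  which is exactly what the tests do.
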