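---
title: "COI barcode diagnostics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{COI barcode diagnostics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coidiag)
```

## The problem

Biosecurity surveillance for tussock moths (*Lymantria*, including the gypsy
moth *L. dispar*) depends on identifying trapped or intercepted specimens
that are often immature, damaged, or morphologically ambiguous. Two
molecular approaches address this from the same mitochondrial gene region:
the full ~658-bp COI DNA barcode, and a legacy two-enzyme restriction-digest
typing of a shorter COI amplicon (the "NB system": presence/absence of an
NlaIII and a BamHI site). This package implements the complete analytical
toolkit around a COI barcode reference library — auditing the library's
diagnostic power, assigning unknown specimens to species and subspecies,
and emulating the NB digest in silico so the two systems can be compared on
the same sequences.

## Distances and the barcode gap

Pairwise divergence uses the Kimura 2-parameter model,

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q),$$

where $P$ and $Q$ are the proportions of transition (A↔G, C↔T) and
transversion differences over the *comparable* sites of the pair. Sites
where either sequence carries a gap, N, or another IUPAC ambiguity code are
excluded per pair (pairwise deletion), which is the right behaviour for
libraries that mix full-length barcodes with short legacy fragments. Two
degeneracies are flagged rather than silently propagated: pairs with no
comparable sites ("undefined") and pairs where a log argument is
non-positive ("saturated"); both are excluded from, but counted by, every
summary.

Species-level diagnosis rests on the barcode gap: the separation between
the distribution of within-species distances and between-species distances.
Following common practice for libraries of this shape, the intraspecific
set pools all within-species pairs over species with at least two members,
while the interspecific set takes one value per species pair (the mean of
all cross pairs), so a 36-species library always yields
$\binom{36}{2} = 630$ interspecific comparisons. `overlap_analysis()`
counts both sets inside a closed percent window (default [2, 4]%, the zone
where the two distributions can touch) and names the species involved —
these are exactly the taxa whose identifications deserve a second look.

## Trees, monophyly, and the differentiation tally

`nj_tree()` is a from-scratch Saitou–Nei neighbour-joining implementation.
It is deterministic: ties in the Q matrix break on the lowest (row, column)
pair in the current ordering, and negative branch lengths are clamped to
zero with the deficit moved to the sibling edge (the convention of the
distance-tree software this field has historically used; raw values are
retained in an attribute). On an additive matrix the implementation
reproduces the generating tree exactly — topology and branch lengths — which
the test suite verifies against 100 random trees and against ape's
independent NJ.

Node confidence comes from a nonparametric bootstrap that resamples
alignment columns with replacement and recomputes the K2P matrix (pairwise
deletion re-applied) and NJ tree per replicate; each internal bipartition of
the reference tree is scored by the percent of replicates containing it.
Replicates whose resampled matrix contains an undefined distance are
redrawn (with a hard cap); replicates with merely saturated pairs keep
going, substituting the largest defined distance, since those only perturb
the deepest branches.

A species is *successfully differentiated* when its barcodes form a
monophyletic cluster on the tree and none of its haplotypes is shared with
another species; a species sampled once is judged on haplotype sharing
alone. Monophyly needs a root: an outgroup when one is supplied, otherwise
midpoint rooting. The overall tally (successes / species) is the headline
number of a library audit. The package ships a fixture generator,
`simulate_paraphyly_library()`, that reproduces the one canonical failure
mode — a deep (default 2.9%) intraspecific split with another species'
singleton nested inside it — for which the tally is exactly
$(n-1)/n$ (97.2% at 36 species).

## Haplotypes with missing data

Real libraries contain truncated sequences, so haplotype identity is not
well-defined without a convention. Ours: two records share a haplotype iff
they are identical at every column where both are unambiguous *and* that
shared coverage is at least `min_overlap` columns (default 300); grouping is
the transitive closure of this relation, and records with fewer than
`min_overlap` unambiguous bases are set aside and reported. Ambiguity codes
never match anything — a conservative choice that splits rather than lumps —
whereas for distances the same codes are merely excluded columns, an
unbiased choice. Reported haplotype totals therefore depend on
`min_overlap`, and totals from libraries with many short sequences should
be read with that in mind.

## Bayesian assignment from segregating sites

The assignment test asks, for each candidate taxon: *if this query belonged
here, how surprising would the joint sample be?* Concretely, for candidate
$j$ with $n_j$ sequences and $S_j$ segregating sites, the taxon's mutation
rate is estimated by Watterson's
$\hat\theta_j = S_j / \sum_{i=1}^{n_j-1} 1/i$; the query is added and the
segregating sites recounted ($S'_j$); the likelihood is
$\Pr(S_{n_j+1} = S'_j \mid \hat\theta_j)$ under the neutral coalescent with
infinite-sites mutation. A conspecific query adds few or no sites; a
foreign query at ~14% divergence adds dozens, which the coalescent
distribution penalises by many orders of magnitude. Posteriors follow from
a prior over candidates (uniform by default) and the reported risk of
mis-assignment is $1 - $ posterior, i.e. 0–1 loss. This is a deliberately
transparent loss choice; published assignment tables built on other
software imply a different (unreproducible) loss function, so risks are
comparable within this package but not across programs.

The distribution of $S_n$ is computed exactly: while $i$ lineages remain,
the number of mutations in that coalescent epoch is geometric with success
probability $(i-1)/(\theta+i-1)$, independently across epochs, so the pmf
is a convolution of $n-1$ geometrics. The convolution involves only
positive terms and an $O(k)$ recurrence per epoch, making it numerically
stable at any sample size — unlike the equivalent alternating
inclusion–exclusion series, which cancels catastrophically beyond a few
dozen sequences (and which the tests keep as an independent small-$n$
oracle).

Three degenerate situations have explicit policies, all flagged in the
per-candidate output:

* **Truncated queries.** Columns where the query is a gap or ambiguity are
  dropped for all of that query's computations (query-wise pairwise
  deletion), including the candidates' own $S_j$ and $\hat\theta_j$, so the
  comparison is apples-to-apples on the covered region.
* **Singleton candidates.** A taxon sampled once has no $\hat\theta$; it is
  scored as a two-sequence sample (singleton + query) with the library-wide
  median $\hat\theta$ borrowed as its rate.
* **Monomorphic candidates.** $\hat\theta = 0$ is a degenerate estimate
  under which any new variant is impossible, which would veto the *true*
  species whenever the query carries even one private substitution. Such
  candidates also borrow the median $\hat\theta$ (the same empirical
  borrowing as singletons). With no polymorphic taxon anywhere in the
  library, $\theta = 0$ semantics apply unchanged: likelihood 1 iff the
  query adds nothing.

Ties break lexicographically on the taxon label and are reported.
`loo_validate()` wraps the standard leave-one-out design: for every taxon
with at least three members, one seeded-random sequence is removed and
assigned back against the remainder.

## The NB system in silico

NB typing reads the two diagnostic windows directly from sequence:
NlaIII (CATG) and BamHI (GGATCC) presence yields the four classes N±B±.
A window not covered by unambiguous bases gives "undeterminable" — distinct
from site absence, which matters for truncated legacy material. Digest
prediction cuts at every motif occurrence (NlaIII after position 4 of its
motif, BamHI after position 1, the enzymes' actual cut sides; this shifts
fragment sizes by ±3 bp at most) and fragment lengths always sum to the
amplicon length.

The historical assay's exact coordinates are only schematic in the
literature, so the window locations are configuration, shipped as a JSON
file and defaulted so that the classic fragment signatures are reproduced:
on the 378-bp legacy amplicon, NlaIII gives ~350 + ~28 bp when N+ and
BamHI ~360 + ~18 bp when B+; on the full barcode, a monomorphic 5' NlaIII
site means an NlaIII digest shows two bands (N−) or three (N+). The
simulator plants sites through the same configuration, so typing is
testable end to end. One caveat: on *random* background sequence, CATG
recurs incidentally about once per 256 bp; real COI lacks these extra
sites, so exact band-count claims are made on canonical (incidental-motif
free) amplicons, while the conservation invariant holds on any input.
`nb_vs_barcode_report()` makes the comparison the toolkit exists for: NB
classes are four at most and collide across species, while barcode
haplotypes are species-unique whenever the library says so — a specimen
misidentified before an NB assay can be typed to a class that reads as the
wrong species' provenance.

## The simulator: what it emulates and what it does not

`simulate_library()` generates the study conditions the analyses assume:
a uniform random root; species ancestors diverged from it by Poisson
numbers of K80 substitutions with mean `mean_inter_divergence * L / 2`
each (star phylogeny, so pairwise between-species distances centre on the
configured mean, 14.02% by default); individuals diverged from their
species ancestor with mean `mean_intra_divergence * L / 2` (pairwise
within-species mean 0.66% by default); optional subspecies ancestors in
between; NB windows overwritten per the site plan; truncation applied
last. The K80 process (transition fraction $\kappa/(\kappa+2)$, default
$\kappa = 2$) is chosen to match the K2P estimator's assumptions, because
the quantity under test is K2P recovery, not model robustness. Substitution
counts are Poisson draws on expected distances with multiple hits allowed,
so realized distances shrink slightly below the nominal means at high
divergence — the recovery tests allow ±20% for this plus sampling noise.

Default sizes are the desk-scale study conditions: 36 species × 5 members ×
658 bp for the audit and assignment checks, 100 held-out queries, 100
bootstrap replicates, three seeds where a claim is stochastic. These sizes
keep the full test suite around a minute while leaving Monte-Carlo margins
comfortable.

What the simulator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: rate variation among sites and lineages
(real COI is GTR+I+G-ish, so real K2P distances are mildly model-mismatched),
non-star species phylogenies with shared internal branches, indels and
pseudogenes (absent from curated barcode data anyway), geographic
population structure within species, and incidental restriction sites in
non-window regions of real amplicons. The differentiation tally on default
simulations is 100% by construction; the engineered-paraphyly fixture
exists precisely because real libraries fail in structured ways that
uniform simulations never produce.

## Numerical and interface choices

* Distances: flagged (undefined/saturated) pairs are `NA`, excluded from
  summaries, counted in `n_flagged`. The overlap window is closed on both
  ends; boundaries are configurable.
* NJ: tie-break and clamping as above; input with any undefined entry is
  an error naming the offending pairs.
* `prob_segsites(n, theta = 0, k)` is the point mass at 0; the convolution
  truncates at the largest `k` requested.
* Posteriors sum to 1 within 1e-9 by construction; an all-zero likelihood
  vector yields an explicit "unassignable" result, never an exception.
* Haplotype collapsing, bootstrap, query draws and the simulator all take
  explicit integer seeds; identical seeds give byte-identical outputs.
* Alignment is assumed given (COI barcodes are length-conserved); ragged
  FASTA input is rejected unless `assume_5prime_anchored = TRUE`, which
  right-pads with gaps.

## Known limitations

Assignment risks are 0–1-loss complements, not expected misclassification
costs under a calibrated loss. Haplotype totals depend on the
`min_overlap` convention. The NB window defaults are a faithful but not
historically exact reconstruction of the legacy assay's coordinates.
Bootstrap supports on very short resampled alignments can be depressed by
the saturated-distance substitution. None of these affect the package's
comparative conclusions (barcode vs NB resolution, species vs subspecies
confidence), which the acceptance script recomputes from scratch on every
run.
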