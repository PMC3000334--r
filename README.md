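# coidiag

COI DNA-barcode diagnostics for species identification and biosurveillance,
built around the workflow used for tussock moths (*Lymantria*, including the
gypsy moth): audit a barcode reference library, assign unknown specimens to
species and subspecies with a coalescent Bayesian test, and emulate the
legacy two-enzyme "NB" restriction-digest typing system in silico.

## Who this is for

Anyone building or using a curated COI reference library for diagnostics:
biosecurity and monitoring labs assigning trapped/intercepted specimens,
and barcoding projects that need to quantify how well their library
separates the species it covers.

## What it computes

* **Distances & barcode gap.** Kimura 2-parameter distances with pairwise
  deletion, `d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)` over the sites comparable
  per pair; pooled intraspecific vs per-species-pair interspecific
  summaries; counts of comparisons in a configurable overlap window
  (default the closed [2, 4]% zone); divergence histograms.
* **Trees & differentiation.** From-scratch deterministic neighbour-joining
  (exact on additive matrices), column-resampling bootstrap supports, and
  the two-part differentiation criterion: a species succeeds when its
  barcodes are monophyletic and share no haplotype with another species
  (haplotype sharing alone for singletons).
* **Haplotypes.** Overlap-identity collapsing with transitive closure for
  libraries that mix full-length and truncated sequences.
* **Bayesian assignment.** For each candidate taxon, the query is added to
  the sample and the number of segregating sites re-counted; the likelihood
  of the enlarged count under the taxon's Watterson estimate
  `theta_hat = S / sum(1/i)` and the exact coalescent distribution of
  segregating sites gives posteriors, risks (1 - posterior) and
  diagnostic-site counts, with leave-one-out validation.
* **NB restriction typing.** NlaIII/BamHI site presence read from sequence
  (classes N+B+, N+B-, N-B+, N-B-), predicted digest fragments for the
  legacy ~378-bp amplicon and the 658-bp barcode, and a comparison report
  showing where the four-class NB partition collides across species while
  barcode haplotypes stay species-unique.
* **Simulator.** A seeded generator reproducing the study conditions
  (36 species x 5 members, 0.66% within- / 14.02% between-species K2P,
  K80 mutation, planted NB sites, truncation), plus held-out and
  novel-species query generators and an engineered-paraphyly fixture.

## Worked example

```r
library(coidiag)

sim   <- simulate_library(sim_config(seed = 1))   # 36 species x 5 members
audit <- run_library_audit(sim$library, bootstrap_replicates = 100, seed = 1)
print(audit)
```

```
library audit: 180 records, 36 species
  intra: mean 0.67% (SD 0.31, max 1.85); inter: mean 14.81% (SD 1.55, range 10.48-18.56); ratio 22.2x
  overlap window: 0 of 360 intra, 0 of 630 inter comparisons
  haplotypes: 178 (0 shared between species)
  differentiation: 36 of 36 species (100.0%)
```

The audit says the simulated library behaves like a healthy reference
library: within-species variation (0.67%) sits ~22-fold below
between-species divergence (14.81%), no distances fall in the [2, 4]%
overlap zone, no haplotype is shared between species, and every species
passes the monophyly + unshared-haplotype criterion.

Assigning a held-out specimen back against the library:

```r
q   <- simulate_queries(sim$library, sim$truth, 3, "held_out", seed = 101)
res <- assign_query(q$library, q$queries$seq[1, ],
                    query_id = rownames(q$queries$seq)[1])
print(res)
```

```
query sp15_03 -> sp15 (posterior 1.000, risk 1.78e-04, 20 diagnostic sites)
```

The query is returned to its true species with posterior ~1; the 20
diagnostic sites are columns where sp15 is fixed for a state seen in no
other species. NB typing of any record reads the two diagnostic windows
and predicts the digest:

```r
print(nb_type(sim$library$seq["sp01_01", ]))
```

```
NB haplotype: N-B-
legacy amplicon NlaIII: 341/37 bp; BamHI: 378 bp
```

A thin command-line wrapper over the same functions lives at
`inst/cli/coidiag.R` (subcommands `simulate`, `audit`, `assign`,
`nb-type`).

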