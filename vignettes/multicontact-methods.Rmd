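---
title: "Multi-contact 3C analysis with TriContact: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-contact 3C analysis with TriContact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TriContact)
```

## The data and the problem

Viewpoint-primed multi-contact chromosome conformation capture (3C-HTGTS,
MC-4C and relatives) produces sequencing reads that are concatemers of
restriction fragments ligated in a single proximity-ligation event.  Every
read is primed from one bait fragment — the *viewpoint* (VP) — so each read
reports a set of loci that were simultaneously close to the viewpoint in one
cell.  Pairwise 4C-style profiles discard this simultaneity; the value of
multi-contact data is precisely that a read with fragments *A* and *B*
witnesses a *triple* (VP, A, B) in a single nucleus.

TriContact covers the computational chain from raw concatemer reads to
classified triples:

1. in-silico digestion of a genome into a restriction fragment map, with an
   exact-match sequence index (`digestGenome()`, `buildSequenceIndex()`);
2. decomposition of each read into an ordered *fragment chain* with
   off-target, self-ligation and continuous-fragment filtering
   (`splitRead()`, `assignFragments()`, `buildChain()`, `readsToChains()`);
3. viewpoint profiles with counts-per-million-in-cis (CPM-in-cis)
   normalization and bedGraph export (`countPairwise()`,
   `cpmCisNormalize()`);
4. binned three-way contact matrices, total-count normalization,
   subtraction and loop calling (`buildThreewayMatrix()`,
   `normalizeMatrixTotal()`, `subtractMatrices()`, `callLoops()`);
5. the VP-SOI resampling z-score test classifying third sites as
   cooperative, random or competitive partners of a viewpoint-SOI pair
   (`vpSoiTest()`);
6. a synthetic concatemer generator with planted ground truth
   (`locusModel()`, `simulateGenome()`, `simulateReads()`,
   `emitConditionPair()`).

## Digestion model

A `RestrictionEnzyme` is a recognition sequence in IUPAC code plus a *cut
offset*: an occurrence starting at 0-based position $s$ contributes a
fragment boundary at $s + \text{cutOffset}$.  Both strands are scanned; a
minus-strand occurrence contributes the mirrored physical cut
$s + (\ell - \text{cutOffset})$ for site length $\ell$ (a no-op for
palindromic sites).  Boundaries are deduplicated, 0 and the chromosome
length added, and the fragments between consecutive boundaries tile the
chromosome with no gaps.  Fragment ids are global and consecutive within a
chromosome, so an id difference of 1 is genomic adjacency — the property
the downstream self-ligation and continuous-fragment filters rely on.

IUPAC codes in the site match their base sets; code N matches any base and
a literal N, while a genomic N is matched by *no other* code, so N-runs in
an assembly cannot create spurious cut sites.  Overlapping occurrences each
contribute a boundary.

The default enzyme is an NlaIII-like 4-cutter: site `CATG`, cut offset 4,
leaving `CATG` at the 3' end of the upstream fragment.  Multi-contact 3C
protocols conventionally use a frequent 4-bp cutter to obtain fine fragment
resolution; the enzyme is fully configurable and nothing downstream depends
on this default.

Fragment assignment is by exact sequence lookup: each fragment's sequence
and reverse complement are indexed, fragments shorter than `minLength`
(default 20 bp, about the shortest uniquely mappable length at this
fragment density) are skipped, and sequences shared by more than one
fragment are excluded as ambiguous rather than guessed.  This replaces a
short-read aligner for the exact-sequence regime the package targets;
externally aligned fragment chains can be supplied as TSV via
`readChains()`.

## Fragment chains and artifact filters

`buildChain()` applies the filters in a fixed order:

* **Off-target rejection** — a read whose first assigned fragment is not
  the viewpoint fragment was not primed from the bait and is rejected.
* **Self-ligation** — members within `selfLigationWindow` fragment ids of
  the viewpoint (default 1, i.e. the viewpoint and its immediate
  neighbours) are removed; these arise from re-ligation of the bait to
  itself or from incomplete digestion at the bait, and would otherwise
  dominate every profile.  The window of 1 is standard 4C practice.
* **Continuous fragments** — consecutive members that are genomically
  adjacent (id difference at most 1) are runs of undigested neighbours, a
  digestion artifact rather than three independent contacts; each run is
  collapsed to its first member.
* **Duplicates** — repeated member ids keep their first occurrence.

A chain emptied by filtering is rejected (`EMPTY_AFTER_FILTER`); all
rejections and member-level drops are tallied by category and conserved:
reads in = retained + rejected.  PCR deduplication by identical
(viewpoint, members) tuples is available behind `dedupReads` and off by
default, since a legitimate recurrent contact configuration is
indistinguishable from a duplicate at this level.

## Pairwise profiles

`countPairwise()` defaults to `first_only`: one count per chain, for the
first digested fragment ligated behind the viewpoint — the fragment
captured by the primary ligation event, and the conventional 4C-type
signal.  `all_members` counts every distinct member once per chain and is
provided for sensitivity analysis; it is never smaller fragment-wise.

CPM-in-cis normalization scales counts so that the viewpoint chromosome's
counts total $10^6$: $\text{scale} = 10^6 / \text{cis total}$.  Trans
fragments are retained and scaled by the same cis-derived factor (the
denominator is "in cis" by definition); `dropTrans = TRUE` removes them.
The invariant — cis normalized values sum to exactly $10^6$ whenever any
cis count exists — is what makes profiles with different sequencing depths
comparable, and is enforced by tests to $10^{-6}$ relative tolerance.

## Three-way contact matrices

`binGrid()` defines half-open bins of fixed resolution over an analysis
window; 3, 5 and 10 kb are the conventional choices at this locus scale.
Fragments map to bins by midpoint (a fragment is a single restriction
fragment, much smaller than a bin, so the midpoint convention matters only
at bin edges).

`buildThreewayMatrix()` counts viewpoint-anchored bin pairs per chain:

* `first_two` — the first two digested fragments following the viewpoint;
  one pair per chain; skipped when either of those two is outside the
  window;
* `all_triples` — every unordered pair of distinct members; a chain with
  $m$ in-window members contributes $\binom{m}{2}$ pairs, each pair being
  one VP-anchored triple.  Read-order permutations are not distinguished.

Each unordered pair is counted **once** in the matrix total; the stored
matrix mirrors off-diagonal counts so displays are symmetric.  Same-bin
pairs increment the diagonal once.  This convention removes the
double-counting ambiguity from "normalize to a total of 1,000,000
interactions": `normalizeMatrixTotal()` scales a raw matrix so the
unordered-pair total is exactly $10^6$, and a zero matrix maps to zero.

Subtraction (`subtractMatrices()`) is entrywise on identical grids of two
normalized matrices, as in knockout-minus-wild-type difference heatmaps;
`crossBoundarySum()` aggregates a difference matrix over bin pairs
straddling a boundary coordinate.  Loop calling (`callLoops()`) applies an
inclusive threshold (default 5) to *raw* contact frequencies on the
off-diagonal upper triangle — normalization rescales all entries equally
and would make the threshold depth-dependent.  No adjacent-bin merging is
performed.

## The VP-SOI resampling test

Given a second site of interest (SOI), reads split into a **positive set**
(viewpoint and SOI co-occur in the read) and a **negative set** (viewpoint
only).  For every bin, the observed statistic is the fraction of positive
reads with at least one member in the bin — per-read presence, not
fragment counts, so one read never contributes more than once to a bin.

The null distribution is built by resampling: each of `nIterations`
(default 1,000) iterations draws as many negative reads as the positive
set holds, removes one uniformly chosen member from each drawn read — the
counterpart of the SOI fragment that every positive read necessarily
carries — and tallies the same per-bin presence fraction.  The per-bin
mean $\mu_b$ and population standard deviation $\sigma_b$ across
iterations give

$$ z_b = \frac{f_b - \mu_b}{\sigma_b}, $$

and bins classify as cooperative ($z \ge$ `zThreshold`), competitive
($z \le -$`zThreshold`) or random, with the threshold defaulting to 2 —
a conventional two-sigma rule, surfaced in the output metadata since any
choice here is a display convention rather than a calibrated error rate.
Bins overlapping the viewpoint fragment or the SOI are labelled `excluded`
instead of classified, to avoid trivial self-signals.

### Why sampled reads are matched by size

Reads with more fragments are more likely to contain the SOI, so the
positive set is enriched for large reads.  Removing one fragment from each
sampled negative read equalizes the *mean* number of informative fragments
only if the two sets share a read-size distribution; with size-blind
sampling the positive set retains more fragments per read and every bin's
z-score inflates.  On synthetic null libraries (no planted triads, 20,000
reads) size-blind sampling gives a genome-wide mean z of roughly +0.5 to
+1.0, growing with the positive-set size; matching the sampled reads'
member counts to the positive set's member counts (nearest non-empty size
stratum when one is exhausted) restores the mean to about 0.02.
`matchCardinality = TRUE` is therefore the default; the size-blind variant
remains available for comparison.

### Numerical conventions

* Sampling is without replacement by default; `allowReplacement = TRUE`
  permits positive sets larger than the negative pool (each duplicate draw
  of a read loses its own independently chosen fragment).
* $\sigma_b = 0$ leaves $z$ undefined: the bin is `random` when
  $f_b = \mu_b$ and otherwise classified by sign, with $z$ reported as
  $\pm\infty$ (written `inf`/`-inf` in TSV output).
* The population (n-denominator) standard deviation is used across
  iterations; with one iteration it is zero by definition.
* All randomness derives from a single integer seed; identical seeds and
  inputs give bit-identical results, and the caller's RNG state is
  restored on exit.

## The synthetic generator

`locusModel()` describes a single toy locus; its defaults are the regime
the package is meant for, chosen once:

| parameter | default | rationale |
|---|---|---|
| `genomeLength` | 500 kb | a sub-megabase locus, the scale of a large antigen-receptor locus analysis window |
| `siteSpacing` | 150 bp | mean NlaIII-like fragment length in mammalian genomes (4-cutter, $4^4 = 256$ bp naive expectation, shorter in GC-rich loci) |
| `minFragLength` | 50 bp | shortest fragment that assigns reliably at the default index `minLength` |
| `viewpointPos` | 250 kb | mid-locus, so both directions are observable |
| `decayExponent` | 1 | the distance-decay slope commonly observed for intra-TAD 3C contact frequency |
| `cardinalityProbs` | (.35, .30, .20, .10, .05) | reads carry 1–5 ligated partners, most reads small — typical concatemer cardinality |

`simulateGenome()` plants recognition sites at exponentially distributed
spacing, scrubs accidental sites from fragment interiors (mutating one
base per occurrence until none remain), regenerates any colliding
fragment sequences so the exact-match index is unambiguous, and verifies
that digesting the emitted sequence reproduces the planted boundaries.

`simulateReads()` draws, per read, a partner count $k$ from the
cardinality distribution and then $k$ distinct partners sequentially with
probability $\propto d^{-\alpha}$ ($d$ = midpoint distance to the
viewpoint; the viewpoint fragment and its immediate neighbours are never
partners, mirroring the self-ligation filter).  Two planted structures
modulate the weights:

* **boundary insulation** — partners across `boundaryPos` from the
  viewpoint are down-weighted by $\gamma \in (0, 1]$, emulating a TAD
  boundary; `emitConditionPair()` emits two libraries differing only in
  $\gamma$ (matched but independent seed streams), the wild-type vs
  boundary-knockout contrast;
* **triads** — after a fragment inside interval A is drawn, weights of
  fragments in interval B are multiplied by $\beta$ for the remaining
  draws ($\beta > 1$ cooperative, $\beta < 1$ competitive).  The effect
  acts on selection weights, a deliberately simple mechanism whose
  expected co-occurrence is analytically checkable; note the realized
  co-occurrence change is smaller than $\beta$ because only draws after
  the first A-hit are modulated.

Reads are emitted as the viewpoint fragment sequence followed by partner
sequences in drawn order; the cut-offset construction leaves the
recognition-site remnant at each junction, so splitting the read at
recognition sites recovers the planted fragments exactly.  Partners are
emitted in genomic (+) orientation: with exact-match assignment, a
reverse-oriented junction (two 3' `CATG` ends ligated head-to-head) sheds
a 4 bp site remnant as its own piece and the flanking piece no longer
equals any indexed fragment, so the generator's exact round-trip contract
could not hold.  Reverse-complement lookup is exercised directly by the
assignment tests instead.  Sequencing errors are not modelled (assignment
is exact-match by design); the optional pipeline for error-tolerant data
is external alignment plus `readChains()`.

### What the generator does and does not emulate

It reproduces the features the pipeline's statistics depend on: dense
restriction fragments, viewpoint anchoring, 1–5 partner cardinality,
power-law distance decay, boundary insulation and planted three-way
structure.  It does **not** model polymer physics beyond a power law,
replicate-level biological variability, PCR duplication, chimeric
mis-ligations or sequencing errors.  Passing tests therefore demonstrate
the correctness and calibration of the *computation*, not robustness of
the full method to the noise structure of real libraries.

## Validation study designs

The test suite runs these studies at fixed problem sizes:

* **Digest oracle** — 200 random toy genomes (150–600 bp, five enzymes
  including degenerate sites, some with N-runs) against an independent
  regex-based IUPAC scanner.
* **Null calibration** — 20 libraries of 20,000 reads over the 500 kb
  locus, no planted triads, SOI = a strong near-viewpoint interactor
  (215–230 kb); pooled z over non-excluded 5 kb bins must have mean
  within $\pm 0.3$ with at least 90% of $|z| < 3$.
* **Triad recovery** — 20 libraries per direction of 40,000 reads with
  $\beta = 4$ (or $0.25$) planted between the SOI interval and a 5 kb
  third site at 265–270 kb; the third-site bin must reach $z \ge 2$
  ($z \le -2$) in at least 90% of replicates.  The interval geometry and
  library size follow a power analysis targeting per-replicate power
  above 99%, so that the 90%-of-replicates bar is met with margin rather
  than at the knife's edge.
* **Insulation contrast** — matched libraries at $\gamma_{WT} = 1$ vs
  $\gamma_{KO} = 0.5$ (boundary at 350 kb, 20,000 reads each); the
  KO − WT normalized difference matrix must be negative in aggregate over
  cross-boundary bin pairs.
* **Resampling oracle** — a two-negative-read configuration whose
  one-fragment-removal null is exhaustively enumerable (mean $1/2$,
  population sd $\sqrt{0.125}$); the resampled estimates must fall within
  three standard errors at 1,000 iterations.

## Known limitations

* Exact-match assignment requires reads without sequencing errors at
  fragment boundaries; real libraries should be aligned externally and
  imported as chains.
* The continuous-fragment filter collapses only *consecutive* adjacent
  members; an adjacency separated by an intervening distal fragment is
  treated as two genuine contacts, which is the intended reading but not
  the only possible one.
* Loop calling thresholds raw counts on a single matrix; pooling of
  replicates, if any, must happen upstream.
* No multiple-testing correction is applied across bins in the VP-SOI
  test — z-scores are descriptive, as in the source methodology; a
  genome-wide screen would need one.
* Four-way and higher-order interactions are out of scope; all statistics
  condition on a single viewpoint (and at most one SOI).
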