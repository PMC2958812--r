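---
title: "Methods: predicting dif sites and replication-polarized words"
author: "xerscan"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, parameter choices and
numerical conventions. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# Biological model

Chromosome-dimer resolution sites (*dif*) are ~28 bp quasi-palindromes: two
11 bp recombinase-binding arms separated by a 6 bp central spacer, located
in the replication-termination region of circular chromosomes. They sit in
intergenic DNA, are imperfectly self-complementary (the two arms of the
*P. abyssi* site disagree at 2 of 11 positions), and are conserved between
related genomes far above the background. Short strand-polarized words
(KOPS in Proteobacteria, their 4 nt analogues in Archaea) are
over-represented on the leading strand of each replichore and invert their
polarity at the terminus/dif region. The package's two workflows mirror
these two signals:

* `run_dif_discovery()`: intergenic imperfect-inverted-repeat enumeration,
  cross-genome conservation filtering, consensus construction,
  origin-relative localization.
* `run_asps_analysis()`: word over-representation and strand skew under a
  rotating artificial terminus, then a cumulative-skew summit.

# Candidate enumeration

`enumerate_ir_candidates()` reports every `(start, arm length, spacer
length)` combination with arms 11–15 bp, spacers 4–10 bp, and at most
`max_arm_mismatches` positional mismatches between arm 1 and the reverse
complement of arm 2. All overlapping candidates are reported; per-locus
reduction is a separate, auditable step (`best_site()`). Windows containing
`N` are skipped. Sites are canonicalized to the lexicographic minimum of
the sequence and its reverse complement so the two orientations of a
quasi-palindrome count once.

**Mismatch tolerance (default 5).** No external definition of "imperfect"
fixes this number, so it is calibrated from two constraints. First, the
known archaeal sites carry 2 arm mismatches, and conservation filtering —
not arm quality — is the intended selective step, so the tolerance must
admit diverged copies of a 2-mismatch site with margin: at tolerance 3 a
planted site copy is lost from enumeration whenever divergence adds two net
arm mismatches, which happens often enough to break cross-genome recovery.
Second, published candidate counts for this family of scans (hundreds of
thousands of candidates over a few megabases of intergenic DNA) correspond
to an acceptance rate near 0.3–0.8 candidates per intergenic base pair,
which at these geometries implies a per-arm tolerance of about 5–6
mismatches at arm length 11. The default is therefore 5 (~55% arm
identity), exposed in `search_params()`.

**Best-site ordering.** `best_site()` minimizes the arm mismatch fraction
(`mismatches / arm_len`), then prefers longer arms, then the *larger*
spacer, then the smaller start. The larger-spacer preference needs a word:
a real site is typically flanked by candidates that are truncations of the
same locus (the 43 nt *P. abyssi* oligonucleotide, for instance, carries
both an 11+6+11 candidate and an 11+4+11 candidate with the same 2/11
mismatch fraction, the latter being a sub-interval of the former). At
equal arm quality the candidate covering more sequence is the maximal
representative of the locus, so it wins; preferring the smaller spacer
would systematically report truncation artifacts.

# Conservation filtering

`site_similarity()` is ungapped positional identity over the full
2·arm+spacer site, maximized over the two orientations of the second
sequence. No indels are modelled: the site class is defined by a fixed
geometry, and only candidates with identical `(arm_len, spacer_len)` are
compared. `conserved_groups()` emits a group when one candidate per genome
exists with all pairwise similarities at or above the threshold (default
0.80); candidates join at most one group, greedily by descending minimum
pairwise similarity with full deterministic tie-breaking, which makes the
output invariant under permutation of genome and candidate order.

Pair finding uses a seed-block filter: with at most
`floor(w(1-threshold))` mismatches allowed over width `w`, two matching
sites must share at least one of `floor(w(1-threshold))+1` consecutive
blocks exactly (pigeonhole), so only block-sharing pairs are scored. This
is exact, not heuristic.

Flank conservation is reported descriptively (`flank_at_fraction()`, AT
fraction of ±25 bp) and never used as a filter.

# Profile extension

The profile is a positional log2-odds matrix with column probabilities
`(count + pseudocount·background) / (n + pseudocount)`. It is the
match-state core of a profile HMM; insert/delete states are deliberately
omitted because the site alignment is ungapped and fixed-width, so they
would add parameters without adding signal. Significance is empirical:
`calibrate_threshold()` takes the `(1-alpha)` quantile of the genome-wide
maximum score over `n_shuffles` (≥100) dinucleotide-preserving
(Altschul–Erikson) shuffles of the target genome. The dinucleotide-exact
null preserves the AT richness and nearest-neighbour structure that
dominate archaeal intergenic DNA, which a mononucleotide shuffle would
misrepresent. Hits report the empirical p-value of their score under that
null.

# Word statistics and the rotating terminus

For a word `w` of length `k` (4–8), occurrences are counted with overlaps
on a single strand. The expectation under the maximal-order (k−2) Markov
model, estimated from the same sequence, is
`E = N(w[1..k-1]) N(w[2..k]) / N(w[2..k-1])`, with the Gaussian variance
`E (1 − N(w[1..k-1])/N(w[2..k-1])) (1 − N(w[2..k])/N(w[2..k-1]))`. The
test suite calibrates this null by simulation from order-(k−2) chains
(mean ≈ 0, sd ≈ 1 over replicates). Words with a nontrivial period are
flagged `self_overlap`: their occurrence counts clump, the Gaussian
approximation is optimistic, and no compound-Poisson correction is
applied. This matters in practice — the 4-mer `GTTG` itself is period-3
self-overlapping — so the flag travels with every ranking.

Because the statistic reads one strand, the chromosome is rewritten as its
*leading-strand view*: the origin→terminus segment kept forward, the
terminus→origin segment reverse complemented. The true terminus is
unknown, so the analysis repeats over artificial terminus angles from 120°
to 200° in 5° steps from the origin. A word is retained only if its strand
skew `(fwd − rev)/(fwd + rev)` keeps the same sign across every rotation;
the composite ranking score is `median z × median skew` across rotations,
and each word/reverse-complement pair is reported once, in its
over-represented orientation. Palindromic words have zero skew by
construction and are excluded. The choice of median-z × skew as the
composite is a package decision (any monotone combination of
"over-represented" and "skewed" would do); it is deterministic and exposed
in the ranking table so other scores can be recomputed from the columns.

`cumulative_skew()` walks the circle once from the origin, accumulating +1
per forward occurrence and −1 per reverse-complement occurrence, binned at
1 kb by default. The summit is the global maximum; on a tie the midpoint
of the longest maximal plateau (first such plateau if several tie equal
length). Occurrences spanning the linearization point are not counted —
at most `k−1` positions out of the whole chromosome.

# Angular coordinates

Positions are reported as signed degrees in `(-180, 180]` from the origin,
positive in the direction of increasing sequence coordinate;
quarters are `[0,90)`, `[90,180]`, `(-180,-90]`, `(-90,0)`. Deposited
genome orientations differ, so cross-genome comparisons of signed angles
are meaningful only up to a global sign; absolute angles are the robust
quantity. When the replication origin is known only as an interval, its
midpoint is used.

# The synthetic-genome generator

`sim_config()` defaults describe an archaeal-like chromosome: 1 Mb, 45%
GC, 85% coding density, mean gene length 900 bp. Genes are sequence-free
masks (only the intergenic mask matters to the pipeline); gene lengths are
gamma-distributed and rescaled so coding density is hit exactly up to
rounding. The planted site defaults to the 28 bp *P. abyssi* dif sequence;
the planted polarized word to `GTTG` at 2 per kb in leading orientation
versus 0.5 per kb lagging, inverting at the same angle (130°) where the
site is planted, since polarity inverts at the dimer-resolution locus in
real chromosomes.

Divergence is i.i.d. substitution (uniform exchange, no indels — the
analysis is ungapped, so indel realism would only break what the pipeline
cannot detect by design). The background rate defaults to 0.3 per site per
copy (pairwise identity ~0.55, far below any threshold); the planted site
is protected at 0.025 per site per copy, i.e. expected pairwise identity
~0.95 — the upper end of the 0.85–0.95 conservation band that characterizes
real cross-species dif sites (the three *Pyrococcus* sites average ~0.93
pairwise identity), chosen a priori as the generator's study condition.
Every generator is a pure function of its config and seed, and all planted
truth (site intervals, word placements, terminus position) is recorded on
the genome object and serialized next to the FASTA/GFF3 by
`write_genome()`, so recovery tests assert against exact truth.

What the simulations do *not* emulate: codon structure, repeated elements,
CRISPR arrays (whose spacers can mimic conserved candidates in real
genomes and must be excluded by inspection), rearrangements and
inversions, and compositional heterogeneity along the chromosome. Passing
the synthetic studies therefore demonstrates correctness and statistical
calibration of the method, not that real genomes are free of such
confounders.

# Problem sizes used by the validation studies

The test suite runs (i) exact oracle equivalence of the enumerator against
a brute-force triple loop on 200 random 80-mers; (ii) end-to-end recovery
of the planted site as the unique top conserved group on 100 replicate
quartets of 1 Mb genomes (≥95 required); (iii) terminus recovery within 3°
mean absolute error over 20 replicate 1 Mb genomes; (iv) null calibration
of the word z-score over 100 order-2 Markov sequences of 200 kb. Unit
tests exercise the same operations at kilobase scale. The profile null
calibration is tested at 100 shuffles on 3–20 kb genomes; scaling the
shuffled null to megabase genomes is linear in `n_shuffles × L` and left
to the user's patience.

# Numerical conventions and degenerate inputs

* Coordinates: 0-based half-open internally; intervals wrapping the
  coordinate origin carry `end > L`. GFF3 output is 1-based inclusive,
  BED 0-based half-open.
* `N` bases are legal input; every scanner skips windows containing them.
* Zero-count denominators in the word statistic (`N(infix) = 0`) are an
  error, not a silent zero; variance ≤ 0 yields `NA` z-scores that are
  dropped from rankings.
* Ties everywhere break deterministically (documented per function), so
  identical inputs give byte-identical outputs, including across input
  permutations.
* Seeds: every stochastic routine takes an explicit seed or derives fixed
  offsets from the config seed; nothing depends on the global RNG state.

# Known limitations

* The conservation step compares only identical-geometry candidates; a
  site whose arms lengthen or shorten between genomes would be missed.
* The Gaussian word statistic is optimistic for self-overlapping words
  (flagged, not corrected).
* Cross-k comparability of the composite ASPS score is limited: counts and
  z-scales differ between 4-mers and 8-mers, and no normalization beyond
  the z-score itself is applied.
* The profile scanner assumes a fixed site width; it cannot discover
  variant-spacer sites.
* Real-genome candidate lists can contain CRISPR spacers and other
  repeats; the package reports all conserved groups and leaves exclusion
  to the user.
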