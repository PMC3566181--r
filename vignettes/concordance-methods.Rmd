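---
title: "Methods: multi-platform variant-call concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-platform variant-call concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordkit)
```

## The problem

When the same genome is sequenced on several platforms, each platform's
variant caller reports a different set of single-nucleotide variants. The
interesting questions are structural: which call locations are shared by
all platforms, which are supported by only one or two, *why* a given
platform failed to call a site the others agree on, and how many of a
platform's exclusive ("singleton") calls are likely false positives.
`concordkit` implements that analysis as a reusable pipeline over standard
formats (VCF subset, BED, TSV evidence tables, FASTA) together with a
synthetic multi-platform generator used to validate every component
end to end.

## Venn partitioning and aggregation

Call locations are compared by `(chrom, pos)` only. Requiring
allele agreement would conflate two distinct phenomena - disagreement about
*whether* a site is variant and disagreement about *what* the variant is -
and the downstream miss-classification only makes sense for the former. A
shared location with differing alternate alleles is therefore counted as
concordant and flagged (`allele_mismatch`) in the partition, so callers can
report it separately. Each location belongs to exactly one cell of the
$2^k - 1$ non-empty platform subsets; per-platform totals are sums of the
cells containing that platform, and the discordant count is the union minus
the all-platform cell. These identities are asserted on every pipeline run.

Coordinates are 0-based half-open internally; VCF readers and writers
convert at the boundary. This keeps interval arithmetic (uniqueome runs,
indel matching, BED I/O) free of off-by-one special cases.

## Why a platform misses a site

For every location a platform did not call, the per-site pileup evidence
(post-deduplication depth, alternate-allele observations, RMS mapping
quality, SNP quality, neighbourhood features) is classified into exactly
one of nine causes plus an explicit residual:

1. `NO_COVERAGE` - depth 0;
2. `LOW_COVERAGE` - depth below the platform minimum;
3. `EXCESS_COVERAGE` - depth above the per-chromosome-class maximum
   (high depth signals collapsed repeats or structural variation, so such
   sites are excluded from calling);
4. `ALT_NOT_SEEN` - the alternate allele was never observed;
5. `ALT_SEEN_ONCE` - observed once, below the two-observation requirement
   common to pileup callers;
6. `SNP_CLUSTER` - more than `cluster_max_snps` other candidates within
   `cluster_window_bp`;
7. `NEAR_INDEL` - within `indel_distance_bp` of a high-quality indel;
8. `LOW_RMS_MAPQ` - RMS mapping quality below `min_rms_mapq`; for
   platforms whose aligner reports no mapping quality this slot is instead
   `NON_UNIQUE`, fired when the site lies outside the uniquely mappable
   region - the analogous ambiguity signal for such aligners;
9. `LOW_SNP_QUAL` - call quality below `min_qual`;
10. `UNEXPLAINED` - none of the above. Making the residual explicit keeps
    the classifier total, and `UNEXPLAINED` counts are reported separately
    rather than folded into a named cause.

The first matching rule wins. The precedence follows the three-group
logic of the analysis - coverage problems first, then alternate-allele
problems, then calling-filter problems - with rules 6-9 in the order
listed. A deterministic single label per (site, platform) is a design
requirement (summaries must sum to the number of missed sites); the
ordering within group three is our choice and is configurable only by
changing the code, so it is stated here explicitly.

Defaults for the group-three thresholds (cluster: more than 2 other
candidates within 10 bp; indel proximity: within 3 bp of an indel with
quality at least 50; RMS mapping quality below 25) follow the filter
conventions of classical pileup-based callers; all are per-platform
configuration fields.

## Retention filtering

A call is retained when its depth lies inside the inclusive per-class
bounds, its quality reaches the platform minimum (platforms without a
comparable quality skip the rule), and sex-chromosome or mitochondrial
calls are homozygous. "Between 2 and 30" and "minimum coverage of 4" are
read inclusively; boundary tests pin the convention (depth 2 and 30 kept,
1 and 31 rejected; quality 20 kept, 19 rejected). A call is homozygous
when the alternate fraction strictly exceeds 0.8, so 0.80 is heterozygous
and 0.81 homozygous.

The fixed per-platform bounds are the defaults. `derive_depth_limits()`
offers a model-derived mode that reconciles the fixed thresholds with the
Poisson coverage model: autosome bounds from the Poisson tail quantiles at
the platform's mean depth, sex-chromosome bounds at half that mean
(haploid coverage), mitochondrial ceiling effectively unbounded.

## Poisson coverage model

`poisson_expected()` tabulates the depth pmf in log space (stable to
means of $10^4$); `poisson_depth_bounds(lambda, alpha)` returns the
smallest $d$ with $F(d) \ge 1-\alpha$ as the upper bound and the largest
$d$ with $F(d-1) \le \alpha$ as the lower bound. Both are tested against
an independent term-by-term summation oracle. The depth histogram includes
zero-depth bases in its denominator so fractions describe the whole
reference. Real short-read depth distributions are over-dispersed relative
to Poisson (a gamma mixture fits better); the package deliberately keeps
the Poisson model and notes the limitation rather than fitting a heavier
model without published parameters.

## GC-bias profiling

GC fraction and mean depth are computed in non-overlapping windows
(default 50 kbp; the bundled demo uses 1 kbp on its 200-kbp genome so
there are enough windows for a regression). N bases are excluded from the
GC numerator and denominator and all-N windows are dropped, matching the
non-N convention of the coverage denominator. `fit_gc_bias()` regresses
log mean window depth on centred GC; under the generator's model
$\lambda(w) = \mu\, e^{\beta\,(\mathrm{gc}(w) - 0.5)}$ the slope estimates
$\beta$. Parameter-recovery tests plant $\beta \in \{-2, 0, +1\}$ and
require recovery within two standard errors.

## Uniqueome

The uniquely mappable region for reads of length $L$ is computed by
self-masking tiling: the reference is cut into fragments of length $L$
overlapping by $L/2$ (one extra fragment anchored at the chromosome end
when the tiling would otherwise fall short), every fragment is placed
gaplessly at every offset on both strands, and a placement counts when it
has at most $\lfloor d \cdot L \rfloor$ mismatches. A base is uniquely
mappable when its placement counter does not exceed its tile multiplicity
- two for interior bases, one near chromosome ends covered by a single
tile. Gapless mismatch-only matching (default divergence 5%) replaces
aligner-specific scoring because it gives a contract an exhaustive oracle
can verify; the original aligner-based procedure with dynamic masking is a
performance approximation of exactly this count. Reverse-strand
placements are counted because reads align to both strands. Exhaustive
equivalence is tested against a brute-force all-placement scan on random,
homopolymer, planted-duplication and diverged-copy references up to a few
kilobases, along with monotonicity in the divergence budget and
strand-reflection symmetry.

Indel-tolerant placement is out of scope; per-read-length uniqueomes are
obtained by running the tool once per fragment length.

## False-positive estimation

A singleton call is excused as plausibly true when, for *each* other
platform, the coverage at the site was compromised (zero, below minimum,
above maximum) or the alternate allele was seen at least once there;
otherwise it is a putative false positive. The defining sentence of this
criterion is grammatically ambiguous between AND and OR readings of the
two clauses; the per-platform (coverage-compromised OR alt-seen) reading
is implemented as the documented interpretation, not asserted as the
source's intent. The estimate is bounded by construction between 0 and
the singleton count.

## Indel matching with slop

Indel intervals match exactly when they intersect, and slop-only when
they intersect after symmetric expansion by `indel_slop_bp` (default 10).
Each query interval matches at most one target - the nearest, leftmost on
ties - and the exact / slop-only / unmatched categories are disjoint.
With slop 0 the slop-only category is empty by construction.

## The synthetic generator

The generator defines the study conditions for all end-to-end tests:

* **Reference**: i.i.d. bases at a target GC (default demo 0.45, 200 kbp),
  optional per-1-kbp-block GC jitter (`gc_sd`, demo 0.1) to give windows a
  GC spread, and exact planted duplications (demo: one 2-kbp segment,
  two copies) with recorded coordinates.
* **Truth variants**: per-bp Bernoulli substitutions (demo $10^{-3}$) and
  1-3 bp anchored indels (demo $2 \times 10^{-4}$), thinned to a 2-bp
  minimum spacing, het:hom 2:1.
* **Platforms**: three archetypes at the study's post-deduplication mean
  depths (10, 55, 53), with GC-bias coefficients (-0.2, -2, -2), duplicate
  fractions (0.027, 0.062, 0.176) matching the study's duplicate-read
  proportions, homopolymer-adjacent false calls for the long-read
  archetype (rate 0.02 next to runs of 4 or more), uniform spurious calls
  derived from the per-read substitution error rate, and a 40-unit
  mapping-quality penalty inside planted repeats for the short-read
  archetypes. The GC-bias magnitudes are illustrative: the source data
  shows the bias only graphically, so no published coefficient exists.
* **Planted miss-causes**: each platform misses a disjoint set of truth
  sites with engineered evidence at least 2 units away from every
  threshold, cycling through the categories applicable to that platform.
  `LOW_COVERAGE` cannot be planted with that margin on a platform whose
  minimum depth is 2 (no depth is both positive and 2 below the
  threshold), so it is skipped there, as are quality categories on
  platforms without the corresponding quality. Coordinated
  "exclusive singleton" sites are missed by both other platforms for
  coverage reasons, giving the false-positive estimator a planted
  plausible-true set, while planted false calls give it a planted
  putative-false-positive set.

Evidence at sites meant to be called is clamped inside the retention
bounds with the same 2-unit margin, so planted labels always survive
filtering. This makes label recovery exact by construction - which is the
point: the suite verifies that classifier, filter and estimator implement
their documented rules, not that they are robust to borderline evidence.
Real data has no margins, correlated errors, alignment artefacts or
reference bias, so 100% recovery on synthetic data says nothing about
real-data accuracy; it certifies the bookkeeping, not the biology.

Problem sizes used by the suites: 200-kbp genomes for the end-to-end
study, 60-100 kbp for module tests, $10^6$ bases for the Poisson marginal
(total-variation distance below 0.01-0.02), 300 windows for GC recovery,
2-8 kbp references for the uniqueome oracle, 1000-record fixtures for
duplicate marking and slop matching.

## Configuration

A single YAML file drives a run: per-platform thresholds (filled from the
three archetype defaults), an explicit chromosome-class map (`autosome` /
`sex` / `mito`; classes are configuration, never name heuristics, so the
pipeline is species-agnostic), `gc_window_bp`, `indel_slop_bp`, the seed,
and an optional `pipeline` section for the synthetic study. Unknown keys
are rejected with the list of valid keys. Runs are deterministic per
(config, seed); reports contain no timestamps so identical runs are
byte-identical, and each run directory is named by the config file's MD5
hash plus the seed.

## Known limitations

* The Poisson depth model understates the tails of real short-read data.
* Venn matching by location only cannot detect allele-level discordance
  beyond flagging it.
* The uniqueome is mismatch-only; indels within a read are not modelled.
* The generator plants evidence per site; it does not simulate reads, so
  read-level artefacts (strand bias, quality decay along the read,
  mate-pair geometry) are outside what passing tests demonstrate.
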