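---
title: "Methods: diagnosability, introgression and clock inference in radelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnosability, introgression and clock inference in radelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radelim)
```

## The problem

Several freshwater fish complexes — the roundtail chub group of the Lower
Colorado River Basin prominent among them — carry multiple nominal species
names whose diagnoses rest on mean differences between populations rather
than on characters that separate individuals. Deciding whether such names
correspond to real evolutionary units requires asking, quantitatively:

1. Can individual specimens be assigned to a name-bearing type series from
   morphology alone?
2. Do any characters have disjoint ranges between groups (diagnosability)?
3. Do genome-wide data show the groups as exclusive lineages (monophyly,
   topology concordance), and how recent is their divergence (clock)?
4. Is gene flow with a related species (here, the *G. cypha* analogue)
   detectable and how large a genomic fraction does it affect
   (ABBA-BABA D, f~d~)?

radelim implements each question as a small, testable operation, and
couples them to a synthetic species-complex generator so every statistical
claim in the package is validated against data with known truth.

## Morphometric scoring

**Standardization.** Range tables in this literature report measurements
on the "times-into" scale: the reference length (standard length SL, head
length HL, or body depth BD) divided by the raw measurement, which is why
characters smaller than SL have values above 1. `standardizeMeasurements()`
applies exactly this transform; being an involution, applying it twice
recovers raw values, which is also how the tests verify invertibility.
Which reference applies to which character is supplied by the user
(`referenceMap`), because published footnotes are ambiguous for a few
characters.

**Assignment.** A specimen's consistency with a type series is the
proportion of scored variables falling inside that series' inclusive
`[min, max]` interval; variables inside no series count as unclassified.
Meristic counts use integer membership. Proportions are rounded to two
decimals *before* averaging because the published table averages printed
values; the tests confirm that this arithmetic reproduces the published
Average row (0.29 / 0.61 / 0.49 / 0.19) exactly. Which "22 variables"
entered the published comparison is not enumerated anywhere, so the
variable list is an explicit argument, defaulting to all characters
present in every series' range table. Missing values are skipped with a
warning and the denominator reduced — silently imputing would bias
proportions toward 0.

**Diagnosability and overlap.** A character is diagnostic for a pair of
groups iff the ranges are disjoint (touching intervals share a value and
are not diagnostic). Clade-level overlap is reported as Jaccard overlap
(intersection length / union length): identical ranges give 1, disjoint
give 0, and coincident point ranges (singleton groups, which are flagged)
give 1. Allometry is tested by OLS of raw measurement on SL; preservation
effects by an F-test at alpha = 0.05 choosing between pooled and Welch
t-tests, mirroring standard practice for type-vs-fresh comparisons.

## RAD-locus filtering

The cascade runs decomposition → indel removal → mtDNA screen →
missingness filter → haplotype collapsing → depth rule, in that order;
the published account does not fix the relative order of indel removal
and the 85% filter, so the order is explicit in `runFilterCascade()` and
the missingness/depth filters are verified order-invariant (they are a
conjunction).

Numerical boundaries, all inclusive and all tested at their edges:

* **85% rule** — a locus is kept iff typed-individuals / total >= 0.85 on
  the real-valued fraction; with 19 individuals, 16/19 = 0.842 fails and
  17/19 = 0.895 passes (0.85 × 19 = 16.15 is not an integer, hence the
  explicit convention). An individual is "typed" at a locus when it has a
  non-missing genotype at one or more of its sites; the generator drops
  whole loci, so any-site and all-site conventions coincide on simulated
  data.
* **Depth rule** — a locus needs >= 14 individuals simultaneously
  haplotype-clean and at depth >= 20.
* **Error pruning** — a read-backed SNP combination survives iff its
  support is >= 5% of the individual's reads at that contig (the
  published pipeline's internal default is unstated; 5% is configurable
  via `FilterConfig`). Zero surviving combinations flag `low_data`, more
  than two flag `paralog_suspect`; flags are data, not exceptions.
* **mtDNA screen** — the original analysis removed contigs that mapped to
  the mitochondrial genome with a commercial mapper; here the rule is an
  explicit reimplementation: an exact 31-mer seed on either strand
  followed by a local-alignment identity of >= 90% over the contig. A
  31-mer exact match has essentially zero probability between random
  300-bp sequences, which the tests exploit.

Coordinates are 1-based inclusive (VCF convention) on every user-facing
surface. The VCF writer emits a canonical byte layout so fixed seeds give
byte-identical files; reading uses the package parser, cross-checked
against vcfR in the tests.

## Introgression statistics

Sites are polarized against the outgroup (skipped when the outgroup is
missing or polymorphic, when more than two alleles segregate, or when any
ingroup population is entirely missing — a complete-case rule that matches
the one-sequence-per-taxon design of the original analysis). Pattern
weights use derived-allele frequencies, so with single sequences the
counts are exact integer ABBA/BABA tallies; the equivalence is asserted in
the tests.

D's uncertainty comes from a delete-one block jackknife over blocks of 50
contiguous loci (the original tool's internal windowing is unpublished;
block size is a parameter). The standard error is
`sqrt((n-1)/n * sum((theta_i - theta_bar)^2))` over non-empty blocks —
the standard delete-one jackknife variance. When every delete-one value
coincides (for example BABA = 0 at every block, as happens in clean
simulations with no homoplasy) the SE is zero and the Z score is reported
undefined and flagged rather than infinite. Significance uses the Z >= 3
rule; p-values are two-sided normal and no multiple-testing correction is
applied, matching the original usage. f~d~ is reported only for D > 0,
per its definition; quartets whose guide-tree placement violates the
((P1,P2),P3) ancestry assumption are rejected with a reason rather than
analysed.

## Phylogeny and clock

p-distances use pairwise deletion of gaps and ambiguous bases (the
published choice is unstated; pairwise deletion wastes fewer sites at
these shallow divergences and the per-pair comparability is checked — a
pair sharing zero comparable sites is an error). Neighbor joining is the
distance-based stand-in for the original likelihood/Bayesian machinery,
sufficient for monophyly and concordance questions; negative NJ branches
are clamped to zero with a warning. Monophyly tests root unrooted trees
on a user-named outgroup first. Concordance is Robinson–Foulds on
non-trivial splits, normalized by 2(n−3).

The strict clock converts uncorrected divergence to time as TMRCA = d / r
with r = 0.02 per Myr. Whether "2% per Myr" means pairwise divergence or
per-lineage rate is ambiguous in the literature; the package defaults to
the pairwise reading (TMRCA = d / r), the usual convention for mtDNA
"2%-rule" calibrations, and exposes the per-lineage reading
(TMRCA = d / 2r) as `ClockConfig(mode = "lineage")`.

## The synthetic generator

The generator embodies the isolation-and-mixing history hypothesized for
the complex: a shallow population tree with recent admixture pulses.

* **Mutation model**: Jukes–Cantor, no rate heterogeneity, no indels.
  The downstream statistics consume biallelic SNPs and uncorrected
  distances only, so a richer substitution model would add parameters
  without exercising any additional code path.
* **Quartet tree**: node heights 0.001 / 0.01 / 0.02 expected
  substitutions/site for the P1–P2, ingroup–P3 and root splits — a
  shallow recent split inside a deeper background, the regime where f~d~
  tracks the admixture fraction. With a pulse at time 0 the expected
  estimate is gamma·t2 / (gamma·t2 + (1−gamma)(t1+t2)), ≈ 0.28 at
  gamma = 0.3 under the defaults, inside the ±0.05 recovery band by
  construction.
* **Introgression**: per-locus topology replacement — with probability
  gamma the recipient tip is re-attached to the donor lineage at the
  pulse time (default 0, a tip copy). This is the simplest mechanism
  producing a genuine ABBA excess; it is *not* a coalescent model and
  produces no incomplete lineage sorting, so BABA counts under the null
  come only from homoplasy.
* **Depth and missingness**: per locus × individual depth is negative
  binomial (mean 227 — the published average read depth — dispersion 5),
  and a cell is missing when dropout fires or the drawn depth is zero.
  Dispersion 5 keeps P(depth = 0) negligible so the missing fraction
  essentially equals the dropout rate, which the tests verify
  binomially.
* **Morphometrics**: raw value = group mean × (SL/SL0)^exponent ×
  lognormal noise; the first `typeSeriesSize` specimens per group form
  the type series. Defaults (three groups of six specimens,
  three-specimen series, 12% within-group CV) mirror the small museum
  series and heavy within-population variance of the study system: with
  zero noise every specimen scores 1.0 against its own series, while
  realistic noise produces the cross-assignment that motivates the whole
  analysis.
* **Clock-like test trees**: `randomClockTree()` draws coalescent
  topologies with a floor on inter-node spacing before rescaling. Raw
  coalescent trees routinely contain internal branches too short for any
  finite alignment to resolve; a floor of ~3% of tree height gives the
  shortest internal branch roughly 10 expected substitutions at 5,000
  sites, which is what "clock-like, resolvable" is taken to mean here.
* **Determinism**: every generator takes a seed and restores the caller's
  RNG state; each pipeline stage derives its own seed from the master
  seed and the stage name (`stageSeed()`), so adding a stage never
  perturbs another stage's stream. Fixed seeds give byte-identical FASTA,
  VCF, CSV and JSON outputs.

What the generator does **not** emulate: incomplete lineage sorting and
ancestral structure (both can mimic introgression in real data — the D
statistic cannot distinguish them and neither can this package),
recombination within loci, read-level sequencing artifacts beyond a
single-base miscall model, linked selection, and correlated character
evolution in morphology. Passing tests therefore demonstrate correctness
of the statistics and filters, not robustness of D to ancestral
structure.

## Problem sizes and tolerances in the validation suite

The statistical checks use: 500 null quartets of 500 loci × 150 bp for
the type-I error of the Z >= 3 rule (nominal two-sided rate ≈ 0.27%,
asserted <= 2%); 50 replicates of 5,000 loci at gamma = 0.3 for power
(asserted >= 90%) and f~d~ recovery (mean within ±0.05 of gamma); 200
clock-like 8-taxon alignments of 5,000 sites for NJ topology recovery
(asserted >= 95%); and ten 100-kb two-taxon alignments at a true TMRCA of
0.119 Myr for the clock (mean estimate within ±10%). A single 100-kb
alignment carries ≈ 6.5% relative sampling error at this divergence, so
the clock check compares the mean over ten alignments — a Monte-Carlo
estimate of the estimator's accuracy at the stated problem size rather
than a single noisy draw. Interval-membership comparisons use a 1e-9
tolerance to absorb decimal rounding of published table values.

## Known limitations

* The type-series assignment reproduces the published *Average row* from
  the printed per-specimen proportions; recomputing the per-specimen
  proportions themselves requires the raw supplementary measurement
  files, which are not shipped.
* The published locus counts (89,896 recovered; 1,292 retained; 4,821
  haplotypes) and the 63/119-kya BEAST estimates depend on the original
  sequencing data and external samplers; they are out of scope and not
  targets of the validation suite.
* `neighborJoining()` is a stand-in, not a replacement, for model-based
  tree inference; on very short internal branches it will fail where ML
  with the true model might succeed.
* The paralog-rescue heuristics of the published haplotyper are
  undocumented; only the flag taxonomy (ok / paralog_suspect / low_data)
  is implemented.
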