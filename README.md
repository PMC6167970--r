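# radelim

Diagnostics for species delimitation in morphologically plastic fish
complexes, built around the evidence chain used to evaluate the roundtail
chub (*Gila robusta*) group of the Lower Colorado River Basin: are the
nominal species diagnosable from their name-bearing type series, from
fresh material, or from reduced-representation genomic data?

The package is aimed at systematists and conservation geneticists who need
to *test* a proposed species boundary rather than assume one. It provides
four coordinated toolsets plus a synthetic data generator that produces
inputs with known truth for validating every step.

## What it computes

**Morphometric diagnosability.** Measurements are standardized by the
"times-into" convention (standardized value = reference length /
measurement, so a body depth of 5.2 means body depth fits 5.2 times into
standard length). Group ranges are inclusive `[min, max]` envelopes; a
character is *diagnostic* for a pair of groups iff their ranges are
disjoint. A specimen is scored against each type series as the proportion
of variables consistent with (inside) that series' intervals; proportions
may sum to more than 1 across series because ranges overlap, and the
table-level "Average" is the mean of the 2-decimal per-specimen values.

**RAD-locus filtering.** The published retention cascade: complex variants
decomposed to SNPs, indels removed, contigs matching the mitochondrial
genome removed (31-mer seed + 90% identity), loci typed in < 85% of
individuals excluded (16/19 fails, 17/19 passes), read-backed SNP
combinations collapsed to haplotypes (combinations under 5% of an
individual's reads pruned as sequencing error; more than two surviving
haplotypes flags a paralog), and a final rule keeping a locus only when at
least 14 of 19 individuals are cleanly haplotyped at depth >= 20.

**Introgression.** For a quartet (((P1,P2),P3),O), derived-allele
frequencies are polarized against the outgroup and the site patterns
weighted as ABBA = (1-p1)p2p3, BABA = p1(1-p2)p3. Patterson's

    D = (ABBA - BABA) / (ABBA + BABA)

with a delete-one block jackknife over contiguous locus blocks,
SE = sqrt((n-1)/n * sum_i (theta_i - theta_bar)^2), Z = D/SE, and the
Z >= 3 significance rule. The admixture fraction is estimated by
f_d = S(P1,P2,P3) / S(P1,P_D,P_D), where S is the summed ABBA-BABA weight
difference and P_D takes, per site, the larger of the P2/P3 derived
frequencies (defined only for D > 0).

**Phylogeny and clock.** Uncorrected p-distances (pairwise deletion),
neighbor-joining trees, monophyly checks, Robinson-Foulds topology
concordance, and strict-clock conversion TMRCA = d / r with r = 2%
pairwise divergence per Myr by default (per-lineage reading available).

## Worked example

Score the seventeen fresh specimens of the published assignment table
against the three type series, then test a synthetic quartet for
introgression:

```r
library(radelim)

tab <- read.csv(system.file("extdata", "gila-type-assignment.csv",
                            package = "radelim"))
averageAssignmentProportions(
  tab[, c("robusta", "nigra", "intermedia", "unclassified")])
#>      robusta        nigra   intermedia unclassified
#>         0.29         0.61         0.49         0.19

cfg <- SimConfig(nLoci = 2000L, locusLength = 150L, seed = 1L,
                 admixturePulses = data.frame(donor = "P3",
                                              recipient = "P2",
                                              gamma = 0.3))
sim <- simulateQuartetLoci(cfg)
popmap <- setNames(rownames(sim$alignment), rownames(sim$alignment))
runAbbaBaba(sim$alignment, popmap,
            data.frame(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"),
            guideTree = cfg@tree, locusIndex = sim$locusIndex)
#> QuartetResult: 1 quartets (block size 50 loci)
#>  P1 P2 P3 O     D    fd   Z significant status
#>  P1 P2 P3 O 0.993 0.277 253        TRUE     ok
```

The Average row says that on average only 29% of a fresh specimen's
variables are consistent with the *G. robusta* types (61% with *G. nigra*,
49% with *G. intermedia*, 19% with none) — no specimen can be assigned to
a single series. In the quartet, 30% of loci carry introgressed history;
D is strongly positive (Z >> 3) and f_d ≈ 0.28 recovers the simulated
admixture fraction. On the published fresh-material ranges,

```r
ranges <- read.csv(system.file("extdata", "gila-range-tables.csv",
                               package = "radelim"))
characterDiagnosability(ranges[ranges$material == "fresh", ])$diagnostic
#> character(0)
```

no character separates the nominal species.

An end-to-end synthetic run (generator → morphometrics → filtering →
introgression → phylogeny/clock) is available as
`runPipeline(pipelineConfig(seed = 1L), "out/")`, which writes a fixture
bundle, per-stage artifact files, `report.md`/`report.json` and a
`manifest.json` of file hashes; `inst/scripts/pipeline.R` wraps it for the
shell.

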