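## S4 classes for the central data objects and parameter bundles.

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Locus-retention filter thresholds
#'
#' Parameter bundle for the RAD-locus filtering cascade. Defaults reproduce
#' the published regime: loci present in fewer than 85% of individuals are
#' excluded, and a haplotyped locus is kept only when at least 14 of the 19
#' individuals carry it at a read depth of at least 20.
#'
#' @slot minIndividualFraction minimum fraction of individuals with a typed
#'   genotype for a locus to survive the missingness filter (default 0.85).
#'   The comparison uses `>=` on the real-valued fraction, so with 19
#'   individuals 16/19 (0.842) fails and 17/19 (0.895) passes.
#' @slot minIndividualsHaplotyped minimum count of individuals haplotyped at
#'   depth for the final retention rule (default 14).
#' @slot totalIndividuals number of individuals in the study (default 19).
#' @slot minDepth minimum per-individual read depth (default 20, inclusive).
#' @slot errorFraction read-support fraction below which a SNP combination is
#'   pruned as sequencing error during haplotype collapsing (default 0.05).
#' @slot kmerSize exact-match seed length for mitochondrial-contig screening
#'   (default 31).
#' @slot identityThreshold minimum identity over the contig for a seeded
#'   mtDNA match to trigger removal (default 0.9).
#' @export
setClass("FilterConfig",
  representation(minIndividualFraction = "numeric",
                 minIndividualsHaplotyped = "integer",
                 totalIndividuals = "integer",
                 minDepth = "integer",
                 errorFraction = "numeric",
                 kmerSize = "integer",
                 identityThreshold = "numeric"),
  prototype(minIndividualFraction = 0.85,
            minIndividualsHaplotyped = 14L,
            totalIndividuals = 19L,
            minDepth = 20L,
            errorFraction = 0.05,
            kmerSize = 31L,
            identityThreshold = 0.9))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (!(object@minIndividualFraction > 0 && object@minIndividualFraction <= 1))
    msg <- c(msg, "minIndividualFraction must be in (0, 1]")
  if (object@minIndividualsHaplotyped > object@totalIndividuals)
    msg <- c(msg, "minIndividualsHaplotyped must be <= totalIndividuals")
  if (object@minDepth < 0L) msg <- c(msg, "minDepth must be >= 0")
  if (!(object@errorFraction >= 0 && object@errorFraction < 1))
    msg <- c(msg, "errorFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn FilterConfig-class constructor.
#' @param minIndividualFraction,minIndividualsHaplotyped,totalIndividuals,minDepth,errorFraction,kmerSize,identityThreshold
#'   see slot documentation.
#' @return a `FilterConfig` object.
#' @examples
#' FilterConfig()
#' FilterConfig(minDepth = 10L)
#' @export
FilterConfig <- function(minIndividualFraction = 0.85,
                         minIndividualsHaplotyped = 14L,
                         totalIndividuals = 19L,
                         minDepth = 20L,
                         errorFraction = 0.05,
                         kmerSize = 31L,
                         identityThreshold = 0.9) {
  new("FilterConfig",
      minIndividualFraction = minIndividualFraction,
      minIndividualsHaplotyped = as.integer(minIndividualsHaplotyped),
      totalIndividuals = as.integer(totalIndividuals),
      minDepth = as.integer(minDepth),
      errorFraction = errorFraction,
      kmerSize = as.integer(kmerSize),
      identityThreshold = identityThreshold)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: locus-retention thresholds\n",
      "  missingness : locus typed in >= ",
      object@minIndividualFraction * 100, "% of ",
      object@totalIndividuals, " individuals\n",
      "  haplotyping : >= ", object@minIndividualsHaplotyped,
      " individuals at depth >= ", object@minDepth, "\n",
      "  error prune : combination support < ", object@errorFraction,
      " of reads\n",
      "  mtDNA screen: ", object@kmerSize, "-mer seed, identity >= ",
      object@identityThreshold, "\n", sep = "")
})

#' Strict molecular clock configuration
#'
#' The clock converts uncorrected pairwise divergence to time since the most
#' recent common ancestor. The default rate is the mtDNA convention of 2%
#' sequence divergence per million years, read as a *pairwise* rate so that
#' TMRCA = d / r. The alternative per-lineage reading (TMRCA = d / 2r) is
#' available via `mode = "lineage"`.
#'
#' @slot rate divergence rate per million years (default 0.02).
#' @slot mode `"pairwise"` (default) or `"lineage"`.
#' @export
setClass("ClockConfig",
  representation(rate = "numeric", mode = "character"),
  prototype(rate = 0.02, mode = "pairwise"))

setValidity("ClockConfig", function(object) {
  msg <- character()
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (!object@mode %in% c("pairwise", "lineage"))
    msg <- c(msg, "mode must be 'pairwise' or 'lineage'")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClockConfig-class constructor.
#' @param rate,mode see slot documentation.
#' @return a `ClockConfig` object.
#' @examples
#' ClockConfig()
#' @export
ClockConfig <- function(rate = 0.02, mode = "pairwise") {
  new("ClockConfig", rate = rate, mode = mode)
}

setMethod("show", "ClockConfig", function(object) {
  cat("ClockConfig: strict clock, ", object@rate * 100,
      "% divergence / Myr (", object@mode, " rate)\n", sep = "")
})

#' Genetic simulation configuration
#'
#' Parameters for the synthetic species-complex generators. The population
#' tree carries branch lengths in expected substitutions per site; admixture
#' pulses move a fraction `gamma` of loci onto a topology that groups the
#' recipient with the donor (per-locus topology replacement, joining the
#' donor lineage at `admixtureTime` before the present — 0 means the
#' recipient tip is a copy of the donor's).
#'
#' @slot tree an [ape::phylo] population tree, branch lengths in expected
#'   substitutions/site.
#' @slot admixturePulses data.frame with columns `donor`, `recipient`,
#'   `gamma` (each gamma in \[0,1\]).
#' @slot admixtureTime time (substitutions/site units) before present at
#'   which an introgressed recipient lineage joins the donor; default 0.
#' @slot nLoci,locusLength number of loci and locus length in bp.
#' @slot depthMean,depthDispersion negative-binomial read-depth mean and
#'   dispersion (size) per locus x individual cell.
#' @slot dropout probability a locus is untyped in an individual.
#' @slot nIndividualsPerPop diploid individuals sampled per population.
#' @slot withinPopDiversity extra terminal branch length (substitutions/site)
#'   given to each sampled haplotype, creating within-population variation.
#' @slot seed RNG seed (fixed seed implies bit-identical output).
#' @export
setClass("SimConfig",
  representation(tree = "ANY", admixturePulses = "data.frame",
                 admixtureTime = "numeric",
                 nLoci = "integer", locusLength = "integer",
                 depthMean = "numeric", depthDispersion = "numeric",
                 dropout = "numeric", nIndividualsPerPop = "integer",
                 withinPopDiversity = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
  else if (any(object@tree$edge.length < 0))
    msg <- c(msg, "branch lengths must be >= 0")
  ap <- object@admixturePulses
  if (nrow(ap) && (!all(c("donor", "recipient", "gamma") %in% names(ap)) ||
                   any(ap$gamma < 0 | ap$gamma > 1)))
    msg <- c(msg, "admixturePulses needs donor/recipient/gamma with gamma in [0,1]")
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
  if (object@locusLength < 1L) msg <- c(msg, "locusLength must be >= 1")
  if (object@depthMean <= 0) msg <- c(msg, "depthMean must be > 0")
  if (object@dropout < 0 || object@dropout > 1)
    msg <- c(msg, "dropout must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Default four-tip quartet tree for introgression simulations
#'
#' A clock-like rooted tree (((P1,P2),P3),O) with node heights 0.001
#' (P1-P2), 0.01 (+P3) and 0.02 (+O) expected substitutions/site: a shallow
#' recent split inside a deeper background divergence, the regime in which
#' the f_d estimator tracks the admixture fraction.
#'
#' @param t1,t2,t3 node heights (substitutions/site) for the P1-P2 split,
#'   the ingroup-P3 split and the root.
#' @param tips tip labels, in the order P1, P2, P3, outgroup.
#' @return an [ape::phylo] object.
#' @examples
#' quartetTree()
#' @export
quartetTree <- function(t1 = 0.001, t2 = 0.01, t3 = 0.02,
                        tips = c("P1", "P2", "P3", "O")) {
  stopifnot(0 <= t1, t1 <= t2, t2 <= t3, length(tips) == 4L)
  txt <- sprintf("(((%s:%g,%s:%g):%g,%s:%g):%g,%s:%g);",
                 tips[1], t1, tips[2], t1, t2 - t1, tips[3], t2,
                 t3 - t2, tips[4], t3)
  ape::read.tree(text = txt)
}

#' @describeIn SimConfig-class constructor. With no arguments it describes a
#'   four-population quartet with no gene flow.
#' @param tree,admixturePulses,admixtureTime,nLoci,locusLength,depthMean,depthDispersion,dropout,nIndividualsPerPop,withinPopDiversity,seed
#'   see slot documentation.
#' @return a `SimConfig` object.
#' @examples
#' SimConfig(nLoci = 100L, seed = 1L)
#' @export
SimConfig <- function(tree = quartetTree(),
                      admixturePulses = data.frame(donor = character(),
                                                   recipient = character(),
                                                   gamma = numeric()),
                      admixtureTime = 0,
                      nLoci = 1000L, locusLength = 150L,
                      depthMean = 227, depthDispersion = 5,
                      dropout = 0.05, nIndividualsPerPop = 5L,
                      withinPopDiversity = 0.001, seed = 1L) {
  new("SimConfig", tree = tree, admixturePulses = admixturePulses,
      admixtureTime = admixtureTime, nLoci = as.integer(nLoci),
      locusLength = as.integer(locusLength), depthMean = depthMean,
      depthDispersion = depthDispersion, dropout = dropout,
      nIndividualsPerPop = as.integer(nIndividualsPerPop),
      withinPopDiversity = withinPopDiversity, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", length(object@tree$tip.label), " populations, ",
      object@nLoci, " loci x ", object@locusLength, " bp\n",
      "  depth ~ NegBin(mean = ", object@depthMean, ", size = ",
      object@depthDispersion, "), dropout = ", object@dropout, "\n",
      "  admixture pulses: ", nrow(object@admixturePulses),
      "; seed = ", object@seed, "\n", sep = "")
})

#' Morphometric simulation configuration
#'
#' Emulates measurement tables for a species complex in which within-group
#' variance can exceed between-group differences (the regime of the
#' roundtail chub complex). Each specimen's raw character value is
#' `mean * (SL / SL0)^exponent * exp(N(0, withinSd))`, where SL is the
#' specimen's standard length; a type series is the first
#' `typeSeriesSize` specimens of each group, mirroring the small
#' name-bearing series (2-5 specimens) of museum collections.
#'
#' @slot groupMeans numeric matrix, characters x groups: mean raw value (mm)
#'   at the reference standard length.
#' @slot withinSd per-character log-scale standard deviation (coefficient of
#'   variation) of within-group noise; recycled if scalar.
#' @slot allometryExponent per-character scaling exponent versus standard
#'   length (1 = isometry); recycled if scalar.
#' @slot nPerGroup specimens simulated per group.
#' @slot typeSeriesSize specimens per group entering the type-series range
#'   table (must be <= nPerGroup).
#' @slot standardLengthMean,standardLengthCv lognormal parameters for
#'   specimen standard length (mm).
#' @slot seed RNG seed.
#' @export
setClass("MorphoSimConfig",
  representation(groupMeans = "matrix", withinSd = "numeric",
                 allometryExponent = "numeric", nPerGroup = "integer",
                 typeSeriesSize = "integer", standardLengthMean = "numeric",
                 standardLengthCv = "numeric", seed = "integer"))

setValidity("MorphoSimConfig", function(object) {
  msg <- character()
  if (any(object@withinSd < 0)) msg <- c(msg, "withinSd must be >= 0")
  if (object@typeSeriesSize > object@nPerGroup)
    msg <- c(msg, "typeSeriesSize must be <= nPerGroup")
  if (any(object@groupMeans <= 0)) msg <- c(msg, "groupMeans must be > 0")
  if (is.null(rownames(object@groupMeans)) ||
      is.null(colnames(object@groupMeans)))
    msg <- c(msg, "groupMeans needs character rownames and group colnames")
  if (length(msg)) msg else TRUE
})

defaultGroupMeans <- function() {
  ## three nominal groups, five characters, means close enough that the
  ## default within-group noise makes ranges overlap broadly (raw mm at
  ## SL = 100 mm)
  m <- rbind(body_depth      = c(20.0, 23.0, 26.0),
             head_length     = c(28.0, 28.5, 30.5),
             snout_length    = c(29.0, 30.0, 29.5) / 3.5,
             peduncle_depth  = c(9.0, 9.6, 10.2),
             pectoral_length = c(19.0, 18.0, 17.0))
  colnames(m) <- c("robusta", "nigra", "intermedia")
  m
}

#' @describeIn MorphoSimConfig-class constructor. Defaults emulate three
#'   overlapping groups of six specimens with three-specimen type series.
#' @param groupMeans,withinSd,allometryExponent,nPerGroup,typeSeriesSize,standardLengthMean,standardLengthCv,seed
#'   see slot documentation.
#' @return a `MorphoSimConfig` object.
#' @examples
#' MorphoSimConfig(seed = 2L)
#' @export
MorphoSimConfig <- function(groupMeans = defaultGroupMeans(),
                            withinSd = 0.12, allometryExponent = 1,
                            nPerGroup = 6L, typeSeriesSize = 3L,
                            standardLengthMean = 100,
                            standardLengthCv = 0.2, seed = 1L) {
  new("MorphoSimConfig", groupMeans = groupMeans, withinSd = withinSd,
      allometryExponent = allometryExponent, nPerGroup = as.integer(nPerGroup),
      typeSeriesSize = as.integer(typeSeriesSize),
      standardLengthMean = standardLengthMean,
      standardLengthCv = standardLengthCv, seed = as.integer(seed))
}

setMethod("show", "MorphoSimConfig", function(object) {
  cat("MorphoSimConfig: ", ncol(object@groupMeans), " groups x ",
      nrow(object@groupMeans), " characters, ", object@nPerGroup,
      " specimens/group (type series ", object@typeSeriesSize,
      "), seed = ", object@seed, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Data classes
## ---------------------------------------------------------------------------

#' Genotype matrix with per-cell read depth
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding biallelic variant
#' records: `rowData` carries `contig`, `pos` (1-based, VCF convention),
#' `ref` and `alt`; assays `geno` (0/1/2 alternate-allele counts, `NA` when
#' untyped) and `depth` (reads per variant x individual) have one column per
#' individual. Missing genotypes are recorded as `NA`, never as depth-0
#' homozygotes.
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  rd <- rowData(object)
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(rd)))
    msg <- c(msg, "rowData must have contig, pos, ref, alt")
  else if (nrow(object) && any(rd$pos < 1L))
    msg <- c(msg, "positions are 1-based and must be >= 1")
  if (!all(c("geno", "depth") %in% names(assays(object))))
    msg <- c(msg, "assays 'geno' and 'depth' are required")
  else {
    g <- assay(object, "geno"); d <- assay(object, "depth")
    if (any(d < 0, na.rm = TRUE)) msg <- c(msg, "depth must be >= 0")
    if (any(g < 0 | g > 2, na.rm = TRUE))
      msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeMatrix-class constructor.
#' @param geno integer matrix (variants x individuals) of alternate-allele
#'   counts 0/1/2, `NA` = missing.
#' @param depth integer matrix of read depths, same shape as `geno`.
#' @param contig,pos,ref,alt per-variant record fields.
#' @return a `GenotypeMatrix`.
#' @examples
#' gm <- GenotypeMatrix(geno = matrix(c(0L, 1L, 2L, NA), 2),
#'                      depth = matrix(25L, 2, 2),
#'                      contig = c("locus_1", "locus_1"), pos = c(5L, 9L),
#'                      ref = c("A", "C"), alt = c("G", "T"))
#' genotypes(gm)
#' @export
GenotypeMatrix <- function(geno, depth, contig, pos, ref, alt) {
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("ind_", seq_len(ncol(geno)))
  colnames(depth) <- colnames(geno)
  se <- SummarizedExperiment(
    assays = list(geno = geno, depth = depth),
    rowData = S4Vectors::DataFrame(contig = as.character(contig),
                                   pos = as.integer(pos),
                                   ref = as.character(ref),
                                   alt = as.character(alt)))
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix-class genotype assay accessor.
#' @param x a `GenotypeMatrix`.
#' @export
genotypes <- function(x) assay(x, "geno")

#' @describeIn GenotypeMatrix-class depth assay accessor.
#' @export
readDepths <- function(x) assay(x, "depth")

#' @describeIn GenotypeMatrix-class variant records (contig/pos/ref/alt) as a
#'   data.frame.
#' @export
variantRecords <- function(x) as.data.frame(rowData(x))

setMethod("show", "GenotypeMatrix", function(object) {
  g <- assay(object, "geno")
  cat("GenotypeMatrix: ", nrow(object), " variants on ",
      length(unique(rowData(object)$contig)), " contigs x ", ncol(object),
      " individuals (", sprintf("%.1f", 100 * mean(is.na(g))),
      "% missing)\n", sep = "")
})

#' Type-series character ranges
#'
#' The per-character \[min, max\] envelope of one name-bearing type series on
#' the standardized ("times-into") scale, the reference against which fresh
#' specimens are scored by [assignToTypeSeries()].
#'
#' @slot seriesName name of the type series (e.g. the nominal species).
#' @slot ranges data.frame with columns `character`, `min`, `max`.
#' @slot nSpecimens number of specimens the envelope summarizes.
#' @export
setClass("TypeSeriesRange",
  representation(seriesName = "character", ranges = "data.frame",
                 nSpecimens = "integer"))

setValidity("TypeSeriesRange", function(object) {
  r <- object@ranges
  if (!all(c("character", "min", "max") %in% names(r)))
    return("ranges needs columns character, min, max")
  if (any(r$min > r$max + 1e-12)) return("min must be <= max")
  TRUE
})

#' @describeIn TypeSeriesRange-class constructor.
#' @param seriesName,ranges,nSpecimens see slot documentation.
#' @return a `TypeSeriesRange`.
#' @examples
#' TypeSeriesRange("robusta",
#'                 data.frame(character = "lateral_line_scales",
#'                            min = 89, max = 92), 2L)
#' @export
TypeSeriesRange <- function(seriesName, ranges, nSpecimens = NA_integer_) {
  new("TypeSeriesRange", seriesName = seriesName,
      ranges = as.data.frame(ranges), nSpecimens = as.integer(nSpecimens))
}

#' @describeIn TypeSeriesRange-class series name accessor.
#' @param x a `TypeSeriesRange`.
#' @export
seriesName <- function(x) x@seriesName

#' @describeIn TypeSeriesRange-class range table accessor.
#' @export
seriesRanges <- function(x) x@ranges

setMethod("show", "TypeSeriesRange", function(object) {
  cat("TypeSeriesRange '", object@seriesName, "': ",
      nrow(object@ranges), " characters, n = ", object@nSpecimens,
      " specimens\n", sep = "")
})

#' ABBA-BABA quartet results
#'
#' One row per tested quartet (P1, P2, P3, outgroup): weighted ABBA/BABA
#' counts, Patterson's D, f_d (NA unless D > 0), block-jackknife SE, Z,
#' two-sided p and the Z >= 3 significance flag. Rejected quartets (guide
#' tree violates ((P1,P2),P3) ancestry) carry the rejection reason.
#'
#' @slot table the results data.frame.
#' @slot blockSize number of contiguous loci per jackknife block.
#' @export
setClass("QuartetResult",
  representation(table = "data.frame", blockSize = "integer"))

#' @describeIn QuartetResult-class results table accessor.
#' @param x a `QuartetResult`.
#' @return `quartetTable()` returns the underlying data.frame.
#' @export
quartetTable <- function(x) x@table

setMethod("show", "QuartetResult", function(object) {
  tb <- object@table
  cat("QuartetResult: ", nrow(tb), " quartets (block size ",
      object@blockSize, " loci)\n", sep = "")
  if (nrow(tb)) {
    shown <- tb[, intersect(c("P1", "P2", "P3", "O", "D", "fd", "Z",
                              "significant", "status"), names(tb))]
    print(head(shown, 8), digits = 3, row.names = FALSE)
    if (nrow(tb) > 8) cat("  ... and", nrow(tb) - 8, "more\n")
  }
})
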