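## Synthetic species-complex generators.
##
## The genetic model: populations diverge along a tree with branch lengths
## in expected substitutions/site; Jukes-Cantor mutation, no rate
## heterogeneity, no indels (the downstream statistics only consume
## biallelic SNPs and uncorrected distances). Introgression is per-locus
## topology replacement: with probability gamma a locus's recipient lineage
## is detached and re-attached to the donor lineage at `admixtureTime`
## before the present (0 = tip copy). This is the simplest mechanism that
## produces the ABBA excess the D and f_d statistics detect; the cyclical
## isolation-and-mixing history hypothesized for the chub complex is
## emulated by recent pulses over a shallow tree.

DNA_STATES <- c("A", "C", "G", "T")

## one Jukes-Cantor branch: each site substitutes with probability
## 3/4 (1 - exp(-4 b / 3)) and then picks uniformly among the other bases
jcEvolve <- function(states, b) {
  if (b <= 0) return(states)
  p <- 0.75 * (1 - exp(-4 * b / 3))
  mut <- which(runif(length(states)) < p)
  if (length(mut))
    states[mut] <- 1L + (states[mut] - 1L +
                         sample.int(3L, length(mut), replace = TRUE)) %% 4L
  states
}

## evolve nSites iid sites down a rooted tree; returns integer matrix
## (tips x sites), states 1..4
evolveJC <- function(tree, nSites) {
  tree <- stats::reorder(tree, "cladewise")
  nTips <- length(tree$tip.label)
  seqs <- vector("list", nTips + tree$Nnode)
  seqs[[nTips + 1L]] <- sample.int(4L, nSites, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    seqs[[tree$edge[e, 2L]]] <- jcEvolve(seqs[[tree$edge[e, 1L]]],
                                         tree$edge.length[e])
  }
  m <- do.call(rbind, seqs[seq_len(nTips)])
  rownames(m) <- tree$tip.label
  m
}

decodeStates <- function(m) {
  out <- matrix(DNA_STATES[m], nrow(m), dimnames = dimnames(m))
  out
}

#' Per-locus topology replacement for an admixture pulse
#'
#' Detaches the recipient tip and re-attaches it to the donor's terminal
#' branch at `time` before the present, producing the locus genealogy of an
#' introgressed locus. `time = 0` makes the recipient a copy of the donor
#' tip.
#'
#' @param tree rooted [ape::phylo].
#' @param donor,recipient tip labels.
#' @param time attachment height above the tips (same units as branch
#'   lengths); must not exceed the donor's terminal branch length.
#' @return the rearranged [ape::phylo].
#' @export
introgressedTree <- function(tree, donor, recipient, time = 0) {
  stopifnot(donor %in% tree$tip.label, recipient %in% tree$tip.label,
            donor != recipient)
  pruned <- ape::drop.tip(tree, recipient)
  donorIdx <- match(donor, pruned$tip.label)
  donorEdge <- pruned$edge.length[pruned$edge[, 2L] == donorIdx]
  if (time > donorEdge + 1e-12)
    stop("admixture time exceeds the donor's terminal branch length")
  if (time > 0) {
    graft <- ape::read.tree(text = sprintf("(%s:%.12g);", recipient, time))
    ape::bind.tree(pruned, graft, where = donorIdx, position = time)
  } else {
    ## position = 0 would replace the donor tip, so graft a cherry of the
    ## donor and recipient (both on zero branches) in its place
    graft <- ape::read.tree(text = sprintf("(%s:0,%s:0);", donor, recipient))
    ape::bind.tree(pruned, graft, where = donorIdx, position = 0)
  }
}

#' Simulate quartet loci with optional introgression
#'
#' Generates per-locus sequence data for a four-taxon comparison with
#' ancestry (((P1,P2),P3),O). Each locus follows the species tree, except
#' that with probability gamma (per admixture pulse in the config) the
#' recipient lineage is re-attached to the donor at the pulse time. The
#' truth record of which loci were introgressed is returned for recovery
#' tests.
#'
#' @param config a [SimConfig] whose tree has exactly 4 tips with the
#'   topology ((P1,P2),P3),O (tip names are free; P1/P2/P3/O roles are the
#'   first/second/third ingroup and the outgroup by tree position, matched
#'   to [quartetTree()]'s defaults).
#' @return list with `alignment` (4 x sites character matrix),
#'   `locusIndex` (locus id per site), `truth` (data.frame `locus`,
#'   `introgressed`), `gamma`, and `config`.
#' @examples
#' cfg <- SimConfig(nLoci = 50L, locusLength = 100L, seed = 1L)
#' sim <- simulateQuartetLoci(cfg)
#' dim(sim$alignment)
#' @export
simulateQuartetLoci <- function(config) {
  stopifnot(is(config, "SimConfig"))
  tree <- config@tree
  if (length(tree$tip.label) != 4L) stop("quartet simulation needs 4 tips")
  pulses <- config@admixturePulses
  if (nrow(pulses) > 1L)
    stop("quartet simulation supports a single admixture pulse")
  gamma <- if (nrow(pulses)) pulses$gamma[1] else 0
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  nLoci <- config@nLoci; L <- config@locusLength
  withSeed(config@seed, {
    intro <- if (gamma > 0) runif(nLoci) < gamma else rep(FALSE, nLoci)
    siteClass <- rep(intro, each = L)
    aln <- matrix(NA_integer_, 4L, nLoci * L,
                  dimnames = list(tree$tip.label, NULL))
    nSpecies <- sum(!siteClass)
    if (nSpecies > 0) {
      sp <- evolveJC(tree, nSpecies)
      aln[rownames(sp), !siteClass] <- sp
    }
    nIntro <- sum(siteClass)
    if (nIntro > 0) {
      itree <- introgressedTree(tree, pulses$donor[1], pulses$recipient[1],
                                config@admixtureTime)
      it <- evolveJC(itree, nIntro)
      aln[rownames(it), siteClass] <- it
    }
    list(alignment = decodeStates(aln),
         locusIndex = rep(seq_len(nLoci), each = L),
         truth = data.frame(locus = seq_len(nLoci), introgressed = intro),
         gamma = gamma, config = config)
  })
}

## expand a population tree into a haplotype tree: each population tip
## becomes a polytomy of 2 * nInd haplotype tips on branches of length w
haplotypeTree <- function(popTree, nInd, w) {
  tree <- popTree
  for (pop in popTree$tip.label) {
    hapNames <- paste0(pop, "_i", rep(seq_len(nInd), each = 2L),
                       "_h", rep(1:2, nInd))
    sub <- ape::read.tree(text = paste0(
      "(", paste0(hapNames, ":", w, collapse = ","), ");"))
    tipIdx <- match(pop, tree$tip.label)
    tree <- ape::bind.tree(tree, sub, where = tipIdx, position = 0)
  }
  tree
}

#' Simulate a multi-population RADseq dataset
#'
#' Generates diploid genotypes at biallelic SNPs for `nIndividualsPerPop`
#' individuals per population, with per-locus x individual read depths
#' drawn from a negative binomial and cells going missing when dropout
#' fires or the drawn depth is zero. Admixture pulses act per locus as in
#' [simulateQuartetLoci()]. The true genealogy is recorded.
#'
#' @param config a [SimConfig] with a tree of >= 2 populations.
#' @return list with `genotypes` (a [GenotypeMatrix]), `haplotypes`
#'   (haplotype x site character matrix), `locusIndex`, `locusDepth`
#'   (loci x individuals), `missing` (logical loci x individuals),
#'   `truth` (per-locus pulse class), `popTree`, `hapTree`, `popmap`
#'   (individual -> population), and `config`.
#' @export
simulateComplexRadseq <- function(config) {
  stopifnot(is(config, "SimConfig"))
  popTree <- config@tree
  if (length(popTree$tip.label) < 2L) stop("need at least 2 populations")
  if (config@depthMean <= 0) stop("depthMean must be positive")
  nInd <- config@nIndividualsPerPop
  nLoci <- config@nLoci; L <- config@locusLength
  pulses <- config@admixturePulses
  withSeed(config@seed, {
    ## per-locus class: 0 = species tree, k = pulse k (first that fires)
    class <- rep(0L, nLoci)
    if (nrow(pulses)) {
      for (k in seq_len(nrow(pulses))) {
        fire <- runif(nLoci) < pulses$gamma[k]
        class[class == 0L & fire] <- k
      }
    }
    siteClass <- rep(class, each = L)
    hapNames <- NULL
    aln <- NULL
    for (k in sort(unique(class))) {
      pt <- if (k == 0L) popTree else
        introgressedTree(popTree, pulses$donor[k], pulses$recipient[k],
                         config@admixtureTime)
      ht <- haplotypeTree(pt, nInd, config@withinPopDiversity)
      mk <- evolveJC(ht, sum(siteClass == k))
      if (is.null(aln)) {
        hapNames <- sort(rownames(mk))
        aln <- matrix(NA_integer_, length(hapNames), nLoci * L,
                      dimnames = list(hapNames, NULL))
      }
      aln[rownames(mk), siteClass == k] <- mk
    }
    pops <- sub("_i[0-9]+_h[12]$", "", hapNames)
    indiv <- sub("_h[12]$", "", hapNames)
    individuals <- unique(indiv)
    popmap <- setNames(sub("_i[0-9]+$", "", individuals), individuals)

    ## biallelic SNP discovery across haplotypes
    nS <- ncol(aln)
    mn <- rep(5L, nS); mx <- rep(0L, nS)
    for (r in seq_len(nrow(aln))) {
      mn <- pmin(mn, aln[r, ]); mx <- pmax(mx, aln[r, ])
    }
    poly <- mn != mx
    cntMn <- rep(0L, nS); cntMx <- rep(0L, nS)
    for (r in seq_len(nrow(aln))) {
      cntMn <- cntMn + (aln[r, ] == mn); cntMx <- cntMx + (aln[r, ] == mx)
    }
    snpSites <- which(poly & (cntMn + cntMx == nrow(aln)))
    ## ref = majority allele (ties -> smaller state for determinism)
    major <- cntMn[snpSites] >= cntMx[snpSites]
    refState <- ifelse(major, mn[snpSites], mx[snpSites])
    altState <- ifelse(major, mx[snpSites], mn[snpSites])
    hap1 <- aln[paste0(individuals, "_h1"), snpSites, drop = FALSE]
    hap2 <- aln[paste0(individuals, "_h2"), snpSites, drop = FALSE]
    ## variants x individuals count of alt alleles
    geno <- (t(hap1) == altState) + (t(hap2) == altState)
    storage.mode(geno) <- "integer"
    rownames(geno) <- NULL
    colnames(geno) <- individuals

    ## depth and missingness at the locus level
    nIndTot <- length(individuals)
    locusDepth <- matrix(
      rnbinom(nLoci * nIndTot, size = config@depthDispersion,
              mu = config@depthMean),
      nLoci, nIndTot, dimnames = list(sprintf("locus_%04d", seq_len(nLoci)),
                                      individuals))
    drop <- matrix(runif(nLoci * nIndTot) < config@dropout, nLoci, nIndTot)
    locusDepth[drop] <- 0L
    missing <- drop | locusDepth == 0L

    snpLocus <- rep(seq_len(nLoci), each = L)[snpSites]
    depth <- locusDepth[snpLocus, , drop = FALSE]
    rownames(depth) <- NULL
    geno[missing[snpLocus, , drop = FALSE]] <- NA_integer_

    gm <- GenotypeMatrix(
      geno = geno, depth = depth,
      contig = sprintf("locus_%04d", snpLocus),
      pos = (snpSites - 1L) %% L + 1L,
      ref = DNA_STATES[refState], alt = DNA_STATES[altState])
    list(genotypes = gm, haplotypes = decodeStates(aln),
         locusIndex = rep(seq_len(nLoci), each = L),
         locusDepth = locusDepth, missing = missing,
         truth = data.frame(locus = seq_len(nLoci), pulse = class),
         popTree = popTree, popmap = popmap, config = config)
  })
}

#' Random clock-like tree with well-separated coalescence events
#'
#' Draws a random coalescent topology whose inter-node intervals include a
#' guaranteed spacing floor, then rescales the tree to the requested root
#' height. Compared to raw coalescent trees this avoids the vanishingly
#' short internal branches that no finite alignment could resolve, which is
#' the regime intended by "clock-like" test trees.
#'
#' @param nTips number of tips.
#' @param height root height after rescaling (e.g. Myr).
#' @param minIntervalFrac floor on each coalescence interval, as a fraction
#'   of the mean interval, before rescaling (default 0.3).
#' @param seed RNG seed (`NULL` to use the current stream).
#' @return an ultrametric [ape::phylo].
#' @export
randomClockTree <- function(nTips, height = 5, minIntervalFrac = 0.3,
                            seed = NULL) {
  stopifnot(nTips >= 3L, height > 0)
  withSeed(seed, {
    gaps <- minIntervalFrac + stats::rexp(nTips - 1L)
    tr <- ape::rcoal(nTips, br = gaps)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * height / depth
    tr
  })
}

#' Simulate a clock-like mtDNA alignment
#'
#' Evolves an alignment down an ultrametric tree calibrated in Myr, under a
#' strict pairwise divergence rate (per-lineage rate = rate / 2). In the
#' small-distance regime the expected uncorrected p-distance between two
#' tips equals rate x TMRCA.
#'
#' @param tree ultrametric [ape::phylo] with branch lengths in Myr.
#' @param rate pairwise divergence per Myr (default 0.02).
#' @param length alignment length in bp.
#' @param seed RNG seed.
#' @return list with `alignment` (tips x sites character matrix),
#'   `tmrca` (true pairwise TMRCA matrix, Myr), `rate`.
#' @export
simulateMtdnaAlignment <- function(tree, rate = 0.02, length = 10000L,
                                   seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  depth <- max(ape::node.depth.edgelength(tree))
  if (length(tree$tip.label) > 1L && depth > 0 &&
      !ape::is.ultrametric(tree, tol = 1e-6))
    stop("tree must be ultrametric (calibrated in Myr)")
  subTree <- tree
  subTree$edge.length <- tree$edge.length * rate / 2
  withSeed(seed, {
    aln <- decodeStates(evolveJC(subTree, as.integer(length)))
    tmrca <- ape::cophenetic.phylo(tree) / 2
    list(alignment = aln, tmrca = tmrca, rate = rate)
  })
}

#' Simulate morphometric specimen tables with type-series subsamples
#'
#' Each specimen draws a standard length (lognormal) and raw character
#' values `mean * (SL / SL0)^exponent * exp(N(0, withinSd))`, with SL0 the
#' reference standard length. The first `typeSeriesSize` specimens of each
#' group form its type series, whose standardized ranges are returned as
#' the assignment reference — small series of large-variance populations is
#' exactly the regime where assignment back to types breaks down.
#'
#' @param config a [MorphoSimConfig].
#' @return list with `specimens` (raw mm), `standardized` (times-into
#'   scale), `typeSeries` (list of [TypeSeriesRange]), `typeSpecimens`
#'   (ids in the series), and `truth` (specimen -> group).
#' @export
simulateMorphometrics <- function(config) {
  stopifnot(is(config, "MorphoSimConfig"))
  gm <- config@groupMeans
  chars <- rownames(gm); groups <- colnames(gm)
  if (config@nPerGroup < 1L) stop("empty groups")
  sdv <- rep(config@withinSd, length.out = length(chars))
  expo <- rep(config@allometryExponent, length.out = length(chars))
  SL0 <- config@standardLengthMean
  withSeed(config@seed, {
    rows <- list()
    for (g in groups) for (i in seq_len(config@nPerGroup)) {
      sl <- SL0 * exp(rnorm(1, 0, config@standardLengthCv))
      vals <- gm[, g] * (sl / SL0)^expo * exp(rnorm(length(chars), 0, sdv))
      rows[[length(rows) + 1L]] <-
        c(list(specimen_id = sprintf("%s_%02d", g, i), group = g,
               standard_length = sl), as.list(setNames(vals, chars)))
    }
    specimens <- do.call(rbind, lapply(rows, as.data.frame))
    refMap <- setNames(rep("SL", length(chars)), chars)
    standardized <- standardizeMeasurements(specimens, refMap)
    typeIds <- unlist(lapply(groups, function(g)
      sprintf("%s_%02d", g, seq_len(config@typeSeriesSize))))
    typeRows <- standardized$specimen_id %in% typeIds
    ranges <- summarizeGroupRanges(standardized[typeRows, ],
                                   standardized$group[typeRows], chars)
    typeSeries <- lapply(groups, function(g) {
      sub <- ranges[ranges$group == g, c("character", "min", "max")]
      TypeSeriesRange(g, sub, config@typeSeriesSize)
    })
    list(specimens = specimens, standardized = standardized,
         typeSeries = typeSeries, typeSpecimens = typeIds,
         truth = setNames(specimens$group, specimens$specimen_id))
  })
}

#' Simulate per-read SNP-combination observations
#'
#' Derives the read-observation table consumed by
#' [collapseReadsToHaplotypes()] from a RADseq simulation: at every typed
#' locus x individual, reads split between the two haplotype combinations
#' over the locus's variant sites, and each read independently suffers a
#' single-base miscall with probability `errorRate`.
#'
#' @param radsim result of [simulateComplexRadseq()].
#' @param errorRate per-read probability of a sequencing miscall.
#' @param seed RNG seed.
#' @return data.frame `contig`, `individual`, `combination`, `count`.
#' @export
simulateReadObservations <- function(radsim, errorRate = 0.01, seed = 1L) {
  gm <- radsim$genotypes
  rd <- variantRecords(gm)
  contigs <- unique(rd$contig)
  individuals <- colnames(genotypes(gm))
  haps <- radsim$haplotypes
  L <- radsim$config@locusLength
  withSeed(seed, {
    out <- vector("list", 2048L); nOut <- 0L
    for (ct in contigs) {
      rows <- which(rd$contig == ct)
      locus <- as.integer(sub("locus_", "", ct))
      sitePos <- (locus - 1L) * L + rd$pos[rows]
      for (ind in individuals) {
        dp <- radsim$locusDepth[ct, ind]
        if (is.na(dp) || dp == 0L || radsim$missing[locus, ind]) next
        h1 <- paste(haps[paste0(ind, "_h1"), sitePos], collapse = "")
        h2 <- paste(haps[paste0(ind, "_h2"), sitePos], collapse = "")
        n1 <- rbinom(1L, dp, 0.5)
        combos <- c(rep(h1, n1), rep(h2, dp - n1))
        err <- which(runif(dp) < errorRate)
        for (e in err) {
          p <- sample.int(nchar(h1), 1L)
          old <- substring(combos[e], p, p)
          substring(combos[e], p, p) <- sample(setdiff(DNA_STATES, old), 1L)
        }
        tab <- table(combos)
        nOut <- nOut + 1L
        out[[nOut]] <- data.frame(contig = ct, individual = ind,
                                  combination = names(tab),
                                  count = as.integer(tab))
      }
    }
    res <- do.call(rbind, out[seq_len(nOut)])
    rownames(res) <- NULL
    res
  })
}
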