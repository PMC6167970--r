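makeGm <- function(contig, pos, ref, alt, nInd = 3L, geno = NULL) {
  n <- length(contig)
  if (is.null(geno))
    geno <- matrix(1L, n, nInd)
  GenotypeMatrix(geno = geno, depth = matrix(30L, n, nInd),
                 contig = contig, pos = as.integer(pos), ref = ref,
                 alt = alt)
}

test_that("complex variants decompose into per-base SNPs", {
  gm <- makeGm("c1", 5L, "AT", "GC")
  out <- variantRecords(decomposeComplexVariants(gm))
  expect_equal(out$pos, c(5L, 6L))
  expect_equal(out$ref, c("A", "T"))
  expect_equal(out$alt, c("G", "C"))

  ## identical-base positions inside an MNP emit no record
  gm2 <- makeGm("c1", 10L, "ATG", "ATC")
  out2 <- variantRecords(decomposeComplexVariants(gm2))
  expect_equal(out2$pos, 12L)
  expect_equal(out2$ref, "G")

  ## pure SNP input is untouched
  gm3 <- makeGm(c("c1", "c2"), c(3L, 8L), c("A", "C"), c("G", "T"))
  expect_equal(variantRecords(decomposeComplexVariants(gm3)),
               variantRecords(gm3))

  ## substituted-base count is conserved over random MNP sets
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  for (i in 1:10) {
    len <- sample(2:5, 1)
    ref <- paste(sample(bases, len, TRUE), collapse = "")
    alt <- paste(sample(bases, len, TRUE), collapse = "")
    nDiff <- sum(strsplit(ref, "")[[1]] != strsplit(alt, "")[[1]])
    gmR <- makeGm("c1", 100L, ref, alt)
    if (nDiff == 0) expect_error(decomposeComplexVariants(gmR), "identical")
    else expect_equal(nrow(decomposeComplexVariants(gmR)), nDiff)
  }
})

test_that("indel records are removed, SNPs kept", {
  gm <- makeGm(c("c1", "c1"), c(4L, 9L), c("A", "A"), c("AT", "G"))
  out <- variantRecords(removeIndels(gm))
  expect_equal(nrow(out), 1L)
  expect_equal(out$alt, "G")

  snps <- makeGm(c("c1", "c2"), c(1L, 2L), c("A", "C"), c("T", "G"))
  expect_equal(nrow(removeIndels(snps)), 2L)

  ## 100 generated records with 23 indels leave 77
  set.seed(9)
  isIndel <- rep(c(TRUE, FALSE), c(23, 77))[sample(100)]
  ref <- rep("A", 100)
  alt <- ifelse(isIndel, "AG", "G")
  mixed <- makeGm(sprintf("c%03d", 1:100), rep(5L, 100), ref, alt)
  expect_equal(nrow(removeIndels(mixed)), 77L)
})

test_that("mtDNA-matching contigs are removed by seed + identity", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  mt <- paste(sample(bases, 2000, TRUE), collapse = "")
  inMt <- substring(mt, 501, 800)                  # verbatim mtDNA substring
  rnd <- paste(sample(bases, 300, TRUE), collapse = "")  # independent contig
  gm <- makeGm(c("mt_like", "nuc"), c(10L, 20L), c("A", "A"), c("G", "G"))
  res <- removeMtdnaContigs(gm, c(mt_like = inMt, nuc = rnd), mt)
  expect_identical(res$removed, "mt_like")
  expect_identical(unique(variantRecords(res$records)$contig), "nuc")

  ## reverse-complement matches are caught too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(inMt)))
  res2 <- removeMtdnaContigs(makeGm("rcg", 1L, "A", "G"), c(rcg = rc), mt)
  expect_identical(res2$removed, "rcg")

  empty <- makeGm(character(), integer(), character(), character())
  expect_equal(nrow(removeMtdnaContigs(empty, character(), mt)$records), 0L)
  expect_error(removeMtdnaContigs(gm, c(a = "ACGT"), ""), "empty")
})

test_that("85% missingness rule uses the real-valued fraction boundary", {
  nInd <- 19L
  g16 <- matrix(1L, 1, nInd); g16[1, 1:3] <- NA  # 16/19 = 0.842 typed
  g17 <- matrix(1L, 1, nInd); g17[1, 1:2] <- NA  # 17/19 = 0.895 typed
  gm <- GenotypeMatrix(geno = rbind(g16, g17),
                       depth = matrix(30L, 2, nInd),
                       contig = c("c16", "c17"), pos = c(1L, 1L),
                       ref = c("A", "A"), alt = c("G", "G"))
  kept <- unique(variantRecords(filterLocusMissingness(gm))$contig)
  expect_identical(kept, "c17")

  ## equality with a brute-force scan on a simulated matrix
  gmR <- randomGenotypeMatrix(nLoci = 200, nInd = 19, seed = 14,
                              missingRate = 0.12)
  keptPkg <- unique(variantRecords(filterLocusMissingness(gmR))$contig)
  rd <- variantRecords(gmR); g <- genotypes(gmR)
  keptBf <- character()
  for (ct in unique(rd$contig)) {
    sub <- g[rd$contig == ct, , drop = FALSE]
    typed <- sum(colSums(!is.na(sub)) > 0)
    if (typed / ncol(g) >= 0.85) keptBf <- c(keptBf, ct)
  }
  expect_setequal(keptPkg, keptBf)
})

test_that("haplotype collapsing prunes errors and flags paralogs", {
  het <- collapseReadsToHaplotypes(data.frame(
    contig = "c1", individual = "i1",
    combination = c("AT", "GC"), count = c(10L, 12L)))
  expect_identical(het$flag, "ok")
  expect_setequal(c(het$haplotype1, het$haplotype2), c("GC", "AT"))

  par <- collapseReadsToHaplotypes(data.frame(
    contig = "c1", individual = "i1",
    combination = c("AT", "GC", "AC"), count = c(10L, 12L, 9L)))
  expect_identical(par$flag, "paralog_suspect")

  ## 1 of 41 reads is below the 5% error fraction: pruned, homozygote
  hom <- collapseReadsToHaplotypes(data.frame(
    contig = "c1", individual = "i1",
    combination = c("AT", "AC"), count = c(40L, 1L)))
  expect_identical(hom$flag, "ok")
  expect_identical(hom$haplotype1, "AT")
  expect_identical(hom$haplotype2, "AT")
  expect_equal(hom$nSurviving, 1L)

  ## boundary: support exactly at the threshold survives (1/20 at 5%)
  bd <- collapseReadsToHaplotypes(data.frame(
    contig = "c1", individual = "i1",
    combination = c("AT", "AC"), count = c(19L, 1L)))
  expect_equal(bd$nSurviving, 2L)
})

test_that("the 14-of-19-at-depth-20 rule is inclusive on both bounds", {
  mkCalls <- function(nOk, depths) {
    data.frame(contig = "c1",
               individual = paste0("i", seq_len(19)),
               flag = rep(c("ok", "low_data"), c(nOk, 19 - nOk)),
               nReads = c(depths, rep(5L, 19 - nOk)))
  }
  expect_identical(filterHaplotypedLoci(mkCalls(14, rep(20L, 14))), "c1")
  ## one qualifying individual at depth 19 leaves only 13: dropped
  expect_length(filterHaplotypedLoci(mkCalls(14, c(rep(20L, 13), 19L))), 0L)
})

test_that("the cascade equals a single-pass brute-force predicate", {
  cfg <- SimConfig(tree = quartetTree(0.004, 0.008, 0.012),
                   nLoci = 120L, locusLength = 150L,
                   nIndividualsPerPop = 5L, dropout = 0.12, seed = 31L)
  rs <- simulateComplexRadseq(cfg)
  obs <- simulateReadObservations(rs, seed = 32L)
  fc <- FilterConfig(minIndividualsHaplotyped = 14L, totalIndividuals = 20L)
  res <- runFilterCascade(rs$genotypes, fc, observations = obs,
                          locusDepth = rs$locusDepth)

  ## brute force: per locus, conjunction of the missingness rule and the
  ## haplotype rule evaluated directly on the raw data
  calls <- collapseReadsToHaplotypes(obs, fc)
  rd <- variantRecords(rs$genotypes); g <- genotypes(rs$genotypes)
  bf <- character()
  for (ct in unique(rd$contig)) {
    sub <- g[rd$contig == ct, , drop = FALSE]
    typed <- sum(colSums(!is.na(sub)) > 0)
    missOk <- typed / ncol(g) >= fc@minIndividualFraction
    cc <- calls[calls$contig == ct, ]
    qual <- sum(cc$flag == "ok" &
                rs$locusDepth[ct, cc$individual] >= fc@minDepth)
    if (missOk && qual >= fc@minIndividualsHaplotyped) bf <- c(bf, ct)
  }
  expect_setequal(res$retainedLoci, bf)

  ## monotonicity: tightening any threshold never adds loci
  for (tighter in list(FilterConfig(minIndividualFraction = 0.95,
                                    minIndividualsHaplotyped = 14L,
                                    totalIndividuals = 20L),
                       FilterConfig(minIndividualsHaplotyped = 17L,
                                    totalIndividuals = 20L),
                       FilterConfig(minDepth = 60L,
                                    minIndividualsHaplotyped = 14L,
                                    totalIndividuals = 20L))) {
    resT <- runFilterCascade(rs$genotypes, tighter, observations = obs,
                             locusDepth = rs$locusDepth)
    expect_true(all(resT$retainedLoci %in% res$retainedLoci))
  }

  ## order invariance of the missingness and depth filters (conjunction)
  gmM <- filterLocusMissingness(rs$genotypes, fc)
  hapKeep <- filterHaplotypedLoci(calls, rs$locusDepth, fc)
  ab <- intersect(unique(variantRecords(gmM)$contig), hapKeep)
  gmH <- rs$genotypes[variantRecords(rs$genotypes)$contig %in% hapKeep, ]
  ba <- unique(variantRecords(filterLocusMissingness(gmH, fc))$contig)
  expect_setequal(ab, ba)
})

test_that("VCF export round-trips losslessly and byte-stably", {
  gmR <- randomGenotypeMatrix(nLoci = 30, nInd = 5, seed = 8)
  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(gmR, p1)
  back <- readGenotypeVcf(p1)
  expect_equal(genotypes(back), genotypes(gmR))
  expect_equal(readDepths(back), readDepths(gmR))
  expect_equal(variantRecords(back), variantRecords(gmR))
  writeGenotypeVcf(back, p2)
  expect_identical(readBin(p1, "raw", 1e6), readBin(p2, "raw", 1e6))

  ## per-locus genotype counts are conserved through export
  gTab <- table(variantRecords(gmR)$contig, genotypes(gmR)[, 1], useNA = "no")
  bTab <- table(variantRecords(back)$contig, genotypes(back)[, 1],
                useNA = "no")
  expect_equal(gTab, bTab)

  ## empty set gives a header-only VCF
  empty <- gmR[integer(0), ]
  p3 <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(empty, p3)
  lines <- readLines(p3)
  expect_true(all(startsWith(lines, "#")))
  expect_equal(nrow(readGenotypeVcf(p3)), 0L)
})

test_that("our VCF writer agrees with an independent parser", {
  gmR <- randomGenotypeMatrix(nLoci = 10, nInd = 4, seed = 19)
  p <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(gmR, p)
  v <- vcfR::read.vcfR(p, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  conv <- matrix(match(gt, c("0/0", "0/1", "1/1")) - 1L, nrow(gt))
  expect_equal(unname(conv), unname(genotypes(gmR)))
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  expect_equal(unname(dp), unname(readDepths(gmR)) + 0)
})
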