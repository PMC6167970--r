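## ABBA-BABA site-pattern statistics: Patterson's D, f_d, block jackknife.
##
## Input is an alignment as a character matrix (individuals x sites, states
## A/C/G/T with N or - for missing) plus a population map assigning each
## individual to P1, P2, P3 or the outgroup. With one sequence per taxon the
## derived-allele frequencies are 0/1 and the frequency-weighted counts
## reduce to integer pattern counts.

alignmentMatrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is(aln, "DNAStringSet")) {
    m <- t(vapply(as.character(aln),
                  function(s) strsplit(s, "")[[1]],
                  character(Biostrings::width(aln)[1])))
    rownames(m) <- names(aln)
    return(m)
  }
  stop("alignment must be a character matrix or DNAStringSet")
}

## case-folding ACGT integer coding; anything else (N, -, ?) becomes NA
codeStates <- function(m) {
  codes <- match(m, c("A", "C", "G", "T", "a", "c", "g", "t"))
  codes <- (codes - 1L) %% 4L + 1L
  matrix(codes, nrow(m))
}

#' Polarize sites against an outgroup
#'
#' For every biallelic site, the outgroup allele defines the ancestral
#' state and derived-allele frequencies are computed for P1, P2 and P3.
#' Sites are skipped when the outgroup is polymorphic or missing, when more
#' than two alleles segregate, or when any ingroup population has no typed
#' individual (complete-case rule; with one sequence per taxon this means
#' any missing base skips the site).
#'
#' @param aln character matrix (individuals x sites) or
#'   [Biostrings::DNAStringSet]; `N`, `-` and `?` are missing.
#' @param popmap named character vector individual -> population.
#' @param P1,P2,P3,outgroup population labels.
#' @param locusIndex optional integer vector (one per site) giving the
#'   locus each site belongs to, used for jackknife blocking; defaults to
#'   site index (every site its own locus).
#' @return data.frame with columns `site`, `locus`, `p1`, `p2`, `p3` for
#'   the used sites.
#' @export
polarizeSites <- function(aln, popmap, P1 = "P1", P2 = "P2", P3 = "P3",
                          outgroup = "O", locusIndex = NULL) {
  m <- alignmentMatrix(aln)
  if (is.null(rownames(m))) stop("alignment rows must be named")
  pops <- popmap[rownames(m)]
  if (!outgroup %in% pops) stop("outgroup population absent from alignment")
  for (p in c(P1, P2, P3))
    if (!p %in% pops) stop("population absent from alignment: ", p)
  if (is.null(locusIndex)) locusIndex <- seq_len(ncol(m))
  stopifnot(length(locusIndex) == ncol(m))
  codes <- codeStates(m)
  nS <- ncol(codes)
  rowsO <- which(pops == outgroup)
  rows1 <- which(pops == P1); rows2 <- which(pops == P2)
  rows3 <- which(pops == P3)
  colRange <- function(rows) {
    mn <- rep(5L, nS); mx <- rep(0L, nS); nn <- rep(0L, nS)
    for (r in rows) {
      v <- codes[r, ]; okv <- !is.na(v)
      mn[okv] <- pmin(mn[okv], v[okv]); mx[okv] <- pmax(mx[okv], v[okv])
      nn <- nn + okv
    }
    list(mn = mn, mx = mx, n = nn)
  }
  countEq <- function(rows, val) {
    s <- rep(0L, nS)
    for (r in rows) {
      v <- codes[r, ]
      s <- s + (!is.na(v) & !is.na(val) & v == val)
    }
    s
  }
  og <- colRange(rowsO)
  okO <- og$n > 0L & og$mn == og$mx            # outgroup typed and fixed
  anc <- og$mn; anc[!okO] <- NA_integer_
  ingRows <- c(rows1, rows2, rows3)
  nIngNA <- rep(0L, nS)
  for (r in ingRows) nIngNA <- nIngNA + is.na(codes[r, ])
  okIn <- nIngNA == 0L                          # complete-case ingroups
  allR <- colRange(c(ingRows, rowsO))
  mono <- allR$mn == allR$mx
  biallelic <- mono |
    countEq(c(ingRows, rowsO), allR$mn) +
    countEq(c(ingRows, rowsO), allR$mx) == allR$n
  ok <- okO & okIn & biallelic
  ## derived allele: whichever of the two segregating states is not ancestral
  derivedCmp <- allR$mx
  swap <- !is.na(anc) & anc == allR$mx
  derivedCmp[swap] <- allR$mn[swap]
  derivedCmp[mono] <- -1L
  popFreq <- function(rows) {
    num <- rep(0, nS)
    for (r in rows) {
      v <- codes[r, ]
      num <- num + (!is.na(v) & v == derivedCmp)
    }
    num / length(rows)
  }
  data.frame(site = which(ok), locus = locusIndex[ok],
             p1 = popFreq(rows1)[ok], p2 = popFreq(rows2)[ok],
             p3 = popFreq(rows3)[ok])
}

#' Count ABBA and BABA site patterns
#'
#' Frequency-weighted pattern counts over polarized sites: per site,
#' ABBA weight = (1-p1) p2 p3 and BABA weight = p1 (1-p2) p3 (the outgroup
#' is fixed ancestral after polarization). With frequencies in \{0,1\} the
#' weights are exact 0/1 pattern indicators. Sites are assigned to
#' contiguous blocks of `blockSize` loci for the jackknife.
#'
#' @param freqs data.frame from [polarizeSites()].
#' @param blockSize number of contiguous loci per jackknife block
#'   (default 50).
#' @return list with `abba`, `baba` (weighted totals), `nSites`, and
#'   `blocks` (data.frame `block`, `abba`, `baba`; subtotals sum to the
#'   totals).
#' @export
countSitePatterns <- function(freqs, blockSize = 50L) {
  if (blockSize < 1L) stop("block size must be >= 1")
  abbaW <- (1 - freqs$p1) * freqs$p2 * freqs$p3
  babaW <- freqs$p1 * (1 - freqs$p2) * freqs$p3
  locusRank <- match(freqs$locus, sort(unique(freqs$locus)))
  blk <- (locusRank - 1L) %/% as.integer(blockSize)
  blocks <- data.frame(
    block = sort(unique(blk)),
    abba = as.numeric(rowsum(abbaW, blk)),
    baba = as.numeric(rowsum(babaW, blk)))
  list(abba = sum(abbaW), baba = sum(babaW), nSites = nrow(freqs),
       blocks = blocks)
}

#' Patterson's D statistic
#'
#' D = (ABBA - BABA) / (ABBA + BABA). Defined only when ABBA + BABA > 0;
#' otherwise an error of class `radelim_undefined` is signaled rather than
#' propagating NaN.
#'
#' @param counts list from [countSitePatterns()] (or anything with `abba`
#'   and `baba` elements).
#' @return D in \[-1, 1\].
#' @examples
#' pattersonD(list(abba = 30, baba = 10))  # 0.5
#' @export
pattersonD <- function(counts) {
  tot <- counts$abba + counts$baba
  if (!is.finite(tot) || tot <= 0)
    undefinedStat("D undefined: ABBA + BABA is zero")
  (counts$abba - counts$baba) / tot
}

#' f_d admixture-fraction estimator
#'
#' Estimates the fraction of the genome shared through complete
#' introgression: f_d = S(P1, P2, P3) / S(P1, P_D, P_D), where S is the
#' summed ABBA-BABA weight difference and P_D is, per site, whichever of
#' P2/P3 has the larger derived-allele frequency. Per its definition f_d is
#' reported only for quartets with D > 0; otherwise `NA` is returned with a
#' warning.
#'
#' @param freqs data.frame from [polarizeSites()].
#' @return f_d, or `NA_real_` when D <= 0 (undefined).
#' @export
fD <- function(freqs) {
  num <- sum((1 - freqs$p1) * freqs$p2 * freqs$p3 -
             freqs$p1 * (1 - freqs$p2) * freqs$p3)
  if (num <= 0) {
    warning("f_d undefined for D <= 0; returning NA")
    return(NA_real_)
  }
  pd <- pmax(freqs$p2, freqs$p3)
  den <- sum((1 - freqs$p1) * pd * pd - freqs$p1 * (1 - pd) * pd)
  if (den == 0) {
    warning("f_d denominator is zero; returning NA")
    return(NA_real_)
  }
  num / den
}

#' Block-jackknife standard error, Z and p
#'
#' Delete-one-block jackknife for a genome-wide statistic computed from
#' per-block subtotals: the statistic is recomputed with each block
#' removed, SE = sqrt((n-1)/n * sum((theta_i - theta_bar)^2)) over the n
#' non-empty blocks, Z = theta_hat / SE and the p-value is two-sided
#' normal. When every delete-one value coincides the SE is zero and the
#' result is flagged (`zeroSe = TRUE`, Z undefined).
#'
#' @param blocks data.frame of per-block subtotals with columns `abba` and
#'   `baba` (empty blocks, with zero total weight, are dropped).
#' @param statistic function of a subtotal data.frame returning the scalar
#'   statistic; defaults to Patterson's D.
#' @return list with `estimate`, `se`, `z`, `p`, `nBlocks`, `zeroSe`.
#' @examples
#' b <- data.frame(abba = c(10, 14, 12), baba = c(4, 5, 3))
#' blockJackknife(b)
#' @export
blockJackknife <- function(blocks,
                           statistic = function(b)
                             pattersonD(list(abba = sum(b$abba),
                                             baba = sum(b$baba)))) {
  nonEmpty <- blocks[blocks$abba + blocks$baba > 0, , drop = FALSE]
  n <- nrow(nonEmpty)
  if (n < 2L) stop("need at least 2 non-empty blocks")
  est <- statistic(nonEmpty)
  loo <- vapply(seq_len(n),
                function(i) statistic(nonEmpty[-i, , drop = FALSE]),
                numeric(1))
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  if (se == 0)
    return(list(estimate = est, se = 0, z = NA_real_, p = NA_real_,
                nBlocks = n, zeroSe = TRUE))
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)),
       nBlocks = n, zeroSe = FALSE)
}

## does the guide tree place P1 and P2 as mutual closest ingroups relative
## to P3? TRUE iff the smallest clade containing all P1+P2 tips excludes
## every P3 tip
validQuartetTopology <- function(tree, popmap, P1, P2, P3) {
  tipPop <- popmap[tree$tip.label]
  tips12 <- tree$tip.label[tipPop %in% c(P1, P2)]
  tips3 <- tree$tip.label[tipPop %in% P3]
  if (!length(tips12) || !length(tips3)) return(FALSE)
  if (length(tips12) == 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, tips12)
  clade <- ape::extract.clade(tree, mrca)$tip.label
  !any(tips3 %in% clade)
}

#' Run ABBA-BABA tests over a set of quartets
#'
#' For each requested (P1, P2, P3, outgroup) comparison: checks on the
#' guide tree that P1 and P2 are each other's closest ingroup relative to
#' P3 (comparisons violating the ((P1,P2),P3) ancestry assumption are
#' rejected with a reason), then polarizes sites, counts patterns, and
#' reports D, f_d, the block-jackknife SE, Z, two-sided p, and the Z >= 3
#' significance call.
#'
#' @param aln alignment (character matrix or DNAStringSet), individuals x
#'   sites.
#' @param popmap named character vector individual -> population.
#' @param quartets data.frame with columns `P1`, `P2`, `P3`, `O`.
#' @param guideTree [ape::phylo] with tips that are individuals (mapped
#'   through `popmap`) or population labels; `NULL` skips the topology
#'   check.
#' @param blockSize jackknife block size in loci (default 50).
#' @param locusIndex optional per-site locus index (see [polarizeSites()]).
#' @return a [QuartetResult].
#' @export
runAbbaBaba <- function(aln, popmap, quartets, guideTree = NULL,
                        blockSize = 50L, locusIndex = NULL) {
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(quartets)))
  m <- alignmentMatrix(aln)
  rows <- lapply(seq_len(nrow(quartets)), function(i) {
    q <- quartets[i, ]
    base <- data.frame(P1 = q$P1, P2 = q$P2, P3 = q$P3, O = q$O,
                       abba = NA_real_, baba = NA_real_, D = NA_real_,
                       fd = NA_real_, se = NA_real_, Z = NA_real_,
                       p = NA_real_, significant = NA, status = "ok")
    if (!is.null(guideTree)) {
      pm <- popmap
      extra <- setdiff(guideTree$tip.label, names(pm))
      pm[extra] <- extra  # population-labeled tips map to themselves
      if (!validQuartetTopology(guideTree, pm, q$P1, q$P2, q$P3)) {
        base$status <- "rejected: guide tree violates ((P1,P2),P3) ancestry"
        return(base)
      }
    }
    freqs <- polarizeSites(m, popmap, q$P1, q$P2, q$P3, q$O,
                           locusIndex = locusIndex)
    counts <- countSitePatterns(freqs, blockSize)
    base$abba <- counts$abba; base$baba <- counts$baba
    d <- tryCatch(pattersonD(counts), radelim_undefined = function(e) NA_real_)
    if (is.na(d)) { base$status <- "undefined: no informative sites"; return(base) }
    base$D <- d
    base$fd <- if (d > 0) suppressWarnings(fD(freqs)) else NA_real_
    jk <- tryCatch(blockJackknife(counts$blocks), error = function(e) NULL)
    if (!is.null(jk) && !jk$zeroSe) {
      base$se <- jk$se; base$Z <- jk$z; base$p <- jk$p
      base$significant <- jk$z >= 3
    } else {
      base$significant <- FALSE
      base$status <- "flagged: jackknife SE is zero or blocks insufficient"
    }
    base
  })
  tb <- do.call(rbind, rows)
  rownames(tb) <- NULL
  new("QuartetResult", table = tb, blockSize = as.integer(blockSize))
}
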