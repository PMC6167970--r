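## Independent brute-force oracles used across tests. These deliberately
## re-derive results by direct per-element scans, separate from the
## vectorized package implementations.

## per-site polarization by the stated rules: outgroup fixed and typed,
## complete-case ingroups, at most two alleles
bfPolarize <- function(m, popmap, P1, P2, P3, O, locusIndex = NULL) {
  if (is.null(locusIndex)) locusIndex <- seq_len(ncol(m))
  miss <- c("N", "-", "?")
  pops <- popmap[rownames(m)]
  out <- NULL
  for (s in seq_len(ncol(m))) {
    col <- toupper(m[, s])
    og <- col[pops == O]; og <- og[!og %in% miss]
    if (!length(og) || length(unique(og)) > 1) next
    ing <- lapply(c(P1, P2, P3), function(p) col[pops == p])
    if (any(unlist(ing) %in% miss)) next
    alleles <- unique(c(og[1], unlist(ing)))
    if (length(alleles) > 2) next
    derived <- setdiff(alleles, og[1])
    fr <- if (!length(derived)) c(0, 0, 0)
          else vapply(ing, function(v) mean(v == derived), numeric(1))
    out <- rbind(out, data.frame(site = s, locus = locusIndex[s],
                                 p1 = fr[1], p2 = fr[2], p3 = fr[3]))
  }
  if (is.null(out))
    data.frame(site = integer(), locus = integer(), p1 = numeric(),
               p2 = numeric(), p3 = numeric())
  else out
}

## direct interval-membership assignment scan
bfAssign <- function(vals, rangesList, variables) {
  props <- numeric(length(rangesList))
  noneCount <- 0
  for (v in variables) {
    insideAny <- FALSE
    for (k in seq_along(rangesList)) {
      rr <- rangesList[[k]]@ranges
      row <- rr[rr$character == v, ]
      if (nrow(row) && !is.na(vals[v]) &&
          vals[v] >= row$min[1] - 1e-9 && vals[v] <= row$max[1] + 1e-9) {
        props[k] <- props[k] + 1
        insideAny <- TRUE
      }
    }
    if (!insideAny) noneCount <- noneCount + 1
  }
  list(props = round(props / length(variables), 2),
       unclassified = round(noneCount / length(variables), 2))
}

## per-pair per-site p-distance scan
bfPDist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  good <- function(x) toupper(x) %in% c("A", "C", "G", "T")
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- good(m[i, ]) & good(m[j, ])
    d[i, j] <- d[j, i] <- sum(toupper(m[i, ok]) != toupper(m[j, ok])) / sum(ok)
  }
  d
}

## clade enumeration: all descendant tip sets of internal nodes
bfCladeSets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- list()
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  for (node in (n + 1):(n + tree$Nnode)) sets[[node - n]] <- desc(node)
  sets
}

bfMonophyly <- function(tree, labels) {
  sets <- c(bfCladeSets(tree), as.list(tree$tip.label))
  containing <- Filter(function(s) all(labels %in% s), sets)
  sizes <- vapply(containing, length, integer(1))
  smallest <- containing[[which.min(sizes)]]
  list(monophyletic = setequal(smallest, labels),
       cladeSize = length(smallest))
}

## non-trivial splits of an unrooted tree as canonical strings
bfSplits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  sets <- bfCladeSets(tree)
  keep <- Filter(function(s) length(s) >= 2 && length(s) <= length(tips) - 2,
                 sets)
  unique(vapply(keep, function(s) {
    a <- sort(s); b <- sort(setdiff(tips, s))
    if (paste(a, collapse = ",") < paste(b, collapse = ","))
      paste(paste(a, collapse = ","), paste(b, collapse = ","), sep = "|")
    else paste(paste(b, collapse = ","), paste(a, collapse = ","), sep = "|")
  }, character(1)))
}

## small random genotype matrix builder
randomGenotypeMatrix <- function(nLoci, nInd, seed, missingRate = 0.1,
                                 snpsPerLocus = 2L) {
  set.seed(seed)
  nVar <- nLoci * snpsPerLocus
  geno <- matrix(sample(0:2, nVar * nInd, replace = TRUE), nVar, nInd)
  miss <- matrix(runif(nLoci * nInd) < missingRate, nLoci, nInd)
  locus <- rep(seq_len(nLoci), each = snpsPerLocus)
  geno[miss[locus, ]] <- NA_integer_
  depth <- matrix(rpois(nVar * nInd, 30), nVar, nInd)
  depth[is.na(geno)] <- 0L
  colnames(geno) <- paste0("ind_", seq_len(nInd))
  GenotypeMatrix(geno = geno, depth = depth,
                 contig = sprintf("locus_%04d", locus),
                 pos = rep(seq_len(snpsPerLocus) * 10L, nLoci),
                 ref = rep("A", nVar), alt = rep("G", nVar))
}

## one-call quartet D run used by several tests
quartetDRun <- function(nLoci, gamma, seed, blockSize = 50L,
                        locusLength = 150L) {
  pulses <- if (gamma > 0)
    data.frame(donor = "P3", recipient = "P2", gamma = gamma)
  else data.frame(donor = character(), recipient = character(),
                  gamma = numeric())
  cfg <- SimConfig(nLoci = as.integer(nLoci),
                   locusLength = as.integer(locusLength),
                   admixturePulses = pulses, seed = as.integer(seed))
  sim <- simulateQuartetLoci(cfg)
  pm <- setNames(rownames(sim$alignment), rownames(sim$alignment))
  res <- runAbbaBaba(sim$alignment, pm,
                     data.frame(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"),
                     blockSize = blockSize, locusIndex = sim$locusIndex)
  quartetTable(res)
}
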