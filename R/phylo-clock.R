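## Uncorrected distances, a distance-based tree stand-in, monophyly and
## concordance checks, and strict-clock divergence-time conversion.
##
## Tree inference here is deliberately lightweight: neighbor joining on
## uncorrected p-distances stands in for external likelihood/Bayesian
## machinery, which is enough for monophyly and concordance questions on
## shallow, clock-like divergences.

#' Uncorrected p-distance matrix
#'
#' Pairwise proportion of differing sites, counting only positions where
#' both sequences are unambiguous (pairwise deletion of gaps and Ns). No
#' multiple-hit correction is applied — this is the "uncorrected pairwise
#' divergence" the strict clock consumes.
#'
#' @param aln equal-length aligned sequences: character matrix (taxa x
#'   sites), [Biostrings::DNAStringSet], or [ape::DNAbin].
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' aln <- rbind(a = strsplit("ACGT", "")[[1]], b = strsplit("ACGA", "")[[1]])
#' pDistanceMatrix(aln)["a", "b"]  # 0.25
#' @export
pDistanceMatrix <- function(aln) {
  if (is(aln, "DNAStringSet")) aln <- alignmentMatrix(aln)
  bin <- if (inherits(aln, "DNAbin")) aln
         else if (is.matrix(aln)) {
           m <- aln; m[] <- tolower(m)
           ape::as.DNAbin(m)
         } else stop("unsupported alignment type")
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d)))
    stop("a sequence pair shares zero comparable sites")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard rate-corrected agglomerative joining (via `ape::nj`); negative
#' branch-length artifacts are clamped to zero with a warning. Topology is
#' invariant to the input taxon order.
#'
#' @param d symmetric distance matrix (>= 3 taxa) or `dist` object.
#' @return an unrooted [ape::phylo] tree.
#' @export
neighborJoining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Convert p-distance to divergence time under a strict clock
#'
#' TMRCA = d / r under the default pairwise reading of the rate (2%
#' pairwise divergence per million years), or d / (2r) when the
#' [ClockConfig] uses the per-lineage reading.
#'
#' @param d uncorrected p-distance (scalar, vector or matrix), >= 0.
#' @param config a [ClockConfig].
#' @return time(s) to the most recent common ancestor, in Myr.
#' @examples
#' strictClockTime(0.02)  # 1 Myr at the default 2%/Myr
#' @export
strictClockTime <- function(d, config = ClockConfig()) {
  if (any(d < 0)) stop("p-distance must be >= 0")
  if (config@mode == "pairwise") d / config@rate else d / (2 * config@rate)
}

#' Test a label set for monophyly
#'
#' Whether the smallest clade containing all the given tips contains no
#' others. Unrooted trees are rooted on `outgroup` first; single tips and
#' the full tip set are trivially monophyletic.
#'
#' @param tree an [ape::phylo].
#' @param labels tip labels to test (must all be in the tree).
#' @param outgroup optional tip used to root an unrooted tree.
#' @return list with `monophyletic` and `cladeSize` (tip count of the
#'   smallest containing clade).
#' @export
checkMonophyly <- function(tree, labels, outgroup = NULL) {
  bad <- setdiff(labels, tree$tip.label)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup))
      stop("tree is unrooted; supply an outgroup to root on")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  if (length(labels) <= 1L)
    return(list(monophyletic = TRUE, cladeSize = length(labels)))
  if (length(labels) == length(tree$tip.label))
    return(list(monophyletic = TRUE, cladeSize = length(labels)))
  mrca <- ape::getMRCA(tree, labels)
  clade <- ape::extract.clade(tree, mrca)$tip.label
  list(monophyletic = length(clade) == length(labels),
       cladeSize = length(clade))
}

#' Topology concordance between two trees
#'
#' Robinson-Foulds symmetric difference of non-trivial splits, its
#' normalization by 2(n-3), and the number of shared splits. RF 0 means
#' identical unrooted topologies ("high concordance"); normalized RF 1
#' means no shared split.
#'
#' @param treeA,treeB [ape::phylo] trees over the same tip set.
#' @return list with `rf`, `normalizedRf`, `sharedSplits`.
#' @export
topologyConcordance <- function(treeA, treeB) {
  if (!setequal(treeA$tip.label, treeB$tip.label))
    stop("trees must share an identical tip set")
  ua <- ape::unroot(treeA); ub <- ape::unroot(treeB)
  rf <- as.numeric(phangorn::RF.dist(ua, ub))
  n <- length(ua$tip.label)
  denom <- 2 * (n - 3)
  splitsA <- ua$Nnode - 1L   # internal edges of an unrooted tree
  splitsB <- ub$Nnode - 1L
  list(rf = rf,
       normalizedRf = if (denom > 0) rf / denom else 0,
       sharedSplits = (splitsA + splitsB - rf) / 2)
}
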