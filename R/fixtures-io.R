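## Writing simulation outputs to standard on-disk formats, with a JSON
## truth manifest, and reading them back. All writers are deterministic in
## byte layout so fixed-seed runs reproduce files exactly.

alignmentToFasta <- function(m, path) {
  seqs <- Biostrings::DNAStringSet(apply(m, 1, paste0, collapse = ""))
  names(seqs) <- rownames(m)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

fastaToAlignment <- function(path) {
  alignmentMatrix(Biostrings::readDNAStringSet(path))
}

writeCsvCanonical <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a simulation fixture bundle
#'
#' Serializes the outputs of the synthetic generators to a directory of
#' standard formats — per-locus FASTA alignments for quartet data, VCF +
#' depth CSV + Newick for RADseq data, FASTA + TMRCA CSV for the clock
#' alignment, CSVs for morphometrics — plus a `manifest.json` recording
#' every file, its md5 checksum, and the simulation truth (introgressed
#' loci, pulse classes, group labels, seeds).
#'
#' @param outputs named list with any of `quartet`
#'   ([simulateQuartetLoci()] result), `radseq`
#'   ([simulateComplexRadseq()] result), `mtdna`
#'   ([simulateMtdnaAlignment()] result), `morpho`
#'   ([simulateMorphometrics()] result).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
writeFixtureBundle <- function(outputs, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  if (file.access(dir, mode = 2) != 0) stop("unwritable path: ", dir)
  files <- character()
  truth <- list()
  ## all artifact paths are built with file.path(dir, ...), so relative
  ## paths are just the tail beyond the directory prefix
  rel <- function(p) sub("^/+", "", substring(p, nchar(dir) + 1L))

  if (!is.null(outputs$quartet)) {
    q <- outputs$quartet
    qd <- file.path(dir, "quartet")
    dir.create(qd, showWarnings = FALSE)
    for (l in unique(q$locusIndex)) {
      p <- file.path(qd, sprintf("locus_%04d.fasta", l))
      alignmentToFasta(q$alignment[, q$locusIndex == l, drop = FALSE], p)
      files <- c(files, p)
    }
    truth$quartet <- list(gamma = q$gamma,
                          introgressed_loci =
                            q$truth$locus[q$truth$introgressed],
                          n_loci = nrow(q$truth),
                          seed = q$config@seed)
  }
  if (!is.null(outputs$radseq)) {
    r <- outputs$radseq
    p1 <- file.path(dir, "radseq_genotypes.vcf")
    writeGenotypeVcf(r$genotypes, p1)
    p2 <- file.path(dir, "radseq_depth.csv")
    writeCsvCanonical(data.frame(locus = rownames(r$locusDepth),
                                 r$locusDepth, check.names = FALSE), p2)
    p3 <- file.path(dir, "radseq_true_tree.nwk")
    ape::write.tree(r$popTree, p3)
    files <- c(files, p1, p2, p3)
    truth$radseq <- list(pulse_class = r$truth$pulse,
                         popmap = as.list(r$popmap),
                         seed = r$config@seed)
  }
  if (!is.null(outputs$mtdna)) {
    mtd <- outputs$mtdna
    p1 <- file.path(dir, "mtdna_alignment.fasta")
    alignmentToFasta(mtd$alignment, p1)
    p2 <- file.path(dir, "mtdna_tmrca.csv")
    writeCsvCanonical(data.frame(tip = rownames(mtd$tmrca), mtd$tmrca,
                                 check.names = FALSE), p2)
    files <- c(files, p1, p2)
    truth$mtdna <- list(rate = mtd$rate)
  }
  if (!is.null(outputs$morpho)) {
    mo <- outputs$morpho
    p1 <- file.path(dir, "morpho_specimens.csv")
    writeCsvCanonical(mo$specimens, p1)
    p2 <- file.path(dir, "morpho_standardized.csv")
    writeCsvCanonical(mo$standardized, p2)
    p3 <- file.path(dir, "morpho_type_ranges.csv")
    writeCsvCanonical(do.call(rbind, lapply(mo$typeSeries, function(ts)
      data.frame(series = seriesName(ts), seriesRanges(ts)))), p3)
    files <- c(files, p1, p2, p3)
    truth$morpho <- list(groups = as.list(mo$truth),
                         type_specimens = mo$typeSpecimens)
  }
  manifest <- list(
    files = lapply(files, function(f)
      list(path = rel(f), md5 = unname(md5sum(f)))),
    truth = truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture bundle back
#'
#' Re-loads the components written by [writeFixtureBundle()]; matrices and
#' tables come back equal to the in-memory originals.
#'
#' @param dir bundle directory containing `manifest.json`.
#' @return named list with the available components (`quartet$alignment`,
#'   `radseq$genotypes`, `radseq$locusDepth`, `radseq$popTree`,
#'   `mtdna$alignment`, `mtdna$tmrca`, `morpho$...`) plus `manifest`.
#' @export
readFixtureBundle <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  out <- list(manifest = mf)
  qd <- file.path(dir, "quartet")
  if (dir.exists(qd)) {
    fs <- sort(list.files(qd, pattern = "\\.fasta$", full.names = TRUE))
    alns <- lapply(fs, fastaToAlignment)
    out$quartet <- list(
      alignment = do.call(cbind, alns),
      locusIndex = rep(seq_along(alns),
                       vapply(alns, ncol, integer(1))))
  }
  if (file.exists(file.path(dir, "radseq_genotypes.vcf"))) {
    depthDf <- read.csv(file.path(dir, "radseq_depth.csv"),
                        check.names = FALSE)
    ld <- as.matrix(depthDf[, -1, drop = FALSE])
    rownames(ld) <- depthDf$locus
    out$radseq <- list(
      genotypes = readGenotypeVcf(file.path(dir, "radseq_genotypes.vcf")),
      locusDepth = ld,
      popTree = ape::read.tree(file.path(dir, "radseq_true_tree.nwk")))
  }
  if (file.exists(file.path(dir, "mtdna_alignment.fasta"))) {
    tm <- read.csv(file.path(dir, "mtdna_tmrca.csv"), check.names = FALSE)
    tmm <- as.matrix(tm[, -1, drop = FALSE])
    rownames(tmm) <- tm$tip
    out$mtdna <- list(
      alignment = fastaToAlignment(file.path(dir, "mtdna_alignment.fasta")),
      tmrca = tmm)
  }
  if (file.exists(file.path(dir, "morpho_specimens.csv"))) {
    out$morpho <- list(
      specimens = read.csv(file.path(dir, "morpho_specimens.csv")),
      standardized = read.csv(file.path(dir, "morpho_standardized.csv")),
      typeRanges = read.csv(file.path(dir, "morpho_type_ranges.csv")))
  }
  out
}
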