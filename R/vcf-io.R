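## Plain-text VCF 4.2 export/import for GenotypeMatrix objects.
##
## The writer emits a canonical byte layout (fixed header, tab-separated
## body, "\n" line endings) so that fixed-seed runs and write->read->write
## round trips are byte-stable. Reading uses a small column parser for the
## GT:DP:AD fields we emit; tests cross-check it against the vcfR parser.

vcfGenoString <- function(g) {
  ifelse(is.na(g), "./.", c("0/0", "0/1", "1/1")[g + 1L])
}

#' Write a GenotypeMatrix to VCF
#'
#' Emits VCF 4.2 with FORMAT fields GT, DP and AD. AD is reconstructed from
#' depth and genotype as (ref reads, alt reads) with the alt share
#' proportional to the alternate-allele dosage. Missing genotypes are
#' written as `./.` with their recorded depth.
#'
#' @param gm a [GenotypeMatrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  rd <- variantRecords(gm)
  g <- genotypes(gm); d <- readDepths(gm)
  header <- c("##fileformat=VCFv4.2",
              "##source=radelim",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  body <- character(nrow(rd))
  for (i in seq_len(nrow(rd))) {
    gi <- g[i, ]; di <- d[i, ]
    altReads <- ifelse(is.na(gi), 0L, as.integer(round(di * gi / 2)))
    cells <- paste0(vcfGenoString(gi), ":", di, ":",
                    di - altReads, ",", altReads)
    body[i] <- paste(c(rd$contig[i], rd$pos[i], ".", rd$ref[i], rd$alt[i],
                       ".", "PASS", ".", "GT:DP:AD", cells), collapse = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a VCF into a GenotypeMatrix
#'
#' Parses a VCF with GT and DP FORMAT fields (such as those written by
#' [writeGenotypeVcf()], or any biallelic single-sample-field VCF) into a
#' [GenotypeMatrix]. Genotypes other than 0/0, 0/1, 1/0, 1/1 (any phasing
#' separator) are treated as missing.
#'
#' @param path VCF file path.
#' @return a `GenotypeMatrix`.
#' @export
readGenotypeVcf <- function(path) {
  lines <- readLines(path)
  dataLines <- lines[!startsWith(lines, "##")]
  hdr <- dataLines[1]
  if (!startsWith(hdr, "#CHROM")) stop("missing #CHROM header line")
  cols <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- dataLines[-1]
  if (!length(body)) {
    empty <- matrix(integer(), 0, length(samples),
                    dimnames = list(NULL, samples))
    return(GenotypeMatrix(geno = empty, depth = empty, contig = character(),
                          pos = integer(), ref = character(),
                          alt = character()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nSamp <- length(samples)
  geno <- matrix(NA_integer_, length(body), nSamp,
                 dimnames = list(NULL, samples))
  depth <- matrix(0L, length(body), nSamp, dimnames = list(NULL, samples))
  contig <- character(length(body)); pos <- integer(length(body))
  ref <- character(length(body)); alt <- character(length(body))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    contig[i] <- f[1]; pos[i] <- as.integer(f[2])
    ref[i] <- f[4]; alt[i] <- f[5]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gtIdx <- match("GT", fmt); dpIdx <- match("DP", fmt)
    for (j in seq_len(nSamp)) {
      parts <- strsplit(f[9 + j], ":", fixed = TRUE)[[1]]
      gt <- gsub("\\|", "/", parts[gtIdx])
      geno[i, j] <- switch(gt, "0/0" = 0L, "0/1" = 1L, "1/0" = 1L,
                           "1/1" = 2L, NA_integer_)
      if (!is.na(dpIdx) && dpIdx <= length(parts))
        depth[i, j] <- suppressWarnings(as.integer(parts[dpIdx]))
    }
  }
  depth[is.na(depth)] <- 0L
  GenotypeMatrix(geno = geno, depth = depth, contig = contig, pos = pos,
                 ref = ref, alt = alt)
}
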