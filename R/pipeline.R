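## End-to-end orchestration: simulate -> morphometrics -> RAD filtering ->
## introgression -> phylogeny/clock, with a manifest, a Markdown report and
## a machine-readable JSON summary. Every stage draws from its own RNG
## substream (stageSeed), so outputs are byte-identical for a fixed master
## seed regardless of which stages are enabled.

#' Build a pipeline configuration
#'
#' @param stages character vector of stages to run, any of `"simulate"`,
#'   `"morphometrics"`, `"rad_filtering"`, `"introgression"`,
#'   `"phylo_clock"` (analysis stages require `"simulate"`, which supplies
#'   their inputs).
#' @param seed master seed; per-stage seeds are derived with [stageSeed()].
#' @param simConfig a [SimConfig] for the genetic generators (its `seed`
#'   is overridden by the derived stage seed).
#' @param morphoConfig a [MorphoSimConfig] (same seed handling).
#' @param filterConfig a [FilterConfig].
#' @param clockConfig a [ClockConfig].
#' @param gamma admixture fraction for the quartet introgression stage.
#' @param blockSize jackknife block size (loci).
#' @param mtdnaTreeMyr ultrametric [ape::phylo] in Myr for the clock stage
#'   (default: the simulation population tree rescaled so the root is
#'   0.119 Myr deep).
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(stages = c("simulate", "morphometrics",
                                      "rad_filtering", "introgression",
                                      "phylo_clock"),
                           seed = 1L,
                           simConfig = SimConfig(),
                           morphoConfig = MorphoSimConfig(),
                           filterConfig = FilterConfig(
                             minIndividualsHaplotyped = 14L,
                             totalIndividuals = 19L),
                           clockConfig = ClockConfig(),
                           gamma = 0.3, blockSize = 50L,
                           mtdnaTreeMyr = NULL) {
  known <- c("simulate", "morphometrics", "rad_filtering", "introgression",
             "phylo_clock")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, seed = as.integer(seed),
                 simConfig = simConfig, morphoConfig = morphoConfig,
                 filterConfig = filterConfig, clockConfig = clockConfig,
                 gamma = gamma, blockSize = as.integer(blockSize),
                 mtdnaTreeMyr = mtdnaTreeMyr),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields (`stages`, `seed`, `gamma`, `blockSize`, and the numeric
#' fields of the filter/clock/simulation configs) can be set in a YAML
#' file; unspecified fields keep their defaults.
#'
#' @param path YAML file.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("stages", "seed", "gamma", "blockSize"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$filter))
    args$filterConfig <- do.call(FilterConfig, y$filter)
  if (!is.null(y$clock))
    args$clockConfig <- do.call(ClockConfig, y$clock)
  if (!is.null(y$sim))
    args$simConfig <- do.call(SimConfig, y$sim)
  if (!is.null(y$morpho))
    args$morphoConfig <- do.call(MorphoSimConfig, y$morpho)
  do.call(pipelineConfig, args)
}

pipelineLog <- function(stage, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), stage, ": ", ...)
}

#' Run the full synthetic-complex pipeline
#'
#' Executes the enabled stages end to end on synthetic data and writes
#' every artifact (fixture bundle, assignment table, quartet table, trees,
#' clock estimates), a `manifest.json` with input hashes and parameters, a
#' human-readable `report.md` and a machine-readable `report.json`. A stage
#' failure aborts with a stage-tagged error; artifacts already written are
#' preserved.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#' @return invisibly, the report list.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  report <- list(seed = config$seed, stages = config$stages)
  artifacts <- character()
  runStage <- function(stage, fn) {
    if (!stage %in% config$stages) return(NULL)
    pipelineLog(stage, "running")
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sims <- runStage("simulate", function() {
    sc <- config$simConfig
    sc@seed <- stageSeed(config$seed, "radseq")
    rad <- simulateComplexRadseq(sc)

    qc <- SimConfig(tree = quartetTree(),
                    admixturePulses = data.frame(donor = "P3",
                                                 recipient = "P2",
                                                 gamma = config$gamma),
                    nLoci = sc@nLoci, locusLength = sc@locusLength,
                    seed = stageSeed(config$seed, "quartet"))
    quartet <- simulateQuartetLoci(qc)

    mc <- config$morphoConfig
    mc@seed <- stageSeed(config$seed, "morpho")
    morpho <- simulateMorphometrics(mc)

    mtTree <- config$mtdnaTreeMyr
    if (is.null(mtTree)) {
      mtTree <- config$simConfig@tree
      depth <- max(ape::node.depth.edgelength(mtTree)[
        seq_along(mtTree$tip.label)])
      mtTree$edge.length <- mtTree$edge.length / depth * 0.119
    }
    mtdna <- simulateMtdnaAlignment(mtTree, rate = config$clockConfig@rate,
                                    length = 20000L,
                                    seed = stageSeed(config$seed, "mtdna"))
    out <- list(quartet = quartet, radseq = rad, mtdna = mtdna,
                morpho = morpho)
    writeFixtureBundle(out[c("radseq", "mtdna", "morpho")],
                       file.path(outDir, "fixtures"))
    out
  })
  if (is.null(sims) && length(setdiff(config$stages, "simulate")))
    stop("analysis stages need the simulate stage to supply inputs")

  morphoRes <- runStage("morphometrics", function() {
    std <- sims$morpho$standardized
    assign <- assignTableToTypeSeries(std, sims$morpho$typeSeries)
    avg <- averageAssignmentProportions(assign)
    ranges <- summarizeGroupRanges(std, std$group)
    diag <- characterDiagnosability(ranges)
    writeCsvCanonical(assign, file.path(outDir, "assignment_table.csv"))
    writeCsvCanonical(ranges, file.path(outDir, "group_ranges.csv"))
    list(assignment = assign, average = as.list(avg), ranges = ranges,
         diagnosticCharacters = diag$diagnostic)
  })

  radRes <- runStage("rad_filtering", function() {
    obs <- simulateReadObservations(sims$radseq,
                                    seed = stageSeed(config$seed, "reads"))
    res <- runFilterCascade(sims$radseq$genotypes,
                            config = config$filterConfig,
                            observations = obs,
                            locusDepth = sims$radseq$locusDepth)
    writeGenotypeVcf(res$records, file.path(outDir, "filtered_loci.vcf"))
    list(nInputLoci = length(unique(
           variantRecords(sims$radseq$genotypes)$contig)),
         nRetainedLoci = length(res$retainedLoci))
  })

  introRes <- runStage("introgression", function() {
    q <- sims$quartet
    popmap <- setNames(rownames(q$alignment), rownames(q$alignment))
    res <- runAbbaBaba(q$alignment, popmap,
                       data.frame(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"),
                       guideTree = q$config@tree,
                       blockSize = config$blockSize,
                       locusIndex = q$locusIndex)
    writeCsvCanonical(quartetTable(res),
                      file.path(outDir, "quartet_table.csv"))
    list(table = quartetTable(res), trueGamma = q$gamma)
  })

  phyloRes <- runStage("phylo_clock", function() {
    aln <- sims$mtdna$alignment
    d <- pDistanceMatrix(aln)
    tr <- neighborJoining(d)
    ape::write.tree(tr, file.path(outDir, "nj_tree.nwk"))
    times <- strictClockTime(d, config$clockConfig)
    conc <- topologyConcordance(tr, sims$radseq$popTree)
    mono <- lapply(setNames(nm = unique(sims$radseq$popmap)), function(p) {
      tips <- intersect(tr$tip.label, names(
        sims$radseq$popmap)[sims$radseq$popmap == p])
      if (length(tips) > 0) checkMonophyly(tr, tips,
                                           outgroup = tr$tip.label[1])
      else NULL
    })
    list(clockTimes = times, concordance = conc,
         monophyly = Filter(Negate(is.null), mono))
  })

  report <- generateReport(list(seed = config$seed, stages = config$stages,
                                morphometrics = morphoRes,
                                rad_filtering = radRes,
                                introgression = introRes,
                                phylo_clock = phyloRes),
                           outDir)
  manifestFiles <- setdiff(list.files(outDir, recursive = TRUE),
                           "manifest.json")
  manifest <- list(
    seed = config$seed,
    parameters = list(
      gamma = config$gamma, blockSize = config$blockSize,
      minIndividualFraction = config$filterConfig@minIndividualFraction,
      minIndividualsHaplotyped = config$filterConfig@minIndividualsHaplotyped,
      minDepth = config$filterConfig@minDepth,
      clockRate = config$clockConfig@rate),
    files = lapply(sort(manifestFiles), function(f)
      list(path = f, md5 = unname(md5sum(file.path(outDir, f))))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Generate the summary report
#'
#' Assembles the Markdown and JSON summaries from stage artifacts: the
#' range tables, the assignment matrix with its Average row, the quartet
#' table, monophyly verdicts and clock times. A missing artifact marks its
#' section absent rather than failing.
#'
#' @param artifacts named list of stage results (NULL entries allowed);
#'   must contain `seed`.
#' @param outDir directory for `report.md` and `report.json` (`NULL` to
#'   skip writing).
#' @return the report list, invisibly when written.
#' @export
generateReport <- function(artifacts, outDir = NULL) {
  secNames <- c("morphometrics", "rad_filtering", "introgression",
                "phylo_clock")
  report <- list(seed = artifacts$seed,
                 stages = artifacts$stages %||% character(),
                 sections = list())
  md <- c("# Species-complex diagnostics report", "",
          paste0("Master seed: ", artifacts$seed %||% "unset"), "")
  for (s in secNames) {
    a <- artifacts[[s]]
    if (is.null(a)) {
      report$sections[[s]] <- list(status = "absent")
      md <- c(md, paste0("## ", s), "", "_Section absent._", "")
      next
    }
    sec <- list(status = "present")
    md <- c(md, paste0("## ", s), "")
    if (s == "morphometrics") {
      sec$average_assignment <- a$average
      sec$diagnostic_characters <- a$diagnosticCharacters
      sec$n_specimens <- nrow(a$assignment)
      md <- c(md, "Average assignment proportions:",
              paste0("- ", names(a$average), ": ",
                     unlist(a$average)), "",
              paste0("Diagnostic characters: ",
                     if (length(a$diagnosticCharacters))
                       paste(a$diagnosticCharacters, collapse = ", ")
                     else "none"), "")
    } else if (s == "rad_filtering") {
      sec$n_input_loci <- a$nInputLoci
      sec$n_retained_loci <- a$nRetainedLoci
      md <- c(md, paste0("Loci: ", a$nInputLoci, " in, ",
                         a$nRetainedLoci, " retained"), "")
    } else if (s == "introgression") {
      tb <- a$table
      sec$quartets <- lapply(seq_len(nrow(tb)), function(i) as.list(tb[i, ]))
      md <- c(md, paste0("Quartets tested: ", nrow(tb), "; significant: ",
                         sum(tb$significant, na.rm = TRUE)), "")
    } else if (s == "phylo_clock") {
      sec$monophyly <- lapply(a$monophyly, function(m)
        list(monophyletic = m$monophyletic, cladeSize = m$cladeSize))
      sec$rf = a$concordance$rf
      sec$max_clock_time_myr <- max(a$clockTimes)
      md <- c(md, paste0("RF distance to true tree: ", a$concordance$rf),
              paste0("Deepest clock TMRCA: ",
                     signif(max(a$clockTimes), 4), " Myr"), "")
    }
    report$sections[[s]] <- sec
  }
  if (!is.null(outDir)) {
    writeLines(md, file.path(outDir, "report.md"), sep = "\n")
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(report)
}

#' Validate a report JSON against the shipped schema
#'
#' A minimal structural validator: checks the required top-level keys and
#' section statuses laid out in `inst/extdata/report-schema.json`.
#'
#' @param path path to a `report.json`.
#' @param schemaPath schema file (defaults to the shipped schema).
#' @return `TRUE` if valid, otherwise a character vector of problems.
#' @export
validateReportJson <- function(path,
                               schemaPath = system.file(
                                 "extdata", "report-schema.json",
                                 package = "radelim")) {
  schema <- jsonlite::read_json(schemaPath)
  obj <- jsonlite::read_json(path)
  problems <- character()
  for (k in unlist(schema$required))
    if (is.null(obj[[k]])) problems <- c(problems, paste0("missing key: ", k))
  if (!is.null(obj$sections)) {
    for (s in names(obj$sections)) {
      st <- obj$sections[[s]]$status
      if (is.null(st) || !st %in% c("present", "absent"))
        problems <- c(problems, paste0("section without valid status: ", s))
    }
  }
  if (length(problems)) problems else TRUE
}
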