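## Morphometric standardization, diagnosability and type-series assignment.
##
## Conventions. Published range tables for this complex report characters as
## the number of times a measurement fits into a reference length ("body
## depth 5.2" means SL / body depth = 5.2), which is why values for
## characters smaller than SL exceed 1. standardizeMeasurements() therefore
## divides the reference length by the raw measurement; applying it twice is
## the identity, which is also how raw values are recovered. Meristic counts
## are never standardized.

normalizeCharNames <- function(x) {
  gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
}

#' Standardize measurements by a reference length
#'
#' Converts raw measurements (mm) to the "times-into" scale used by the
#' published range tables: standardized value = reference length / raw
#' measurement. Each character's reference length (standard length, head
#' length or body depth) is given by `referenceMap`. Because the transform
#' is an involution, calling it twice recovers the raw values. Meristic
#' columns named in `meristics` pass through unchanged.
#'
#' @param specimens data.frame with one row per specimen, containing the
#'   reference-length columns `standard_length`, and (if used by
#'   `referenceMap`) `head_length` and `body_depth`, in mm, plus raw
#'   measurement columns.
#' @param referenceMap named character vector mapping measurement column ->
#'   one of `"SL"`, `"HL"`, `"BD"`. Names are matched case-insensitively
#'   after whitespace normalization.
#' @param meristics character vector of meristic (count) columns to pass
#'   through untouched.
#' @return `specimens` with the mapped measurement columns standardized.
#' @examples
#' sp <- data.frame(standard_length = 100, body_depth = 20)
#' standardizeMeasurements(sp, c(body_depth = "SL"))$body_depth  # 5
#' @export
standardizeMeasurements <- function(specimens, referenceMap,
                                    meristics = character()) {
  stopifnot(is.data.frame(specimens), length(referenceMap) > 0)
  refCols <- c(SL = "standard_length", HL = "head_length", BD = "body_depth")
  bad <- setdiff(unique(referenceMap), names(refCols))
  if (length(bad))
    stop("unknown reference tag(s): ", paste(bad, collapse = ", "),
         " (expected SL, HL or BD)")
  colKey <- setNames(names(specimens), normalizeCharNames(names(specimens)))
  out <- specimens
  for (i in seq_along(referenceMap)) {
    chr <- normalizeCharNames(names(referenceMap)[i])
    if (chr %in% normalizeCharNames(meristics)) next
    col <- colKey[chr]
    if (is.na(col)) stop("measurement column not found: ", names(referenceMap)[i])
    refCol <- refCols[referenceMap[i]]
    if (!refCol %in% names(specimens))
      stop("reference length column missing: ", refCol)
    refLen <- specimens[[refCol]]
    meas <- specimens[[col]]
    nonpos <- !is.na(meas) & meas <= 0
    if (any(nonpos) || any(!is.na(refLen) & refLen <= 0))
      stop("zero or negative measurement in column ", col)
    out[[col]] <- refLen / meas
  }
  out
}

#' Test for allometric growth
#'
#' Ordinary least-squares regression of each raw character on standard
#' length. Proportional (isometric) scaling shows as a significant slope
#' with an intercept indistinguishable from zero; `interceptP` is the
#' evidence against proportionality.
#'
#' @param specimens data.frame with `standard_length` and raw measurement
#'   columns.
#' @param characters measurement columns to test (default: all numeric
#'   columns other than the reference lengths and an id column).
#' @return data.frame with one row per character: `slope`, `intercept`,
#'   `slopeP`, `interceptP`, `r2`, `residualSd`.
#' @examples
#' sp <- data.frame(standard_length = c(80, 100, 120, 140, 160))
#' sp$body_depth <- 0.2 * sp$standard_length
#' testAllometry(sp, "body_depth")
#' @export
testAllometry <- function(specimens, characters = NULL) {
  if (nrow(specimens) < 3L) stop("need at least 3 specimens")
  sl <- specimens$standard_length
  if (is.null(sl)) stop("specimens must have a standard_length column")
  if (length(unique(sl)) < 2L) stop("standard length is constant (degenerate)")
  if (is.null(characters)) {
    skip <- c("standard_length", "head_length", "body_depth", "specimen_id")
    characters <- setdiff(names(specimens)[vapply(specimens, is.numeric,
                                                  logical(1))], skip)
  }
  res <- lapply(characters, function(ch) {
    fit <- lm(specimens[[ch]] ~ sl)
    sm <- summary(fit)
    co <- sm$coefficients
    data.frame(character = ch,
               slope = co[2, 1], intercept = co[1, 1],
               slopeP = co[2, 4], interceptP = co[1, 4],
               r2 = sm$r.squared, residualSd = sm$sigma)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Test preservation effects between type and fresh material
#'
#' Two-sample comparison of a standardized variable between preserved type
#' specimens and fresh specimens. An F-test of variance equality at `alpha`
#' chooses between the pooled-variance and Welch unequal-variance t-test;
#' both the F and t results are reported.
#'
#' @param typeValues,freshValues numeric vectors (each length >= 2).
#' @param alpha significance level for the variance pre-test (default 0.05).
#' @return list with `F`, `Fp`, `t`, `tp` and `variant`
#'   (`"pooled"` or `"unequal-variance"`).
#' @examples
#' testPreservationEffects(c(5.2, 5.3, 5.4), c(5.1, 5.35, 5.6))
#' @export
testPreservationEffects <- function(typeValues, freshValues, alpha = 0.05) {
  typeValues <- typeValues[!is.na(typeValues)]
  freshValues <- freshValues[!is.na(freshValues)]
  if (length(typeValues) < 2L || length(freshValues) < 2L)
    stop("both samples must have at least 2 values")
  if (stats::var(typeValues) == 0 && stats::var(freshValues) == 0) {
    if (isTRUE(all.equal(mean(typeValues), mean(freshValues))))
      return(list(F = NA_real_, Fp = NA_real_, t = 0, tp = 1,
                  variant = "degenerate"))
    stop("zero variance in both samples")
  }
  ft <- var.test(typeValues, freshValues)
  unequal <- ft$p.value < alpha
  tt <- t.test(typeValues, freshValues, var.equal = !unequal)
  list(F = unname(ft$statistic), Fp = ft$p.value,
       t = unname(tt$statistic), tp = tt$p.value,
       variant = if (unequal) "unequal-variance" else "pooled")
}

#' Summarize per-group character ranges
#'
#' Inclusive \[min, max\] of every character within every group — the
#' operation behind published range tables for type series, fresh material
#' and phylogenetic clades.
#'
#' @param specimens data.frame of (standardized) values.
#' @param grouping factor/character vector, one group label per row.
#' @param characters columns to summarize (default: all numeric columns
#'   except reference lengths and ids).
#' @return data.frame with columns `group`, `character`, `min`, `max`, `n`.
#' @examples
#' sp <- data.frame(ll = c(89, 92, 60, 71))
#' summarizeGroupRanges(sp, c("a", "a", "b", "b"), "ll")
#' @export
summarizeGroupRanges <- function(specimens, grouping, characters = NULL) {
  stopifnot(nrow(specimens) == length(grouping))
  if (any(is.na(grouping))) stop("every specimen needs a group")
  if (is.null(characters)) {
    skip <- c("standard_length", "head_length", "body_depth", "specimen_id")
    characters <- setdiff(names(specimens)[vapply(specimens, is.numeric,
                                                  logical(1))], skip)
  }
  grps <- unique(as.character(grouping))
  out <- do.call(rbind, lapply(grps, function(g) {
    sub <- specimens[grouping == g, , drop = FALSE]
    do.call(rbind, lapply(characters, function(ch) {
      v <- sub[[ch]][!is.na(sub[[ch]])]
      data.frame(group = g, character = ch,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_,
                 n = length(v))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Character diagnosability between groups
#'
#' A character is diagnostic for a pair of groups when their value ranges
#' are disjoint; otherwise the overlap length is reported. The returned
#' `diagnostic` vector lists characters whose ranges are disjoint for
#' *every* group pair — the "single diagnostic character" a taxonomy would
#' need.
#'
#' @param ranges data.frame as returned by [summarizeGroupRanges()]
#'   (columns `group`, `character`, `min`, `max`).
#' @return list with `pairs` (per character x group pair: `diagnostic`
#'   flag and `overlap` length) and `diagnostic` (character vector).
#' @examples
#' r <- data.frame(group = c("robusta", "intermedia"),
#'                 character = "lateral_line_scales",
#'                 min = c(89, 59), max = c(92, 71))
#' characterDiagnosability(r)$pairs
#' @export
characterDiagnosability <- function(ranges) {
  grps <- unique(ranges$group)
  if (length(grps) < 2L) stop("need at least 2 groups")
  chars <- unique(ranges$character)
  rows <- list()
  for (ch in chars) {
    sub <- ranges[ranges$character == ch, ]
    for (i in seq_len(length(grps) - 1L)) for (j in seq(i + 1L, length(grps))) {
      a <- sub[sub$group == grps[i], ]; b <- sub[sub$group == grps[j], ]
      if (!nrow(a) || !nrow(b) || is.na(a$min[1]) || is.na(b$min[1])) next
      disjoint <- a$max[1] < b$min[1] || b$max[1] < a$min[1]
      ov <- if (disjoint) 0 else
        intervalIntersection(a$min[1], a$max[1], b$min[1], b$max[1])
      rows[[length(rows) + 1L]] <-
        data.frame(character = ch, group1 = grps[i], group2 = grps[j],
                   diagnostic = disjoint, overlap = ov)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character = character(), group1 = character(),
               group2 = character(), diagnostic = logical(),
               overlap = numeric())
  diag <- vapply(chars, function(ch) {
    sub <- pairs[pairs$character == ch, ]
    nrow(sub) > 0 && all(sub$diagnostic)
  }, logical(1))
  list(pairs = pairs, diagnostic = chars[diag])
}

#' Assign a specimen to type series by character consistency
#'
#' Scores a standardized specimen against each type series: the proportion
#' of the scored variables whose value falls inside that series' inclusive
#' \[min, max\] interval, plus the proportion consistent with *no* series
#' (unclassified). Because ranges overlap, proportions across series may sum
#' to more than 1. Proportions are rounded to 2 decimals, matching the
#' printed assignment tables. Variables with a missing value are skipped
#' with a warning and the denominator reduced.
#'
#' @param specimen named numeric vector (or 1-row data.frame) of
#'   standardized values; names are matched to range characters
#'   case-insensitively after whitespace normalization.
#' @param ranges list of [TypeSeriesRange] objects.
#' @param variables character vector of variables to score (default: every
#'   character present in all series' range tables). The published
#'   comparison used 22 variables shared between the type and fresh tables.
#' @param specimenId identifier carried into the result.
#' @return one-row data.frame: `specimen_id`, one proportion column per
#'   series, `unclassified`, `n_variables`.
#' @examples
#' rng <- list(TypeSeriesRange("robusta",
#'   data.frame(character = c("body_depth", "head_length"),
#'              min = c(5.2, 3.5), max = c(5.4, 3.6)), 2L))
#' assignToTypeSeries(c(body_depth = 5.3, head_length = 3.55), rng)
#' @export
assignToTypeSeries <- function(specimen, ranges, variables = NULL,
                               specimenId = "specimen") {
  if (is.data.frame(specimen)) {
    stopifnot(nrow(specimen) == 1L)
    specimen <- unlist(specimen[vapply(specimen, is.numeric, logical(1))])
  }
  names(specimen) <- normalizeCharNames(names(specimen))
  rangeChars <- lapply(ranges, function(r) {
    rr <- seriesRanges(r)
    rr$character <- normalizeCharNames(rr$character)
    rr
  })
  if (is.null(variables)) {
    variables <- Reduce(intersect, lapply(rangeChars, `[[`, "character"))
  } else {
    variables <- normalizeCharNames(variables)
    known <- unique(unlist(lapply(rangeChars, `[[`, "character")))
    if (length(setdiff(variables, known)))
      stop("variables not present in range tables: ",
           paste(setdiff(variables, known), collapse = ", "))
  }
  vals <- specimen[variables]
  missing <- is.na(vals)
  if (any(missing)) {
    warning("skipping variable(s) with missing value: ",
            paste(variables[missing], collapse = ", "))
    variables <- variables[!missing]
    vals <- vals[!missing]
  }
  n <- length(variables)
  if (n == 0L) stop("no variables left to score")
  inside <- vapply(rangeChars, function(rr) {
    idx <- match(variables, rr$character)
    inInterval(vals, rr$min[idx], rr$max[idx]) & !is.na(idx)
  }, logical(n))
  inside <- matrix(inside, nrow = n)  # n == 1 safety
  props <- colSums(inside, na.rm = TRUE) / n
  unclassified <- sum(rowSums(inside, na.rm = TRUE) == 0) / n
  out <- data.frame(specimen_id = specimenId)
  for (i in seq_along(ranges))
    out[[seriesName(ranges[[i]])]] <- round(props[i], 2)
  out$unclassified <- round(unclassified, 2)
  out$n_variables <- n
  out
}

#' Assign a table of specimens to type series
#'
#' Vectorized [assignToTypeSeries()] over the rows of a standardized
#' specimen table, producing the analogue of a published assignment matrix.
#'
#' @param specimens data.frame of standardized values, optionally with a
#'   `specimen_id` column.
#' @inheritParams assignToTypeSeries
#' @return data.frame with one row per specimen.
#' @export
assignTableToTypeSeries <- function(specimens, ranges, variables = NULL) {
  ids <- specimens$specimen_id %||% paste0("spec_", seq_len(nrow(specimens)))
  num <- specimens[vapply(specimens, is.numeric, logical(1))]
  num$specimen_id <- NULL
  out <- do.call(rbind, lapply(seq_len(nrow(specimens)), function(i) {
    assignToTypeSeries(unlist(num[i, , drop = FALSE]), ranges,
                       variables = variables, specimenId = as.character(ids[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Average assignment proportions across specimens
#'
#' The "Average" column of an assignment table: the arithmetic mean of the
#' 2-decimal per-specimen proportions, itself rounded to 2 decimals — the
#' same arithmetic as the published table, which averages printed values.
#'
#' @param results data.frame from [assignTableToTypeSeries()] (or any
#'   data.frame whose numeric columns are per-specimen proportions), or a
#'   numeric matrix with one column per series.
#' @return named numeric vector of per-series means (2 dp).
#' @examples
#' averageAssignmentProportions(data.frame(robusta = c(0.22, 0.35, 0.30)))
#' @export
averageAssignmentProportions <- function(results) {
  if (is.matrix(results)) results <- as.data.frame(results)
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) stop("empty input")
  num <- results[vapply(results, is.numeric, logical(1))]
  num$n_variables <- NULL
  if (!ncol(num)) stop("no proportion columns found")
  vapply(num, function(p) round(mean(round(p, 2)), 2), numeric(1))
}

#' Morphological overlap between phylogenetic clades
#'
#' Builds per-clade character ranges and computes, for every character and
#' clade pair, the overlap fraction of the two intervals (intersection
#' length / union length; identical ranges give 1, disjoint ranges 0,
#' coincident point ranges 1). The verdict lists characters diagnostic
#' (disjoint) between at least one clade pair; an empty verdict is the
#' "nearly 100% overlap" outcome.
#'
#' @param specimens data.frame of standardized values.
#' @param cladeAssignment clade label per specimen (no NAs).
#' @param characters columns to compare (default as in
#'   [summarizeGroupRanges()]).
#' @return list with `overlap` (per character x pair data.frame),
#'   `diagnostic` (characters disjoint for >= 1 pair), `medianOverlap`,
#'   and `singletonClades` (clades with one specimen, whose degenerate
#'   ranges are flagged).
#' @export
cladeMorphologyOverlap <- function(specimens, cladeAssignment,
                                   characters = NULL) {
  if (any(is.na(cladeAssignment))) stop("every specimen must be assigned a clade")
  ranges <- summarizeGroupRanges(specimens, cladeAssignment, characters)
  singles <- names(which(table(cladeAssignment) == 1L))
  if (length(singles))
    warning("singleton clade(s) with degenerate ranges: ",
            paste(singles, collapse = ", "))
  grps <- unique(ranges$group)
  rows <- list()
  for (ch in unique(ranges$character)) {
    sub <- ranges[ranges$character == ch, ]
    for (i in seq_len(length(grps) - 1L)) for (j in seq(i + 1L, length(grps))) {
      a <- sub[sub$group == grps[i], ]; b <- sub[sub$group == grps[j], ]
      if (!nrow(a) || !nrow(b) || is.na(a$min[1]) || is.na(b$min[1])) next
      inter <- intervalIntersection(a$min[1], a$max[1], b$min[1], b$max[1])
      uni <- max(a$max[1], b$max[1]) - min(a$min[1], b$min[1])
      frac <- if (uni == 0) {
        ## two point ranges: 1 when coincident, 0 otherwise
        as.numeric(isTRUE(all.equal(a$min[1], b$min[1])))
      } else if (inter == 0 &&
                 (a$max[1] < b$min[1] || b$max[1] < a$min[1])) 0
      else inter / uni
      disjoint <- a$max[1] < b$min[1] || b$max[1] < a$min[1]
      rows[[length(rows) + 1L]] <-
        data.frame(character = ch, clade1 = grps[i], clade2 = grps[j],
                   overlap = frac, diagnostic = disjoint)
    }
  }
  overlap <- do.call(rbind, rows)
  list(overlap = overlap,
       diagnostic = unique(overlap$character[overlap$diagnostic]),
       medianOverlap = stats::median(overlap$overlap),
       singletonClades = singles)
}
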