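test_that("standardization follows the times-into convention and inverts", {
  sp <- data.frame(standard_length = 100, body_depth = 20)
  expect_equal(standardizeMeasurements(sp, c(body_depth = "SL"))$body_depth, 5)

  ## a raw head length of 28.57 mm at SL 100 round-trips to the printed 3.5
  sp2 <- data.frame(standard_length = 100, head_length = 28.57,
                    hl_char = 10)
  std <- standardizeMeasurements(sp2, c(head_length = "SL"))
  expect_equal(std$head_length, 3.5, tolerance = 1e-4)

  ## involution: standardizing twice recovers raw values
  set.seed(1)
  tab <- data.frame(standard_length = runif(20, 80, 200),
                    head_length = runif(20, 20, 60),
                    body_depth = runif(20, 15, 50),
                    snout = runif(20, 5, 15), eye = runif(20, 3, 9))
  ## reference columns themselves stay raw, so the transform inverts
  map <- c(snout = "HL", eye = "HL", body_depth = "SL")
  std <- standardizeMeasurements(tab, map)
  back <- standardizeMeasurements(std, map)
  expect_equal(back$snout, tab$snout, tolerance = 1e-9)
  expect_equal(back$body_depth, tab$body_depth, tolerance = 1e-9)
  ## a reference length standardized against another reference also inverts
  map2 <- c(head_length = "SL")
  expect_equal(standardizeMeasurements(standardizeMeasurements(tab, map2),
                                       map2)$head_length,
               tab$head_length, tolerance = 1e-9)

  expect_error(standardizeMeasurements(tab, c(snout = "XX")), "unknown")
  tab$snout[1] <- -1
  expect_error(standardizeMeasurements(tab, map), "negative")
})

test_that("meristics pass through standardization unchanged", {
  sp <- data.frame(standard_length = 120, body_depth = 30,
                   lateral_line_scales = 88L)
  std <- standardizeMeasurements(
    sp, c(body_depth = "SL", lateral_line_scales = "SL"),
    meristics = "lateral_line_scales")
  expect_identical(std$lateral_line_scales, 88L)
  expect_equal(std$body_depth, 4)
})

test_that("allometry regression matches the closed-form OLS solution", {
  sp <- data.frame(standard_length = c(80, 100, 120, 140, 160))
  sp$depth <- 0.2 * sp$standard_length
  fit <- suppressWarnings(testAllometry(sp, "depth"))  # perfect-fit note
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$residualSd, 0, tolerance = 1e-10)

  ## arbitrary 5-point table against the normal equations
  x <- c(81, 95, 110, 132, 150); y <- c(17.2, 20.1, 21.9, 26.0, 30.3)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  slopeOracle <- sxy / sxx
  interceptOracle <- mean(y) - slopeOracle * mean(x)
  fit2 <- testAllometry(data.frame(standard_length = x, ch = y), "ch")
  expect_equal(fit2$slope, slopeOracle, tolerance = 1e-12)
  expect_equal(fit2$intercept, interceptOracle, tolerance = 1e-12)

  expect_error(testAllometry(data.frame(standard_length = c(1, 2),
                                        ch = c(1, 2))), "3 specimens")
  expect_error(testAllometry(data.frame(standard_length = rep(100, 5),
                                        ch = 1:5)), "constant")
})

test_that("preservation-effect test picks the t-test variant by F-test", {
  ## identical samples: no difference at all
  r <- testPreservationEffects(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$tp, 1)

  ## hand-computed pooled two-sample t
  x <- c(10, 12, 14); y <- c(11, 15, 19, 21)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  tOracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  r2 <- testPreservationEffects(x, y)
  if (r2$variant == "pooled")
    expect_equal(r2$t, tOracle, tolerance = 1e-12)
  expect_equal(r2$F, var(x) / var(y), tolerance = 1e-12)

  ## variance ratio 100 with n = 20 each: F far beyond the critical value
  set.seed(7)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 0, 10)
  fRatio <- var(a) / var(b)
  expect_true(fRatio < qf(0.025, 19, 19))  # oracle: outside acceptance band
  r3 <- testPreservationEffects(a, b)
  expect_identical(r3$variant, "unequal-variance")

  expect_error(testPreservationEffects(c(1, 1), c(2, 2)), "zero variance")
})

test_that("group ranges are inclusive min/max and never shrink", {
  one <- summarizeGroupRanges(data.frame(ch = 5.5), "g", "ch")
  expect_equal(one$min, one$max)

  set.seed(42)
  tab <- data.frame(a = rnorm(30, 10), b = runif(30, 0, 5))
  grp <- sample(c("x", "y", "z"), 30, replace = TRUE)
  rg <- summarizeGroupRanges(tab, grp)
  for (g in unique(grp)) for (ch in c("a", "b")) {
    v <- tab[[ch]][grp == g]
    row <- rg[rg$group == g & rg$character == ch, ]
    expect_equal(row$min, min(v))  # brute-force scan
    expect_equal(row$max, max(v))
  }

  ## adding a specimen never shrinks any range
  for (i in 1:5) {
    tab2 <- rbind(tab, data.frame(a = rnorm(1, 10), b = runif(1, 0, 5)))
    grp2 <- c(grp, "x")
    rg2 <- summarizeGroupRanges(tab2, grp2)
    m <- merge(rg, rg2, by = c("group", "character"))
    expect_true(all(m$min.y <= m$min.x + 1e-12))
    expect_true(all(m$max.y >= m$max.x - 1e-12))
    tab <- tab2; grp <- grp2; rg <- rg2
  }
})

test_that("diagnosability flags disjoint ranges and measures overlap", {
  ranges <- read.csv(system.file("extdata", "gila-range-tables.csv",
                                 package = "radelim"))
  ## type series: lateral-line scales separate robusta from intermedia
  typ <- ranges[ranges$material == "type" &
                ranges$group %in% c("robusta", "intermedia"), ]
  dTyp <- characterDiagnosability(typ)
  llTyp <- dTyp$pairs[dTyp$pairs$character == "lateral_line_scales", ]
  expect_true(llTyp$diagnostic)
  expect_true("lateral_line_scales" %in% dTyp$diagnostic)

  ## fresh material: the same character overlaps
  fre <- ranges[ranges$material == "fresh" &
                ranges$group %in% c("robusta", "intermedia"), ]
  dFre <- characterDiagnosability(fre)
  llFre <- dFre$pairs[dFre$pairs$character == "lateral_line_scales", ]
  expect_false(llFre$diagnostic)
  expect_gt(llFre$overlap, 0)

  ## identical intervals overlap over their full width
  same <- data.frame(group = c("a", "b"), character = "ch",
                     min = c(2, 2), max = c(7, 7))
  dSame <- characterDiagnosability(same)
  expect_false(dSame$pairs$diagnostic)
  expect_equal(dSame$pairs$overlap, 5)
})

test_that("type-series assignment equals brute-force interval membership", {
  rob <- TypeSeriesRange("robusta", data.frame(
    character = c("body_depth", "head_length", "lateral_line_scales"),
    min = c(5.2, 3.5, 89), max = c(5.4, 3.6, 92)), 2L)
  int <- TypeSeriesRange("intermedia", data.frame(
    character = c("body_depth", "head_length", "lateral_line_scales"),
    min = c(3.7, 3.1, 59), max = c(4.0, 3.4, 71)), 4L)

  ## toy specimen consistent with every robusta interval, no intermedia one
  r <- assignToTypeSeries(c(body_depth = 5.3, head_length = 3.5,
                            lateral_line_scales = 90), list(rob, int))
  expect_equal(r$robusta, 1.00)
  expect_equal(r$intermedia, 0.00)
  expect_equal(r$unclassified, 0.00)

  ## interval midpoints give 1.00 for that series
  mid <- setNames((rob@ranges$min + rob@ranges$max) / 2, rob@ranges$character)
  expect_equal(assignToTypeSeries(mid, list(rob, int))$robusta, 1)

  ## outside every interval: fully unclassified
  far <- c(body_depth = 99, head_length = 99, lateral_line_scales = 1)
  rFar <- assignToTypeSeries(far, list(rob, int))
  expect_equal(rFar$unclassified, 1.00)
  expect_equal(rFar$robusta, 0.00)

  ## random specimens agree with the brute-force scan
  set.seed(11)
  vars <- c("body_depth", "head_length", "lateral_line_scales")
  for (i in 1:25) {
    vals <- setNames(c(runif(2, 3, 6), runif(1, 50, 100)), vars)
    got <- assignToTypeSeries(vals, list(rob, int), vars)
    want <- bfAssign(vals, list(rob, int), vars)
    expect_equal(c(got$robusta, got$intermedia), want$props)
    expect_equal(got$unclassified, want$unclassified)
    ## invariant: unclassified <= 1 - max series proportion
    expect_lte(got$unclassified, 1 - max(got$robusta, got$intermedia) + 1e-9)
  }
})

test_that("assignment denominators shrink consistently", {
  rng <- list(TypeSeriesRange("s1", data.frame(
    character = c("a", "b", "c", "d"), min = c(0, 0, 0, 0),
    max = c(1, 1, 1, 1)), 3L))
  vals <- c(a = 0.5, b = 2, c = 0.5, d = 2)
  full <- assignToTypeSeries(vals, rng, c("a", "b", "c", "d"))
  expect_equal(full$s1, 0.5)
  ## restricting to a subset scores exactly that subset
  sub <- assignToTypeSeries(vals, rng, c("a", "b"))
  expect_equal(sub$s1, 0.5)
  expect_equal(sub$n_variables, 2L)

  ## missing value: warn, skip, reduce the denominator
  vals2 <- c(a = 0.5, b = NA, c = 0.5, d = 2)
  expect_warning(res <- assignToTypeSeries(vals2, rng,
                                           c("a", "b", "c", "d")),
                 "missing")
  expect_equal(res$n_variables, 3L)
  expect_equal(res$s1, 0.67)
})

test_that("average assignment proportions use printed-table arithmetic", {
  expect_equal(unname(averageAssignmentProportions(
    data.frame(s = c(0.3, 0.3, 0.3)))), 0.3)
  ## mean over 2-dp rounded inputs, itself reported at 2 dp: rounding the
  ## inputs first is visible (unrounded mean 0.224 would print 0.22)
  expect_equal(unname(averageAssignmentProportions(
    data.frame(s = c(0.226, 0.226, 0.221)))), 0.23)
  expect_error(averageAssignmentProportions(data.frame(s = numeric())),
               "empty")
})

test_that("clade overlap is Jaccard on ranges with degenerate cases", {
  sp <- data.frame(ch1 = c(1, 3, 1, 3), ch2 = c(0, 1, 10, 11))
  res <- cladeMorphologyOverlap(sp, c("A", "A", "B", "B"))
  ov1 <- res$overlap[res$overlap$character == "ch1", ]
  expect_equal(ov1$overlap, 1)           # identical ranges
  ov2 <- res$overlap[res$overlap$character == "ch2", ]
  expect_equal(ov2$overlap, 0)           # disjoint
  expect_true(ov2$diagnostic)
  expect_identical(res$diagnostic, "ch2")

  expect_warning(
    cladeMorphologyOverlap(data.frame(ch = c(1, 2, 3)),
                           c("A", "B", "B")), "singleton")

  ## a random split of one homogeneous population overlaps heavily
  set.seed(5)
  pop <- data.frame(a = rnorm(40, 10, 2), b = rnorm(40, 5, 1))
  res2 <- cladeMorphologyOverlap(pop, sample(c("c1", "c2"), 40, TRUE))
  expect_gt(res2$medianOverlap, 0.5)
  expect_length(res2$diagnostic, 0)
})
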