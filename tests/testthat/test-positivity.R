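test_that("control thresholds are the stated order statistic", {
  # degenerate control
  expect_equal(controlThreshold(rep(20, 600)), 20)

  # sort-and-index oracle at percentile 99.5
  set.seed(5)
  x <- rlnorm(1000, log(20), 0.4)
  expect_equal(controlThreshold(x, percentile = 0.995),
               sort(x)[ceiling(0.995 * 1000)])

  expect_error(controlThreshold(rnorm(100)), "control insufficiency")
})

test_that("fixed-threshold gates cut at exactly 40 and 100 FU", {
  cs <- smallSample(nEvents = 1000, seed = 3)
  ev <- cs$tubes[["full"]]
  g40 <- buildStrategyGate(9999, "fixed40", ev, marker = "Ki-67")
  g100 <- buildStrategyGate(1, "fixed100", ev, marker = "Ki-67")
  expect_equal(g40@params$cutoff, 40)
  expect_equal(g100@params$cutoff, 100)
  probe <- matrix(c(39.999, 40.001, 99.999, 100.001), 4, 1,
                  dimnames = list(NULL, "Ki-67-FITC"))
  expect_equal(applyGate(g40, probe), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(applyGate(g100, probe), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("a flat control collapses the polygon gate onto the rectangle", {
  set.seed(9)
  n <- 2000
  ev <- EventTable(cbind("Ki-67-FITC" = rlnorm(n, log(50), 1),
                         "SSC-INT" = runif(n, 50, 800)))
  ctrl <- rep(20, 1000)                    # constant control, no SSC trend
  ctrlSsc <- runif(1000, 50, 800)
  thr <- controlThreshold(ctrl)
  poly <- buildStrategyGate(thr, "polygon", ev, controlValues = ctrl,
                            controlSsc = ctrlSsc, marker = "Ki-67")
  rect <- buildStrategyGate(thr, "rectangle", ev, marker = "Ki-67")
  expect_identical(applyGate(poly, ev), applyGate(rect, ev))
})

test_that("a rising control baseline separates polygon from rectangle", {
  set.seed(13)
  nC <- 1600
  ctrlSsc <- runif(nC, 0, 800)
  ctrl <- 10 + 30 * ctrlSsc / 800          # baseline rises 30 FU across SSC
  popSsc <- runif(400, 0, 800)
  ev <- EventTable(cbind("Ki-67-FITC" = rep(30, 400), "SSC-INT" = popSsc))
  thr <- controlThreshold(ctrl)
  poly <- buildStrategyGate(thr, "polygon", ev, controlValues = ctrl,
                            controlSsc = ctrlSsc, marker = "Ki-67")
  rect <- buildStrategyGate(thr, "rectangle", ev, marker = "Ki-67")

  # independent oracle: recompute the per-bin boundaries from scratch with
  # sort-and-index percentiles over the same equal-count SSC bins
  edges <- unique(quantile(popSsc, seq(0, 1, length.out = 9), type = 7))
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  bin <- findInterval(ctrlSsc, edges, all.inside = TRUE)
  cutoffs <- vapply(seq_len(length(edges) - 1), function(b) {
    v <- sort(ctrl[bin == b])
    v[ceiling(0.995 * length(v))]
  }, numeric(1))
  evBin <- findInterval(popSsc, edges, all.inside = TRUE)
  expPoly <- rep(30, 400) > cutoffs[evBin]
  expect_equal(applyGate(poly, ev), expPoly)

  # events at 30 FU: above the low-SSC boundary, below the global cutoff
  pp <- applyGate(poly, ev)
  rr <- applyGate(rect, ev)
  expect_false(any(rr))                    # global cutoff ~ 40 FU
  expect_gt(sum(pp & !rr), 0)              # polygon recovers dim positives
})

test_that("positive fractions are exact counts with boundary QC flags", {
  mk <- "Ki-67-FITC"
  vals <- c(rep(50, 1234), rep(10, 8766))
  ev <- EventTable(cbind(matrix(vals, ncol = 1,
                                dimnames = list(NULL, mk)),
                         "SSC-INT" = 100))
  g <- thresholdGate(mk, 40)
  r <- positiveFraction(ev, "Ki-67", g)
  expect_identical(r$positive, 1234L)
  expect_equal(r$fraction, 0.1234)
  expect_identical(r$qc, "")

  # all below threshold
  evLow <- EventTable(cbind(matrix(rep(10, 500), ncol = 1,
                                   dimnames = list(NULL, mk)),
                            "SSC-INT" = 100))
  rLow <- positiveFraction(evLow, "Ki-67", g)
  expect_equal(rLow$fraction, 0)
  expect_match(rLow$qc, "insufficient_positives")

  # the 100-positive-cell rule is enforced exactly at the boundary
  mkEv <- function(npos) EventTable(cbind(
    matrix(c(rep(50, npos), rep(10, 1000 - npos)), ncol = 1,
           dimnames = list(NULL, mk)), "SSC-INT" = 100))
  expect_match(positiveFraction(mkEv(99), "Ki-67", g)$qc,
               "insufficient_positives")
  expect_identical(positiveFraction(mkEv(100), "Ki-67", g)$qc, "")

  # empty population: missing fraction, never zero
  ev0 <- EventTable(matrix(numeric(0), 0, 2,
                           dimnames = list(NULL, c(mk, "SSC-INT"))))
  r0 <- positiveFraction(ev0, "Ki-67", g)
  expect_true(is.na(r0$fraction))
  expect_identical(r0$qc, "insufficient_population")
})

test_that("raising a cutoff never increases the positive fraction", {
  cs <- smallSample(nEvents = 5000, seed = 17)
  ev <- cs$tubes[["full"]]
  fr <- vapply(c(20, 40, 60, 100, 200), function(cut) {
    sum(applyGate(thresholdGate("Ki-67-FITC", cut), ev)) / nEvents(ev)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("a full sample yields 32 indices with nested-threshold order", {
  cs <- smallSample(nEvents = 30000, seed = 19)
  ev <- cs$tubes[["full"]]
  g <- gateSample(ev)
  idx <- computeAllIndices(ev, g$masks)
  expect_equal(nrow(idx), 32L)
  expect_equal(sort(unique(idx$strategy)),
               sort(c("polygon", "rectangle", "fixed40", "fixed100")))
  wide <- reshape(idx[, c("population", "marker", "strategy", "fraction")],
                  idvar = c("population", "marker"),
                  timevar = "strategy", direction = "wide")
  expect_true(all(wide$fraction.fixed100 <= wide$fraction.fixed40 + 1e-12))
})

test_that("control-anchored strategies recover the latent blast Ki-67 index", {
  tpf <- cbind("Ki-67" = c(blast = 0.30, erythroid = 0.3, myeloid = 0.25,
                           monocytic = 0.2, lymphoid = 0.05,
                           eosinophil = 0.05, platelet = 0, debris = 0),
               "Bcl-2" = c(0.4, 0.1, 0.2, 0.35, 0.4, 0.1, 0, 0))
  pr <- caseProfile("rec", targetFractions = c(blast = 15, erythroid = 15,
                                               myeloid = 40, monocytic = 4,
                                               debris = 3),
                    truePositiveFractions = tpf, nEvents = 80000L)
  cs <- generateCase(pr, seed = 13, tubes = "full")
  ev <- cs$tubes[["full"]]
  g <- gateSample(ev)
  expect_gt(sum(maskVector(g$masks$blast)), 10000)  # >= 10,000 blasts
  idx <- computeAllIndices(ev, g$masks)
  for (st in c("polygon", "rectangle")) {
    got <- idx$fraction[idx$population == "blast" & idx$marker == "Ki-67" &
                          idx$strategy == st]
    expect_lt(abs(got - 0.30), 0.02, label = st)
  }
})

test_that("isotype controls drive thresholds when provided", {
  pr <- smallProfile(20000)
  cs <- generateCase(pr, seed = 23, tubes = c("full"))
  ev <- cs$tubes[["full"]]          # carries IgG1 channels
  g <- gateSample(ev)
  idxIso <- computeAllIndices(ev, g$masks, controlSource = "isotype")
  idxInt <- computeAllIndices(ev, g$masks,
                              controlSource = "internal_negative")
  expect_equal(nrow(idxIso), 32L)
  # both control routes land near the latent truth for the myeloid Ki-67
  truthKi <- myeloFlow:::.DEFAULT_TPF$non_malignant["myeloid", "Ki-67"]
  for (idx in list(idxIso, idxInt)) {
    got <- idx$fraction[idx$population == "myeloid" & idx$marker == "Ki-67" &
                          idx$strategy == "rectangle"]
    expect_lt(abs(got - truthKi), 0.02)
  }
  # isotype route errors when the channels are absent
  evNoIso <- ev[seq_len(nEvents(ev))]
  keep <- setdiff(channels(ev), c("IgG1-FITC", "IgG1-PE-CF594"))
  evNoIso@exprs <- exprs(ev)[, keep]
  expect_error(computeAllIndices(evNoIso, g$masks,
                                 controlSource = "isotype"),
               "isotype")
})
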