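test_that("debris/doublet exclusion retains clean samples and removes tagged events", {
  # nothing to remove
  prClean <- caseProfile("clean", targetFractions = c(blast = 2,
                                                      erythroid = 15,
                                                      myeloid = 50,
                                                      monocytic = 5,
                                                      doublet = 0,
                                                      debris = 0),
                         nEvents = 20000L)
  csClean <- generateCase(prClean, seed = 21, tubes = "full")
  sClean <- excludeDebrisDoublets(csClean$tubes[["full"]])
  expect_gte(mean(maskVector(sClean)), 0.99)

  # 10% tagged doublets
  prDbl <- caseProfile("dbl", targetFractions = c(blast = 2, erythroid = 15,
                                                  myeloid = 45,
                                                  monocytic = 5,
                                                  doublet = 10, debris = 3),
                       nEvents = 30000L)
  csDbl <- generateCase(prDbl, seed = 3, tubes = "full")
  s <- maskVector(excludeDebrisDoublets(csDbl$tubes[["full"]]))
  isDbl <- csDbl$truth@label == "doublet"
  isSinglet <- !isDbl & csDbl$truth@label != "debris"
  expect_gte(mean(!s[isDbl]), 0.90)          # >= 90% of doublets removed
  expect_lte(mean(!s[isSinglet]), 0.02)      # <= 2% of singlets removed

  # containment: singlet mask is a subset of all events
  expect_lte(sum(s), length(s))
  expect_error(excludeDebrisDoublets(
    EventTable(matrix(1, 2, 1, dimnames = list(NULL, "CD45-KO")))),
    "scatter")
})

test_that("relevant-event counting excludes debris only", {
  pr <- caseProfile("deb", targetFractions = c(blast = 2, erythroid = 15,
                                               myeloid = 45, monocytic = 5,
                                               doublet = 2, debris = 5),
                    nEvents = 100000L)
  cs <- generateCase(pr, seed = 1, tubes = "full")
  ev <- cs$tubes[["full"]]
  rel <- countRelevantEvents(ev)
  expect_lt(abs(rel - 95000), 950)           # within 1% of the tagged count
  # doublets are retained: relevant count >= singlet count
  expect_gte(rel, sum(maskVector(excludeDebrisDoublets(ev))))

  # no debris -> everything is relevant
  pr0 <- caseProfile("nodeb", targetFractions = c(erythroid = 20,
                                                  myeloid = 60,
                                                  debris = 0),
                     nEvents = 10000L)
  ev0 <- generateCase(pr0, seed = 2, tubes = "full")$tubes[["full"]]
  expect_equal(countRelevantEvents(ev0), 10000L)
})

test_that("CD34+ blast gating recovers configured fractions with high purity", {
  pr <- profileFromFixture("MDS", 10, nEvents = 100000)   # blasts 8.5%
  cs <- generateCase(pr, seed = 11, tubes = "full")
  ev <- cs$tubes[["full"]]
  singlets <- excludeDebrisDoublets(ev)
  blast <- gateCd34Blasts(ev, singlets)
  rel <- countRelevantEvents(ev)
  recovered <- 100 * sum(maskVector(blast)) / rel
  expect_lt(abs(recovered - pr@targetFractions[["blast"]]), 1.5)
  expect_lt(abs(recovered - 8.5), 1.5)

  # precision / recall against ground-truth labels
  truthBlast <- cs$truth@label == "blast"
  got <- maskVector(blast)
  precision <- sum(got & truthBlast) / sum(got)
  recall <- sum(got & truthBlast) / sum(truthBlast)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

test_that("a sample without blasts yields a near-zero blast fraction", {
  pr <- caseProfile("nb", targetFractions = c(erythroid = 20, myeloid = 55,
                                              monocytic = 5, debris = 3),
                    nEvents = 50000L)
  cs <- generateCase(pr, seed = 13, tubes = "full")
  ev <- cs$tubes[["full"]]
  g <- gateSample(ev)
  expect_lte(g$fractions$fraction[g$fractions$population == "blast"], 0.2)
})

test_that("erythroid exclusion chain recovers the configured fraction", {
  pr <- profileFromFixture("non_malignant", 2, nEvents = 60000)  # 19.3%
  cs <- generateCase(pr, seed = 17, tubes = "full")
  ev <- cs$tubes[["full"]]
  singlets <- excludeDebrisDoublets(ev)
  ery <- gateErythroid(ev, singlets)
  rel <- countRelevantEvents(ev)
  recovered <- 100 * sum(maskVector(ery)) / rel
  expect_lt(abs(recovered - pr@targetFractions[["erythroid"]]), 2)

  # every intermediate mask is contained in its predecessor
  audit <- ery@audit
  for (i in seq_along(audit)[-1])
    expect_true(all(audit[[i]] <= audit[[i - 1]]),
                label = names(audit)[i])

  # without platelets the platelet-exclusion step is nearly a no-op
  prNoPlt <- caseProfile("noplt",
                         targetFractions = c(blast = 2, erythroid = 20,
                                             myeloid = 45, monocytic = 4,
                                             platelet = 0, debris = 3),
                         nEvents = 30000L)
  cs2 <- generateCase(prNoPlt, seed = 19, tubes = "full")
  ery2 <- gateErythroid(cs2$tubes[["full"]],
                        excludeDebrisDoublets(cs2$tubes[["full"]]))
  a <- ery2@audit
  removed <- sum(a$minus_lymphoid) - sum(a$minus_platelet)
  expect_lte(removed / max(1, sum(a$minus_lymphoid)), 0.005)
})

test_that("myeloid gating recovers dense samples and excludes eosinophils", {
  pr <- profileFromFixture("non_malignant", 9, nEvents = 60000)  # 83.8%
  cs <- generateCase(pr, seed = 23, tubes = "full")
  ev <- cs$tubes[["full"]]
  singlets <- excludeDebrisDoublets(ev)
  mye <- gateMyeloid(ev, singlets)
  rel <- countRelevantEvents(ev)
  recovered <- 100 * sum(maskVector(mye)) / rel
  expect_lt(abs(recovered - pr@targetFractions[["myeloid"]]), 3)
  expect_lt(abs(recovered - 83.8), 3)

  # tagged eosinophils are removed from the myeloid mask
  prEos <- caseProfile("eos", targetFractions = c(blast = 2, erythroid = 15,
                                                  myeloid = 45,
                                                  monocytic = 4,
                                                  eosinophil = 3,
                                                  debris = 3),
                       nEvents = 40000L)
  cs2 <- generateCase(prEos, seed = 29, tubes = "full")
  ev2 <- cs2$tubes[["full"]]
  mye2 <- gateMyeloid(ev2, excludeDebrisDoublets(ev2))
  isEos <- cs2$truth@label == "eosinophil"
  inPre <- mye2@audit$minus_mature_mono
  removedEos <- sum(isEos & inPre & !maskVector(mye2))
  expect_gte(removedEos / max(1, sum(isEos & inPre)), 0.80)
})

test_that("monocyte backgating recovers fractions and degrades gracefully", {
  pr <- profileFromFixture("AML", 24, nEvents = 60000)   # monocytic 35.4%
  cs <- generateCase(pr, seed = 31, tubes = "full")
  ev <- cs$tubes[["full"]]
  singlets <- excludeDebrisDoublets(ev)
  mono <- gateMonocytes(ev, singlets)
  rel <- countRelevantEvents(ev)
  recovered <- 100 * sum(maskVector(mono)) / rel
  expect_lt(abs(recovered - pr@targetFractions[["monocytic"]]), 3)

  # zero monocytes: degenerate-seed warning and near-zero fraction
  pr0 <- caseProfile("nomono", targetFractions = c(blast = 2,
                                                   erythroid = 20,
                                                   myeloid = 55,
                                                   debris = 3),
                     nEvents = 30000L)
  cs0 <- generateCase(pr0, seed = 37, tubes = "full")
  ev0 <- cs0$tubes[["full"]]
  expect_warning(m0 <- gateMonocytes(ev0, excludeDebrisDoublets(ev0)),
                 "degenerate")
  expect_lte(100 * sum(maskVector(m0)) / countRelevantEvents(ev0), 0.5)

  # recovered fraction is monotone in the configured fraction
  rec <- vapply(c(2, 10, 30), function(fr) {
    p <- caseProfile("m", targetFractions = c(blast = 2, erythroid = 15,
                                              myeloid = 40,
                                              monocytic = fr, debris = 3),
                     nEvents = 30000L)
    csx <- generateCase(p, seed = 41, tubes = "full")
    evx <- csx$tubes[["full"]]
    100 * sum(maskVector(gateMonocytes(evx, excludeDebrisDoublets(evx)))) /
      countRelevantEvents(evx)
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("population fractions are exact ratios and validate inputs", {
  masks <- list(blast = rep(c(TRUE, FALSE), c(300, 99700)),
                erythroid = rep(c(FALSE, TRUE, FALSE),
                                c(300, 9400, 90300)),
                myeloid = rep(c(FALSE, TRUE, FALSE),
                              c(9700, 63600, 26700)),
                monocytic = rep(c(FALSE, TRUE, FALSE),
                                c(73300, 600, 26100)))
  fr <- populationFractions(masks, 100000)
  expect_equal(fr$fraction, c(0.3, 9.4, 63.6, 0.6))
  expect_equal(fr$count / attr(fr, "relevant_count") * 100, fr$fraction)

  # permutation invariance
  set.seed(1)
  perm <- sample.int(100000)
  frPerm <- populationFractions(lapply(masks, function(m) m[perm]), 100000)
  expect_equal(frPerm$fraction, fr$fraction)

  # all-zero masks and empty samples
  z <- lapply(masks, function(m) m & FALSE)
  expect_equal(populationFractions(z, 100)$fraction, rep(0, 4))
  expect_error(populationFractions(masks, 0), "empty sample")
})

test_that("final population masks are pairwise disjoint subsets of singlets", {
  cs <- smallSample(nEvents = 30000, seed = 43)
  g <- gateSample(cs$tubes[["full"]])
  s <- maskVector(g$singlets)
  mats <- vapply(g$masks, maskVector, logical(length(s)))
  expect_true(all(rowSums(mats) <= 1))           # exclusivity
  for (j in seq_len(ncol(mats)))
    expect_true(all(mats[, j] <= s))             # containment
})

test_that("density-valley thresholds agree with a grid-search oracle", {
  set.seed(55)
  for (rep in 1:3) {
    x <- c(rlnorm(600, log(20), 0.35), rlnorm(400, log(300), 0.4))
    got <- valleyThreshold(x)$threshold
    # independent oracle: explicit Gaussian-kernel density on a fine grid,
    # minimised between the two highest local maxima
    z <- log10(x + 1)
    bw <- bw.nrd0(z)
    grid <- seq(min(z) - 3 * bw, max(z) + 3 * bw, length.out = 4000)
    dens <- vapply(grid, function(g) mean(dnorm((g - z) / bw)) , numeric(1))
    k <- length(dens)
    locmax <- which(c(FALSE, dens[2:(k - 1)] > dens[1:(k - 2)] &
                        dens[2:(k - 1)] >= dens[3:k], FALSE))
    top2 <- sort(locmax[order(dens[locmax], decreasing = TRUE)][1:2])
    between <- top2[1]:top2[2]
    oracle <- 10^grid[between[which.min(dens[between])]] - 1
    expect_lt(abs(log10(got + 1) - log10(oracle + 1)), 0.05)
  }
  # degenerate / unimodal inputs yield no threshold
  expect_true(is.na(valleyThreshold(rep(20, 100))$threshold))
  expect_true(is.na(valleyThreshold(rlnorm(500, log(20), 0.3))$threshold))
})

test_that("gate audit trails export one row per event", {
  cs <- smallSample(nEvents = 2000, seed = 47)
  g <- suppressWarnings(gateSample(cs$tubes[["full"]]))  # tiny n: seed gate
  f <- tempfile(fileext = ".csv")
  exportAuditTrail(g$masks, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), 2000)
  expect_true("erythroid.cd45_negative" %in% names(df))
})
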