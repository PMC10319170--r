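test_that("profiles built from fixture rows carry the printed targets", {
  p <- profileFromFixture("non_malignant", 1)
  expect_equal(unname(p@targetFractions[c("blast", "erythroid", "myeloid",
                                          "monocytic")]),
               c(0.3, 9.4, 63.6, 0.6))
  # over-full printed rows are scaled onto 100 with nuisance dropped first
  p9 <- profileFromFixture("non_malignant", 9)
  rel <- p9@targetFractions[setdiff(names(p9@targetFractions), "debris")]
  expect_lte(sum(rel), 100 + 1e-9)
  expect_gt(p9@targetFractions[["myeloid"]], 80)
})

test_that("profile validation rejects impossible compositions", {
  expect_error(caseProfile("x", targetFractions = c(blast = 60,
                                                    myeloid = 60)),
               "sum above 100")
  expect_error(caseProfile("x", targetFractions = c(nonsense = 5)),
               "unknown population")
})

test_that("ground-truth fractions track configured targets at n = 100,000", {
  pr <- caseProfile("bin", targetFractions = c(blast = 10, erythroid = 15,
                                               myeloid = 40, monocytic = 5,
                                               debris = 5),
                    nEvents = 100000L)
  cs <- generateCase(pr, seed = 7, tubes = "full")
  truth <- cs$truth
  nRel <- sum(truth@label != "debris")
  blastFrac <- sum(truth@label == "blast") / nRel
  # binomial 99% interval around 10% at the realised denominator
  interval <- qbinom(c(0.005, 0.995), nRel, 0.10) / nRel
  expect_gte(blastFrac, interval[1])
  expect_lte(blastFrac, interval[2])
  # exact bookkeeping: stored true fractions equal recomputed label counts
  expect_equal(truth@trueFractions[["blast"]],
               100 * sum(truth@label == "blast") / nRel)
})

test_that("zero nuisance fractions leave only labelled cell populations", {
  pr <- caseProfile("clean", targetFractions = c(blast = 5, erythroid = 20,
                                                 myeloid = 50,
                                                 monocytic = 5,
                                                 doublet = 0, debris = 0),
                    nEvents = 5000L)
  cs <- generateCase(pr, seed = 11, tubes = "full")
  expect_false(any(cs$truth@label %in% c("debris", "doublet")))
  expect_equal(length(cs$truth@label), 5000L)
})

test_that("all tubes of a case share N and ground truth; seeds reproduce", {
  pr <- smallProfile(3000)
  cs1 <- generateCase(pr, seed = 5, tubes = c("1", "3", "7", "full"))
  ns <- vapply(cs1$tubes, nEvents, integer(1))
  expect_true(all(ns == ns[1]))
  cs2 <- generateCase(pr, seed = 5, tubes = c("1", "3", "7", "full"))
  expect_identical(exprs(cs1$tubes[["3"]]), exprs(cs2$tubes[["3"]]))
  expect_identical(cs1$truth@label, cs2$truth@label)
  cs3 <- generateCase(pr, seed = 6, tubes = "full")
  expect_false(identical(exprs(cs1$tubes[["full"]]),
                         exprs(cs3$tubes[["full"]])))
})

test_that("latent positivity fractions follow the configured probabilities", {
  tpf <- cbind("Ki-67" = c(blast = 0.5, erythroid = 0.2, myeloid = 0.3,
                           monocytic = 0.1, lymphoid = 0, eosinophil = 0,
                           platelet = 0, debris = 0),
               "Bcl-2" = c(0.9, 0.1, 0.2, 0.3, 0, 0, 0, 0))
  pr <- caseProfile("tp", targetFractions = c(blast = 20, erythroid = 20,
                                              myeloid = 40, monocytic = 10,
                                              debris = 0),
                    truePositiveFractions = tpf, nEvents = 50000L)
  cs <- generateCase(pr, seed = 8, tubes = "full")
  isBlast <- cs$truth@label == "blast"
  expect_equal(mean(cs$truth@ki67Positive[isBlast]), 0.5, tolerance = 0.05)
  expect_equal(mean(cs$truth@bcl2Positive[isBlast]), 0.9, tolerance = 0.05)
})

test_that("default cohort matches the study demographics exactly", {
  co <- generateCohort(seed = 31)
  m <- co$metadata
  expect_equal(sum(m$cohort == "non_malignant"), 50)
  expect_equal(sum(m$cohort == "MDS"), 25)
  expect_equal(sum(m$cohort == "AML"), 27)
  expect_equal(median(m$age[m$cohort == "non_malignant"]), 70)
  expect_equal(median(m$age[m$cohort == "MDS"]), 75)
  expect_equal(median(m$age[m$cohort == "AML"]), 72)
  expect_true(all(m$age[m$cohort == "non_malignant"] >= 45 &
                    m$age[m$cohort == "non_malignant"] <= 89))
  expect_equal(sum(m$sex[m$cohort == "non_malignant"] == "M"), 25)
  expect_equal(sum(m$sex[m$cohort == "MDS"] == "M"), 16)
  expect_equal(sum(m$sex[m$cohort == "AML"] == "M"), 13)
})

test_that("cohort generation is deterministic under a fixed seed", {
  c1 <- generateCohort(seed = 12)
  c2 <- generateCohort(seed = 12)
  expect_identical(c1$metadata, c2$metadata)
  # event values reproduce from the recorded per-case seed
  pr <- c1$profiles[["MDS_03"]]
  pr@nEvents <- 2000L
  s <- c1$metadata$seed[c1$metadata$case_id == "MDS_03"]
  e1 <- generateCase(pr, seed = s, tubes = "full")
  e2 <- generateCase(pr, seed = s, tubes = "full")
  expect_identical(exprs(e1$tubes[["full"]]), exprs(e2$tubes[["full"]]))
})

test_that("cohort config validates sizes and age ranges", {
  expect_error(cohortConfig(sizes = c(non_malignant = 0, MDS = 25,
                                      AML = 27)))
  expect_error(cohortConfig(ageMedian = c(non_malignant = 30, MDS = 75,
                                          AML = 72)),
               "outside range")
})
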