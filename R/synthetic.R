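## Synthetic bone-marrow cohort generator.
##
## Per-event intensities are drawn log-normally around population- and
## positivity-specific means on a linear FU scale calibrated so that
## unstained/negative clouds centre at ~10-30 FU and bright positives at
## 200-1000 FU, which makes the fixed 40/100 FU positivity thresholds
## meaningful. Every tube of a case shares the same latent cells; tubes
## differ only in which marker columns are observed.

.POPULATIONS <- c("blast", "erythroid", "myeloid", "mono_mature",
                  "mono_immature", "lymphoid", "eosinophil", "platelet",
                  "debris")

# mean intensities (FU) per (marker, population)
.POP_MEANS <- local({
  m <- rbind(
    #          blast eryth myelo monoM monoI lymph  eos  plat debris
    "FSC"    = c(350,  250,  500,  450,  420,  300,  520,  120,  25),
    "SSC"    = c(140,   80,  650,  280,  250,   90,  850,   40,  20),
    "CD45"   = c(100,   18,  150,  400,  350,  700,  160,   15,  12),
    "CD34"   = c(350,   18,   20,   20,   25,   20,   20,   15,  12),
    "CD13"   = c( 35,   18,  300,  250,  200,   20,  260,   18,  12),
    "CD33"   = c(120,   18,  250,  500,  400,   20,  220,   18,  12),
    "CD117"  = c(250,   20,   22,   20,   22,   18,   20,   15,  12),
    "HLA-DR" = c(300,   20,   22,  400,  380,  150,   22,   18,  12),
    "CD36"   = c( 25,  250,   30,  300,  250,   20,   25,  300,  12),
    "CD71"   = c( 60,  400,   30,   40,   50,   25,   25,   20,  12),
    "CD235a" = c( 20,  400,   20,   20,   20,   20,   20,   25,  12),
    "CD14"   = c( 25,   18,   30,  500,   28,   20,   30,   18,  12),
    "CD10"   = c( 40,   18,  100,   22,   25,  150,   60,   18,  12),
    "CD11b"  = c( 30,   18,  400,  350,  200,   25,  350,   20,  12))
  colnames(m) <- .POPULATIONS
  m
})

# log-normal sdlog per marker (population-independent except blast CD45)
.POP_SDLOG <- c(FSC = 0.20, SSC = 0.18, CD45 = 0.22, CD34 = 0.30,
                CD13 = 0.30, CD33 = 0.30, CD117 = 0.30, "HLA-DR" = 0.30,
                CD36 = 0.30, CD71 = 0.30, CD235a = 0.30, CD14 = 0.30,
                CD10 = 0.30, CD11b = 0.30)

# Ki-67 / Bcl-2 / isotype intensity model (FU)
.KI_NEG_MEAN <- 20; .KI_NEG_SDLOG <- 0.40
.KI_POS_MEAN <- 350; .KI_POS_SDLOG <- 0.45

# fraction of the monocytic compartment that is immature (CD14-, HLA-DR+)
.MONO_IMMATURE_FRAC <- 0.3

# eosinophil autofluorescence on the FITC / PE-CF594 channels (FU)
.EOS_AUTOFLUOR <- 2000

# default latent positive fractions per cohort; implementation defaults for
# exercising the pipeline, not measured study indices
.DEFAULT_TPF <- list(
  non_malignant = cbind("Ki-67" = c(blast = 0.20, erythroid = 0.40,
                                    myeloid = 0.25, monocytic = 0.20,
                                    lymphoid = 0.05, eosinophil = 0.05,
                                    platelet = 0.01, debris = 0),
                        "Bcl-2" = c(0.30, 0.10, 0.20, 0.35, 0.40, 0.10,
                                    0.01, 0)),
  MDS = cbind("Ki-67" = c(blast = 0.30, erythroid = 0.35, myeloid = 0.22,
                          monocytic = 0.20, lymphoid = 0.05,
                          eosinophil = 0.05, platelet = 0.01, debris = 0),
              "Bcl-2" = c(0.45, 0.12, 0.22, 0.35, 0.40, 0.10, 0.01, 0)),
  AML = cbind("Ki-67" = c(blast = 0.40, erythroid = 0.30, myeloid = 0.20,
                          monocytic = 0.18, lymphoid = 0.05,
                          eosinophil = 0.05, platelet = 0.01, debris = 0),
              "Bcl-2" = c(0.60, 0.15, 0.25, 0.40, 0.40, 0.10, 0.01, 0)))

#' Construct a CaseProfile
#'
#' @param caseId identifier.
#' @param cohort `"non_malignant"`, `"MDS"` or `"AML"`.
#' @param targetFractions named numeric: percentages of relevant events for
#'   `blast`, `erythroid`, `myeloid`, `monocytic` and the nuisance
#'   populations `lymphoid`, `eosinophil`, `platelet`, `doublet`, plus
#'   `debris` as a percentage of total acquired events. Omitted entries
#'   default to 0; `lymphoid` defaults to the unallocated remainder.
#' @param truePositiveFractions populations x markers matrix of latent
#'   Ki-67/Bcl-2 positivity probabilities; defaults per cohort.
#' @param nEvents total events to draw (default 100000, the acquisition
#'   minimum for relevant events).
#' @param age,sex demographic metadata.
#' @param autofluorescenceShift named numeric, additive FU offset on the
#'   FITC/PE-CF594 channels per population (eosinophils always receive
#'   their own high autofluorescence in addition).
#' @return a \linkS4class{CaseProfile}.
#' @export
caseProfile <- function(caseId, cohort = "non_malignant",
                        targetFractions = c(blast = 1, erythroid = 15,
                                            myeloid = 50, monocytic = 3),
                        truePositiveFractions = NULL, nEvents = 100000L,
                        age = 70, sex = "F",
                        autofluorescenceShift = numeric(0)) {
  known <- c("blast", "erythroid", "myeloid", "monocytic", "lymphoid",
             "eosinophil", "platelet", "doublet", "debris")
  bad <- setdiff(names(targetFractions), known)
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  f <- stats::setNames(numeric(length(known)), known)
  f[names(targetFractions)] <- targetFractions
  if (!"lymphoid" %in% names(targetFractions)) {
    rel <- sum(f[setdiff(known, c("lymphoid", "debris"))])
    f["lymphoid"] <- max(0, 100 - rel)
  }
  if (is.null(truePositiveFractions))
    truePositiveFractions <- .DEFAULT_TPF[[cohort]]
  new("CaseProfile", caseId = as.character(caseId), cohort = cohort,
      age = age, sex = sex, targetFractions = f,
      truePositiveFractions = truePositiveFractions,
      nEvents = as.integer(nEvents),
      autofluorescenceShift = autofluorescenceShift)
}

#' Build a CaseProfile from a packaged fixture row
#'
#' The four printed population percentages become the profile's targets.
#' Nuisance fills (debris 5% of total; doublet 2%, platelet 2%,
#' eosinophil 1.5% of relevant; lymphoid = remainder) are added; when a
#' printed row's populations leave no room, nuisance fills are shrunk first
#' and the populations are rescaled onto 100% only if still necessary.
#'
#' @param cohort cohort id, see [loadFractionFixture()].
#' @param case printed case number within the cohort table.
#' @param nEvents events to draw.
#' @param age,sex optional demographics.
#' @return a \linkS4class{CaseProfile}.
#' @examples
#' p <- profileFromFixture("non_malignant", 1)
#' p@targetFractions[c("blast", "erythroid", "myeloid", "monocytic")]
#' @export
profileFromFixture <- function(cohort, case, nEvents = 100000L, age = 70,
                               sex = "F") {
  tab <- loadFractionFixture(cohort)
  row <- tab[tab$case == case, ]
  if (nrow(row) != 1) stop("no such case in fixture: ", cohort, " ", case)
  pops <- c(blast = row$blast_pct, erythroid = row$erythroid_pct,
            myeloid = row$myeloid_pct, monocytic = row$monocytic_pct)
  nuis <- c(doublet = 2, platelet = 2, eosinophil = 1.5)
  popsum <- sum(pops)
  room <- 100 - popsum
  if (room < sum(nuis)) nuis <- nuis * max(0, room) / sum(nuis)
  if (popsum > 100) pops <- pops * 100 / popsum
  lymph <- max(0, 100 - sum(pops) - sum(nuis))
  caseProfile(caseId = sprintf("%s_%02d", cohort, case), cohort = cohort,
              targetFractions = c(pops, nuis, lymphoid = lymph, debris = 5),
              nEvents = nEvents, age = age, sex = sex)
}

# integer counts from percentages summing exactly to n (largest remainder)
.apportion <- function(n, frac) {
  raw <- n * frac / sum(frac)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

.fullChannelSet <- function() {
  mk <- rownames(.POP_MEANS)[-(1:2)]  # fluorescence markers
  c(.SCATTER_CHANNELS, vapply(mk, .channelName, character(1)),
    .channelName("Ki-67"), .channelName("Bcl-2"),
    .channelName("IgG1-FITC"), .channelName("IgG1-PE"))
}

#' Generate one multi-tube synthetic case
#'
#' Draws latent cells for every population of the profile, measures them on
#' each requested tube of the panel (all tubes share the same cells) and
#' returns per-event ground truth. The pseudo-tube `"full"` carries every
#' channel including the isotype-control channels and is the convenient
#' single-table input for gating.
#'
#' @param profile a \linkS4class{CaseProfile}.
#' @param panel a \linkS4class{PanelDefinition}.
#' @param seed integer RNG seed.
#' @param tubes character vector of tube ids to emit; may include `"full"`.
#' @param tubeNoiseSd multiplicative log-normal measurement noise (sdlog)
#'   applied independently per physical tube, emulating tube-to-tube
#'   technical variation of separately stained aliquots; the `"full"`
#'   pseudo-tube carries the noise-free latent values.
#' @return list with `tubes` (named list of \linkS4class{EventTable}) and
#'   `truth` (a \linkS4class{GroundTruth}).
#' @export
generateCase <- function(profile, panel = defaultPanel(), seed = 1L,
                         tubes = c(names(panelTubes(panel)), "full"),
                         tubeNoiseSd = 0.04) {
  stopifnot(is(profile, "CaseProfile"))
  validObject(profile)
  set.seed(seed)
  n <- profile@nEvents
  f <- profile@targetFractions

  nDebris <- round(n * f[["debris"]] / 100)
  nRel <- n - nDebris
  relNames <- c("blast", "erythroid", "myeloid", "monocytic", "lymphoid",
                "eosinophil", "platelet", "doublet")
  relFrac <- f[relNames]
  slack <- max(0, 100 - sum(relFrac))
  relFrac["lymphoid"] <- relFrac["lymphoid"] + slack
  counts <- stats::setNames(.apportion(nRel, relFrac), relNames)
  nMono <- counts[["monocytic"]]
  nMonoI <- round(nMono * .MONO_IMMATURE_FRAC)
  genCounts <- c(blast = counts[["blast"]], erythroid = counts[["erythroid"]],
                 myeloid = counts[["myeloid"]],
                 mono_mature = nMono - nMonoI, mono_immature = nMonoI,
                 lymphoid = counts[["lymphoid"]],
                 eosinophil = counts[["eosinophil"]],
                 platelet = counts[["platelet"]], debris = nDebris)

  markers <- rownames(.POP_MEANS)
  nSinglet <- sum(genCounts)
  popOf <- rep(names(genCounts), genCounts)
  m <- matrix(0, nSinglet, length(markers), dimnames = list(NULL, markers))
  for (mk in markers) {
    mu <- log(.POP_MEANS[mk, popOf])
    m[, mk] <- stats::rlnorm(nSinglet, mu, .POP_SDLOG[[mk]])
  }

  # reported population labels (monocytic subtypes collapse)
  label <- popOf
  label[label %in% c("mono_mature", "mono_immature")] <- "monocytic"

  # latent Ki-67 / Bcl-2 positivity and marker channels
  tpf <- profile@truePositiveFractions
  pKi <- pBc <- numeric(nSinglet)
  hit <- label %in% rownames(tpf)
  pKi[hit] <- tpf[label[hit], "Ki-67"]
  pBc[hit] <- tpf[label[hit], "Bcl-2"]
  kiPos <- stats::rbinom(nSinglet, 1, pKi) == 1
  bcPos <- stats::rbinom(nSinglet, 1, pBc) == 1
  drawKi <- function(pos) {
    v <- stats::rlnorm(length(pos), log(.KI_NEG_MEAN), .KI_NEG_SDLOG)
    v[pos] <- stats::rlnorm(sum(pos), log(.KI_POS_MEAN), .KI_POS_SDLOG)
    v
  }
  ki <- drawKi(kiPos)
  bc <- drawKi(bcPos)
  igF <- stats::rlnorm(nSinglet, log(.KI_NEG_MEAN), .KI_NEG_SDLOG)
  igP <- stats::rlnorm(nSinglet, log(.KI_NEG_MEAN), .KI_NEG_SDLOG)

  # autofluorescence: shared per-event factor, correlated across FITC and
  # PE-CF594; eosinophils always get their own high autofluorescence
  af <- numeric(nSinglet)
  isEos <- popOf == "eosinophil"
  if (any(isEos))
    af[isEos] <- stats::rlnorm(sum(isEos), log(.EOS_AUTOFLUOR), 0.25)
  shift <- profile@autofluorescenceShift
  for (p in names(shift)) {
    sel <- label == p & !isEos
    if (any(sel) && shift[[p]] > 0)
      af[sel] <- af[sel] + stats::rlnorm(sum(sel), log(shift[[p]]), 0.25)
  }
  jit <- function(x) x * exp(stats::rnorm(length(x), 0, 0.10))
  ki <- ki + jit(af); bc <- bc + jit(af)
  igF <- igF + jit(af); igP <- igP + jit(af)

  # scatter peak channel: singlets have integral ~ peak
  fsPeak <- m[, "FSC"] * exp(stats::rnorm(nSinglet, 0, 0.05))

  full <- cbind(m, "Ki-67" = ki, "Bcl-2" = bc, "IgG1-FITC" = igF,
                "IgG1-PE" = igP, "FS-PEAK" = fsPeak)

  # doublets: two singlet cells measured as one event; integral channels
  # add, the peak channel follows the larger constituent
  nDbl <- counts[["doublet"]]
  if (nDbl > 0) {
    relRows <- which(popOf != "debris")
    i1 <- sample(relRows, nDbl, replace = TRUE)
    i2 <- sample(relRows, nDbl, replace = TRUE)
    dbl <- full[i1, , drop = FALSE] + full[i2, , drop = FALSE]
    dbl[, "FS-PEAK"] <- pmax(full[i1, "FS-PEAK"], full[i2, "FS-PEAK"]) *
      exp(stats::rnorm(nDbl, 0, 0.03))
    full <- rbind(full, dbl)
    label <- c(label, rep("doublet", nDbl))
    kiPos <- c(kiPos, kiPos[i1] | kiPos[i2])
    bcPos <- c(bcPos, bcPos[i1] | bcPos[i2])
  }

  ord <- sample.int(nrow(full))
  full <- full[ord, , drop = FALSE]
  label <- label[ord]; kiPos <- kiPos[ord]; bcPos <- bcPos[ord]

  relevant <- label != "debris"
  pops <- c("blast", "erythroid", "myeloid", "monocytic")
  trueFrac <- vapply(pops, function(p) 100 * sum(label == p) / sum(relevant),
                     numeric(1))
  truth <- new("GroundTruth", label = label, ki67Positive = kiPos,
               bcl2Positive = bcPos, trueFractions = trueFrac)

  chanOf <- function(markerNames) {
    vapply(markerNames, function(mk) {
      if (mk == "FSC") "FSC-INT" else if (mk == "SSC") "SSC-INT"
      else .channelName(mk)
    }, character(1), USE.NAMES = FALSE)
  }
  colnames(full) <- c(chanOf(markers), .channelName("Ki-67"),
                      .channelName("Bcl-2"), .channelName("IgG1-FITC"),
                      .channelName("IgG1-PE"), "FS-PEAK")
  colnames(full)[1:2] <- c("FSC-INT", "SSC-INT")

  tubeTabs <- panelTubes(panel)
  out <- list()
  for (tb in tubes) {
    if (tb == "full") {
      keep <- c("FSC-INT", "SSC-INT", "FS-PEAK",
                setdiff(colnames(full), c("FSC-INT", "SSC-INT", "FS-PEAK")))
    } else {
      tab <- tubeTabs[[tb]]
      if (is.null(tab)) stop("unknown tube id: ", tb)
      keep <- c("FSC-INT", "SSC-INT", "FS-PEAK", tab$channel)
    }
    mat <- full[, keep, drop = FALSE]
    if (tb != "full" && tubeNoiseSd > 0) {
      set.seed(.childSeed(seed, paste0("tubenoise_", tb)))
      mat <- mat * exp(matrix(stats::rnorm(length(mat), 0, tubeNoiseSd),
                              nrow(mat)))
    }
    out[[tb]] <- EventTable(mat,
                           sampleId = profile@caseId, tubeId = tb,
                           keywords = list(COHORT = profile@cohort,
                                           SEED = as.character(seed)))
  }
  list(tubes = out, truth = truth)
}

#' Cohort configuration
#'
#' Defaults follow the study demographics: 50 non-malignant (25 M / 25 F,
#' median age 70, range 45-89), 25 MDS (16 M / 9 F, median 75, range 58-94)
#' and 27 AML (13 M / 14 F, median 72, range 50-87) cases, one per packaged
#' fixture row.
#'
#' @param sizes named integer cohort sizes.
#' @param ageMedian,ageRange named numeric medians / list of ranges.
#' @param males named integer male counts per cohort.
#' @param nEvents events per case when event data are generated.
#' @return list of class `cohortConfig`.
#' @export
cohortConfig <- function(sizes = c(non_malignant = 50, MDS = 25, AML = 27),
                         ageMedian = c(non_malignant = 70, MDS = 75, AML = 72),
                         ageRange = list(non_malignant = c(45, 89),
                                         MDS = c(58, 94), AML = c(50, 87)),
                         males = NULL, nEvents = 100000L) {
  stopifnot(all(sizes > 0))
  if (is.null(males)) {
    # study sex ratios: 25/50, 16/25 and 13/27 males
    ratio <- c(non_malignant = 25 / 50, MDS = 16 / 25, AML = 13 / 27)
    males <- round(sizes * ratio[names(sizes)])
  }
  for (co in names(sizes)) {
    r <- ageRange[[co]]
    if (ageMedian[[co]] < r[1] || ageMedian[[co]] > r[2])
      stop("age median outside range for cohort ", co)
  }
  structure(list(sizes = sizes, ageMedian = ageMedian, ageRange = ageRange,
                 males = males, nEvents = as.integer(nEvents)),
            class = "cohortConfig")
}

# uniform integer ages post-adjusted so the sample median is exactly the
# target: extremes on the heavy side are moved onto the target until the
# median lands
.sampleAges <- function(n, range, targetMedian) {
  a <- sample(seq(range[1], range[2]), n, replace = TRUE)
  for (i in seq_len(n)) {
    m <- stats::median(a)
    if (m == targetMedian) break
    j <- if (m > targetMedian) which.max(a) else which.min(a)
    a[j] <- targetMedian
  }
  a
}

#' Generate a synthetic cohort
#'
#' Emits one case profile per packaged fixture row (or per the configured
#' sizes) with demographics drawn to match the printed medians exactly,
#' plus a metadata table. Event data are generated on demand (`events =
#' TRUE`) with per-case seeds fanned out from `seed`, so individual cases
#' can be reproduced independently.
#'
#' @param config a [cohortConfig()].
#' @param panel a \linkS4class{PanelDefinition}.
#' @param seed integer seed.
#' @param cohorts cohorts to include.
#' @param events also generate event tables per case (expensive).
#' @param tubes tubes to emit when `events = TRUE`.
#' @return list with `profiles` (list of \linkS4class{CaseProfile}),
#'   `metadata` (data.frame: case_id, cohort, age, sex, seed) and, when
#'   requested, `cases` (per-case output of [generateCase()]).
#' @export
generateCohort <- function(config = cohortConfig(), panel = defaultPanel(),
                           seed = 1L,
                           cohorts = names(config$sizes), events = FALSE,
                           tubes = "full") {
  profiles <- list()
  meta <- list()
  for (co in cohorts) {
    nCo <- config$sizes[[co]]
    fixture <- loadFractionFixture(co)
    set.seed(.childSeed(seed, paste0("demographics_", co)))
    ages <- .sampleAges(nCo, config$ageRange[[co]], config$ageMedian[[co]])
    sexes <- sample(rep(c("M", "F"),
                        c(config$males[[co]], nCo - config$males[[co]])))
    for (i in seq_len(nCo)) {
      fixRow <- fixture$case[(i - 1) %% nrow(fixture) + 1]
      pr <- profileFromFixture(co, fixRow, nEvents = config$nEvents,
                               age = ages[i], sex = sexes[i])
      pr@caseId <- sprintf("%s_%02d", co, i)
      profiles[[pr@caseId]] <- pr
      meta[[pr@caseId]] <- data.frame(
        case_id = pr@caseId, cohort = co, age = ages[i], sex = sexes[i],
        seed = .childSeed(seed, pr@caseId))
    }
  }
  metadata <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  out <- list(profiles = profiles, metadata = metadata)
  if (events) {
    out$cases <- lapply(profiles, function(pr) {
      generateCase(pr, panel, seed = .childSeed(seed, pr@caseId),
                   tubes = tubes)
    })
  }
  out
}
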