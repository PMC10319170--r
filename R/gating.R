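## Hierarchical gating of bone-marrow populations.
##
## The manual gates of the published strategy are replaced by deterministic
## surrogates: 1-D density valleys (Silverman bandwidth) locate the
## negative/dim/bright CD45 bands, the debris boundary on FSC and marker
## positivity cutoffs; doublets are excluded on the integral/peak scatter
## ratio; the monocyte gate backgates from the mature CD14+ monocytes.
## Every smoothing/fallback constant lives in gatingConfig().

#' PopulationMask: gated event membership
#'
#' @slot label population label.
#' @slot mask logical membership per event.
#' @slot parentLabel label of the parent mask (containment is enforced at
#'   construction).
#' @slot audit named list of intermediate masks of the exclusion chain.
#' @export
setClass("PopulationMask",
  representation(label = "character", mask = "logical",
                 parentLabel = "character", audit = "list"),
  prototype(parentLabel = "all", audit = list()))

#' Construct a PopulationMask
#' @param label population label.
#' @param mask logical membership.
#' @param parent optional parent \linkS4class{PopulationMask} or logical
#'   vector; membership is intersected with it so containment holds by
#'   construction.
#' @param audit named list of intermediate masks.
#' @return a \linkS4class{PopulationMask}.
#' @export
populationMask <- function(label, mask, parent = NULL, audit = list()) {
  parentLabel <- "all"
  if (!is.null(parent)) {
    pv <- if (is(parent, "PopulationMask")) parent@mask else parent
    if (length(pv) != length(mask))
      stop("parent mask length mismatch")
    mask <- mask & pv
    if (is(parent, "PopulationMask")) parentLabel <- parent@label
    else parentLabel <- "parent"
  }
  new("PopulationMask", label = label, mask = mask,
      parentLabel = parentLabel, audit = audit)
}

#' Membership vector of a PopulationMask
#' @param x a \linkS4class{PopulationMask}.
#' @return logical vector.
#' @export
maskVector <- function(x) if (is(x, "PopulationMask")) x@mask else x

setMethod("show", "PopulationMask", function(object) {
  cat(sprintf("PopulationMask '%s' (parent %s): %d / %d events\n",
              object@label, object@parentLabel, sum(object@mask),
              length(object@mask)))
})

#' Gating constants
#'
#' All smoothing, fallback and percentile constants of the gating chain in
#' one block. Units are linear FU on the generator's calibrated scale.
#'
#' @param ... overrides of the defaults.
#' @return named list of constants.
#' @export
gatingConfig <- function(...) {
  cfg <- list(
    minModeWeight = 0.01,     # relative mode height for valley finding
    debrisFscMax = 100,       # a leftmost FSC mode below this is debris
    singletMadK = 3,          # singlet band: median +/- k*MAD of INT/PEAK
    cd45NegMax = 60,          # a leftmost CD45 mode below this is negative
    cd45BrightMin = 300,      # a rightmost CD45 mode above this is bright
    cd45FallbackBand = c(45, 550),  # dim band when valleys are missing
    sscHighFallback = 430,    # high-SSC cutoff when no granulocyte valley
    sscHighMin = 400,         # SSC mode above this is the granulocyte mode
    positivityNMads = 3.5,    # robust fence for unimodal marker cutoffs
    eosPercentile = 0.995,    # joint FITC/PE upper-tail autofluorescence gate
    monoSeedMin = 50,         # mature-monocyte seeds below this = degenerate
    monoSscMin = 120,         # lower SSC edge of the mature monocyte seed
    monoBoxQuantiles = c(0.005, 0.995),  # seed bounding-box quantiles
    monoBoxExpand = 0.10,     # log-scale expansion of the backgated box
    monoFallbackSsc = c(150, 480),   # degenerate-seed fallback box
    monoFallbackCd45 = c(230, 700))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# debris boundary: first density valley above a low leftmost FSC mode;
# -Inf (keep everything) when no low-scatter cloud exists
.debrisThreshold <- function(fsc, cfg) {
  dv <- densityValleys(fsc, minModeWeight = cfg$minModeWeight)
  if (!length(dv$valleys) || min(dv$modes) > cfg$debrisFscMax) return(-Inf)
  dv$valleys[1]
}

# CD45 dim band between the negative and bright clouds
.cd45DimBand <- function(cd45, cfg) {
  dv <- densityValleys(cd45, minModeWeight = cfg$minModeWeight)
  lo <- cfg$cd45FallbackBand[1]
  hi <- cfg$cd45FallbackBand[2]
  if (length(dv$valleys)) {
    m <- dv$modes; v <- dv$valleys
    if (min(m) < cfg$cd45NegMax) lo <- min(v[v > min(m)])
    if (max(m) > cfg$cd45BrightMin) hi <- max(v[v < max(m)])
  }
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) cfg$cd45FallbackBand
  else c(lo, hi)
}

# high-SSC cutoff: valley directly left of the granulocyte SSC mode
.sscHighCutoff <- function(ssc, cfg) {
  dv <- densityValleys(ssc, minModeWeight = cfg$minModeWeight)
  m <- dv$modes
  high <- m[m > cfg$sscHighMin]
  if (!length(high) || !length(dv$valleys)) return(cfg$sscHighFallback)
  gran <- high[1]
  v <- dv$valleys[dv$valleys < gran]
  if (!length(v)) return(cfg$sscHighFallback)
  max(v)
}

.requireScatter <- function(ev, peak = FALSE) {
  need <- c("FSC-INT", "SSC-INT", if (peak) "FS-PEAK")
  missing <- setdiff(need, channels(ev))
  if (length(missing))
    stop("missing scatter channel(s): ", paste(missing, collapse = ", "))
}

#' Exclude debris and doublets
#'
#' Debris is removed below a density-valley threshold on FSC; doublets are
#' removed outside the singlet band of the integral/peak scatter ratio
#' (median +/- k*MAD).
#'
#' @param ev an \linkS4class{EventTable} with FSC-INT, SSC-INT and FS-PEAK.
#' @param config a [gatingConfig()].
#' @return a \linkS4class{PopulationMask} labelled `"singlet"`; its `audit`
#'   holds the intermediate debris-excluded mask.
#' @export
excludeDebrisDoublets <- function(ev, config = gatingConfig()) {
  .requireScatter(ev, peak = TRUE)
  m <- exprs(ev)
  fsc <- m[, "FSC-INT"]
  thr <- .debrisThreshold(fsc, config)
  notDebris <- fsc >= thr
  ratio <- m[, "FSC-INT"] / pmax(m[, "FS-PEAK"], .Machine$double.eps)
  med <- stats::median(ratio[notDebris])
  madv <- stats::mad(ratio[notDebris])
  band <- med + c(-1, 1) * config$singletMadK * madv
  singlet <- notDebris & ratio >= band[1] & ratio <= band[2]
  populationMask("singlet", singlet,
                 audit = list(not_debris = notDebris))
}

#' Count relevant events
#'
#' Relevant events are all events above the debris boundary on the FSC vs
#' SSC plot: doublets and erythroid cells are retained. This count is the
#' denominator of all population fractions and the basis of the acquisition
#' QC rule (minimum 100,000, ideally 500,000).
#'
#' @inheritParams excludeDebrisDoublets
#' @return integer count.
#' @export
countRelevantEvents <- function(ev, config = gatingConfig()) {
  .requireScatter(ev)
  fsc <- exprs(ev)[, "FSC-INT"]
  sum(fsc >= .debrisThreshold(fsc, config))
}

#' Gate CD34+ blast cells
#'
#' Events within the CD45-dim band (between the density valleys bounding
#' the negative and bright CD45 clouds) that are above the CD34 positivity
#' cutoff.
#'
#' @param ev an \linkS4class{EventTable} with CD45 and CD34 channels.
#' @param singlets singlet \linkS4class{PopulationMask} from
#'   [excludeDebrisDoublets()].
#' @param config a [gatingConfig()].
#' @return a \linkS4class{PopulationMask} labelled `"blast"`.
#' @export
gateCd34Blasts <- function(ev, singlets, config = gatingConfig()) {
  s <- maskVector(singlets)
  cd45 <- markerValues(ev, "CD45")
  cd34 <- markerValues(ev, "CD34")
  band <- .cd45DimBand(cd45[s], config)
  cut34 <- .positivityCutoff(cd34[s], config$positivityNMads)
  mask <- cd45 > band[1] & cd45 < band[2] & cd34 > cut34
  populationMask("blast", mask, parent = singlets,
                 audit = list(cd45_dim = s & cd45 > band[1] & cd45 < band[2]))
}

#' Gate erythroid cells
#'
#' The sequential exclusion chain: CD45-negative events, minus CD13 (or
#' CD33) positives, minus CD117-negative HLA-DR-positive lymphoid cells,
#' minus platelets (CD36+CD71-), proliferating non-erythroid cells
#' (CD36-CD71+) and non-nucleated red cells (CD71+CD235a-). Each
#' intermediate mask is retained in `audit`.
#'
#' @inheritParams gateCd34Blasts
#' @return a \linkS4class{PopulationMask} labelled `"erythroid"`.
#' @export
gateErythroid <- function(ev, singlets, config = gatingConfig()) {
  s <- maskVector(singlets)
  cd45 <- markerValues(ev, "CD45")
  myeloChan <- findChannel(ev, "CD13", required = FALSE)
  if (is.na(myeloChan)) myeloChan <- findChannel(ev, "CD33")
  cdm <- exprs(ev)[, myeloChan]
  cd117 <- markerValues(ev, "CD117")
  hladr <- markerValues(ev, "HLA-DR")
  cd36 <- markerValues(ev, "CD36")
  cd71 <- markerValues(ev, "CD71")
  cd235 <- markerValues(ev, "CD235a")

  band <- .cd45DimBand(cd45[s], config)
  nm <- config$positivityNMads
  cutM <- .positivityCutoff(cdm[s], nm)
  cut117 <- .positivityCutoff(cd117[s], nm)
  cutDR <- .positivityCutoff(hladr[s], nm)
  cut36 <- .positivityCutoff(cd36[s], nm)
  cut71 <- .positivityCutoff(cd71[s], nm)
  cut235 <- .positivityCutoff(cd235[s], nm)

  s1 <- s & cd45 < band[1]                       # CD45 negative
  s2 <- s1 & !(cdm > cutM)                       # remove CD13(/CD33)+
  s3 <- s2 & !(cd117 < cut117 & hladr > cutDR)   # remove lymphoid
  s4 <- s3 & !(cd36 > cut36 & cd71 < cut71)      # remove platelets
  s5 <- s4 & !(cd36 < cut36 & cd71 > cut71)      # remove proliferating
  s6 <- s5 & !(cd71 > cut71 & cd235 < cut235)    # remove non-nucleated RBC
  populationMask("erythroid", s6, parent = singlets,
                 audit = list(cd45_negative = s1, minus_myeloid = s2,
                              minus_lymphoid = s3, minus_platelet = s4,
                              minus_proliferating = s5,
                              minus_nonnucleated = s6))
}

# joint FITC/PE upper-tail autofluorescence gate; cutoffs are the
# configured percentile of each channel among events that are not jointly
# above an initial robust fence
.eosinophilFlag <- function(fitc, pe, mask, cfg) {
  f0 <- .positivityCutoff(fitc[mask], cfg$positivityNMads)
  p0 <- .positivityCutoff(pe[mask], cfg$positivityNMads)
  base <- mask & !(fitc > f0 & pe > p0)
  if (!any(base)) base <- mask
  cF <- stats::quantile(fitc[base], cfg$eosPercentile, names = FALSE, type = 1)
  cP <- stats::quantile(pe[base], cfg$eosPercentile, names = FALSE, type = 1)
  fitc > cF & pe > cP
}

#' Gate myeloid (granulocytic) cells
#'
#' High-SSC CD45-dim events, minus mature CD14+ monocytes, minus
#' eosinophils (joint FITC/PE high-autofluorescence tail), minus immature
#' CD117-negative HLA-DR-positive monocytes.
#'
#' @inheritParams gateCd34Blasts
#' @return a \linkS4class{PopulationMask} labelled `"myeloid"`.
#' @export
gateMyeloid <- function(ev, singlets, config = gatingConfig()) {
  s <- maskVector(singlets)
  .requireScatter(ev)
  ssc <- exprs(ev)[, "SSC-INT"]
  cd45 <- markerValues(ev, "CD45")
  cd14 <- markerValues(ev, "CD14")
  cd117 <- markerValues(ev, "CD117")
  hladr <- markerValues(ev, "HLA-DR")
  fitc <- markerValues(ev, "Ki-67")
  pe <- markerValues(ev, "Bcl-2")

  band <- .cd45DimBand(cd45[s], config)
  thrSS <- .sscHighCutoff(ssc[s], config)
  nm <- config$positivityNMads
  cut14 <- .positivityCutoff(cd14[s], nm)
  cut117 <- .positivityCutoff(cd117[s], nm)
  cutDR <- .positivityCutoff(hladr[s], nm)

  m1 <- s & ssc > thrSS & cd45 > band[1] & cd45 < band[2]
  m2 <- m1 & !(cd14 > cut14)
  eos <- .eosinophilFlag(fitc, pe, m2, config)
  m3 <- m2 & !eos
  m4 <- m3 & !(cd117 < cut117 & hladr > cutDR)
  populationMask("myeloid", m4, parent = singlets,
                 audit = list(high_ssc_dim_cd45 = m1, minus_mature_mono = m2,
                              minus_eosinophil = m3,
                              minus_immature_mono = m4))
}

#' Gate monocytic cells by backgating
#'
#' Mature monocytes (intermediate SSC, CD14+) seed a bounding box in the
#' SSC vs CD45 plane (robust quantiles, expanded on the log scale) that
#' selects the total monocyte population including CD14- HLA-DR+ immature
#' forms; high-SSC CD13+ myeloid and CD10+CD11b- lymphoid events are then
#' excluded. With fewer than `monoSeedMin` seeds a degenerate-seed warning
#' is raised and a fixed fallback box is used.
#'
#' @inheritParams gateCd34Blasts
#' @return a \linkS4class{PopulationMask} labelled `"monocytic"`.
#' @export
gateMonocytes <- function(ev, singlets, config = gatingConfig()) {
  s <- maskVector(singlets)
  .requireScatter(ev)
  ssc <- exprs(ev)[, "SSC-INT"]
  cd45 <- markerValues(ev, "CD45")
  cd14 <- markerValues(ev, "CD14")
  cd13chan <- findChannel(ev, "CD13", required = FALSE)
  cd13 <- if (is.na(cd13chan)) markerValues(ev, "CD33")
          else exprs(ev)[, cd13chan]
  cd10 <- markerValues(ev, "CD10")
  cd11b <- markerValues(ev, "CD11b")

  nm <- config$positivityNMads
  thrSS <- .sscHighCutoff(ssc[s], config)
  cut14 <- .positivityCutoff(cd14[s], nm)
  cut13 <- .positivityCutoff(cd13[s], nm)
  cut10 <- .positivityCutoff(cd10[s], nm)
  cut11b <- .positivityCutoff(cd11b[s], nm)

  mature <- s & cd14 > cut14 & ssc > config$monoSscMin & ssc < thrSS
  if (sum(mature) < config$monoSeedMin) {
    warning("degenerate mature-monocyte seed (", sum(mature),
            " events); falling back to fixed SSC/CD45 band")
    sscBox <- config$monoFallbackSsc
    cd45Box <- config$monoFallbackCd45
  } else {
    q <- config$monoBoxQuantiles
    ex <- config$monoBoxExpand
    expand <- function(b) {
      w <- log(b[2] / b[1])
      c(b[1] * exp(-ex * w), b[2] * exp(ex * w))
    }
    sscBox <- expand(stats::quantile(ssc[mature], q, names = FALSE))
    cd45Box <- expand(stats::quantile(cd45[mature], q, names = FALSE))
  }
  total <- s & ssc > sscBox[1] & ssc < sscBox[2] &
    cd45 > cd45Box[1] & cd45 < cd45Box[2]
  t2 <- total & !(ssc > thrSS & cd13 > cut13)    # myeloid exclusion
  t3 <- t2 & !(cd10 > cut10 & cd11b < cut11b)    # lymphoid exclusion
  populationMask("monocytic", t3, parent = singlets,
                 audit = list(mature_seed = mature, backgated_box = total,
                              minus_myeloid = t2, minus_lymphoid = t3))
}

#' Population fractions of relevant events
#'
#' @param masks named list of \linkS4class{PopulationMask} (or logical
#'   vectors) for blast, erythroid, myeloid and monocytic cells.
#' @param relevantCount denominator, from [countRelevantEvents()].
#' @return data.frame with columns `population`, `count`, `fraction`
#'   (percent of relevant events); the relevant count is attached as
#'   attribute `relevant_count`.
#' @export
populationFractions <- function(masks, relevantCount) {
  if (relevantCount <= 0) stop("empty sample: no relevant events")
  counts <- vapply(masks, function(m) sum(maskVector(m)), numeric(1))
  out <- data.frame(population = names(masks), count = as.integer(counts),
                    fraction = 100 * counts / relevantCount,
                    row.names = NULL)
  attr(out, "relevant_count") <- as.integer(relevantCount)
  out
}

#' Run the full gating strategy on one sample
#'
#' Debris/doublet exclusion, relevant-event counting and the four
#' population gates, with pairwise exclusivity enforced by priority
#' (blast > erythroid > myeloid > monocytic).
#'
#' @param ev an \linkS4class{EventTable} carrying scatter plus CD45, CD34,
#'   CD13 (or CD33), CD117, HLA-DR, CD36, CD71, CD235a, CD14, CD10, CD11b
#'   and the Ki-67/Bcl-2 channels.
#' @param config a [gatingConfig()].
#' @return list with `singlets`, `relevantCount`, `masks` (named list of
#'   disjoint \linkS4class{PopulationMask}) and `fractions`.
#' @export
gateSample <- function(ev, config = gatingConfig()) {
  singlets <- excludeDebrisDoublets(ev, config)
  relevant <- countRelevantEvents(ev, config)
  blast <- gateCd34Blasts(ev, singlets, config)
  ery <- gateErythroid(ev, singlets, config)
  mye <- gateMyeloid(ev, singlets, config)
  mono <- gateMonocytes(ev, singlets, config)
  taken <- maskVector(blast)
  ery@mask <- ery@mask & !taken; taken <- taken | ery@mask
  mye@mask <- mye@mask & !taken; taken <- taken | mye@mask
  mono@mask <- mono@mask & !taken
  masks <- list(blast = blast, erythroid = ery, myeloid = mye,
                monocytic = mono)
  list(singlets = singlets, relevantCount = relevant, masks = masks,
       fractions = populationFractions(masks, relevant))
}

#' Export a gating audit trail
#'
#' Writes one row per event with its population path (which intermediate
#' and final masks contain it).
#'
#' @param masks named list of \linkS4class{PopulationMask}.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
exportAuditTrail <- function(masks, path) {
  cols <- list()
  for (nm in names(masks)) {
    m <- masks[[nm]]
    for (an in names(m@audit))
      cols[[paste(nm, an, sep = ".")]] <- m@audit[[an]]
    cols[[nm]] <- maskVector(m)
  }
  df <- data.frame(event = seq_along(cols[[1]]), cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
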