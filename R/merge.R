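## Backbone-marker tube merging ("merge and calculate" equivalent).
##
## Tubes of one sample that share a backbone marker set are combined by
## nearest-neighbour matching in standardized (median/MAD per channel)
## backbone space: each event of the reference tube gains imputed values
## for markers it lacks, taken as the mean of its k nearest neighbours
## among events of a donor tube measuring that marker.

#' Merge-and-calculate eligibility
#'
#' A population is eligible for merged analysis when it comprises at least
#' 1000 events.
#'
#' @param populationCounts named non-negative integer counts.
#' @param minimum event minimum (default 1000).
#' @return named logical.
#' @export
checkMergeEligibility <- function(populationCounts, minimum = 1000) {
  stopifnot(all(populationCounts >= 0))
  populationCounts >= minimum
}

# median/MAD standardization per column; degenerate spread falls back to sd
.robustScale <- function(m) {
  for (j in seq_len(ncol(m))) {
    med <- stats::median(m[, j])
    s <- stats::mad(m[, j])
    if (s == 0) s <- stats::sd(m[, j])
    if (is.na(s) || s == 0) s <- 1
    m[, j] <- (m[, j] - med) / s
  }
  m
}

# brute-force k nearest neighbours (Euclidean), chunked; ties resolve to
# the lowest donor index so results are order-stable
.knnIndices <- function(query, donor, k = 1L) {
  nq <- nrow(query)
  out <- matrix(0L, nq, k)
  d2d <- rowSums(donor^2)
  chunk <- max(1L, floor(2e7 / max(1L, nrow(donor))))
  for (s in seq(1, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1)
    q <- query[s:e, , drop = FALSE]
    d <- outer(rowSums(q^2), d2d, "+") - 2 * (q %*% t(donor))
    if (k == 1L) {
      out[s:e, 1] <- max.col(-d, ties.method = "first")
    } else {
      out[s:e, ] <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
    }
  }
  out
}

#' Merge tubes on their backbone markers
#'
#' @param tubes list of \linkS4class{EventTable} sharing the backbone
#'   channels.
#' @param backboneChannels character vector of shared channel names (see
#'   [backboneChannels()]).
#' @param k neighbours to average (default 1, nearest neighbour).
#' @param reference index or tube id of the reference tube (default first).
#' @param populationCounts optional named counts; ineligible populations
#'   (< 1000 events) are recorded in the report with a warning.
#' @return list with `events` (the reference \linkS4class{EventTable}
#'   extended by imputed marker columns, provenance in keywords) and
#'   `report` (tube ids, imputed channels with donors, eligibility).
#' @export
mergeAndCalculate <- function(tubes, backboneChannels, k = 1L,
                              reference = 1L, populationCounts = NULL) {
  stopifnot(length(tubes) >= 1)
  ids <- vapply(tubes, tubeId, character(1))
  if (is.character(reference)) reference <- match(reference, ids)
  ref <- tubes[[reference]]
  for (tb in tubes) {
    missing <- setdiff(backboneChannels, channels(tb))
    if (length(missing))
      stop("backbone mismatch: tube ", tubeId(tb), " lacks ",
           paste(missing, collapse = ", "))
  }
  eligibility <- NULL
  if (!is.null(populationCounts)) {
    eligibility <- checkMergeEligibility(populationCounts)
    if (any(!eligibility))
      warning("population(s) ineligible for merged analysis (< 1000 events): ",
              paste(names(eligibility)[!eligibility], collapse = ", "))
  }
  refStd <- .robustScale(exprs(ref)[, backboneChannels, drop = FALSE])
  m <- exprs(ref)
  prov <- list()
  for (di in seq_along(tubes)) {
    if (di == reference) next
    donor <- tubes[[di]]
    newChans <- setdiff(channels(donor),
                        c(colnames(m), backboneChannels, "FS-PEAK"))
    if (!length(newChans)) next
    donorStd <- .robustScale(exprs(donor)[, backboneChannels, drop = FALSE])
    nn <- .knnIndices(refStd, donorStd, k = k)
    dm <- exprs(donor)
    for (ch in newChans) {
      vals <- matrix(dm[nn, ch], nrow = nrow(nn))
      m <- cbind(m, rowMeans(vals))
      colnames(m)[ncol(m)] <- ch
      prov[[paste0("IMPUTED.", ch)]] <- tubeId(donor)
    }
  }
  merged <- EventTable(m, sampleId = sampleId(ref), tubeId = "merged",
                       keywords = c(keywords(ref), prov))
  report <- list(tubes = ids, reference = ids[reference],
                 imputedChannels = prov, eligibility = eligibility, k = k)
  list(events = merged, report = report)
}

#' Imputation noise of the merge procedure
#'
#' Hides a marker that is measured in at least two tubes, re-imputes it in
#' the reference tube from a donor tube, and scores the imputation against
#' the measured values: the median absolute error in FU and the empirical
#' CDF (Kolmogorov-Smirnov) distance.
#'
#' @param tubes list of \linkS4class{EventTable}.
#' @param holdoutMarker marker measured in >= 2 tubes.
#' @param backboneChannels shared backbone channel names.
#' @param k neighbours to average.
#' @return list: `medianAbsError` (FU), `ksDistance`, `holdoutTube`,
#'   `donorTube`, `marker`.
#' @export
mergeNoiseMetric <- function(tubes, holdoutMarker, backboneChannels,
                             k = 1L) {
  chan <- .channelName(holdoutMarker)
  has <- which(vapply(tubes, function(tb)
    !is.na(findChannel(tb, holdoutMarker, required = FALSE)), logical(1)))
  if (length(has) < 2)
    stop("marker ", holdoutMarker, " is not shared by >= 2 tubes")
  refIdx <- has[1]; donorIdx <- has[2]
  ref <- tubes[[refIdx]]
  chanRef <- findChannel(ref, holdoutMarker)
  measured <- exprs(ref)[, chanRef]
  hidden <- ref
  hidden@exprs <- exprs(ref)[, setdiff(channels(ref), chanRef), drop = FALSE]
  res <- mergeAndCalculate(list(hidden, tubes[[donorIdx]]), backboneChannels,
                           k = k, reference = 1L)
  chanDonor <- findChannel(tubes[[donorIdx]], holdoutMarker)
  imputed <- exprs(res$events)[, chanDonor]
  ks <- suppressWarnings(stats::ks.test(imputed, measured))
  list(medianAbsError = stats::median(abs(imputed - measured)),
       ksDistance = unname(ks$statistic),
       holdoutTube = tubeId(ref), donorTube = tubeId(tubes[[donorIdx]]),
       marker = holdoutMarker)
}
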