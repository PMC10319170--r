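## Ki-67 / Bcl-2 positivity under four gating strategies.
##
## polygon    - control-anchored adaptive boundary: per-SSC-bin percentile
##              of the control distribution, the deterministic surrogate of
##              a manually drawn polygon following the negative cloud
## rectangle  - control-anchored global threshold x full SSC range
## fixed40    - predefined 40 FU threshold, ignoring controls
## fixed100   - predefined 100 FU threshold, ignoring controls

STRATEGIES <- c("polygon", "rectangle", "fixed40", "fixed100")

#' Construct simple gates
#'
#' @param channelX,channelY channel names.
#' @param xlim,ylim numeric `c(min, max)` limits (may be infinite).
#' @return a \linkS4class{Gate}.
#' @export
rectangleGate <- function(channelX, channelY = NULL, xlim, ylim = NULL) {
  chans <- c(channelX, channelY)
  limits <- list(xlim)
  if (!is.null(channelY)) limits <- c(limits, list(ylim))
  new("Gate", kind = "rectangle", channels = chans,
      params = list(limits = limits))
}

#' @rdname rectangleGate
#' @param channel channel name for a 1-D threshold gate.
#' @param cutoff threshold in FU.
#' @param side `"above"` or `"below"`.
#' @export
thresholdGate <- function(channel, cutoff, side = "above") {
  new("Gate", kind = "threshold1d", channels = channel,
      params = list(cutoff = cutoff, side = side))
}

#' @rdname rectangleGate
#' @param vertices two-column matrix of polygon vertices (simple polygon).
#' @export
polygonGate <- function(channelX, channelY, vertices) {
  new("Gate", kind = "polygon", channels = c(channelX, channelY),
      params = list(vertices = as.matrix(vertices)))
}

.gateMatrix <- function(events) {
  if (is(events, "EventTable")) exprs(events) else as.matrix(events)
}

#' @rdname applyGate
#' @export
setMethod("applyGate", "Gate", function(gate, events) {
  m <- .gateMatrix(events)
  ch <- gate@channels
  missing <- setdiff(ch, colnames(m))
  if (length(missing))
    stop("gate channels absent from events: ", paste(missing, collapse = ", "))
  p <- gate@params
  switch(gate@kind,
    threshold1d = {
      x <- m[, ch[1]]
      if (identical(p$side, "below")) x < p$cutoff else x > p$cutoff
    },
    rectangle = {
      inside <- rep(TRUE, nrow(m))
      for (i in seq_along(ch)) {
        x <- m[, ch[i]]
        inside <- inside & x > p$limits[[i]][1] & x < p$limits[[i]][2]
      }
      inside
    },
    polygon = {
      v <- p$vertices
      .pointsInPolygon(m[, ch[1]], m[, ch[2]], v[, 1], v[, 2])
    },
    binned = {
      x <- m[, ch[1]]                    # marker intensity
      b <- m[, ch[2]]                    # SSC
      bin <- findInterval(b, p$binEdges, all.inside = TRUE)
      x > p$cutoffs[bin]
    })
})

#' Control-derived positivity threshold
#'
#' The cutoff is the stated percentile (default 99.5) of the control
#' distribution on the marker channel, computed as the inverse-ECDF order
#' statistic. Controls are either the IgG1 isotype channels or the
#' marker-negative population as internal biological control.
#'
#' @param controlEvents an \linkS4class{EventTable} (or numeric vector of
#'   control intensities) with at least 500 events.
#' @param marker marker/channel to read when `controlEvents` is a table.
#' @param percentile percentile in (0, 1], default 0.995.
#' @return cutoff in FU.
#' @export
controlThreshold <- function(controlEvents, marker = "Ki-67",
                             percentile = 0.995) {
  vals <- if (is.numeric(controlEvents)) controlEvents
          else markerValues(controlEvents, marker)
  if (length(vals) < 500)
    stop("control insufficiency: ", length(vals),
         " control events (need >= 500)")
  stats::quantile(vals, percentile, names = FALSE, type = 1)
}

#' Build a positivity gate for one strategy
#'
#' `fixed40`/`fixed100` ignore the control and threshold at exactly 40/100
#' FU. `rectangle` is the control threshold x the full SSC range. `polygon`
#' follows the control's per-SSC-bin percentile across equal-count SSC bins
#' of the population (an adaptive boundary, closed into a simple polygon);
#' with fewer than 3 populated bins it falls back to the rectangle with a
#' warning.
#'
#' @param threshold control-derived cutoff in FU (from [controlThreshold()]).
#' @param strategy one of `r toString(STRATEGIES)`.
#' @param populationEvents \linkS4class{EventTable} of the gated population
#'   (defines the SSC binning for the polygon strategy).
#' @param controlValues numeric control intensities aligned with
#'   `controlSsc` (polygon strategy only).
#' @param controlSsc SSC of the control events.
#' @param marker marker whose channel the gate thresholds.
#' @param percentile per-bin percentile for the polygon boundary.
#' @param nBins number of equal-count SSC bins (default 8).
#' @param minPerBin minimum control events per bin before the global
#'   threshold is substituted in that bin.
#' @return a \linkS4class{Gate}.
#' @export
buildStrategyGate <- function(threshold, strategy, populationEvents = NULL,
                              controlValues = NULL, controlSsc = NULL,
                              marker = "Ki-67", percentile = 0.995,
                              nBins = 8, minPerBin = 20) {
  strategy <- match.arg(strategy, STRATEGIES)
  chan <- if (is(populationEvents, "EventTable"))
    findChannel(populationEvents, marker) else .channelName(marker)
  if (strategy == "fixed40") return(thresholdGate(chan, 40))
  if (strategy == "fixed100") return(thresholdGate(chan, 100))
  if (strategy == "rectangle")
    return(rectangleGate(chan, "SSC-INT", xlim = c(threshold, Inf),
                         ylim = c(-Inf, Inf)))
  # polygon: adaptive per-SSC-bin boundary
  ssc <- exprs(populationEvents)[, "SSC-INT"]
  probs <- seq(0, 1, length.out = nBins + 1)
  edges <- unique(stats::quantile(ssc, probs, names = FALSE, type = 7))
  if (length(edges) - 1 < 3 || is.null(controlValues)) {
    warning("fewer than 3 populated SSC bins; polygon falls back to rectangle")
    return(rectangleGate(chan, "SSC-INT", xlim = c(threshold, Inf),
                         ylim = c(-Inf, Inf)))
  }
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  bin <- findInterval(controlSsc, edges, all.inside = TRUE)
  nb <- length(edges) - 1
  cutoffs <- vapply(seq_len(nb), function(b) {
    v <- controlValues[bin == b]
    if (length(v) < minPerBin) threshold
    else stats::quantile(v, percentile, names = FALSE, type = 1)
  }, numeric(1))
  new("Gate", kind = "binned", channels = c(chan, "SSC-INT"),
      params = list(binEdges = edges, cutoffs = cutoffs,
                    threshold = threshold))
}

#' Positive fraction of a population under a gate
#'
#' The exact membership count divided by the population size. Fewer than
#' 100 positive events raises the `insufficient_positives` QC flag (the
#' acquisition rule demands at least 100 positive cells per population);
#' an empty population yields a missing fraction with
#' `insufficient_population`, never 0.
#'
#' @param populationEvents \linkS4class{EventTable} of the gated population.
#' @param marker marker name (bookkeeping).
#' @param gate a \linkS4class{Gate}.
#' @param population,strategy bookkeeping labels.
#' @param minPositives QC minimum (default 100).
#' @return one-row data.frame: `sample_id`, `population`, `marker`,
#'   `strategy`, `positive`, `total`, `fraction`, `qc` (`;`-separated
#'   flags, empty when clean).
#' @export
positiveFraction <- function(populationEvents, marker, gate,
                             population = "", strategy = "",
                             minPositives = 100) {
  total <- nEvents(populationEvents)
  if (total == 0) {
    return(data.frame(sample_id = sampleId(populationEvents),
                      population = population, marker = marker,
                      strategy = strategy, positive = NA_integer_,
                      total = 0L, fraction = NA_real_,
                      qc = "insufficient_population"))
  }
  pos <- sum(applyGate(gate, populationEvents))
  flags <- character(0)
  if (pos < minPositives) flags <- c(flags, "insufficient_positives")
  data.frame(sample_id = sampleId(populationEvents), population = population,
             marker = marker, strategy = strategy, positive = as.integer(pos),
             total = as.integer(total), fraction = pos / total,
             qc = paste(flags, collapse = ";"))
}

# negative-population internal control: values below the marker's density
# valley (the whole population when unimodal, i.e. mostly negative)
.internalNegative <- function(vals) {
  v <- valleyThreshold(vals)
  if (!is.na(v$threshold)) vals[vals < v$threshold] else vals
}

.controlChannelFor <- function(marker) {
  if (marker == "Ki-67") "IgG1-FITC" else "IgG1-PE"
}

#' Compute all Ki-67 / Bcl-2 indices of one sample
#'
#' For each of the four gated populations x two markers x four strategies
#' (32 results): the control threshold is derived per population - from the
#' IgG1 isotype channels when present/selected, else from the population's
#' own marker-negative events - and the positive fraction is computed with
#' QC flags.
#'
#' @param ev the gated \linkS4class{EventTable} (must carry Ki-67/Bcl-2
#'   channels).
#' @param masks named list of population masks from [gateSample()].
#' @param controlSource `"isotype"` (preferred when isotype channels are
#'   available, as after tube merging) or `"internal_negative"`.
#' @param isotype optional \linkS4class{EventTable} aligned event-for-event
#'   with `ev` carrying the IgG1 channels (e.g. the isotype tube of the
#'   same case, or a merged table); defaults to `ev` itself when it has
#'   them.
#' @param percentile control percentile (default 0.995).
#' @param strategies subset of `r toString(STRATEGIES)`.
#' @param minControl controls below this size add a `control_insufficient`
#'   flag (threshold still computed).
#' @return data.frame of stacked [positiveFraction()] rows.
#' @export
computeAllIndices <- function(ev, masks,
                              controlSource = c("internal_negative",
                                                "isotype"),
                              isotype = NULL, percentile = 0.995,
                              strategies = STRATEGIES, minControl = 500) {
  controlSource <- match.arg(controlSource)
  if (is.null(isotype) &&
      !is.na(findChannel(ev, "IgG1-FITC", required = FALSE)))
    isotype <- ev
  if (controlSource == "isotype" && is.null(isotype))
    stop("isotype controls requested but no isotype channels available")
  out <- list()
  for (popName in names(masks)) {
    mv <- maskVector(masks[[popName]])
    popEv <- ev[mv]
    for (marker in c("Ki-67", "Bcl-2")) {
      markerVals <- if (nEvents(popEv)) markerValues(popEv, marker)
                    else numeric(0)
      if (controlSource == "isotype") {
        iso <- isotype[mv]
        igF <- markerValues(iso, "IgG1-FITC")
        igP <- markerValues(iso, "IgG1-PE")
        # events jointly high on both isotype channels are autofluorescent
        # (e.g. eosinophil-derived after merging) and are excluded from the
        # control before the threshold percentile is taken
        auto <- if (length(igF) >= 10)
          igF > .positivityCutoff(igF) & igP > .positivityCutoff(igP)
        else rep(FALSE, length(igF))
        keep <- which(!auto)
        vals <- if (marker == "Ki-67") igF else igP
        ctrl <- vals[keep]
        ctrlSsc <- if (nEvents(iso)) exprs(iso)[keep, "SSC-INT"]
                   else numeric(0)
      } else {
        v <- valleyThreshold(markerVals)
        negCut <- if (is.na(v$threshold)) Inf else v$threshold
        negIdx <- which(markerVals < negCut)
        ctrl <- markerVals[negIdx]
        ctrlSsc <- if (nEvents(popEv)) exprs(popEv)[negIdx, "SSC-INT"]
                   else numeric(0)
      }
      flags <- if (length(ctrl) < minControl) "control_insufficient" else NULL
      thr <- if (length(ctrl))
        stats::quantile(ctrl, percentile, names = FALSE, type = 1)
        else Inf
      for (strategy in strategies) {
        anchored <- strategy %in% c("polygon", "rectangle")
        g <- if (nEvents(popEv) == 0 || (anchored && !is.finite(thr)))
          thresholdGate(if (nEvents(popEv)) findChannel(popEv, marker)
                        else .channelName(marker), Inf)
        else if (strategy == "polygon" && nEvents(popEv) >= 3)
          suppressWarnings(
            buildStrategyGate(thr, strategy, popEv, controlValues = ctrl,
                              controlSsc = ctrlSsc, marker = marker,
                              percentile = percentile))
        else
          buildStrategyGate(thr,
                            if (strategy == "polygon") "rectangle" else strategy,
                            popEv, marker = marker)
        row <- positiveFraction(popEv, marker, g, population = popName,
                                strategy = strategy)
        if (!is.null(flags) && nzchar(row$qc))
          row$qc <- paste(row$qc, flags, sep = ";")
        else if (!is.null(flags)) row$qc <- flags
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
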