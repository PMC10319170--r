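#' EventTable: per-event fluorescence and scatter intensities
#'
#' The central event-level container: an N x C matrix of intensities on a
#' linear fluorescence-unit (FU) scale, with unique channel names, a sample
#' and tube identity, and free-form acquisition keywords (FCS TEXT segment
#' keys on file-derived tables).
#'
#' @slot exprs numeric matrix (events x channels); all values finite.
#' @slot sampleId character scalar.
#' @slot tubeId character scalar.
#' @slot keywords named list of acquisition metadata.
#'
#' @seealso [readFCS()], [writeFCS()], [applyCompensation()]
#' @export
setClass("EventTable",
  representation(exprs = "matrix", sampleId = "character",
                 tubeId = "character", keywords = "list"),
  prototype(exprs = matrix(numeric(0), 0, 0), sampleId = NA_character_,
            tubeId = NA_character_, keywords = list()))

setValidity("EventTable", function(object) {
  m <- object@exprs
  if (!is.numeric(m)) return("exprs must be a numeric matrix")
  cn <- colnames(m)
  if (ncol(m) > 0 && is.null(cn)) return("channels must be named")
  if (anyDuplicated(cn)) return("channel names must be unique")
  if (length(m) && !all(is.finite(m))) return("all intensities must be finite")
  if (length(object@sampleId) != 1L || length(object@tubeId) != 1L)
    return("sampleId and tubeId must be scalars")
  TRUE
})

#' Construct an EventTable
#'
#' @param values numeric matrix, events in rows; column names are the channel
#'   names (e.g. `"CD45-KO"`, `"FSC-INT"`).
#' @param sampleId,tubeId identifiers carried through the pipeline.
#' @param keywords named list of acquisition metadata.
#' @param channels optional channel names overriding `colnames(values)`.
#' @return an \linkS4class{EventTable}.
#' @examples
#' ev <- EventTable(matrix(c(1, 3, 2, 4), 2, 2,
#'                         dimnames = list(NULL, c("FSC-INT", "SSC-INT"))))
#' nEvents(ev)
#' @export
EventTable <- function(values, sampleId = "sample", tubeId = "1",
                       keywords = list(), channels = NULL) {
  values <- as.matrix(values)
  if (!is.null(channels)) colnames(values) <- channels
  storage.mode(values) <- "double"
  new("EventTable", exprs = values, sampleId = as.character(sampleId),
      tubeId = as.character(tubeId), keywords = keywords)
}

#' @rdname exprs
#' @export
setMethod("exprs", "EventTable", function(object) object@exprs)

#' @rdname channels
#' @export
setMethod("channels", "EventTable", function(object) colnames(object@exprs))

#' @rdname nEvents
#' @export
setMethod("nEvents", "EventTable", function(object) nrow(object@exprs))

#' @rdname sampleId
#' @export
setMethod("sampleId", "EventTable", function(object) object@sampleId)

#' @rdname tubeId
#' @export
setMethod("tubeId", "EventTable", function(object) object@tubeId)

#' @rdname keywords
#' @export
setMethod("keywords", "EventTable", function(object) object@keywords)

setMethod("show", "EventTable", function(object) {
  cat("EventTable:", object@sampleId, "tube", object@tubeId, "\n")
  cat(" ", nrow(object@exprs), "events x", ncol(object@exprs), "channels\n")
  cat("  channels:", paste(colnames(object@exprs), collapse = ", "), "\n")
})

#' Subset an EventTable by events
#'
#' @param x an \linkS4class{EventTable}.
#' @param i logical or integer event selector.
#' @param j unused.
#' @param ... unused.
#' @param drop unused.
#' @return an \linkS4class{EventTable} containing the selected events.
#' @export
setMethod("[", "EventTable", function(x, i, j, ..., drop = FALSE) {
  new("EventTable", exprs = x@exprs[i, , drop = FALSE], sampleId = x@sampleId,
      tubeId = x@tubeId, keywords = x@keywords)
})

#' PanelDefinition: tube-to-marker mapping with backbone groups
#'
#' @slot tubes named list; each element a data.frame with columns `marker`,
#'   `fluorochrome`, `channel`.
#' @slot backboneGroups named list; each element `list(tubes=, markers=)`
#'   where every backbone marker occurs in every tube of the group.
#' @export
setClass("PanelDefinition",
  representation(tubes = "list", backboneGroups = "list"))

setValidity("PanelDefinition", function(object) {
  if (anyDuplicated(names(object@tubes))) return("tube ids must be unique")
  for (g in object@backboneGroups) {
    for (tb in g$tubes) {
      tab <- object@tubes[[tb]]
      if (is.null(tab)) return(sprintf("backbone group names unknown tube %s", tb))
      scatter <- c("FSC", "SSC")
      need <- setdiff(g$markers, scatter)
      if (!all(toupper(need) %in% toupper(tab$marker)))
        return(sprintf("tube %s lacks a backbone marker of its group", tb))
    }
  }
  TRUE
})

setMethod("show", "PanelDefinition", function(object) {
  cat("PanelDefinition:", length(object@tubes), "tubes,",
      length(object@backboneGroups), "backbone groups\n")
  for (tb in names(object@tubes))
    cat(sprintf("  tube %s: %s\n", tb,
                paste(object@tubes[[tb]]$marker, collapse = ", ")))
})

#' Gate: a geometric event-selection region
#'
#' Kinds: `"rectangle"` (axis-aligned box on 1-2 channels), `"polygon"`
#' (simple polygon on 2 channels), `"threshold1d"` (one-sided cutoff on one
#' channel), and `"binned"` (per-SSC-bin adaptive threshold boundary used by
#' the control-anchored polygon strategy; representable as a polygon).
#'
#' @slot kind character scalar.
#' @slot channels character, 1 or 2 channel names.
#' @slot params list of geometry parameters (see [rectangleGate()],
#'   [polygonGate()], [thresholdGate()]).
#' @export
setClass("Gate",
  representation(kind = "character", channels = "character", params = "list"))

setValidity("Gate", function(object) {
  k <- object@kind
  if (!k %in% c("rectangle", "polygon", "threshold1d", "binned"))
    return("unknown gate kind")
  if (k == "polygon") {
    v <- object@params$vertices
    if (is.null(v) || nrow(v) < 3) return("polygon needs >= 3 vertices")
    if (.polygonSelfIntersects(v)) return("polygon must be simple")
  }
  if (k == "rectangle") {
    lim <- object@params$limits
    for (l in lim) if (l[1] >= l[2]) return("rectangle needs min < max per axis")
  }
  TRUE
})

setMethod("show", "Gate", function(object) {
  cat("Gate[", object@kind, "] on",
      paste(object@channels, collapse = " x "), "\n")
})

#' CaseProfile: the latent composition of one synthetic bone-marrow sample
#'
#' @slot caseId character scalar.
#' @slot cohort one of `"non_malignant"`, `"MDS"`, `"AML"`.
#' @slot age numeric, years.
#' @slot sex `"M"` or `"F"`.
#' @slot targetFractions named numeric, percentages of relevant events per
#'   population (`blast`, `erythroid`, `myeloid`, `monocytic` plus nuisance
#'   `lymphoid`, `eosinophil`, `platelet`, `doublet`) and `debris` as a
#'   percentage of total acquired events; sum of relevant-event percentages
#'   must not exceed 100.
#' @slot truePositiveFractions numeric matrix populations x markers
#'   (`Ki-67`, `Bcl-2`), latent per-event positivity probabilities in [0,1].
#' @slot nEvents integer, total events to draw.
#' @slot autofluorescenceShift named numeric, additive FU offset applied to
#'   the FITC and PE-CF594 channels of the named populations.
#' @export
setClass("CaseProfile",
  representation(caseId = "character", cohort = "character", age = "numeric",
                 sex = "character", targetFractions = "numeric",
                 truePositiveFractions = "matrix", nEvents = "integer",
                 autofluorescenceShift = "numeric"))

setValidity("CaseProfile", function(object) {
  f <- object@targetFractions
  if (any(f < 0)) return("fractions must be non-negative")
  rel <- f[setdiff(names(f), "debris")]
  if (sum(rel) > 100 + 1e-8) return("relevant-event fractions sum above 100%")
  if (object@nEvents <= 0L) return("nEvents must be positive")
  tp <- object@truePositiveFractions
  if (length(tp) && (any(tp < 0) || any(tp > 1)))
    return("true positive fractions must lie in [0,1]")
  if (!object@cohort %in% c("non_malignant", "MDS", "AML"))
    return("unknown cohort")
  TRUE
})

setMethod("show", "CaseProfile", function(object) {
  cat("CaseProfile", object@caseId, sprintf("(%s, age %g, %s)\n",
      object@cohort, object@age, object@sex))
  f <- object@targetFractions
  cat("  targets (% relevant):",
      paste(sprintf("%s=%.1f", names(f), f), collapse = " "), "\n")
  cat("  nEvents:", object@nEvents, "\n")
})

#' GroundTruth: latent labels behind a synthetic sample
#'
#' @slot label character vector, per-event population label.
#' @slot ki67Positive,bcl2Positive logical vectors, latent positivity.
#' @slot trueFractions named numeric, exact labelled fractions (% of
#'   relevant events) for the four reported populations.
#' @export
setClass("GroundTruth",
  representation(label = "character", ki67Positive = "logical",
                 bcl2Positive = "logical", trueFractions = "numeric"))

setValidity("GroundTruth", function(object) {
  n <- length(object@label)
  if (length(object@ki67Positive) != n || length(object@bcl2Positive) != n)
    return("positivity flags must match label length")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@label), "events\n")
  print(round(object@trueFractions, 2))
})
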