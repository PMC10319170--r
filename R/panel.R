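## Default 7-tube antibody panel. Backbone sets follow the published design:
## tubes 1/2/5 share FSC, SSC, CD13, CD34, CD45, CD117, HLA-DR and tubes
## 3/4/6/7 share FSC, SSC, CD33, CD45, CD117, HLA-DR. Tube 7 carries the
## IgG1 isotype controls on the Ki-67/Bcl-2 fluorochromes (FITC / PE-CF594).

.SCATTER_CHANNELS <- c("FSC-INT", "SSC-INT", "FS-PEAK")

.MARKER_FLUO <- c(
  "CD45" = "KO", "CD34" = "ECD", "CD13" = "PC5.5", "CD33" = "PC5.5",
  "CD117" = "PE-Cy7", "HLA-DR" = "PB", "CD36" = "APC", "CD71" = "APC-A700",
  "CD235a" = "APC-A750", "CD14" = "APC", "CD10" = "APC-A700",
  "CD11b" = "APC-A750", "Ki-67" = "FITC", "Bcl-2" = "PE-CF594",
  "IgG1-FITC" = "FITC", "IgG1-PE" = "PE-CF594")

.channelName <- function(marker) {
  if (marker == "IgG1-FITC") return("IgG1-FITC")
  if (marker == "IgG1-PE") return("IgG1-PE-CF594")
  paste0(marker, "-", .MARKER_FLUO[[marker]])
}

.tubeTable <- function(markers) {
  data.frame(marker = markers,
             fluorochrome = unname(.MARKER_FLUO[markers]),
             channel = vapply(markers, .channelName, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default 7-tube panel definition
#'
#' Two backbone groups: tubes 1, 2 and 5 share FSC, SSC, CD13, CD34, CD45,
#' CD117 and HLA-DR; tubes 3, 4, 6 and 7 share FSC, SSC, CD33, CD45, CD117
#' and HLA-DR. Tubes 1-6 carry Ki-67 (FITC) and Bcl-2 (PE-CF594); tube 7
#' carries the matched IgG1 isotype controls on the same fluorochromes.
#'
#' @return a \linkS4class{PanelDefinition}.
#' @export
defaultPanel <- function() {
  bbA <- c("CD13", "CD34", "CD45", "CD117", "HLA-DR")
  bbB <- c("CD33", "CD45", "CD117", "HLA-DR")
  ki <- c("Ki-67", "Bcl-2")
  tubes <- list(
    "1" = .tubeTable(c(bbA, "CD36", "CD71", "CD235a", ki)),
    "2" = .tubeTable(c(bbA, "CD14", "CD10", "CD11b", ki)),
    "3" = .tubeTable(c(bbB, "CD14", ki)),
    "4" = .tubeTable(c(bbB, "CD36", "CD71", ki)),
    "5" = .tubeTable(c(bbA, ki)),
    "6" = .tubeTable(c(bbB, "CD10", "CD11b", ki)),
    "7" = .tubeTable(c(bbB, "IgG1-FITC", "IgG1-PE")))
  groups <- list(
    A = list(tubes = c("1", "2", "5"),
             markers = c("FSC", "SSC", "CD13", "CD34", "CD45", "CD117",
                         "HLA-DR")),
    B = list(tubes = c("3", "4", "6", "7"),
             markers = c("FSC", "SSC", "CD33", "CD45", "CD117", "HLA-DR")))
  new("PanelDefinition", tubes = tubes, backboneGroups = groups)
}

#' Accessors for PanelDefinition
#' @param panel a \linkS4class{PanelDefinition}.
#' @return `panelTubes`: named list of tube marker tables; `backboneGroups`:
#'   named list of `list(tubes=, markers=)`.
#' @export
panelTubes <- function(panel) panel@tubes

#' @rdname panelTubes
#' @export
backboneGroups <- function(panel) panel@backboneGroups

#' Backbone channel names for a tube group
#' @param panel a \linkS4class{PanelDefinition}.
#' @param group group id (e.g. `"A"` or `"B"`).
#' @return character vector of channel names for the group's backbone
#'   markers (scatter mapped to integral channels).
#' @export
backboneChannels <- function(panel, group) {
  g <- panel@backboneGroups[[group]]
  if (is.null(g)) stop("unknown backbone group: ", group)
  vapply(g$markers, function(mk) {
    if (mk == "FSC") "FSC-INT" else if (mk == "SSC") "SSC-INT"
    else .channelName(mk)
  }, character(1), USE.NAMES = FALSE)
}

#' Find the channel measuring a marker
#'
#' Marker matching is case-insensitive on the marker part of the
#' `<marker>-<fluorochrome>` channel name; `"FSC"`/`"SSC"` map to the
#' integral scatter channels.
#'
#' @param events an \linkS4class{EventTable} or character vector of channel
#'   names.
#' @param marker marker name (e.g. `"CD45"`, `"HLA-DR"`, `"Ki-67"`).
#' @param required error (TRUE) or return NA (FALSE) when absent.
#' @return the matching channel name.
#' @export
findChannel <- function(events, marker, required = TRUE) {
  chans <- if (is(events, "EventTable")) channels(events) else events
  mk <- toupper(marker)
  if (mk == "FSC") mk <- "FSC-INT"
  if (mk == "SSC") mk <- "SSC-INT"
  up <- toupper(chans)
  hit <- which(up == mk | startsWith(up, paste0(mk, "-")))
  if (!length(hit)) {
    if (required) stop("required channel absent: no channel measures ", marker)
    return(NA_character_)
  }
  chans[hit[1]]
}

#' Marker intensities of an EventTable
#' @param events an \linkS4class{EventTable}.
#' @param marker marker name resolved via [findChannel()].
#' @return numeric vector of intensities.
#' @export
markerValues <- function(events, marker) {
  exprs(events)[, findChannel(events, marker)]
}
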