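## Minimal Gating-ML 2.0 export/import for the package's own gate kinds:
## rectangle and 1-D threshold gates map to RectangleGate dimensions,
## polygon and binned (adaptive-boundary) gates to PolygonGate vertices.

.GML_NS <- c(gating = "http://www.isac-net.org/std/Gating-ML/v2.0/gating",
             `data-type` = "http://www.isac-net.org/std/Gating-ML/v2.0/datatypes")

# binned adaptive boundary -> closed staircase polygon in (SSC, marker)
.binnedAsPolygon <- function(gate, ymax = 1e6) {
  p <- gate@params
  e <- p$binEdges
  lo <- min(e[is.finite(e)]) - 1
  hi <- max(e[is.finite(e)]) + 1
  xs <- pmin(pmax(e, lo), hi)
  vx <- numeric(0); vy <- numeric(0)
  for (b in seq_along(p$cutoffs)) {
    vx <- c(vx, xs[b], xs[b + 1])
    vy <- c(vy, p$cutoffs[b], p$cutoffs[b])
  }
  cbind(c(vx, hi, lo), c(vy, ymax, ymax))
}

#' Export gates as Gating-ML 2.0
#'
#' @param gates named list of \linkS4class{Gate} objects.
#' @param path output XML path.
#' @return `path`, invisibly.
#' @export
exportGatingML <- function(gates, path) {
  root <- xml2::xml_new_root("gating:Gating-ML",
                             "xmlns:gating" = .GML_NS[["gating"]],
                             "xmlns:data-type" = .GML_NS[["data-type"]])
  for (nm in names(gates)) {
    g <- gates[[nm]]
    if (g@kind %in% c("rectangle", "threshold1d")) {
      node <- xml2::xml_add_child(root, "gating:RectangleGate",
                                  "gating:id" = nm)
      lims <- if (g@kind == "rectangle") g@params$limits
              else list(if (identical(g@params$side, "below"))
                          c(-Inf, g@params$cutoff)
                        else c(g@params$cutoff, Inf))
      for (i in seq_along(g@channels)) {
        attrs <- list()
        if (is.finite(lims[[i]][1])) attrs[["gating:min"]] <- lims[[i]][1]
        if (is.finite(lims[[i]][2])) attrs[["gating:max"]] <- lims[[i]][2]
        dim <- xml2::xml_add_child(node, "gating:dimension")
        for (an in names(attrs)) xml2::xml_set_attr(dim, an, attrs[[an]])
        fd <- xml2::xml_add_child(dim, "data-type:fcs-dimension")
        xml2::xml_set_attr(fd, "data-type:name", g@channels[i])
      }
    } else {
      v <- if (g@kind == "binned") .binnedAsPolygon(g)
           else g@params$vertices
      chans <- if (g@kind == "binned") rev(g@channels) else g@channels
      node <- xml2::xml_add_child(root, "gating:PolygonGate",
                                  "gating:id" = nm)
      for (ch in chans) {
        dim <- xml2::xml_add_child(node, "gating:dimension")
        fd <- xml2::xml_add_child(dim, "data-type:fcs-dimension")
        xml2::xml_set_attr(fd, "data-type:name", ch)
      }
      for (i in seq_len(nrow(v))) {
        vert <- xml2::xml_add_child(node, "gating:vertex")
        for (coord in v[i, ]) {
          cn <- xml2::xml_add_child(vert, "gating:coordinate")
          xml2::xml_set_attr(cn, "data-type:value", coord)
        }
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Import gates from Gating-ML 2.0
#'
#' Reads RectangleGate (as rectangle or 1-D threshold) and PolygonGate
#' elements written by [exportGatingML()] or compatible tools.
#'
#' @param path XML path.
#' @return named list of \linkS4class{Gate} objects.
#' @export
importGatingML <- function(path) {
  doc <- xml2::read_xml(path)
  out <- list()
  for (node in xml2::xml_children(doc)) {
    nm <- xml2::xml_attr(node, "id")
    tag <- xml2::xml_name(node)
    dims <- xml2::xml_find_all(node, "./*[local-name()='dimension']")
    chans <- vapply(dims, function(d) {
      fd <- xml2::xml_find_first(d, "./*[local-name()='fcs-dimension']")
      xml2::xml_attr(fd, "name")
    }, character(1))
    if (tag == "RectangleGate") {
      lims <- lapply(dims, function(d) {
        lo <- xml2::xml_attr(d, "min"); hi <- xml2::xml_attr(d, "max")
        c(if (is.na(lo)) -Inf else as.numeric(lo),
          if (is.na(hi)) Inf else as.numeric(hi))
      })
      g <- if (length(chans) == 1 && sum(is.finite(lims[[1]])) == 1) {
        if (is.finite(lims[[1]][1])) thresholdGate(chans, lims[[1]][1])
        else thresholdGate(chans, lims[[1]][2], side = "below")
      } else if (length(chans) == 1) {
        new("Gate", kind = "rectangle", channels = chans,
            params = list(limits = lims))
      } else {
        rectangleGate(chans[1], chans[2], xlim = lims[[1]],
                      ylim = lims[[2]])
      }
    } else {
      verts <- xml2::xml_find_all(node, "./*[local-name()='vertex']")
      v <- t(vapply(verts, function(vt) {
        as.numeric(xml2::xml_attr(
          xml2::xml_find_all(vt, "./*[local-name()='coordinate']"), "value"))
      }, numeric(2)))
      g <- polygonGate(chans[1], chans[2], v)
    }
    out[[nm]] <- g
  }
  out
}
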