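## FCS 3.0/3.1 event-file I/O.
## Layout per the FCS standard: a 58-byte ASCII HEADER with segment offsets,
## a delimited TEXT segment of $-keywords, and a binary DATA segment.
## Beckman Coulter LMD files concatenate an FCS 2.0 and an FCS 3.0 dataset;
## the reader follows $NEXTDATA to the FCS 3.0 one by default.

.readHeader <- function(raw, offset) {
  if (length(raw) < offset + 58)
    stop("FCS parse error: file too short for HEADER segment")
  hdr <- rawToChar(raw[(offset + 1):(offset + 58)])
  version <- substr(hdr, 1, 6)
  if (!grepl("^FCS[0-9]\\.[0-9]$", version))
    stop("FCS parse error: bad version string in HEADER: ", version)
  num <- function(a, b) {
    s <- trimws(substr(hdr, a, b))
    if (s == "") 0L else suppressWarnings(as.integer(s))
  }
  off <- c(textBegin = num(11, 18), textEnd = num(19, 26),
           dataBegin = num(27, 34), dataEnd = num(35, 42))
  if (any(is.na(off)))
    stop("FCS parse error: non-numeric segment offset in HEADER")
  list(version = version, offsets = off)
}

.parseText <- function(raw, begin, end) {
  if (end <= begin) stop("FCS parse error: empty TEXT segment")
  delim <- rawToChar(raw[begin + 1])
  body <- rawToChar(raw[(begin + 2):(end + 1)])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # trailing delimiter produces a final empty element; drop it
  if (length(parts) %% 2 == 1 && parts[length(parts)] == "")
    parts <- parts[-length(parts)]
  if (length(parts) %% 2 == 1)
    stop("FCS parse error: unpaired keyword in TEXT segment")
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  stats::setNames(as.list(vals), trimws(keys))
}

.kw <- function(kws, name, default = NULL) {
  hit <- which(toupper(names(kws)) == toupper(name))
  if (length(hit)) kws[[hit[1]]] else default
}

.readDataset <- function(raw, offset) {
  hd <- .readHeader(raw, offset)
  off <- hd$offsets
  kws <- .parseText(raw, offset + off["textBegin"], offset + off["textEnd"])

  nextData <- as.integer(.kw(kws, "$NEXTDATA", "0"))
  tot <- as.integer(.kw(kws, "$TOT", NA))
  par <- as.integer(.kw(kws, "$PAR", NA))
  if (is.na(tot) || is.na(par))
    stop("FCS parse error: missing required keyword $TOT or $PAR")

  dataBegin <- off["dataBegin"]
  dataEnd <- off["dataEnd"]
  if (dataBegin == 0) {
    dataBegin <- as.integer(.kw(kws, "$BEGINDATA", "0"))
    dataEnd <- as.integer(.kw(kws, "$ENDDATA", "0"))
  }
  dtype <- toupper(.kw(kws, "$DATATYPE", "F"))
  byteord <- .kw(kws, "$BYTEORD", "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  chans <- character(par)
  bits <- integer(par)
  amp <- vector("list", par)
  gain <- numeric(par)
  rng <- numeric(par)
  for (p in seq_len(par)) {
    chans[p] <- .kw(kws, sprintf("$P%dN", p), sprintf("P%d", p))
    bits[p] <- as.integer(.kw(kws, sprintf("$P%dB", p), "32"))
    e <- .kw(kws, sprintf("$P%dE", p), "0,0")
    amp[[p]] <- as.numeric(strsplit(e, ",", fixed = TRUE)[[1]])
    gain[p] <- as.numeric(.kw(kws, sprintf("$P%dG", p), "1"))
    rng[p] <- as.numeric(.kw(kws, sprintf("$P%dR", p), "262144"))
  }

  nvals <- tot * par
  if (nvals > 0) {
    bytesPer <- if (dtype == "D") 8L else if (dtype == "I") bits / 8L else 4L
    need <- if (dtype == "I") tot * sum(bytesPer) else nvals * bytesPer[1]
    avail <- dataEnd - dataBegin + 1
    if (avail < need)
      stop("FCS integrity error: $TOT inconsistent with DATA segment length")
    con <- raw[(offset + dataBegin + 1):(offset + dataBegin + need)]
    if (dtype == "F") {
      vals <- readBin(con, "double", n = nvals, size = 4, endian = endian)
    } else if (dtype == "D") {
      vals <- readBin(con, "double", n = nvals, size = 8, endian = endian)
    } else if (dtype == "I") {
      if (length(unique(bits)) != 1L)
        stop("FCS parse error: mixed $PnB integer widths unsupported")
      vals <- readBin(con, "integer", n = nvals, size = bits[1],
                      endian = endian, signed = bits[1] > 16)
      if (bits[1] <= 16) vals <- as.numeric(vals)
    } else stop("FCS parse error: unsupported $DATATYPE ", dtype)
    m <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  } else {
    m <- matrix(numeric(0), 0, par)
  }

  # $PnE log amplification / $PnG gain -> linear fluorescence units
  for (p in seq_len(par)) {
    a <- amp[[p]]
    if (length(a) >= 1 && !is.na(a[1]) && a[1] > 0) {
      f2 <- if (length(a) >= 2 && a[2] > 0) a[2] else 1
      m[, p] <- f2 * 10^(a[1] * m[, p] / rng[p])
    } else if (!is.na(gain[p]) && gain[p] != 1 && gain[p] > 0) {
      m[, p] <- m[, p] / gain[p]
    }
  }
  colnames(m) <- chans
  list(version = hd$version, matrix = m, keywords = kws, nextData = nextData)
}

#' Read an FCS event file
#'
#' Reads FCS 3.0/3.1 files as well as the Beckman Coulter LMD dialect, in
#' which an FCS 2.0 dataset is followed by an FCS 3.0 dataset holding the
#' same events; by default the FCS 3.x dataset is returned.
#'
#' @param path path to an FCS/LMD file.
#' @param dataset `"auto"` (follow `$NEXTDATA` to the first FCS 3.x dataset)
#'   or a 1-based dataset index to force.
#' @return an \linkS4class{EventTable}; intensities are converted to linear
#'   fluorescence units per the `$PnE`/`$PnG` keywords.
#' @examples
#' f <- tempfile(fileext = ".fcs")
#' writeFCS(EventTable(matrix(c(1, 3, 2, 4), 2, 2,
#'                            dimnames = list(NULL, c("A", "B")))), f)
#' exprs(readFCS(f))
#' @export
readFCS <- function(path, dataset = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  sets <- list()
  offset <- 0
  repeat {
    ds <- .readDataset(raw, offset)
    sets[[length(sets) + 1L]] <- ds
    if (ds$nextData <= 0) break
    offset <- offset + ds$nextData
    if (length(sets) > 16) stop("FCS parse error: runaway $NEXTDATA chain")
  }
  if (identical(dataset, "auto")) {
    pick <- which(vapply(sets, function(d) d$version >= "FCS3.0", logical(1)))
    pick <- if (length(pick)) pick[1] else 1L
  } else {
    pick <- as.integer(dataset)
    if (pick < 1 || pick > length(sets))
      stop("dataset index out of range: file has ", length(sets), " dataset(s)")
  }
  ds <- sets[[pick]]
  kws <- ds$keywords
  EventTable(ds$matrix,
             sampleId = .kw(kws, "SAMPLEID", .kw(kws, "$FIL", "sample")),
             tubeId = .kw(kws, "TUBEID", .kw(kws, "$SMNO", "1")),
             keywords = kws)
}

#' Write an EventTable as FCS 3.1
#'
#' Events are written as little-endian 32-bit floats on the linear scale
#' (`$DATATYPE/F`, `$PnE/0,0`), so read/write round-trips are value-preserving
#' to float32 precision.
#'
#' @param table an \linkS4class{EventTable}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFCS <- function(table, path) {
  stopifnot(is(table, "EventTable"))
  m <- exprs(table)
  n <- nrow(m); p <- ncol(m)
  d <- "/"
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p),
          "SAMPLEID", sampleId(table), "TUBEID", tubeId(table))
  for (j in seq_len(p)) {
    rj <- max(262144, 2^ceiling(log2(max(1, m[, j]) + 1)))
    kv <- c(kv, sprintf("$P%dN", j), colnames(m)[j],
            sprintf("$P%dB", j), "32", sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), format(rj, scientific = FALSE))
  }
  extra <- table@keywords
  extra <- extra[!grepl("^\\$", names(extra)) &
                 !names(extra) %in% c("SAMPLEID", "TUBEID")]
  for (nm in names(extra))
    kv <- c(kv, nm, as.character(extra[[nm]]))

  nbytes <- n * p * 4
  # fixed-width $BEGINDATA/$ENDDATA so TEXT length is stable while offsets
  # are being computed
  pad <- function(x) formatC(x, width = 10, flag = "0", format = "d")
  buildText <- function(db, de) {
    paste0(d, paste(c("$BEGINDATA", pad(db), "$ENDDATA", pad(de), kv),
                    collapse = d), d)
  }
  textBegin <- 58L
  probe <- buildText(0, 0)
  dataBegin <- textBegin + nchar(probe)
  dataEnd <- if (nbytes > 0) dataBegin + nbytes - 1 else 0
  if (nbytes == 0) dataBegin <- 0
  text <- buildText(dataBegin, dataEnd)
  textEnd <- textBegin + nchar(text) - 1

  h8 <- function(x) formatC(x, width = 8, format = "d")
  hdrOff <- if (dataEnd <= 99999999)
    paste0(h8(textBegin), h8(textEnd), h8(dataBegin), h8(dataEnd),
           h8(0), h8(0))
  else paste0(h8(textBegin), h8(textEnd), h8(0), h8(0), h8(0), h8(0))
  header <- paste0("FCS3.1    ", hdrOff)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (nbytes > 0)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

#' SpilloverMatrix: fluorochrome spillover coefficients
#'
#' @slot coefficients square numeric matrix with unit diagonal and
#'   non-negative entries; row/column names are fluorescence channel names.
#'   Entry (i, j) is the fraction of channel i's signal observed in channel j.
#' @export
setClass("SpilloverMatrix", representation(coefficients = "matrix"))

setValidity("SpilloverMatrix", function(object) {
  m <- object@coefficients
  if (nrow(m) != ncol(m)) return("spillover matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("spillover matrix needs matching channel row/column names")
  if (any(abs(diag(m) - 1) > 1e-9)) return("spillover diagonal must be 1")
  if (any(m < 0)) return("spillover entries must be non-negative")
  if (abs(det(m)) < 1e-12) return("spillover matrix is singular")
  TRUE
})

#' Construct a SpilloverMatrix
#' @param coefficients square numeric matrix; see \linkS4class{SpilloverMatrix}.
#' @param channels optional channel names.
#' @return a \linkS4class{SpilloverMatrix}.
#' @export
SpilloverMatrix <- function(coefficients, channels = NULL) {
  coefficients <- as.matrix(coefficients)
  if (!is.null(channels)) dimnames(coefficients) <- list(channels, channels)
  new("SpilloverMatrix", coefficients = coefficients)
}

#' Read a spillover matrix from CSV
#'
#' The CSV has a header row of fluorescence channel names and a square
#' numeric body of spill coefficients.
#'
#' @param path CSV path.
#' @return a \linkS4class{SpilloverMatrix}.
#' @export
readSpillover <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab)
  rownames(m) <- colnames(m)
  SpilloverMatrix(m)
}

#' Apply spillover compensation
#'
#' Replaces the fluorescence columns named in the spillover matrix by
#' `observed %*% solve(spill)`; all other columns (scatter in particular)
#' are untouched.
#'
#' @param table an \linkS4class{EventTable}.
#' @param spill a \linkS4class{SpilloverMatrix} whose channels all occur in
#'   `table`.
#' @return a compensated \linkS4class{EventTable}.
#' @export
applyCompensation <- function(table, spill) {
  stopifnot(is(table, "EventTable"), is(spill, "SpilloverMatrix"))
  sm <- spill@coefficients
  chans <- colnames(sm)
  missing <- setdiff(chans, channels(table))
  if (length(missing))
    stop("compensation configuration error: channels absent from table: ",
         paste(missing, collapse = ", "))
  inv <- tryCatch(solve(sm),
                  error = function(e) stop("singular spillover matrix"))
  m <- exprs(table)
  m[, chans] <- m[, chans, drop = FALSE] %*% inv
  EventTable(m, sampleId = sampleId(table), tubeId = tubeId(table),
             keywords = c(keywords(table), list(COMPENSATED = "1")))
}
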