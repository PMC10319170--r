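# shared fixture builders; everything is generated in code at test time

smallProfile <- function(nEvents = 20000, ...) {
  caseProfile("test_case",
              targetFractions = c(blast = 2, erythroid = 15, myeloid = 45,
                                  monocytic = 5, eosinophil = 1.5,
                                  platelet = 2, doublet = 2, debris = 5),
              nEvents = nEvents, ...)
}

# full-channel single table plus ground truth
smallSample <- function(nEvents = 20000, seed = 1, profile = NULL) {
  if (is.null(profile)) profile <- smallProfile(nEvents)
  generateCase(profile, seed = seed, tubes = "full")
}

# hand-built FCS dataset blob, independent of writeFCS: values laid out per
# the standard (58-byte header, '/'-delimited TEXT, little-endian float32
# DATA); returned as a raw vector so LMD-style multi-dataset files can be
# composed by concatenation
fcsBlob <- function(values, channels, version = "FCS3.1", nextData = 0,
                    totOverride = NULL) {
  n <- nrow(values); p <- ncol(values)
  tot <- if (is.null(totOverride)) n else totOverride
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", as.character(nextData),
          "$TOT", as.character(tot), "$PAR", as.character(p))
  for (j in seq_len(p))
    kv <- c(kv, sprintf("$P%dN", j), channels[j], sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0", sprintf("$P%dR", j), "262144")
  text <- paste0("/", paste(kv, collapse = "/"), "/")
  textBegin <- 58
  textEnd <- textBegin + nchar(text) - 1
  dataBegin <- textEnd + 1
  dataEnd <- dataBegin + n * p * 4 - 1
  h8 <- function(x) formatC(x, width = 8, format = "d")
  header <- paste0(version, "    ", h8(textBegin), h8(textEnd),
                   h8(dataBegin), h8(dataEnd), h8(0), h8(0))
  c(charToRaw(header), charToRaw(text),
    writeBin(as.numeric(t(values)), raw(), size = 4, endian = "little"))
}

handBuiltFCS <- function(path, values, channels, version = "FCS3.1") {
  writeBin(fcsBlob(values, channels, version), path)
  invisible(path)
}
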