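## Shared numeric helpers: density-valley thresholds, robust cutoffs,
## polygon geometry, string-hash seed fan-out.

.log10p <- function(x) log10(pmax(x, 0) + 1)
.unlog10p <- function(y) 10^y - 1

#' Density-valley threshold between the two dominant modes
#'
#' Locates the minimum of a kernel-smoothed density (Silverman's
#' rule-of-thumb bandwidth) between the two highest modes of a distribution,
#' on a log10(x+1) scale for fluorescence-like data. Used as the
#' deterministic surrogate for manually placed boundaries between negative
#' and positive (or debris and cellular) event clouds.
#'
#' @param x numeric values.
#' @param logScale transform to log10(x+1) before smoothing (default TRUE).
#' @param minModeWeight minimum relative height (fraction of tallest mode)
#'   for a local maximum to count as a mode.
#' @param n grid size for the density evaluation.
#' @return list with `threshold` (on the original scale; `NA` when fewer
#'   than two modes are found), `nModes`, and `modes` (mode locations on the
#'   original scale).
#' @export
valleyThreshold <- function(x, logScale = TRUE, minModeWeight = 0.01,
                            n = 512) {
  x <- x[is.finite(x)]
  if (length(x) < 10 || stats::sd(x) == 0)
    return(list(threshold = NA_real_, nModes = as.integer(length(unique(x)) > 0),
                modes = numeric(0)))
  z <- if (logScale) .log10p(x) else x
  d <- stats::density(z, bw = "nrd0", n = n)
  y <- d$y
  g <- d$x
  k <- length(y)
  isMax <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
             FALSE)
  modes <- which(isMax & y >= minModeWeight * max(y))
  if (length(modes) < 2)
    return(list(threshold = NA_real_, nModes = length(modes),
                modes = if (logScale) .unlog10p(g[modes]) else g[modes]))
  top2 <- modes[order(y[modes], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  between <- lo:hi
  cut <- g[between[which.min(y[between])]]
  list(threshold = if (logScale) .unlog10p(cut) else cut,
       nModes = length(modes),
       modes = if (logScale) .unlog10p(g[modes]) else g[modes])
}

#' All density valleys of a distribution
#'
#' Like [valleyThreshold()] but returns every valley between consecutive
#' retained modes, for band construction (e.g. the CD45 negative / dim /
#' bright partition).
#'
#' @inheritParams valleyThreshold
#' @return list with `valleys` and `modes`, both on the original scale.
#' @export
densityValleys <- function(x, logScale = TRUE, minModeWeight = 0.01,
                           n = 512) {
  x <- x[is.finite(x)]
  if (length(x) < 10 || stats::sd(x) == 0)
    return(list(valleys = numeric(0), modes = numeric(0)))
  z <- if (logScale) .log10p(x) else x
  d <- stats::density(z, bw = "nrd0", n = n)
  y <- d$y; g <- d$x; k <- length(y)
  isMax <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
             FALSE)
  modes <- which(isMax & y >= minModeWeight * max(y))
  if (length(modes) < 2)
    return(list(valleys = numeric(0),
                modes = if (logScale) .unlog10p(g[modes]) else g[modes]))
  valleys <- vapply(seq_len(length(modes) - 1), function(i) {
    between <- modes[i]:modes[i + 1]
    g[between[which.min(y[between])]]
  }, numeric(1))
  list(valleys = if (logScale) .unlog10p(valleys) else valleys,
       modes = if (logScale) .unlog10p(g[modes]) else g[modes])
}

# Positivity cutoff for a marker on a mixed population: the density valley
# when the distribution is bimodal, otherwise a robust upper fence
# (median + nmads * MAD on log scale) of the dominant (negative) cloud.
.positivityCutoff <- function(x, nmads = 3.5) {
  v <- valleyThreshold(x)
  if (!is.na(v$threshold)) return(v$threshold)
  z <- .log10p(x)
  .unlog10p(stats::median(z) + nmads * stats::mad(z))
}

# --- polygon geometry -------------------------------------------------------

# even-odd rule point-in-polygon; boundary points count as inside
.pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.segIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

.polygonSelfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (.segIntersect(v[i, ], v[i %% n + 1, ], v[j, ], v[j %% n + 1, ]))
        return(TRUE)
    }
  }
  FALSE
}

# --- seed fan-out -----------------------------------------------------------

# stable polynomial string hash onto [0, 2^31-2]; combines a run seed with a
# case id so per-case streams are reproducible and independent
.childSeed <- function(seed, id) {
  h <- as.double(seed %% 2147483647L)
  for (cc in utf8ToInt(as.character(id)))
    h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}
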