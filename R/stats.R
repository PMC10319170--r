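## Cohort-level statistics: normality-dependent two-group tests with
## significance stars, and median+IQR reporting. As in the source
## procedure, no multiple-testing correction is applied.

#' Choose the two-group test from normality
#'
#' Student's independent t-test when both groups pass Shapiro-Wilk
#' normality at alpha, otherwise the Mann-Whitney U test. Groups that are
#' too small or have zero variance are skipped with a reason.
#'
#' @param x,y numeric group values.
#' @param alpha normality significance level (default 0.05).
#' @param minN minimum group size (default 3).
#' @return `"t_test"`, `"mann_whitney"`, or `"skipped"` with attribute
#'   `reason`.
#' @export
chooseTest <- function(x, y, alpha = 0.05, minN = 3) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < minN || length(y) < minN)
    return(structure("skipped", reason = "group too small"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure("skipped", reason = "zero variance"))
  normal <- stats::shapiro.test(x)$p.value >= alpha &&
    stats::shapiro.test(y)$p.value >= alpha
  if (normal) "t_test" else "mann_whitney"
}

#' Mann-Whitney U test
#'
#' Two-sided; exact enumeration of the U null distribution when both
#' groups have at most `exactMax` events and no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y numeric group values.
#' @param exactMax exact-enumeration size limit per group (default 8).
#' @return list: `statistic` (U of the first group), `p_value`.
#' @export
mannWhitneyTest <- function(x, y, exactMax = 8) {
  exact <- length(x) <= exactMax && length(y) <= exactMax &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Significance stars
#'
#' `""` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001 (strict inequalities).
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of star labels.
#' @export
stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-value outside [0, 1]")
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Compare indices between cohorts
#'
#' All cohort pairs x population x marker x strategy. Missing fractions
#' (insufficient populations) are excluded, never imputed; comparisons
#' that cannot run are recorded as skipped with their reason. No
#' multiple-testing correction is applied.
#'
#' @param indices long data.frame of index rows (as from
#'   [computeAllIndices()]) with an additional `cohort` column, or a named
#'   list of per-cohort index tables.
#' @return data.frame: cohort pair, population, marker, strategy, test,
#'   statistic, p_value, stars, n1, n2, reason.
#' @export
compareIndices <- function(indices) {
  if (is.list(indices) && !is.data.frame(indices)) {
    for (nm in names(indices)) indices[[nm]]$cohort <- nm
    indices <- do.call(rbind, c(indices, list(make.row.names = FALSE)))
  }
  ok <- !is.na(indices$fraction) &
    !grepl("insufficient_population", indices$qc)
  indices <- indices[ok, ]
  cohorts <- sort(unique(indices$cohort))
  if (length(cohorts) < 2) stop("need >= 2 cohorts with valid indices")
  pairs <- utils::combn(cohorts, 2, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    sub <- indices[indices$cohort %in% pr, ]
    for (pop in unique(sub$population)) {
      for (mk in unique(sub$marker)) {
        for (st in unique(sub$strategy)) {
          sel <- sub$population == pop & sub$marker == mk & sub$strategy == st
          x <- sub$fraction[sel & sub$cohort == pr[1]]
          y <- sub$fraction[sel & sub$cohort == pr[2]]
          test <- chooseTest(x, y)
          if (test == "skipped") {
            row <- data.frame(cohort1 = pr[1], cohort2 = pr[2],
                              population = pop, marker = mk, strategy = st,
                              test = "skipped", statistic = NA_real_,
                              p_value = NA_real_, stars = NA_character_,
                              n1 = length(x), n2 = length(y),
                              reason = attr(test, "reason"))
          } else if (test == "t_test") {
            ht <- stats::t.test(x, y, var.equal = TRUE)
            row <- data.frame(cohort1 = pr[1], cohort2 = pr[2],
                              population = pop, marker = mk, strategy = st,
                              test = "t_test",
                              statistic = unname(ht$statistic),
                              p_value = ht$p.value, stars = stars(ht$p.value),
                              n1 = length(x), n2 = length(y), reason = "")
          } else {
            mw <- mannWhitneyTest(x, y)
            row <- data.frame(cohort1 = pr[1], cohort2 = pr[2],
                              population = pop, marker = mk, strategy = st,
                              test = "mann_whitney", statistic = mw$statistic,
                              p_value = mw$p_value, stars = stars(mw$p_value),
                              n1 = length(x), n2 = length(y), reason = "")
          }
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Render the cohort report
#'
#' Per population x marker: one panel per strategy with per-case index
#' points by cohort, the median as a horizontal line and interquartile-range
#' whiskers, annotated with significance stars. Also exports the long index
#' table and the pairwise p-value table as CSV. The report footer notes
#' that no multiple-testing correction is applied.
#'
#' @param comparisons output of [compareIndices()].
#' @param indices long index table with `cohort` column.
#' @param dir output directory (created if needed).
#' @param device `"png"` or `"svg"`.
#' @return (invisibly) list with `files`, and `medians` (the plotted
#'   per-panel medians, for verification).
#' @export
renderReport <- function(comparisons, indices, dir, device = "png") {
  if (is.null(indices) || !nrow(indices)) {
    warning("renderReport: empty input, nothing to render")
    return(invisible(list(files = character(0), medians = NULL)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  idxPath <- file.path(dir, "indices.csv")
  utils::write.csv(indices, idxPath, row.names = FALSE)
  pvalPath <- file.path(dir, "pvalues.csv")
  con <- file(pvalPath, "w")
  writeLines("# Pairwise group comparisons; no multiple-testing correction applied.",
             con)
  utils::write.csv(comparisons, con, row.names = FALSE)
  close(con)
  files <- c(idxPath, pvalPath)

  med <- stats::aggregate(fraction ~ cohort + population + marker + strategy,
                          data = indices, FUN = stats::median)
  names(med)[names(med) == "fraction"] <- "median"
  qlo <- stats::aggregate(fraction ~ cohort + population + marker + strategy,
                          data = indices,
                          FUN = function(v) stats::quantile(v, 0.25,
                                                            names = FALSE))
  qhi <- stats::aggregate(fraction ~ cohort + population + marker + strategy,
                          data = indices,
                          FUN = function(v) stats::quantile(v, 0.75,
                                                            names = FALSE))
  med$q25 <- qlo$fraction
  med$q75 <- qhi$fraction

  starLab <- comparisons[!is.na(comparisons$stars) &
                           comparisons$stars != "", ]
  for (mk in unique(indices$marker)) {
    sub <- indices[indices$marker == mk & !is.na(indices$fraction), ]
    if (!nrow(sub)) next
    msub <- med[med$marker == mk, ]
    p <- ggplot2::ggplot(sub, ggplot2::aes(x = cohort, y = fraction)) +
      ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.6,
                           colour = "grey40") +
      ggplot2::geom_errorbar(data = msub,
        ggplot2::aes(x = cohort, ymin = q25, ymax = q75), width = 0.3,
        inherit.aes = FALSE) +
      ggplot2::geom_segment(data = msub,
        ggplot2::aes(x = as.numeric(factor(cohort)) - 0.25,
                     xend = as.numeric(factor(cohort)) + 0.25,
                     y = median, yend = median),
        linewidth = 0.8, inherit.aes = FALSE) +
      ggplot2::facet_grid(population ~ strategy) +
      ggplot2::labs(y = paste(mk, "positive fraction"), x = NULL,
                    title = paste(mk, "index by cohort and gating strategy"),
                    caption = "median and IQR; no multiple-testing correction") +
      ggplot2::theme_bw(base_size = 9) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                         hjust = 1))
    sl <- starLab[starLab$marker == mk, ]
    if (nrow(sl)) {
      sl$label <- paste0(substr(sl$cohort1, 1, 3), "/",
                         substr(sl$cohort2, 1, 3), " ", sl$stars)
      ann <- stats::aggregate(label ~ population + strategy, data = sl,
                              FUN = paste, collapse = "\n")
      ann$fraction <- max(sub$fraction, na.rm = TRUE)
      p <- p + ggplot2::geom_text(data = ann,
        ggplot2::aes(x = 1.5, y = fraction, label = label),
        size = 2.2, vjust = 1, inherit.aes = FALSE)
    }
    fp <- file.path(dir, paste0("index_", gsub("[^A-Za-z0-9]", "", mk),
                                ".", device))
    ggplot2::ggsave(fp, p, width = 8, height = 7, dpi = 150)
    files <- c(files, fp)
  }
  invisible(list(files = files, medians = med))
}
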