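#' Per-case population fractions of the study cohorts
#'
#' Packaged tables of the printed per-case fractions of CD34+ blast,
#' erythroid, myeloid and monocytic cells (percent of relevant events) in
#' the 50 non-malignant, 25 MDS and 27 AML bone-marrow cases. These tables
#' are the single calibration source of the synthetic cohort generator.
#'
#' @param cohort one of `"non_malignant"`, `"MDS"`, `"AML"`.
#' @return data.frame with columns `case`, `blast_pct`, `erythroid_pct`,
#'   `myeloid_pct`, `monocytic_pct`.
#' @examples
#' tab <- loadFractionFixture("non_malignant")
#' tab[tab$case == 9, "myeloid_pct"]   # 83.8
#' @export
loadFractionFixture <- function(cohort) {
  files <- c(non_malignant = "table2A_non_malignant.csv",
             MDS = "table2B_mds.csv", AML = "table2C_aml.csv")
  if (!cohort %in% names(files))
    stop("unknown cohort id: ", cohort,
         " (expected non_malignant, MDS or AML)")
  path <- system.file("extdata", files[[cohort]], package = "myeloFlow",
                      mustWork = TRUE)
  utils::read.csv(path)
}
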