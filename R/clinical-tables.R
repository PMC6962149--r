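#' Clinicopathological contingency tables of the PDAC discovery cohort
#'
#' The published per-subtype patient counts of the 90-sample PDAC discovery
#' cohort (four molecular subtypes, PDACS1-4) for the categorical clinical
#' variables: sex, radicality of resection (R0/R1), lymph-node metastasis,
#' perineural growth, vasoinvasive growth and IPMN component. Where the
#' original report tabulates patients with unknown status, the "unknown" row
#' is retained as an ordinary category — the association tests on these
#' tables reproduce the published p-values only with that convention.
#'
#' @return A named list of integer matrices (rows: category, columns:
#'   subtype).
#' @export
#' @examples
#' pearson_chisq(pdac_clinical_tables()$radicality)
pdac_clinical_tables <- function() {
  subtypes <- paste0("PDACS", 1:4)
  tab <- function(...) {
    rows <- list(...)
    m <- do.call(rbind, rows)
    colnames(m) <- subtypes
    m
  }
  list(
    sex = tab(male = c(12L, 9L, 13L, 20L), female = c(8L, 10L, 12L, 6L)),
    radicality = tab(R0 = c(7L, 16L, 12L, 12L), R1 = c(13L, 3L, 13L, 14L)),
    lymph_node = tab(no = c(6L, 4L, 5L, 5L), yes = c(14L, 15L, 20L, 21L)),
    perineural = tab(no = c(3L, 5L, 3L, 9L), yes = c(15L, 12L, 21L, 16L),
                     unknown = c(2L, 2L, 1L, 1L)),
    vasoinvasive = tab(no = c(11L, 9L, 13L, 17L), yes = c(9L, 7L, 11L, 7L),
                       unknown = c(0L, 3L, 1L, 2L)),
    ipmn = tab(no = c(12L, 11L, 22L, 19L), yes = c(5L, 4L, 3L, 4L),
               unknown = c(3L, 4L, 0L, 3L))
  )
}
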