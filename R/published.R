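#' Published summary tables of the original 12-item validation study
#'
#' The original validation study of the 12-item HIV knowledge assessment
#' (n = 2552 Brazilian sexual and gender minority respondents) reported,
#' per candidate short-form length, Cronbach's alpha, the concurrent
#' correlations of summed and factor scores with the full form, the
#' convergent correlations with a 15-item ("kq") and a 5-item ("who")
#' knowledge measure, and the corrected equivalence p-values.
#' `published_criteria_table` returns those reported values in the
#' [build_criteria_table] layout so the five-criterion selection rule can
#' be run on them as a worked example; p-values reported only as bounds are
#' encoded as 0.0005 ("<.001") and 0.995 (">.99"), which is exact for every
#' comparison the selection rule makes. `published_counts` returns reported
#' descriptive level counts (HIV-test status, treatment initiation among
#' positives, current PrEP use among negatives, perceived accuracy of the
#' U=U message).
#'
#' @return `published_criteria_table`: a data frame in the criteria-table
#'   layout. `published_counts`: a data frame with columns variable, level,
#'   n.
#' @examples
#' select_final_form(published_criteria_table(), external_measure = "kq")$length
#' @export
published_criteria_table <- function() {
  utils::read.csv(system.file("extdata", "published_criteria.csv",
                              package = "shortform"),
                  stringsAsFactors = FALSE)
}

#' @rdname published_criteria_table
#' @export
published_counts <- function() {
  utils::read.csv(system.file("extdata", "published_counts.csv",
                              package = "shortform"),
                  stringsAsFactors = FALSE)
}
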