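#' Recompute cohort characteristic percentages from counts
#'
#' The published cohort description reports categorical characteristics as
#' `count (percent)`; this helper recomputes the percentages from the counts
#' and denominators, as a machine-checkable consistency table. The bundled
#' default file carries the sex, APOE-e4 and scanner-field-strength counts of
#' the four diagnostic groups plus the behavioral/dysexecutive overlap
#' fraction.
#'
#' @param path CSV with columns characteristic, group, numerator,
#'   denominator, printed_pct; defaults to the bundled table.
#' @return the table with a `computed_pct` column (100 * numerator /
#'   denominator).
#' @export
cohort_percentages <- function(path = system.file("extdata",
                                                  "cohort_counts.csv",
                                                  package = "metaconn")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$computed_pct <- 100 * tab$numerator / tab$denominator
  tab
}
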