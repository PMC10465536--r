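#' Published rumen virome database (RVD) summary tallies
#'
#' Headline counts reported for the public rumen virome database built
#' from 975 rumen metagenomes: taxonomy assignment tallies over the
#' 397,180 vOTUs and host-prediction tallies over the host-matched
#' phages. Shipped as plain TSV under `inst/extdata/rvd_summary.tsv`;
#' percentages recomputed from the numerator/denominator columns must
#' agree with the printed percentage at the printed precision, and the
#' archaeophage plus bacteriophage counts must add up to the printed
#' host-matched total. Used by consistency tests and as denominators for
#' percentage-style summaries.
#'
#' @return Data frame with `metric`, `numerator`, `denominator`,
#'   `printed_percent`, `digits` (printed decimal places; `NA` for plain
#'   counts).
#' @export
rvd_reference_counts <- function() {
  path <- system.file("extdata", "rvd_summary.tsv", package = "rumenvirome",
                      mustWork = TRUE)
  read_tsv_rv(path)
}

#' Percentage of a numerator over a denominator, rounded as printed
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places to round to.
#' @return Rounded percentage.
#' @export
percentage <- function(numerator, denominator, digits = 1) {
  round(100 * numerator / denominator, digits)
}
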