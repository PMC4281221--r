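#' Example validation counts from a savannah wildlife census
#'
#' Reference (consensus manual), classified (automated) and correctly
#' matched animal counts for six 50 m x 50 m validation areas in two
#' pilot regions (`A`: high animal density, `B`: low density) of an East
#' African open-savannah census from 0.5 m satellite imagery.  Useful
#' for exercising [error_rates()], [aggregate_counts()] and
#' [chi2_error_independence()] without running a detection.
#'
#' @return An [area_counts()] data frame.
#' @export
#' @examples
#' counts <- savannah_census_counts()
#' error_rates(aggregate_counts(counts))
savannah_census_counts <- function() {
  df <- read.csv(system.file("extdata", "savannah_census_counts.csv",
                             package = "herdspot"),
                 stringsAsFactors = FALSE)
  area_counts(df$area_id, df$reference, df$classified, df$correct,
              pilot = df$pilot)
}
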