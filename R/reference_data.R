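#' Published per-year accuracy of the wheat-maize class, 2004-2016
#'
#' Reference table of per-year user's and producer's accuracies (percent)
#' reported for a 13-year provincial wheat-maize mapping assessment,
#' shipped with the package for benchmarking summaries. The 13-year
#' arithmetic means are 94.5% (user's) and 90.2% (producer's).
#'
#' @return Data frame with `year`, `users_accuracy_pct`,
#'   `producers_accuracy_pct`.
#' @export
annual_accuracy_reference <- function() {
  path <- system.file("extdata", "annual_accuracy_reference.csv",
                      package = "doublecrop", mustWork = TRUE)
  utils::read.csv(path)
}
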