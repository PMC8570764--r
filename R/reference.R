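#' Published incremental reference tables
#'
#' The published evaluation reports incremental discounted costs, DALYs, and
#' catastrophic-health-expenditure (CHE) cases per strategy, with ICERs.
#' These tables ship with the package as plain CSV so the ICER arithmetic
#' can be re-verified from the printed incremental columns: each published
#' ratio equals the incremental cost divided by the effects averted, rounded
#' to the nearest dollar (the CHE table's effects averted are recomputed as
#' comparator CHE minus strategy CHE, since a few of its printed
#' incremental-CHE cells are internally inconsistent transcriptions).
#'
#' @param which `"daly"` or `"che"`.
#' @return A tibble of the published incremental columns and ICERs.
#' @examples
#' ref <- reference_incrementals("daly")
#' icer(ref$incremental_cost[1], -ref$incremental_dalys[1])$value
#' @export
reference_incrementals <- function(which = c("daly", "che")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_icer_", which, ".csv"),
                      package = "hefsim", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}
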