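#' Bundled FM4-64FX regional fluorescence summaries
#'
#' BFA-corrected regional FM4-64FX fluorescence means (+/- SE, arbitrary
#' units) of trans-differentiating adaxial epidermal cells of cultured
#' Vicia faba cotyledons, for three published pharmacology experiments:
#' `actin_ca` (actin drugs and the Ca2+-channel blocker nifedipine over
#' 0-15 h), `exo_endo` (BDM and Wortmannin over 9 and 9+6 h) and `dynamin`
#' (dynasore/dyngo analogues over 9 and 9+6 h). The companion table holds
#' the per-treatment totals as printed in the original reports; three rows
#' ("actin_ca / 15h Control", "actin_ca / 15h Latrunculin B (100 nM)" and
#' "dynamin / 9h+6h Control") do not equal the sum of their rounded
#' regional means, presumably because the totals were computed before
#' rounding.
#'
#' @return A list with two data frames: `regional` (columns `experiment`,
#'   `treatment`, `region`, `mean`, `se`) and `printed_totals` (columns
#'   `experiment`, `treatment`, `mean`, `se`).
#' @examples
#' tabs <- fm464_example_tables()
#' t4 <- subset(tabs$regional, experiment == "actin_ca")
#' table_totals(t4[, c("treatment", "region", "mean", "se")])
#' @export
fm464_example_tables <- function() {
  reg <- utils::read.csv(system.file("extdata",
                                     "fm464_regional_fluorescence.csv",
                                     package = "papillastats"),
                         stringsAsFactors = FALSE)
  tot <- utils::read.csv(system.file("extdata", "fm464_printed_totals.csv",
                                     package = "papillastats"),
                         stringsAsFactors = FALSE)
  list(regional = reg, printed_totals = tot)
}
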