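#' Select differentially expressed transcripts by the screening criteria
#'
#' Applies the transcript selection gates used to shortlist actin
#' remodelling and vesicle-trafficking candidates from a precomputed
#' expression/statistics table: the transcript must be expressed
#' (RPKM > 1 at 3 h or 12 h of culture) and must either show a log2-fold
#' change > 1 on the 0-3 h or 3-12 h interval with that interval's
#' FDR-corrected p-value < 0.05, or show sustained up-regulation (both
#' log2FCs > 0 with both FDRs < 0.05). When `relax_ca_sensitive = TRUE`,
#' transcripts flagged as encoding Ca2+-sensitive proteins bypass the
#' fold-change magnitude gate — up-regulation (log2FC > 0) with
#' FDR < 0.05 on at least one interval suffices — but never the RPKM or
#' FDR gates.
#'
#' @param records Data frame with columns `gene_id`, `rpkm_3h`,
#'   `rpkm_12h`, `log2fc_0_3`, `log2fc_3_12`, `fdr_0_3`, `fdr_3_12` and
#'   optionally logical `ca_sensitive` (assumed `FALSE` when absent).
#' @param relax_ca_sensitive Apply the relaxed gate to Ca2+-sensitive
#'   transcripts (default `FALSE`).
#' @return The selected rows of `records` (same columns).
#' @export
select_degs <- function(records, relax_ca_sensitive = FALSE) {
  req <- c("gene_id", "rpkm_3h", "rpkm_12h", "log2fc_0_3", "log2fc_3_12",
           "fdr_0_3", "fdr_3_12")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop(sprintf("'records' must contain columns: %s",
                 paste(req, collapse = ", ")))
  }
  if (!"ca_sensitive" %in% names(records)) records$ca_sensitive <- FALSE
  num <- c("rpkm_3h", "rpkm_12h", "log2fc_0_3", "log2fc_3_12",
           "fdr_0_3", "fdr_3_12")
  for (col in num) {
    bad <- which(!is.finite(records[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or missing value in column '%s' at row %d",
                   col, bad[1]))
    }
  }
  bad <- which(records$rpkm_3h < 0 | records$rpkm_12h < 0)
  if (length(bad) > 0L) stop(sprintf("negative RPKM at row %d", bad[1]))
  bad <- which(records$fdr_0_3 < 0 | records$fdr_0_3 > 1 |
                 records$fdr_3_12 < 0 | records$fdr_3_12 > 1)
  if (length(bad) > 0L) stop(sprintf("FDR outside [0, 1] at row %d", bad[1]))

  expressed <- records$rpkm_3h > 1 | records$rpkm_12h > 1
  fc_gate <- (records$log2fc_0_3 > 1 & records$fdr_0_3 < 0.05) |
    (records$log2fc_3_12 > 1 & records$fdr_3_12 < 0.05)
  sustained <- records$log2fc_0_3 > 0 & records$log2fc_3_12 > 0 &
    records$fdr_0_3 < 0.05 & records$fdr_3_12 < 0.05
  pass <- fc_gate | sustained
  if (isTRUE(relax_ca_sensitive)) {
    relaxed <- (records$log2fc_0_3 > 0 & records$fdr_0_3 < 0.05) |
      (records$log2fc_3_12 > 0 & records$fdr_3_12 < 0.05)
    pass <- pass | (records$ca_sensitive & relaxed)
  }
  out <- records[expressed & pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}
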