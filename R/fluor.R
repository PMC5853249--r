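#' Correct fluorescence means for the BFA plasma-membrane baseline
#'
#' FM4-64FX fluorescence measured in cultured cotyledon cells contains a
#' plasma-membrane component; incubation on Brefeldin A (BFA) blocks
#' vesicle cycling and leaves only that component, so cytoplasmic vesicle
#' fluorescence is estimated as treatment minus BFA. The two samples are
#' unpaired, so the SE of the difference is `sqrt(se^2 + bfa_se^2)`.
#' Negative corrected means are clipped to 0 (the floor implied by the
#' zero entries of the published tables); the unclipped difference is
#' returned alongside for diagnostics.
#'
#' @param mean,se Treatment regional mean and SE (vectors allowed).
#' @param bfa_mean,bfa_se BFA baseline mean and SE for the same region(s).
#' @return Data frame with columns `mean` (clipped at 0), `se` and
#'   `raw_mean` (unclipped difference).
#' @examples
#' bfa_correct(400, 3, 16, 4)  # 384 +/- 5
#' @export
bfa_correct <- function(mean, se, bfa_mean, bfa_se) {
  if (any(se < 0) || any(bfa_se < 0)) stop("standard errors must be >= 0")
  d <- mean - bfa_mean
  data.frame(mean = pmax(0, d), se = sqrt(se^2 + bfa_se^2), raw_mean = d)
}

#' BFA-correct a regional fluorescence table
#'
#' Applies [bfa_correct()] region-by-region to every non-baseline
#' treatment of a summary table.
#'
#' @param table Data frame with columns `treatment`, `region`, `mean`,
#'   `se` (and optionally `n`), containing one treatment labelled as the
#'   BFA baseline with every region present.
#' @param bfa_label Treatment label of the baseline rows (default
#'   `"BFA"`).
#' @return Data frame of the corrected non-baseline rows: `treatment`,
#'   `region`, `mean`, `se`, `raw_mean`.
#' @export
bfa_correct_table <- function(table, bfa_label = "BFA") {
  req <- c("treatment", "region", "mean", "se")
  if (!is.data.frame(table) || !all(req %in% names(table))) {
    stop("'table' must contain columns treatment, region, mean, se")
  }
  bfa <- table[table$treatment == bfa_label, , drop = FALSE]
  if (nrow(bfa) == 0L) {
    stop(sprintf("no rows with baseline treatment '%s'", bfa_label))
  }
  rest <- table[table$treatment != bfa_label, , drop = FALSE]
  idx <- match(rest$region, bfa$region)
  if (anyNA(idx)) {
    stop(sprintf("baseline '%s' is missing region '%s'", bfa_label,
                 rest$region[which(is.na(idx))[1]]))
  }
  cor <- bfa_correct(rest$mean, rest$se, bfa$mean[idx], bfa$se[idx])
  out <- data.frame(treatment = rest$treatment, region = rest$region,
                    mean = cor$mean, se = cor$se, raw_mean = cor$raw_mean,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-treatment totals of a corrected regional table
#'
#' Sums the three cytoplasmic regions (outer periclinal, anticlinal,
#' inner periclinal) per treatment; the SE of the total is the root sum of
#' squares of the regional SEs.
#'
#' @param corrected Data frame with columns `treatment`, `region`, `mean`,
#'   `se`; every treatment must carry all the regions listed in
#'   `regions`.
#' @param regions Character vector of region labels that make up a
#'   complete cell (default the three cytoplasmic regions).
#' @return Data frame with columns `treatment`, `mean`, `se`.
#' @export
table_totals <- function(corrected,
                         regions = c("outer_periclinal", "anticlinal",
                                     "inner_periclinal")) {
  req <- c("treatment", "region", "mean", "se")
  if (!is.data.frame(corrected) || !all(req %in% names(corrected))) {
    stop("'corrected' must contain columns treatment, region, mean, se")
  }
  treatments <- unique(corrected$treatment)
  out <- lapply(treatments, function(tr) {
    rows <- corrected[corrected$treatment == tr, , drop = FALSE]
    missing <- setdiff(regions, rows$region)
    if (length(missing) > 0L) {
      stop(sprintf("treatment '%s' is missing region(s): %s", tr,
                   paste(missing, collapse = ", ")))
    }
    rows <- rows[rows$region %in% regions, , drop = FALSE]
    data.frame(treatment = tr, mean = sum(rows$mean),
               se = sqrt(sum(rows$se^2)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative change between two fluorescence totals
#'
#' The derived trafficking statistics reported alongside the corrected
#' tables: `fold_increase` is `(new - ref)/ref` (reported to 1 decimal),
#' `percent_decline` is `100 * (ref - new)/ref` (1 decimal) and
#' `percent_inhibition` is the same quantity rounded to the nearest
#' integer.
#'
#' @param reference Reference total (> 0).
#' @param new New total.
#' @param mode One of `"fold_increase"`, `"percent_decline"`,
#'   `"percent_inhibition"`.
#' @param report If `TRUE` (default) apply the reporting rounding; if
#'   `FALSE` return the raw value.
#' @return A single number.
#' @examples
#' relative_change(76, 424, "fold_increase")       # 4.6
#' relative_change(548, 403, "percent_decline")    # 26.5
#' relative_change(403, 56, "percent_inhibition")  # 86
#' @export
relative_change <- function(reference, new,
                            mode = c("fold_increase", "percent_decline",
                                     "percent_inhibition"),
                            report = TRUE) {
  mode <- match.arg(mode)
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0) {
    stop("'reference' must be a single positive number")
  }
  raw <- switch(mode,
                fold_increase = (new - reference) / reference,
                percent_decline = 100 * (reference - new) / reference,
                percent_inhibition = 100 * (reference - new) / reference)
  if (!report) return(raw)
  switch(mode,
         fold_increase = round(raw, 1),
         percent_decline = round(raw, 1),
         percent_inhibition = round(raw))
}
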