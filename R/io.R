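#' Read per-cell papilla and bundle coordinate tables
#'
#' Reads the two CSV interfaces of the association test and groups rows by
#' cell. The papillae file must have a header `cell_id,x_nm,y_nm`; the
#' bundles file `cell_id,shape,x1_nm,y1_nm,x2_nm,y2_nm,diameter_nm`
#' (circular bundles store their centre in `x1_nm,y1_nm` and ring
#' diameter in `x2_nm`). All coordinates are nm with `.` decimal.
#'
#' @param papillae_path,bundles_path Paths to the CSV files.
#' @param region A [cell_region()] applied to every cell (the cell window
#'   is not part of the CSV schema).
#' @param papilla_diameter Papilla diameter in nm (default 380).
#' @return Named list (one element per `cell_id` present in the papillae
#'   file) of records `list(papillae =, bundles =)`. Cells without bundle
#'   rows get an empty bundle set.
#' @export
read_pattern_tables <- function(papillae_path, bundles_path, region,
                                papilla_diameter = 380) {
  stopifnot(inherits(region, "cell_region"))
  pap <- .read_schema(papillae_path, c("cell_id", "x_nm", "y_nm"),
                      numeric_cols = c("x_nm", "y_nm"))
  bnd <- .read_schema(bundles_path,
                      c("cell_id", "shape", "x1_nm", "y1_nm", "x2_nm",
                        "y2_nm", "diameter_nm"),
                      numeric_cols = c("x1_nm", "y1_nm", "x2_nm",
                                       "diameter_nm"))
  # y2 may be empty for circular bundles
  suppressWarnings(bnd$y2_nm <- as.numeric(bnd$y2_nm))
  bad <- which(bnd$shape == "linear" & !is.finite(bnd$y2_nm))
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: non-numeric 'y2_nm' for a linear bundle",
                 bundles_path, bad[1] + 1L))
  }
  cells <- unique(pap$cell_id)
  out <- lapply(cells, function(id) {
    pr <- pap[pap$cell_id == id, , drop = FALSE]
    br <- bnd[bnd$cell_id == id, , drop = FALSE]
    list(papillae = papilla_pattern(pr$x_nm, pr$y_nm, region,
                                    diameter = papilla_diameter),
         bundles = bundle_set(br$x1_nm, br$y1_nm, br$x2_nm, br$y2_nm,
                              diameter = br$diameter_nm, shape = br$shape,
                              region = region))
  })
  names(out) <- cells
  out
}

.read_schema <- function(path, columns, numeric_cols = character()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(columns, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in numeric_cols) {
    suppressWarnings(v <- as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) > 0L || anyNA(v)) {
      line <- if (length(bad) > 0L) bad[1] else which(is.na(v))[1]
      stop(sprintf("%s line %d: non-numeric value in column '%s'",
                   path, line + 1L, col))
    }
    df[[col]] <- v
  }
  df
}

#' Write per-cell coordinate tables
#'
#' Inverse of [read_pattern_tables()]: serializes generated cell records
#' to the papillae/bundles CSV schema, losslessly at full double
#' precision.
#'
#' @param cells Named list of records `list(papillae =, bundles =)`.
#' @param papillae_path,bundles_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_pattern_tables <- function(cells, papillae_path, bundles_path) {
  ids <- names(cells)
  if (is.null(ids)) ids <- paste0("cell", seq_along(cells))
  pap <- do.call(rbind, lapply(seq_along(cells), function(i) {
    p <- cells[[i]]$papillae
    data.frame(cell_id = ids[i], x_nm = p$x, y_nm = p$y,
               stringsAsFactors = FALSE)
  }))
  bnd <- do.call(rbind, lapply(seq_along(cells), function(i) {
    s <- cells[[i]]$bundles$segments
    if (nrow(s) == 0L) return(NULL)
    data.frame(cell_id = ids[i], shape = s$shape, x1_nm = s$x1,
               y1_nm = s$y1, x2_nm = s$x2, y2_nm = s$y2,
               diameter_nm = s$diameter, stringsAsFactors = FALSE)
  }))
  if (is.null(bnd)) {
    bnd <- data.frame(cell_id = character(), shape = character(),
                      x1_nm = numeric(), y1_nm = numeric(),
                      x2_nm = numeric(), y2_nm = numeric(),
                      diameter_nm = numeric())
  }
  utils::write.csv(format(pap, digits = 17, trim = TRUE, scientific = FALSE),
                   papillae_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(format(bnd, digits = 17, trim = TRUE, scientific = FALSE),
                   bundles_path, row.names = FALSE, quote = FALSE)
  invisible(c(papillae_path, bundles_path))
}

#' Read a regional fluorescence summary table
#'
#' @param path CSV with header `treatment,region,mean,se` and optionally
#'   `n`.
#' @return Data frame with those columns.
#' @export
read_fluor_table <- function(path) {
  df <- .read_schema(path, c("treatment", "region", "mean", "se"),
                     numeric_cols = c("mean", "se"))
  if ("n" %in% names(df)) suppressWarnings(df$n <- as.integer(df$n))
  df
}

#' Write a cohort association report
#'
#' Serializes a [aggregate_cells()] result to JSON (per-cell statistics,
#' cohort summary, configuration echo, seed and package version; raw
#' p-values of 0 also carry the display string "< 1/n_sims") and
#' optionally to a per-cell TSV.
#'
#' @param cohort A `papilla_cohort`.
#' @param path Output JSON path.
#' @param tsv_path Optional per-cell TSV path.
#' @param config Optional named list echoed verbatim into the report.
#' @return Invisibly, the JSON path.
#' @export
write_assoc_report <- function(cohort, path, tsv_path = NULL,
                               config = list()) {
  stopifnot(inherits(cohort, "papilla_cohort"))
  per_cell <- lapply(seq_along(cohort$per_cell_results), function(i) {
    r <- cohort$per_cell_results[[i]]
    list(cell_id = cohort$table$cell_id[i],
         n_papillae = r$n_papillae,
         n_bundles = r$n_bundles,
         n_associated = r$n_associated,
         percent_observed = r$percent_observed,
         p_value = r$p_value,
         p_label = format_p_value(r$p_value, r$n_sims),
         n_sims = r$n_sims,
         threshold_nm = r$threshold,
         seed = r$seed)
  })
  report <- list(
    tool = "papillastats",
    version = as.character(utils::packageVersion("papillastats")),
    config = config,
    cohort = list(n_cells = cohort$n_cells,
                  mean_percent = cohort$mean_percent,
                  se_percent = cohort$se_percent),
    cells = per_cell)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!is.null(tsv_path)) {
    utils::write.table(cohort$table, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
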