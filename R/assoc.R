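#' Count papillae associated with actin bundle ends
#'
#' A WI papilla is scored as associated when at least one endpoint of at
#' least one linear actin bundle lies at Euclidean distance strictly less
#' than `threshold` from the papilla centre. Circular bundles (rings) have
#' no ends and are ignored. This is the observed statistic of the
#' randomization test.
#'
#' @param papillae A [papilla_pattern()] with at least one centre.
#' @param bundles A [bundle_set()]; only its linear segments are used. An
#'   empty (or all-circular) set is valid and yields zero associations.
#' @param threshold Association distance in nm (default 400); strict
#'   inequality is applied at the threshold.
#' @return A list with `n_papillae`, `n_associated`, `percent` (of papillae
#'   associated) and the logical per-papilla vector `associated`.
#' @examples
#' reg <- cell_region(6000, 2000)
#' pap <- papilla_pattern(c(0, 2000, 4000), c(0, 0, 0), reg)
#' bnd <- bundle_set(x1 = c(350, 4395), y1 = c(0, 5),
#'                   x2 = c(1450, 5000), y2 = c(0, 900),
#'                   diameter = 150, region = reg)
#' count_associated_papillae(pap, bnd)$n_associated  # 2
#' @export
count_associated_papillae <- function(papillae, bundles, threshold = 400) {
  stopifnot(inherits(papillae, "papilla_pattern"),
            inherits(bundles, "bundle_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("'threshold' must be a single positive number (nm)")
  }
  n_pap <- length(papillae)
  if (n_pap == 0L) stop("association statistic undefined for an empty papilla set")
  seg <- linear_bundles(bundles)$segments
  if (nrow(seg) == 0L) {
    return(list(n_papillae = n_pap, n_associated = 0L, percent = 0,
                associated = rep(FALSE, n_pap)))
  }
  ex <- c(seg$x1, seg$x2)
  ey <- c(seg$y1, seg$y2)
  d2 <- outer(papillae$x, ex, "-")^2 + outer(papillae$y, ey, "-")^2
  associated <- rowSums(d2 < threshold^2) > 0L
  n_assoc <- sum(associated)
  list(n_papillae = n_pap, n_associated = as.integer(n_assoc),
       percent = 100 * n_assoc / n_pap, associated = associated)
}

#' Fraction of bundles with an end near a papilla
#'
#' Complement of [count_associated_papillae()]: the proportion of linear
#' bundles having at least one endpoint strictly within `threshold` of some
#' papilla centre. Used for generator parameter-recovery checks.
#'
#' @inheritParams count_associated_papillae
#' @return A proportion in \[0, 1\] (NaN for an empty linear set).
#' @export
fraction_bundles_associated <- function(papillae, bundles, threshold = 400) {
  stopifnot(inherits(papillae, "papilla_pattern"),
            inherits(bundles, "bundle_set"))
  seg <- linear_bundles(bundles)$segments
  if (nrow(seg) == 0L) return(NaN)
  d2a <- outer(seg$x1, papillae$x, "-")^2 + outer(seg$y1, papillae$y, "-")^2
  d2b <- outer(seg$x2, papillae$x, "-")^2 + outer(seg$y2, papillae$y, "-")^2
  hit <- rowSums(d2a < threshold^2) > 0L | rowSums(d2b < threshold^2) > 0L
  mean(hit)
}

# Rejection-sample segment placements: midpoint uniform over the window,
# orientation uniform on [0, pi), conditioned on full containment.
# Returns a data frame of endpoints in input order. Consumes the current
# RNG stream; the cap bounds total draws.
.place_segments <- function(width, height, lengths, max_draws = 1e6) {
  n <- length(lengths)
  x1 <- x2 <- y1 <- y2 <- numeric(n)
  if (n == 0L) return(data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2))
  if (any(lengths >= min(width, height))) {
    stop("bundle length must be smaller than the shortest window side for random placement")
  }
  need <- seq_len(n)
  drawn <- 0
  while (length(need) > 0L) {
    k <- length(need)
    drawn <- drawn + k
    if (drawn > max_draws) {
      stop("random bundle placement exceeded the rejection-sampling cap")
    }
    mx <- stats::runif(k, 0, width)
    my <- stats::runif(k, 0, height)
    th <- stats::runif(k, 0, pi)
    hx <- lengths[need] / 2 * cos(th)
    hy <- lengths[need] / 2 * sin(th)
    ax <- mx - hx; ay <- my - hy
    bx <- mx + hx; by <- my + hy
    ok <- ax >= 0 & ax <= width & bx >= 0 & bx <= width &
      ay >= 0 & ay <= height & by >= 0 & by <= height
    idx <- need[ok]
    x1[idx] <- ax[ok]; y1[idx] <- ay[ok]
    x2[idx] <- bx[ok]; y2[idx] <- by[ok]
    need <- need[!ok]
  }
  data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' Lay bundles down at random within a cell window
#'
#' Implements the null model of the association test: each linear bundle
#' keeps its measured length and diameter but is re-placed with its
#' midpoint uniform over the window and its orientation uniform on
#' \[0, pi), conditioned (by rejection sampling) on the whole segment lying
#' inside the window.
#'
#' @param region A [cell_region()].
#' @param lengths,diameters Numeric vectors (nm) of the prescribed segment
#'   dimensions; `diameters` is recycled to `length(lengths)`.
#' @param seed Optional integer seed; when supplied the placement is a pure
#'   function of `(region, lengths, diameters, seed)`.
#' @return A [bundle_set()] of `length(lengths)` linear segments.
#' @export
place_random_bundles <- function(region, lengths, diameters = 150,
                                 seed = NULL) {
  stopifnot(inherits(region, "cell_region"))
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths) | lengths <= 0)) {
    stop("all bundle lengths must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  pl <- .place_segments(region$width, region$height, lengths)
  bundle_set(pl$x1, pl$y1, pl$x2, pl$y2,
             diameter = rep_len(as.numeric(diameters), length(lengths)),
             shape = "linear", region = region)
}

#' Monte Carlo randomization test of bundle-end/papilla association
#'
#' Tests whether the observed percentage of WI papillae with a linear
#' actin bundle end strictly within `threshold` nm of their centre exceeds
#' what random placement of the same bundles would produce. The papilla
#' centres stay fixed at their measured coordinates; in each of `n_sims`
#' replicates the observed linear bundles (same lengths and diameters) are
#' re-placed uniformly at random in the window and the association
#' percentage recomputed. The single-tail p-value is the proportion of
#' replicates with a null percentage greater than or equal to the observed
#' one.
#'
#' @inheritParams count_associated_papillae
#' @param n_sims Number of random re-placements (default 1000).
#' @param seed Optional integer seed making the whole test deterministic.
#' @param pseudo_count If `TRUE`, report the bias-adjusted p-value
#'   (k + 1)/(n_sims + 1) instead of the raw proportion k/n_sims. The raw
#'   proportion is the default; a raw 0 prints as "< 1/n_sims".
#' @return An object of class `papilla_assoc`: a list with `n_papillae`,
#'   `n_bundles` (linear), `n_associated`, `percent_observed`,
#'   `null_percents` (length `n_sims`), `p_value`, `n_sims`, `threshold`,
#'   `seed` and `pseudo_count`.
#' @seealso [aggregate_cells()] to pool per-cell results,
#'   [place_random_bundles()] for the null placement.
#' @export
monte_carlo_test <- function(papillae, bundles, n_sims = 1000,
                             threshold = 400, seed = NULL,
                             pseudo_count = FALSE) {
  stopifnot(inherits(papillae, "papilla_pattern"),
            inherits(bundles, "bundle_set"))
  if (!is.numeric(n_sims) || length(n_sims) != 1L || n_sims < 1) {
    stop("'n_sims' must be a single integer >= 1")
  }
  n_sims <- as.integer(n_sims)
  obs <- count_associated_papillae(papillae, bundles, threshold)
  lengths <- bundle_lengths(bundles)
  m <- length(lengths)
  if (!is.null(seed)) set.seed(seed)
  w <- papillae$region$width
  h <- papillae$region$height
  n_pap <- obs$n_papillae
  px <- papillae$x; py <- papillae$y
  thr2 <- threshold^2

  if (m == 0L) {
    null_pct <- rep(0, n_sims)
  } else {
    # replicates are processed in blocks so the pairwise distance matrix
    # stays small; the RNG stream is consumed sequentially, so results are
    # reproducible for a given seed regardless of timing
    block <- max(1L, min(n_sims, as.integer(ceiling(2e5 / (2 * m * n_pap)))))
    null_pct <- numeric(n_sims)
    done <- 0L
    while (done < n_sims) {
      b <- min(block, n_sims - done)
      pl <- .place_segments(w, h, rep.int(lengths, b))
      ex <- c(pl$x1, pl$x2)
      ey <- c(pl$y1, pl$y2)
      rep_id <- rep.int(rep(seq_len(b), each = m), 2L)
      d2 <- outer(px, ex, "-")^2 + outer(py, ey, "-")^2
      hit <- which(d2 < thr2, arr.ind = TRUE, useNames = FALSE)
      if (nrow(hit) > 0L) {
        key <- unique((rep_id[hit[, 2L]] - 1L) * n_pap + hit[, 1L])
        counts <- tabulate((key - 1L) %/% n_pap + 1L, nbins = b)
      } else {
        counts <- integer(b)
      }
      null_pct[done + seq_len(b)] <- 100 * counts / n_pap
      done <- done + b
    }
  }

  k <- sum(null_pct >= obs$percent)
  p <- if (pseudo_count) (k + 1) / (n_sims + 1) else k / n_sims
  structure(list(n_papillae = n_pap, n_bundles = m,
                 n_associated = obs$n_associated,
                 percent_observed = obs$percent,
                 associated = obs$associated,
                 null_percents = null_pct,
                 p_value = p, n_sims = n_sims, threshold = threshold,
                 seed = seed, pseudo_count = pseudo_count),
            class = "papilla_assoc")
}

#' Format a Monte Carlo p-value for reporting
#'
#' A raw p-value of exactly 0 (no null replicate reached the observed
#' percentage) is rendered as the resolution bound "< 1/n_sims", e.g.
#' "< 0.001" at 1000 simulations; other values print as given.
#'
#' @param p Numeric p-value(s).
#' @param n_sims Number of simulations behind each p-value.
#' @return Character vector of display strings.
#' @export
format_p_value <- function(p, n_sims) {
  ifelse(p == 0, paste0("< ", format(1 / n_sims, digits = 3)),
         format(p, digits = 3))
}

#' @export
print.papilla_assoc <- function(x, ...) {
  cat("Monte Carlo test of bundle-end / papilla association\n")
  cat(sprintf("  %d papillae, %d linear bundles, threshold %g nm\n",
              x$n_papillae, x$n_bundles, x$threshold))
  cat(sprintf("  observed: %d/%d papillae associated (%.1f%%)\n",
              x$n_associated, x$n_papillae, x$percent_observed))
  cat(sprintf("  null: mean %.1f%% over %d random placements\n",
              mean(x$null_percents), x$n_sims))
  cat(sprintf("  single-tail P = %s\n",
              format_p_value(x$p_value, x$n_sims)))
  invisible(x)
}

#' @export
summary.papilla_assoc <- function(object, ...) {
  out <- list(
    percent_observed = object$percent_observed,
    null_mean = mean(object$null_percents),
    null_sd = stats::sd(object$null_percents),
    null_q95 = unname(stats::quantile(object$null_percents, 0.95)),
    p_value = object$p_value,
    p_label = format_p_value(object$p_value, object$n_sims),
    n_sims = object$n_sims)
  class(out) <- "summary.papilla_assoc"
  out
}

#' @export
print.summary.papilla_assoc <- function(x, ...) {
  cat(sprintf("observed %.1f%% | null %.1f +/- %.1f%% (95th pct %.1f%%) | P = %s (%d sims)\n",
              x$percent_observed, x$null_mean, x$null_sd, x$null_q95,
              x$p_label, x$n_sims))
  invisible(x)
}

#' @describeIn monte_carlo_test Histogram of the null association
#'   percentages with the observed percentage marked.
#' @param x A `papilla_assoc` object.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.papilla_assoc <- function(x, ...) {
  graphics::hist(x$null_percents,
                 main = "Null association percentages",
                 xlab = "% papillae associated",
                 xlim = range(c(x$null_percents, x$percent_observed)), ...)
  graphics::abline(v = x$percent_observed, col = "red3", lwd = 2)
  invisible(x)
}

#' Draw further null replicates from a fitted association test
#'
#' Re-runs the random placement of the observed bundle dimensions to
#' produce additional null association percentages (the test statistic
#' under the null), e.g. to refine the null distribution after fitting.
#' Requires the original papillae and bundles.
#'
#' @param object A `papilla_assoc` result.
#' @param nsim Number of null replicates to draw.
#' @param seed Optional seed.
#' @param papillae,bundles The inputs of the original test.
#' @param ... Unused.
#' @return Numeric vector of `nsim` null percentages.
#' @export
simulate.papilla_assoc <- function(object, nsim = 1, seed = NULL,
                                   papillae, bundles, ...) {
  res <- monte_carlo_test(papillae, bundles, n_sims = nsim,
                          threshold = object$threshold, seed = seed)
  res$null_percents
}

#' Aggregate per-cell association results into a cohort summary
#'
#' Pools the per-cell association percentages as a mean with its standard
#' error across cells (sample sd with n - 1 denominator; the SE of a
#' single cell is 0 by convention). Per-cell p-values are carried through
#' unchanged.
#'
#' @param results A non-empty list of `papilla_assoc` objects (one per
#'   cell), optionally named by cell id.
#' @return An object of class `papilla_cohort`: a list with
#'   `per_cell_results`, a per-cell data frame `table`, `mean_percent`,
#'   `se_percent` and `n_cells`.
#' @export
aggregate_cells <- function(results) {
  if (!is.list(results) || length(results) == 0L) {
    stop("'results' must be a non-empty list of per-cell association results")
  }
  ok <- vapply(results, inherits, logical(1), what = "papilla_assoc")
  if (!all(ok)) stop("all elements of 'results' must be 'papilla_assoc' objects")
  pct <- vapply(results, `[[`, numeric(1), "percent_observed")
  p <- vapply(results, `[[`, numeric(1), "p_value")
  ns <- vapply(results, `[[`, numeric(1), "n_sims")
  ids <- names(results)
  if (is.null(ids)) ids <- paste0("cell", seq_along(results))
  n <- length(pct)
  se <- if (n == 1L) 0 else stats::sd(pct) / sqrt(n)
  tab <- data.frame(
    cell_id = ids,
    n_papillae = vapply(results, `[[`, numeric(1), "n_papillae"),
    n_bundles = vapply(results, `[[`, numeric(1), "n_bundles"),
    percent_observed = pct,
    p_value = p,
    p_label = format_p_value(p, ns),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(per_cell_results = results, table = tab,
                 mean_percent = mean(pct), se_percent = se, n_cells = n),
            class = "papilla_cohort")
}

#' @export
print.papilla_cohort <- function(x, ...) {
  cat(sprintf("Association cohort: %d cells\n", x$n_cells))
  cat(sprintf("  mean association %.1f +/- %.1f%% (mean +/- SE across cells)\n",
              x$mean_percent, x$se_percent))
  cat("  per-cell results:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
summary.papilla_cohort <- function(object, ...) {
  object
}

#' Run the association test over a list of cells
#'
#' Convenience driver: applies [monte_carlo_test()] to each cell record and
#' aggregates the results. Per-cell seeds are derived deterministically as
#' `seed + cell index`, so a single seed reproduces the whole cohort.
#'
#' @param cells Named list of cell records, each a list with elements
#'   `papillae` ([papilla_pattern()]) and `bundles` ([bundle_set()]), as
#'   produced by [read_pattern_tables()].
#' @inheritParams monte_carlo_test
#' @return A `papilla_cohort` (see [aggregate_cells()]).
#' @export
assoc_test_cells <- function(cells, n_sims = 1000, threshold = 400,
                             seed = NULL, pseudo_count = FALSE) {
  if (length(cells) == 0L) stop("'cells' is empty")
  results <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    s <- if (is.null(seed)) NULL else seed + i
    results[[i]] <- monte_carlo_test(cells[[i]]$papillae, cells[[i]]$bundles,
                                     n_sims = n_sims, threshold = threshold,
                                     seed = s, pseudo_count = pseudo_count)
  }
  names(results) <- names(cells)
  aggregate_cells(results)
}
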