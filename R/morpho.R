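#' Mean wall thickness from cross-sectional area and cell width
#'
#' The uniform wall layer is uneven, so its average thickness is estimated
#' as the measured cross-sectional area divided by the corresponding cell
#' width (nm^2 / nm = nm).
#'
#' @param area Cross-sectional area(s) in nm^2 (> 0).
#' @param width Cell width(s) in nm (> 0), recycled against `area`.
#' @return Mean thickness in nm.
#' @examples
#' mean_wall_thickness(1e6, 5000)  # 200 nm
#' @export
mean_wall_thickness <- function(area, width) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("'area' must be positive")
  }
  if (any(!is.finite(width)) || any(width <= 0)) {
    stop("'width' must be positive")
  }
  area / width
}

#' Classify a cell as having a remodelled actin network
#'
#' A cell counts as remodelled when over 50% of its outer periclinal cell
#' wall/cytoplasmic interface is occupied by short actin bundles; the
#' boundary is strict (exactly 0.5 is not remodelled).
#'
#' @param fraction Proportion(s) in \[0, 1\] of the interface occupied by
#'   short bundles.
#' @return Logical vector.
#' @export
classify_remodelled <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop("'fraction' must lie in [0, 1]")
  }
  fraction > 0.5
}

#' Gap between adjoining papillae
#'
#' Edge-to-edge clearance between neighbouring WI papillae: the
#' centre-to-centre spacing minus one papilla diameter. At the measured
#' geometry (1.5 um spacing, 380 nm diameter) this is 1.12 um — the space
#' a horizontally oriented short actin bundle must fit into.
#'
#' @param spacing Centre-to-centre spacing in nm (> `diameter`).
#' @param diameter Papilla diameter in nm.
#' @return Gap in nm.
#' @examples
#' papilla_gap(1500, 380)  # 1120 nm, i.e. 1.1 um
#' @export
papilla_gap <- function(spacing, diameter) {
  if (any(spacing <= diameter)) {
    stop("'spacing' must exceed 'diameter'")
  }
  spacing - diameter
}

#' Orientation proportions of linear actin bundles
#'
#' Splits a set of linear bundles into horizontal (in the focal plane) and
#' vertical (through-plane, appearing as dots of bundle-diameter size)
#' percentages. Verticality is an upstream observation flag, not inferred
#' from 2-D coordinates.
#'
#' @param vertical Logical vector, one entry per linear bundle: `TRUE` for
#'   through-plane ("dot") bundles.
#' @return Named numeric vector `c(horizontal=, vertical=)`, percentages
#'   summing to 100.
#' @export
orientation_proportions <- function(vertical) {
  if (length(vertical) == 0L) stop("empty bundle set")
  if (!is.logical(vertical) || anyNA(vertical)) {
    stop("'vertical' must be a logical vector without NA")
  }
  pv <- 100 * mean(vertical)
  c(horizontal = 100 - pv, vertical = pv)
}

#' Best lag and squared correlation between two time courses
#'
#' For each candidate lag, series `b` is shifted back by that lag (its
#' values linearly interpolated at `time + lag`), the overlapping points
#' are paired with series `a`, and the squared Pearson correlation is
#' computed. Returns the lag maximizing R^2. If `b` equals `a` displaced
#' later by L hours, the best lag is L with R^2 = 1. Invariant to affine
#' rescaling of either series.
#'
#' @param time Common time grid in hours.
#' @param a,b The two series (e.g. % cells remodelled and % cells with
#'   papillae) on that grid.
#' @param lags Candidate lags in hours (default 0 to 4 h in 0.25 h steps).
#' @return List with `lag` (best lag), `r2` (its R^2) and `profile` (data
#'   frame of lag, r2, n overlapping points).
#' @export
lagged_r2 <- function(time, a, b, lags = seq(0, 4, by = 0.25)) {
  if (length(time) != length(a) || length(time) != length(b)) {
    stop("'time', 'a' and 'b' must have equal length")
  }
  if (length(lags) == 0L) stop("'lags' is empty")
  prof <- data.frame(lag = lags, r2 = NA_real_, n = NA_integer_)
  for (i in seq_along(lags)) {
    shifted <- stats::approx(time, b, xout = time + lags[i], rule = 1)$y
    ok <- !is.na(shifted)
    prof$n[i] <- sum(ok)
    if (sum(ok) >= 3L && stats::sd(a[ok]) > 0 && stats::sd(shifted[ok]) > 0) {
      prof$r2[i] <- stats::cor(a[ok], shifted[ok])^2
    }
  }
  if (all(is.na(prof$r2))) {
    stop("insufficient overlap between the series at every candidate lag")
  }
  best <- which.max(prof$r2)
  list(lag = lags[best], r2 = prof$r2[best], profile = prof)
}
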