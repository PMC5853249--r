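#' Rectangular cell observation window
#'
#' Defines the axis-aligned rectangular window (origin at (0,0), all
#' dimensions in nm) representing the paradermal focal plane of a single
#' adaxial epidermal cell: the long axis of the cell along `width`, the
#' short axis along `height`. All papilla and bundle coordinates are
#' referenced to this window.
#'
#' @param width Extent in nm along the cell long axis (> 0).
#' @param height Extent in nm along the cell short axis (> 0).
#' @return An object of class `cell_region` with elements `width` and
#'   `height`.
#' @examples
#' cell_region(10000, 10000)  # a 10 x 10 micrometre focal plane
#' @export
cell_region <- function(width, height) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
      width <= 0) {
    stop("'width' must be a single positive number (nm)")
  }
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 0) {
    stop("'height' must be a single positive number (nm)")
  }
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "cell_region")
}

#' @export
print.cell_region <- function(x, ...) {
  cat(sprintf("Cell window: %.0f x %.0f nm (%.2f x %.2f um)\n",
              x$width, x$height, x$width / 1000, x$height / 1000))
  invisible(x)
}

.in_region <- function(x, y, region, tol = 1e-9) {
  x >= -tol & x <= region$width + tol & y >= -tol & y <= region$height + tol
}

#' Wall ingrowth papilla point pattern
#'
#' A fixed set of WI papilla centre coordinates inside a cell window.
#' Papilla centres are measured observations and are never resampled by the
#' association test; only the bundles are randomized.
#'
#' @param x,y Numeric vectors of papilla centre coordinates (nm), equal
#'   length, all inside `region`.
#' @param region A [cell_region()].
#' @param diameter Papilla diameter in nm (default 380, the measured
#'   diameter of WI papillae).
#' @return An object of class `papilla_pattern` with elements `x`, `y`,
#'   `diameter` and `region`.
#' @export
papilla_pattern <- function(x, y, region, diameter = 380) {
  stopifnot(inherits(region, "cell_region"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (anyNA(x) || anyNA(y)) stop("papilla coordinates contain NA")
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0) {
    stop("'diameter' must be a single positive number (nm)")
  }
  bad <- !.in_region(x, y, region)
  if (any(bad)) {
    stop(sprintf("%d papilla centre(s) fall outside the cell window (first: (%g, %g))",
                 sum(bad), x[which(bad)[1]], y[which(bad)[1]]))
  }
  structure(list(x = x, y = y, diameter = diameter, region = region),
            class = "papilla_pattern")
}

#' @export
print.papilla_pattern <- function(x, ...) {
  cat(sprintf("Papilla pattern: %d centres, diameter %g nm, in %.0f x %.0f nm window\n",
              length(x$x), x$diameter, x$region$width, x$region$height))
  invisible(x)
}

#' @export
length.papilla_pattern <- function(x) length(x$x)

#' Set of actin bundle segments within a cell window
#'
#' Holds the short actin bundles recorded in one focal plane. Linear
#' bundles store their two endpoints; circular bundles (actin rings around
#' initiating papillae) store their centre in (`x1`, `y1`) and their ring
#' diameter in `x2`. Only linear bundles have ends and hence only they
#' participate in the end-to-papilla association statistic.
#'
#' @param x1,y1,x2,y2 Numeric endpoint coordinates in nm (see above for the
#'   circular convention; `y2` is ignored for circular bundles).
#' @param diameter Bundle diameter(s) in nm, recycled to the number of
#'   segments.
#' @param shape Character vector of `"linear"` or `"circular"`, recycled.
#' @param region A [cell_region()]; linear segments must lie entirely
#'   inside it and circular centres must fall inside it.
#' @return An object of class `bundle_set`: a list with a data frame
#'   `segments` and the `region`.
#' @export
bundle_set <- function(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                       y2 = numeric(), diameter = numeric(),
                       shape = "linear", region) {
  stopifnot(inherits(region, "cell_region"))
  n <- length(x1)
  if (length(y1) != n || length(x2) != n ||
      (length(y2) != n && n > 0)) {
    stop("endpoint coordinate vectors must have equal length")
  }
  if (n == 0L) {
    seg <- data.frame(shape = character(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), diameter = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(list(segments = seg, region = region),
                     class = "bundle_set"))
  }
  shape <- rep_len(as.character(shape), n)
  diameter <- rep_len(as.numeric(diameter), n)
  bad_shape <- !shape %in% c("linear", "circular")
  if (any(bad_shape)) {
    stop(sprintf("unknown bundle shape '%s' (row %d); must be 'linear' or 'circular'",
                 shape[which(bad_shape)[1]], which(bad_shape)[1]))
  }
  if (any(!is.finite(diameter) | diameter <= 0)) {
    stop("all bundle diameters must be positive")
  }
  lin <- shape == "linear"
  if (any(lin)) {
    len <- sqrt((x2[lin] - x1[lin])^2 + (y2[lin] - y1[lin])^2)
    if (any(len <= 0)) stop("linear bundles must have positive length")
    ok <- .in_region(x1[lin], y1[lin], region) &
      .in_region(x2[lin], y2[lin], region)
    if (!all(ok)) {
      stop(sprintf("%d linear bundle(s) extend outside the cell window",
                   sum(!ok)))
    }
  }
  circ <- !lin
  if (any(circ)) {
    if (any(!is.finite(x2[circ]) | x2[circ] <= 0)) {
      stop("circular bundles must have a positive ring diameter in 'x2'")
    }
    if (!all(.in_region(x1[circ], y1[circ], region))) {
      stop("circular bundle centres must lie inside the cell window")
    }
  }
  seg <- data.frame(shape = shape, x1 = as.numeric(x1), y1 = as.numeric(y1),
                    x2 = as.numeric(x2),
                    y2 = ifelse(lin, as.numeric(y2), NA_real_),
                    diameter = diameter, stringsAsFactors = FALSE)
  structure(list(segments = seg, region = region), class = "bundle_set")
}

#' @export
print.bundle_set <- function(x, ...) {
  n_lin <- sum(x$segments$shape == "linear")
  n_cir <- nrow(x$segments) - n_lin
  cat(sprintf("Bundle set: %d segments (%d linear, %d circular) in %.0f x %.0f nm window\n",
              nrow(x$segments), n_lin, n_cir,
              x$region$width, x$region$height))
  invisible(x)
}

#' @export
length.bundle_set <- function(x) nrow(x$segments)

#' Extract the linear bundles of a bundle set
#'
#' @param bundles A [bundle_set()].
#' @return A `bundle_set` containing only the linear segments.
#' @export
linear_bundles <- function(bundles) {
  stopifnot(inherits(bundles, "bundle_set"))
  seg <- bundles$segments[bundles$segments$shape == "linear", , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(segments = seg, region = bundles$region),
            class = "bundle_set")
}

#' Lengths of the linear segments of a bundle set
#'
#' @param bundles A [bundle_set()].
#' @return Numeric vector of Euclidean lengths (nm) of the linear segments.
#' @export
bundle_lengths <- function(bundles) {
  seg <- linear_bundles(bundles)$segments
  sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
}
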