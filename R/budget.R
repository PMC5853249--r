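#' Geometry of a wall ingrowth papilla
#'
#' A WI papilla is modelled as a cylinder of diameter `diameter`
#' protruding `height` into the cytoplasm, closed either by a flat cap or
#' by a hemispherical cap (in which case the cylindrical shank has height
#' `height - diameter/2`).
#'
#' @param diameter Papilla diameter in nm (default 380, the measured
#'   value).
#' @param height Protrusion depth into the cytoplasm in nm (default 500).
#' @param cap `"flat"` or `"hemispherical"`.
#' @return Object of class `papilla_geometry`.
#' @export
papilla_geometry <- function(diameter = 380, height = 500,
                             cap = c("flat", "hemispherical")) {
  cap <- match.arg(cap)
  if (diameter <= 0 || height <= 0) stop("dimensions must be positive")
  if (cap == "hemispherical" && height < diameter / 2) {
    stop("'height' must be at least diameter/2 for a hemispherical cap")
  }
  structure(list(diameter = diameter, height = height, cap = cap),
            class = "papilla_geometry")
}

# surface area retained on the papilla and papilla wall volume
.papilla_surface_volume <- function(geom) {
  d <- geom$diameter; h <- geom$height; r <- d / 2
  if (geom$cap == "flat") {
    list(area = pi * d * h + pi * d^2 / 4,
         volume = pi * r^2 * h)
  } else {
    shank <- h - r
    list(area = pi * d * shank + pi * d^2 / 2,
         volume = pi * r^2 * shank + (2 / 3) * pi * r^3)
  }
}

#' Plasma-membrane budget of WI papilla construction
#'
#' Balances the membrane delivered by exocytosis against the membrane
#' retained on the papilla surface to estimate the fraction retrieved by
#' endocytosis. The papilla wall volume `V_p` follows from the papilla
#' solid; only the fraction `1 - callose_fraction` of that volume is
#' delivered by vesicles (callose is synthesized in situ at the plasma
#' membrane), so the delivered volume is `V_d = (1 - f_c) V_p`. A
#' spherical vesicle of diameter `d_v` carries membrane area per cargo
#' volume `6/d_v`, giving fused area `A_fus = 6 V_d / d_v`. The retained
#' area `A_ret` is the papilla surface, and the retrieval fraction is
#' `R = 1 - A_ret/A_fus`, clamped at 0 (with a warning flag) when more
#' membrane is retained than fused.
#'
#' @param geom A [papilla_geometry()].
#' @param vesicle_diameter Exocytotic vesicle diameter in nm (> 0).
#' @param callose_fraction Proportion in \[0, 1) of papilla wall volume
#'   synthesized in situ rather than vesicle-delivered.
#' @return Object of class `membrane_budget`: list with `retained_area`,
#'   `wall_volume`, `delivered_volume`, `fused_area`,
#'   `retrieval_fraction`, `clamped` and the inputs.
#' @examples
#' g <- papilla_geometry(380, 500, "flat")
#' compute_budget(g, vesicle_diameter = 100, callose_fraction = 0.5)
#' @export
compute_budget <- function(geom, vesicle_diameter, callose_fraction = 0) {
  stopifnot(inherits(geom, "papilla_geometry"))
  if (vesicle_diameter <= 0) stop("'vesicle_diameter' must be positive")
  if (callose_fraction < 0 || callose_fraction > 1) {
    stop("'callose_fraction' must lie in [0, 1]")
  }
  if (callose_fraction == 1) {
    stop("callose_fraction = 1 leaves no vesicle-delivered volume; budget undefined")
  }
  sv <- .papilla_surface_volume(geom)
  v_d <- (1 - callose_fraction) * sv$volume
  a_fus <- 6 * v_d / vesicle_diameter
  if (a_fus == 0) stop("fused membrane area is zero; budget undefined")
  r <- 1 - sv$area / a_fus
  clamped <- r < 0
  if (clamped) {
    warning("retained area exceeds fused area; retrieval fraction clamped to 0")
    r <- 0
  }
  structure(list(retained_area = sv$area, wall_volume = sv$volume,
                 delivered_volume = v_d, fused_area = a_fus,
                 retrieval_fraction = r, clamped = clamped,
                 geometry = geom, vesicle_diameter = vesicle_diameter,
                 callose_fraction = callose_fraction),
            class = "membrane_budget")
}

#' @export
print.membrane_budget <- function(x, ...) {
  g <- x$geometry
  cat("Plasma-membrane budget of one WI papilla\n")
  cat(sprintf("  papilla: d = %g nm, h = %g nm, %s cap\n",
              g$diameter, g$height, g$cap))
  cat(sprintf("  vesicle diameter %g nm, callose fraction %.2f\n",
              x$vesicle_diameter, x$callose_fraction))
  cat(sprintf("  retained area  %.4g nm^2\n", x$retained_area))
  cat(sprintf("  wall volume    %.4g nm^3 (delivered %.4g nm^3)\n",
              x$wall_volume, x$delivered_volume))
  cat(sprintf("  fused area     %.4g nm^2\n", x$fused_area))
  cat(sprintf("  retrieval      %.1f%% of fused membrane%s\n",
              100 * x$retrieval_fraction,
              if (x$clamped) " (clamped)" else ""))
  invisible(x)
}

#' Calibrate one budget parameter to a target retrieval fraction
#'
#' Solves `compute_budget(...)$retrieval_fraction == target_R` for either
#' the vesicle diameter or the callose fraction, holding the other fixed,
#' by bisection to a relative tolerance of 1e-9. The retrieval fraction is
#' strictly decreasing in both parameters, so the solution is unique when
#' feasible.
#'
#' @param geom A [papilla_geometry()].
#' @param target_R Target retrieval fraction in (0, 1).
#' @param free Which parameter to solve for: `"vesicle_diameter"` or
#'   `"callose_fraction"`.
#' @param vesicle_diameter,callose_fraction The fixed parameter (supply
#'   the one not being solved for).
#' @return The calibrated parameter value.
#' @export
calibrate_budget <- function(geom, target_R,
                             free = c("vesicle_diameter", "callose_fraction"),
                             vesicle_diameter = NULL,
                             callose_fraction = NULL) {
  free <- match.arg(free)
  if (target_R <= 0 || target_R >= 1) stop("'target_R' must lie in (0, 1)")
  r_of <- if (free == "vesicle_diameter") {
    if (is.null(callose_fraction)) {
      stop("supply the fixed 'callose_fraction'")
    }
    function(v) {
      b <- suppressWarnings(compute_budget(geom, vesicle_diameter = v,
                                           callose_fraction = callose_fraction))
      # recover the unclamped value so bisection stays monotone below 0
      1 - b$retained_area / b$fused_area
    }
  } else {
    if (is.null(vesicle_diameter)) {
      stop("supply the fixed 'vesicle_diameter'")
    }
    function(v) {
      b <- suppressWarnings(compute_budget(geom, vesicle_diameter = vesicle_diameter,
                                           callose_fraction = v))
      1 - b$retained_area / b$fused_area
    }
  }
  # bracket: R is strictly decreasing in the free parameter in both cases
  if (free == "vesicle_diameter") {
    lo <- 1e-12
    hi <- 1
    while (r_of(hi) > target_R) {
      hi <- hi * 2
      if (hi > 1e12) stop("target retrieval fraction infeasible")
    }
  } else {
    lo <- 0
    hi <- 1 - 1e-15
    if (r_of(lo) < target_R) stop("target retrieval fraction infeasible at callose_fraction = 0")
  }
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (r_of(mid) >= target_R) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-9 * max(abs(hi), 1e-30)) break
  }
  (lo + hi) / 2
}
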