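#' Generate a jittered lattice of WI papilla centres
#'
#' Emulates the measured geometry of WI papillae: a square lattice at the
#' measured centre-to-centre spacing (1.5 um), each site displaced by an
#' isotropic Gaussian jitter, with points falling outside the window
#' dropped. The lattice holds `floor(width/spacing) x floor(height/spacing)`
#' sites with centres at `(k + 0.5) * spacing`, so the realized density
#' approaches `1/spacing^2` for large windows.
#'
#' @param region A [cell_region()].
#' @param spacing Centre-to-centre lattice pitch in nm (default 1500).
#' @param jitter_sd Standard deviation (nm) of the isotropic Gaussian
#'   jitter applied to each site (default 0).
#' @param diameter Papilla diameter in nm (default 380).
#' @param seed Optional integer seed.
#' @return A [papilla_pattern()].
#' @examples
#' reg <- cell_region(10000, 10000)
#' length(generate_papilla_lattice(reg))  # 36 sites on a 6 x 6 grid
#' @export
generate_papilla_lattice <- function(region, spacing = 1500, jitter_sd = 0,
                                     diameter = 380, seed = NULL) {
  stopifnot(inherits(region, "cell_region"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("'spacing' must be a single positive number (nm)")
  }
  if (spacing <= diameter) stop("'spacing' must exceed the papilla diameter")
  if (jitter_sd < 0) stop("'jitter_sd' must be >= 0")
  nx <- floor(region$width / spacing)
  ny <- floor(region$height / spacing)
  if (nx < 1 || ny < 1) {
    stop("window too small to hold a single lattice site at this spacing")
  }
  gx <- (seq_len(nx) - 0.5) * spacing
  gy <- (seq_len(ny) - 0.5) * spacing
  x <- rep(gx, times = ny)
  y <- rep(gy, each = nx)
  if (!is.null(seed)) set.seed(seed)
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, jitter_sd)
    y <- y + stats::rnorm(length(y), 0, jitter_sd)
    keep <- .in_region(x, y, region)
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) == 0L) stop("all jittered lattice sites fell outside the window")
  papilla_pattern(x, y, region, diameter = diameter)
}

# truncated-normal sampling (> lower), by rejection; means/sds vectorized
.rtnorm_pos <- function(n, mean, sd, lower = 0) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
    guard <- guard + 1L
    if (guard > 1e4) stop("truncated-normal sampling failed to converge")
  }
  out
}

#' Generate actin bundles with a controllable papilla-associated fraction
#'
#' Draws `n_bundles` linear bundles whose lengths and diameters follow
#' truncated normal distributions around the measured dimensions of short,
#' thin actin bundles (1.1 um x 150 nm). Each bundle is, independently with
#' probability `assoc_fraction`, "attached": one endpoint is placed
#' uniformly in the disc of radius `attach_radius` around a uniformly
#' chosen papilla centre (so that endpoint satisfies the association
#' criterion by construction), with orientation uniform and the far
#' endpoint kept inside the window by re-drawing the orientation.
#' Non-attached bundles are placed exactly as [place_random_bundles()].
#'
#' @param papillae A [papilla_pattern()]; required non-empty when
#'   `assoc_fraction > 0`.
#' @param region A [cell_region()].
#' @param n_bundles Number of bundles to draw.
#' @param assoc_fraction Probability in \[0, 1\] that a bundle is attached
#'   to a papilla.
#' @param length_mean,length_sd Bundle length distribution in nm
#'   (defaults 1100 and 100).
#' @param diameter_mean,diameter_sd Bundle diameter distribution in nm
#'   (defaults 150 and 40).
#' @param attach_radius Attachment disc radius in nm (default 400, the
#'   association threshold).
#' @param seed Optional integer seed.
#' @return A [bundle_set()] of `n_bundles` linear segments.
#' @export
generate_bundles <- function(papillae, region, n_bundles,
                             assoc_fraction = 0,
                             length_mean = 1100, length_sd = 100,
                             diameter_mean = 150, diameter_sd = 40,
                             attach_radius = 400, seed = NULL) {
  stopifnot(inherits(region, "cell_region"))
  if (assoc_fraction < 0 || assoc_fraction > 1) {
    stop("'assoc_fraction' must lie in [0, 1]")
  }
  if (assoc_fraction > 0) {
    stopifnot(inherits(papillae, "papilla_pattern"))
    if (length(papillae) == 0L) {
      stop("papillae must be non-empty when 'assoc_fraction' > 0")
    }
  }
  if (length_mean <= 0 || diameter_mean <= 0 || length_sd < 0 ||
      diameter_sd < 0 || attach_radius <= 0) {
    stop("invalid bundle generation parameters")
  }
  if (!is.null(seed)) set.seed(seed)
  n_bundles <- as.integer(n_bundles)
  lens <- .rtnorm_pos(n_bundles, length_mean, length_sd)
  dias <- .rtnorm_pos(n_bundles, diameter_mean, diameter_sd)
  if (any(lens >= min(region$width, region$height))) {
    stop("sampled bundle length exceeds the window; infeasible geometry")
  }
  attached <- stats::runif(n_bundles) < assoc_fraction
  x1 <- x2 <- y1 <- y2 <- numeric(n_bundles)
  free <- which(!attached)
  if (length(free) > 0L) {
    pl <- .place_segments(region$width, region$height, lens[free])
    x1[free] <- pl$x1; y1[free] <- pl$y1
    x2[free] <- pl$x2; y2[free] <- pl$y2
  }
  for (i in which(attached)) {
    placed <- FALSE
    for (try_pt in seq_len(1000L)) {
      j <- sample.int(length(papillae), 1L)
      r <- attach_radius * sqrt(stats::runif(1))
      a <- stats::runif(1, 0, 2 * pi)
      px <- papillae$x[j] + r * cos(a)
      py <- papillae$y[j] + r * sin(a)
      if (!.in_region(px, py, region)) next
      for (try_ang in seq_len(1000L)) {
        phi <- stats::runif(1, 0, 2 * pi)
        qx <- px + lens[i] * cos(phi)
        qy <- py + lens[i] * sin(phi)
        if (.in_region(qx, qy, region)) {
          x1[i] <- px; y1[i] <- py; x2[i] <- qx; y2[i] <- qy
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) stop("could not place an attached bundle; infeasible geometry")
  }
  bundle_set(x1, y1, x2, y2, diameter = dias, shape = "linear",
             region = region)
}

#' Generate a synthetic single-cell coordinate dataset
#'
#' Bundles a jittered papilla lattice and a bundle set with a prescribed
#' associated fraction into one cell record, the unit consumed by
#' [monte_carlo_test()] and [assoc_test_cells()].
#'
#' @inheritParams generate_bundles
#' @inheritParams generate_papilla_lattice
#' @param n_papillae Optional cap: when smaller than the number of lattice
#'   sites, that many sites are subsampled without replacement (keeps the
#'   lattice spacing while matching a prescribed papilla count).
#' @return A list with elements `papillae` and `bundles`.
#' @export
generate_cell <- function(region, n_bundles, assoc_fraction = 0,
                          spacing = 1500, jitter_sd = 100,
                          n_papillae = NULL, diameter = 380,
                          length_mean = 1100, length_sd = 100,
                          diameter_mean = 150, diameter_sd = 40,
                          attach_radius = 400, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pap <- generate_papilla_lattice(region, spacing = spacing,
                                  jitter_sd = jitter_sd,
                                  diameter = diameter)
  if (!is.null(n_papillae) && n_papillae < length(pap)) {
    keep <- sample.int(length(pap), n_papillae)
    pap <- papilla_pattern(pap$x[keep], pap$y[keep], region,
                           diameter = diameter)
  }
  bnd <- generate_bundles(pap, region, n_bundles,
                          assoc_fraction = assoc_fraction,
                          length_mean = length_mean, length_sd = length_sd,
                          diameter_mean = diameter_mean,
                          diameter_sd = diameter_sd,
                          attach_radius = attach_radius)
  list(papillae = pap, bundles = bnd)
}

#' Generate a raw per-cell regional fluorescence dataset
#'
#' Emulates the sampling design of the FM4-64FX experiments: for each
#' treatment (including the BFA baseline), regional pixel intensities are
#' recorded in `n_cells` cells within each of `n_cotyledons` replicate
#' cotyledons; a cell's intensity is the regional true mean plus Gaussian
#' cell-to-cell noise.
#'
#' @param true_means Data frame with columns `treatment`, `region`, `mean`
#'   giving the per-treatment, per-region true intensities. One treatment
#'   label is the BFA baseline.
#' @param cell_sd Cell-to-cell noise standard deviation (intensity units).
#' @param n_cells Cells measured per cotyledon (default 25).
#' @param n_cotyledons Replicate cotyledons (default 4).
#' @param seed Optional integer seed.
#' @return Long-format data frame with columns `treatment`, `cotyledon`,
#'   `cell`, `region`, `intensity`.
#' @export
generate_fluorescence_dataset <- function(true_means, cell_sd = 20,
                                          n_cells = 25, n_cotyledons = 4,
                                          seed = NULL) {
  req <- c("treatment", "region", "mean")
  if (!is.data.frame(true_means) || !all(req %in% names(true_means))) {
    stop("'true_means' must be a data frame with columns treatment, region, mean")
  }
  if (cell_sd < 0) stop("'cell_sd' must be >= 0")
  if (n_cells < 1 || n_cotyledons < 1) stop("counts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_rep <- n_cells * n_cotyledons
  out <- do.call(rbind, lapply(seq_len(nrow(true_means)), function(i) {
    data.frame(treatment = true_means$treatment[i],
               cotyledon = rep(seq_len(n_cotyledons), each = n_cells),
               cell = rep(seq_len(n_cells), times = n_cotyledons),
               region = true_means$region[i],
               intensity = true_means$mean[i] + stats::rnorm(n_rep, 0, cell_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize a raw fluorescence dataset to a regional mean/SE table
#'
#' Averages the `n_cells` cells within each cotyledon, then reports the
#' mean and standard error across cotyledons for every treatment x region
#' combination — the summary format consumed by [bfa_correct_table()].
#'
#' @param raw Long-format data frame from
#'   [generate_fluorescence_dataset()] (columns `treatment`, `cotyledon`,
#'   `region`, `intensity`).
#' @return Data frame with columns `treatment`, `region`, `mean`, `se`,
#'   `n` (number of cotyledons).
#' @export
summarize_fluorescence <- function(raw) {
  req <- c("treatment", "cotyledon", "region", "intensity")
  if (!all(req %in% names(raw))) {
    stop("'raw' must contain columns treatment, cotyledon, region, intensity")
  }
  cm <- stats::aggregate(intensity ~ treatment + region + cotyledon,
                         data = raw, FUN = mean)
  agg <- stats::aggregate(intensity ~ treatment + region, data = cm,
                          FUN = function(v) {
                            c(mean = mean(v),
                              se = if (length(v) > 1) {
                                stats::sd(v) / sqrt(length(v))
                              } else 0,
                              n = length(v))
                          })
  out <- data.frame(treatment = agg$treatment, region = agg$region,
                    mean = agg$intensity[, "mean"],
                    se = agg$intensity[, "se"],
                    n = as.integer(agg$intensity[, "n"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate paired remodelling / papilla-formation time courses
#'
#' Produces the percentage of cells with a remodelled actin network over a
#' culture time grid as a logistic rise, and the percentage of cells with
#' WI papillae as the same logistic displaced later by `lag_h` hours, with
#' optional additive Gaussian noise (values clamped to \[0, 100\]).
#'
#' @param lag_h Lag (hours, >= 0) of papilla formation behind actin
#'   remodelling.
#' @param noise_sd Additive noise standard deviation in percentage points.
#' @param times Time grid in hours (default hourly over 0-15 h of
#'   culture).
#' @param midpoint,rate Logistic midpoint (h) and time scale (h) of the
#'   remodelling curve (defaults 6 and 1.5).
#' @param seed Optional integer seed.
#' @return Data frame with columns `time_h`, `pct_remodelled`,
#'   `pct_papillae`.
#' @export
generate_timecourse <- function(lag_h = 1, noise_sd = 0, times = 0:15,
                                midpoint = 6, rate = 1.5, seed = NULL) {
  if (lag_h < 0) stop("'lag_h' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  logistic <- function(t) 100 / (1 + exp(-(t - midpoint) / rate))
  a <- logistic(times)
  b <- logistic(times - lag_h)
  if (noise_sd > 0) {
    a <- pmin(100, pmax(0, a + stats::rnorm(length(times), 0, noise_sd)))
    b <- pmin(100, pmax(0, b + stats::rnorm(length(times), 0, noise_sd)))
  }
  data.frame(time_h = times, pct_remodelled = a, pct_papillae = b)
}
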