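# Independent oracles kept deliberately naive: plain loops, no reuse of the
# package's vectorized internals.

# brute-force O(papillae x ends) association count
brute_force_assoc <- function(papillae, bundles, threshold = 400) {
  seg <- bundles$segments[bundles$segments$shape == "linear", , drop = FALSE]
  flags <- rep(FALSE, length(papillae$x))
  for (i in seq_along(papillae$x)) {
    for (j in seq_len(nrow(seg))) {
      for (end in 1:2) {
        ex <- if (end == 1) seg$x1[j] else seg$x2[j]
        ey <- if (end == 1) seg$y1[j] else seg$y2[j]
        d <- sqrt((papillae$x[i] - ex)^2 + (papillae$y[i] - ey)^2)
        if (d < threshold) flags[i] <- TRUE
      }
    }
  }
  sum(flags)
}

# one-segment-at-a-time accept/reject placement: the conditioned-uniform
# oracle for the null placement distribution
naive_place_one <- function(width, height, len) {
  repeat {
    mx <- runif(1, 0, width); my <- runif(1, 0, height)
    th <- runif(1, 0, pi)
    x1 <- mx - len / 2 * cos(th); y1 <- my - len / 2 * sin(th)
    x2 <- mx + len / 2 * cos(th); y2 <- my + len / 2 * sin(th)
    if (x1 >= 0 && x1 <= width && x2 >= 0 && x2 <= width &&
        y1 >= 0 && y1 <= height && y2 >= 0 && y2 <= height) {
      return(c(x1 = x1, y1 = y1, x2 = x2, y2 = y2, mx = mx))
    }
  }
}

# random test instance for property checks
random_instance <- function(region) {
  n_pap <- sample(3:25, 1)
  pap <- papilla_pattern(runif(n_pap, 0, region$width),
                         runif(n_pap, 0, region$height), region)
  n_b <- sample(0:25, 1)
  if (n_b > 0) {
    bnd <- place_random_bundles(region, lengths = runif(n_b, 300, 2000))
  } else {
    bnd <- bundle_set(region = region)
  }
  list(papillae = pap, bundles = bnd)
}

# nearest papilla-centre distance for each (x, y) point
distance_to_nearest_papilla <- function(x, y, papillae) {
  vapply(seq_along(x), function(i) {
    min(sqrt((papillae$x - x[i])^2 + (papillae$y - y[i])^2))
  }, numeric(1))
}
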