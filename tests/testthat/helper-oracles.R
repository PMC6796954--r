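# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths.

# Exact distribution of the range of a k-subset of `values`, by the
# order-statistic identity: the number of k-subsets with minimum x_(i) and
# maximum x_(j) is choose(j - i - 1, k - 2).
range_null_moments_oracle <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  total <- choose(n, k)
  m1 <- 0
  m2 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      w <- choose(j - i - 1, k - 2) / total
      r <- x[j] - x[i]
      m1 <- m1 + w * r
      m2 <- m2 + w * r^2
    }
  }
  # k-subsets with all values tied contribute range 0 (only when k > the
  # span allows); with distinct values min < max always except k = 1
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Monte-Carlo voxel integration of an ellipsoid with full axes L, W, H.
ellipsoid_volume_mc_oracle <- function(L, W, H, n = 3e5) {
  x <- runif(n, -L / 2, L / 2)
  y <- runif(n, -W / 2, W / 2)
  z <- runif(n, -H / 2, H / 2)
  inside <- (x / (L / 2))^2 + (y / (W / 2))^2 + (z / (H / 2))^2 <= 1
  mean(inside) * L * W * H
}

# A tiny, fast generator configuration for property tests.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_species = c(bee = 30L, fly = 20L),
                   n_individuals = c(bee = 240L, fly = 120L),
                   n_sites_per_zone = 2L)
  do.call(generator_config,
          c(args, defaults[setdiff(names(defaults), names(args))]))
}

# Build a specimen table by hand (bypasses the generator).
manual_specimens <- function(darkness, volume = NULL, taxon = "bee",
                             life_zone = "ponderosa", cup_id = "cup1",
                             season = "pre_monsoon", species_id = "sp1") {
  n <- length(darkness)
  if (is.null(volume)) volume <- rep(100, n)
  data.frame(
    specimen_id = sprintf("m%04d", seq_len(n)),
    taxon = rep_len(taxon, n),
    species_id = rep_len(species_id, n),
    life_zone = rep_len(life_zone, n),
    site_id = paste0(rep_len(life_zone, n), "_s1"),
    habitat = "meadow",
    season = rep_len(season, n),
    cup_color = "blue",
    body_volume_mm3 = volume,
    darkness = darkness,
    cup_id = rep_len(cup_id, n),
    stringsAsFactors = FALSE
  )
}
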