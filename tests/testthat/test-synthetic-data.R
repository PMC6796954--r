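test_that("configuration validation names the offending field", {
  expect_error(generator_config(n_cups_per_array = 0), "n_cups_per_array")
  expect_error(generator_config(n_sites_per_zone = 2.5), "n_sites_per_zone")
  expect_error(generator_config(p_spill = 1.5), "p_spill")
  expect_error(
    generator_config(zone_trait_means = list(
      bee = list(volume = c(302, 302, 598), darkness = c(35, 35, 300)),
      fly = default_zone_trait_means()$fly)),
    "darkness")
  expect_error(
    generator_config(filtering_strength = list(bee = c(0, 0, -1),
                                               fly = c(0, 0, 0))),
    "filtering_strength")
  expect_silent(validate_config(generator_config()))
})

test_that("design layout produces one slot per cup per season", {
  d <- build_design(generator_config())
  expect_equal(nrow(d), 216L)
  expect_equal(attr(d, "slots_per_season"), 108L)
  expect_equal(sum(d$season == "pre_monsoon"), 108L)
  # colors balanced within arrays: 4 of each per 12-cup array
  one_array <- d[d$site_id == d$site_id[1] & d$season == "pre_monsoon", ]
  expect_equal(as.vector(table(one_array$cup_color)), c(4L, 4L, 4L))

  minimal <- generator_config(
    zones = data.frame(life_zone = "ponderosa", elevation_m = 2400),
    n_sites_per_zone = 1L, n_cups_per_array = 1L, seasons = "pre_monsoon",
    zone_trait_means = lapply(default_zone_trait_means(),
                              lapply, function(v) v[1]),
    filtering_strength = list(bee = 0, fly = 0),
    zone_abundance = list(bee = 1, fly = 1),
    zone_richness = list(bee = 1, fly = 1))
  expect_equal(nrow(build_design(minimal)), 1L)

  two_by_two <- generator_config(
    zones = default_zones()[1:2, ], n_sites_per_zone = 2L,
    zone_trait_means = lapply(default_zone_trait_means(),
                              lapply, function(v) v[1:2]),
    filtering_strength = list(bee = c(0, 0), fly = c(0, 0)),
    zone_abundance = list(bee = c(0.5, 0.5), fly = c(0.5, 0.5)),
    zone_richness = list(bee = c(0.5, 0.5), fly = c(0.5, 0.5)))
  expect_equal(nrow(build_design(two_by_two)), 2L * 2L * 12L * 2L)
})

test_that("species pools respect filtering limits and taxon checks", {
  cfg <- tiny_config()
  expect_error(draw_species_pool(cfg, "wasp"), "unknown taxon")

  # zero filtering: spruce-fir and ponderosa bee pools share the
  # distribution family (same spread up to sampling noise, shifted mean)
  cfg0 <- tiny_config(
    n_species = c(bee = 4000L, fly = 20L),
    filtering_strength = list(bee = c(0, 0, 0), fly = c(0, 0, 0)))
  p0 <- draw_species_pool(cfg0, "bee", seed = 7)
  by_home <- split(p0$species$mean_darkness, p0$species$home_zone)
  expect_gt(sd(by_home$spruce_fir), 0.8 * sd(by_home$ponderosa))
  expect_lt(sd(by_home$spruce_fir), 1.25 * sd(by_home$ponderosa))

  # increasing filtering strength collapses the filtered pool's spread
  # toward zero (the bounded darkness scale approaches it gradually)
  sf_sd <- vapply(c(0, 30, 1e6), function(fs) {
    cfg_fs <- tiny_config(
      n_species = c(bee = 500L, fly = 20L),
      filtering_strength = list(bee = c(0, 0, fs), fly = c(0, 0, 0)))
    p <- draw_species_pool(cfg_fs, "bee", seed = 7)
    sd(p$species$mean_darkness[p$species$home_zone == "spruce_fir"])
  }, numeric(1))
  expect_true(all(diff(sf_sd) < 0))
  expect_lt(sf_sd[3], 3)

  # truncated-and-recentred pool still targets the configured zone mean
  cfg_big <- generator_config(n_species = c(bee = 10000L, fly = 20L))
  pb <- draw_species_pool(cfg_big, "bee", seed = 11)
  sfb <- pb$species[pb$species$home_zone == "spruce_fir", ]
  se <- sd(sfb$mean_darkness) / sqrt(nrow(sfb))
  expect_lt(abs(mean(sfb$mean_darkness) - 78), 2 * se + 1e-6)

  # richness declines with elevation under the default weights
  home_counts <- table(factor(pb$species$home_zone,
                              levels = default_zones()$life_zone))
  expect_true(all(diff(as.integer(home_counts)) < 0))
})

test_that("assembled datasets conserve counts and trait bounds", {
  cfg <- tiny_config()
  spec <- assemble_dataset(cfg, seed = 5)
  expect_equal(nrow(spec), 360L)
  expect_equal(as.vector(table(spec$taxon)), c(240L, 120L))
  expect_true(all(spec$darkness >= 0 & spec$darkness <= 222))
  expect_true(all(spec$body_volume_mm3 > 0))
  expect_true(all(spec$life_zone %in% cfg$zones$life_zone))
  expect_true(all(spec$cup_color %in% cfg$cup_colors))

  # determinism: identical (config, seed) gives identical tables
  expect_identical(spec, assemble_dataset(cfg, seed = 5))
  spec2 <- assemble_dataset(cfg, seed = 6)
  expect_false(identical(spec, spec2))

  # one-taxon run
  only_bee <- assemble_dataset(
    tiny_config(n_individuals = c(bee = 50L, fly = 0L)), seed = 1)
  expect_true(all(only_bee$taxon == "bee"))
  expect_equal(nrow(only_bee), 50L)
  expect_error(
    assemble_dataset(tiny_config(n_individuals = c(bee = 0L, fly = 0L))),
    "configuration error")
})

test_that("stronger bee filtering narrows within-cup ranges at spruce-fir", {
  mean_sf_range <- function(fs, seed) {
    cfg <- tiny_config(
      n_individuals = c(bee = 400L, fly = 20L),
      filtering_strength = list(bee = c(0, 0, fs), fly = c(0, 0, 0)))
    spec <- assemble_dataset(cfg, seed = seed)
    s <- group_samples(spec[spec$taxon == "bee", ])
    rng <- trait_range(s, "darkness")
    mean(rng$obs_range[rng$life_zone == "spruce_fir" & rng$range_defined])
  }
  seeds <- 1:50
  r_none <- vapply(seeds, function(s) mean_sf_range(0, s), numeric(1))
  r_strong <- vapply(seeds, function(s) mean_sf_range(30, s), numeric(1))
  expect_lt(mean(r_strong), mean(r_none))
  # the contrast is large, not marginal
  expect_lt(mean(r_strong), 0.75 * mean(r_none))
})

test_that("configs round-trip through yaml and json files", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("n_sites_per_zone: 2", "p_spill: 0.1", "seed: 99"), yml)
  cfg <- read_config(yml)
  expect_equal(cfg$n_sites_per_zone, 2L)
  expect_equal(cfg$p_spill, 0.1)
  expect_equal(cfg$seed, 99)

  jsn <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(n_cups_per_array = 6,
                            cup_colors = c("white", "blue")),
                       jsn, auto_unbox = TRUE)
  cfg2 <- read_config(jsn)
  expect_equal(cfg2$n_cups_per_array, 6L)
  expect_equal(nrow(build_design(cfg2)) %% 6L, 0L)

  expect_error(read_config(file.path(dir, "missing.yaml")), "not found")
  writeLines("bogus_field: 1", yml)
  expect_error(read_config(yml), "unknown config field")
})
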