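#' Generate a synthetic specimen table
#'
#' Runs the full generative model: draws a species pool per taxon
#' ([draw_species_pool()]), allocates the configured number of individuals
#' across life zones (multinomial on `zone_abundance`) and uniformly across
#' that zone's cup slots, assigns each individual a species by relative
#' abundance among the zone's occupants, and draws individual trait values
#' around the species' zone-specific mean.
#'
#' A species' realized mean in zone `z` is its pool mean shifted by
#' `intraspecific_tracking x (zone target - home-zone target)`; within each
#' (taxon, zone) the abundance-weighted species means are then recentred
#' exactly onto the configured zone target, so zone-level expected trait
#' means equal the configuration regardless of occupancy mixing.  Individual
#' noise is multiplicative lognormal for volume (mean-preserving) and
#' additive Gaussian for darkness (clipped to `[0, 222]`), both with
#' coefficient of variation `noise_cv`.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; defaults to `config$seed`.  Identical
#'   (config, seed) pairs yield identical tables.
#' @return A data frame with one row per individual and columns
#'   `specimen_id`, `taxon`, `species_id`, `life_zone`, `site_id`,
#'   `habitat`, `season`, `cup_color`, `body_volume_mm3`, `darkness`,
#'   `cup_id`.  Row count equals `sum(config$n_individuals)` exactly.
#' @examples
#' spec <- assemble_dataset(generator_config(), seed = 1)
#' nrow(spec)           # 1922
#' table(spec$taxon)    # 1283 bees, 639 flies
#' @export
assemble_dataset <- function(config, seed = NULL) {
  validate_config(config)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  design <- build_design(config)
  zones <- config$zones$life_zone
  tm_all <- config$zone_trait_means
  track <- config$intraspecific_tracking

  out <- vector("list", length(config$taxa))
  if (sum(config$n_individuals) < 1)
    tf_stop("configuration error: n_individuals must total at least 1")
  for (ti in seq_along(config$taxa)) {
    tx <- config$taxa[ti]
    n_tot <- config$n_individuals[[tx]]
    if (n_tot == 0L) next
    pool <- draw_species_pool(config, tx)
    tm <- tm_all[[tx]]

    zone_n <- as.integer(rmultinom(1, n_tot, config$zone_abundance[[tx]]))
    rows <- vector("list", length(zones))
    for (zi in seq_along(zones)) {
      nz_ind <- zone_n[zi]
      if (nz_ind == 0L) next
      occ <- which(pool$occupancy[, zi])
      if (!length(occ)) occ <- which(pool$species$home_zone == zones[zi])
      if (!length(occ))
        tf_stop("no %s species available for zone %s", tx, zones[zi])
      at_home <- pool$species$home_zone[occ] == zones[zi]
      w <- pool$species$abundance[occ] *
        ifelse(at_home, 1, config$spill_abundance)
      w <- w / sum(w)

      home_idx <- match(pool$species$home_zone[occ], zones)
      # species' realized mean in this zone: intraspecific tracking toward
      # the zone target (multiplicative for volume, additive for darkness),
      # then calibrated so the abundance-weighted zone mean equals the
      # configured target exactly
      zone_mu <- function(tr) {
        if (tr == "volume") {
          base <- pool$species$mean_volume[occ]
          real <- base * (tm[[tr]][zi] / tm[[tr]][home_idx])^track
          real <- real * (tm[[tr]][zi] / sum(w * real))
          pmax(real, 1e-6)
        } else {
          base <- pool$species$mean_darkness[occ]
          real <- base + track * (tm[[tr]][zi] - tm[[tr]][home_idx])
          real <- real - (sum(w * real) - tm[[tr]][zi])
          pmin(pmax(real, 0), DARKNESS_MAX)
        }
      }
      mu <- cbind(volume = zone_mu("volume"), darkness = zone_mu("darkness"))

      slot_pool <- which(design$life_zone == zones[zi])
      # catch sizes are overdispersed across cups: gamma attractiveness
      slot_w <- if (is.finite(config$cup_clumping)) {
        stats::rgamma(length(slot_pool), shape = config$cup_clumping, rate = 1)
      } else {
        rep(1, length(slot_pool))
      }
      if (sum(slot_w) <= 0) slot_w <- rep(1, length(slot_pool))
      slot_pick <- slot_pool[sample.int(length(slot_pool), nz_ind,
                                        replace = TRUE, prob = slot_w)]
      sp_pick <- sample.int(length(occ), nz_ind, replace = TRUE, prob = w)

      mv <- mu[sp_pick, "volume"]
      md <- mu[sp_pick, "darkness"]
      cv <- config$noise_cv
      if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        vol <- mv * rlnorm(nz_ind, -sdlog^2 / 2, sdlog)
        dark <- md + rnorm(nz_ind, 0, cv * md)
      } else {
        vol <- mv
        dark <- md
      }
      rows[[zi]] <- data.frame(
        taxon = tx,
        species_id = pool$species$species_id[occ][sp_pick],
        life_zone = design$life_zone[slot_pick],
        site_id = design$site_id[slot_pick],
        habitat = design$habitat[slot_pick],
        season = design$season[slot_pick],
        cup_color = design$cup_color[slot_pick],
        body_volume_mm3 = pmax(vol, .Machine$double.eps),
        darkness = pmin(pmax(dark, 0), DARKNESS_MAX),
        cup_id = design$cup_id[slot_pick],
        stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    tab$specimen_id <- sprintf("%s_%05d", tx, seq_len(nrow(tab)))
    out[[ti]] <- tab
  }
  res <- do.call(rbind, out)
  res <- res[, c("specimen_id", "taxon", "species_id", "life_zone", "site_id",
                 "habitat", "season", "cup_color", "body_volume_mm3",
                 "darkness", "cup_id")]
  rownames(res) <- NULL
  res
}
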