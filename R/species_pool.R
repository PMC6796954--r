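# Trait distribution machinery for the synthetic species pools.
#
# Species trait means within a zone follow:
#   volume   ~ lognormal (positive, right-skewed body sizes)
#   darkness ~ beta scaled to [0, 222] (bounded reflectance channel)
# parameterized by the configured zone mean and SD.  Environmental filtering
# truncates the distribution at its upper q-quantile (q = s / (1 + s)) and
# recentres it to the configured mean, narrowing the pool without moving the
# calibration target.

lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

beta_pars <- function(m, s, scale = DARKNESS_MAX) {
  mu <- m / scale
  v <- (s / scale)^2
  nu <- mu * (1 - mu) / v - 1
  list(shape1 = mu * nu, shape2 = (1 - mu) * nu)
}

# Quantile function of the (untruncated) species-mean distribution for one
# (taxon, zone, trait) cell of the config.
trait_quantile_fun <- function(trait, m, s) {
  if (trait == "volume") {
    p <- lnorm_pars(m, s)
    function(u) qlnorm(u, p$meanlog, p$sdlog)
  } else {
    p <- beta_pars(m, s)
    function(u) DARKNESS_MAX * qbeta(u, p$shape1, p$shape2)
  }
}

# E[X | X > Q(q)] by deterministic quadrature on the quantile scale:
# (1 / (1 - q)) * integral_q^1 Q(u) du.
truncated_mean <- function(qfun, q) {
  if (q <= 0) return(stats::integrate(qfun, 0, 1, rel.tol = 1e-9)$value)
  stats::integrate(qfun, q, 1, rel.tol = 1e-9)$value / (1 - q)
}

# Truncation quantile implied by filtering strength s >= 0.
filter_quantile <- function(s) s / (1 + s)

# Largest-remainder apportionment of n into weights w.
apportion <- function(n, w) {
  w <- w / sum(w)
  raw <- n * w
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1L
  }
  as.integer(out)
}

#' Draw a regional species pool for one taxon
#'
#' Each species gets a "home" life zone (richness declining with elevation
#' per `zone_richness`), trait means drawn from the home zone's target
#' distribution (lognormal volume, scaled-beta darkness), and a lognormal
#' relative-abundance weight.  Species may also occupy adjacent zones with
#' probability `p_spill`; entry into a zone with `filtering_strength > 0`
#' additionally requires the species' zone-adjusted trait mean to exceed
#' that zone's truncation threshold for every filtered trait (the filter
#' acts on immigrants as well as residents).  In filtered home zones,
#' species means are drawn from the upper tail of the target distribution
#' and recentred to the configured zone mean, so `filtering_strength = 0`
#' changes nothing and large values collapse the pool spread toward zero.
#'
#' @param config A [generator_config()].
#' @param taxon One of the configured taxa (`"bee"` or `"fly"` by default).
#' @param seed Optional RNG seed; when `NULL` the current RNG stream is used.
#' @return An object of class `species_pool`: a list with elements
#'   `taxon`, `species` (data frame: `species_id`, `home_zone`,
#'   `mean_volume`, `mean_darkness`, `abundance`), `occupancy` (logical
#'   species x zone matrix) and `zones`.
#' @export
draw_species_pool <- function(config, taxon, seed = NULL) {
  validate_config(config)
  if (!taxon %in% config$taxa)
    tf_stop("unknown taxon '%s' (expected one of: %s)", taxon,
            paste(config$taxa, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  zones <- config$zones$life_zone
  nz <- length(zones)
  n <- config$n_species[[taxon]]
  tm <- config$zone_trait_means[[taxon]]
  ts <- config$zone_trait_sds[[taxon]]
  fs <- config$filtering_strength[[taxon]]

  home_counts <- apportion(n, config$zone_richness[[taxon]])
  home <- rep(seq_len(nz), home_counts)

  means <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("volume", "darkness")))
  for (zi in seq_len(nz)) {
    idx <- which(home == zi)
    if (!length(idx)) next
    q <- filter_quantile(fs[zi])
    for (tr in c("volume", "darkness")) {
      qfun <- trait_quantile_fun(tr, tm[[tr]][zi], ts[[tr]][zi])
      u <- runif(length(idx), min = q, max = 1)
      x <- qfun(u)
      if (q > 0) {
        # recentre the truncated pool onto the zone target: multiplicative
        # for volume (a positive scale variable), additive for darkness
        tmean <- truncated_mean(qfun, q)
        x <- if (tr == "volume") x * (tm[[tr]][zi] / tmean)
             else x - (tmean - tm[[tr]][zi])
      }
      means[idx, tr] <- x
    }
  }
  means[, "darkness"] <- pmin(pmax(means[, "darkness"], 0), DARKNESS_MAX)
  means[, "volume"] <- pmax(means[, "volume"], .Machine$double.eps)

  abundance <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)

  # Occupancy: home zone always; adjacent zones with probability p_spill,
  # gated by the destination zone's trait threshold when it is filtered.
  occupancy <- matrix(FALSE, n, nz, dimnames = list(NULL, zones))
  occupancy[cbind(seq_len(n), home)] <- TRUE
  track <- config$intraspecific_tracking
  for (zi in seq_len(nz)) {
    q <- filter_quantile(fs[zi])
    # admission floor = lower edge of the recentred resident pool: the
    # filter excludes immigrants below the same trait floor that shapes
    # the zone's own species pool
    thresh <- lapply(c("volume", "darkness"), function(tr) {
      if (q <= 0) return(-Inf)
      qfun <- trait_quantile_fun(tr, tm[[tr]][zi], ts[[tr]][zi])
      m <- tm[[tr]][zi]
      if (tr == "volume") qfun(q) * (m / truncated_mean(qfun, q))
      else qfun(q) - (truncated_mean(qfun, q) - m)
    })
    names(thresh) <- c("volume", "darkness")
    for (si in seq_len(n)) {
      if (abs(home[si] - zi) != 1L) next
      if (runif(1) >= config$p_spill) next
      admitted <- TRUE
      for (tr in c("volume", "darkness")) {
        realized <- if (tr == "volume") {
          means[si, tr] * (tm[[tr]][zi] / tm[[tr]][home[si]])^track
        } else {
          means[si, tr] + track * (tm[[tr]][zi] - tm[[tr]][home[si]])
        }
        if (realized < thresh[[tr]]) admitted <- FALSE
      }
      occupancy[si, zi] <- admitted
    }
  }

  species <- data.frame(
    species_id = sprintf("%s_sp%03d", taxon, seq_len(n)),
    home_zone = zones[home],
    mean_volume = means[, "volume"],
    mean_darkness = means[, "darkness"],
    abundance = abundance,
    stringsAsFactors = FALSE
  )
  structure(list(taxon = taxon, species = species, occupancy = occupancy,
                 zones = zones),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("species_pool: %d %s species, zones %s\n",
              nrow(x$species), x$taxon, paste(x$zones, collapse = " < ")))
  cat("  species per zone:",
      paste(colSums(x$occupancy), collapse = " / "), "\n")
  invisible(x)
}
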