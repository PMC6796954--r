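#' Lay out the physical trapping design
#'
#' Expands a configuration into one row per cup sample slot (physical cup x
#' season).  With `layout = "site_array"` each site carries a single
#' `n_cups_per_array`-cup array whose habitat alternates across sites; with
#' `layout = "habitat_array"` every site carries one array per habitat.  Cup
#' colors are assigned evenly within an array.  Under the default
#' configuration the design deploys 108 cups per season (3 zones x 3 sites
#' x 12 cups) and 216 slots in total.
#'
#' @param config A [generator_config()].
#' @return A data frame of class `cup_design` with one row per slot and
#'   columns `slot_id`, `cup_id`, `life_zone`, `site_id`, `habitat`,
#'   `season`, `cup_number`, `cup_color`.  The per-season slot count is
#'   attached as attribute `slots_per_season`.
#' @examples
#' d <- build_design(generator_config())
#' nrow(d)                       # 216
#' attr(d, "slots_per_season")   # 108
#' @export
build_design <- function(config) {
  validate_config(config)
  zones <- config$zones$life_zone
  arrays <- do.call(rbind, lapply(seq_along(zones), function(zi) {
    do.call(rbind, lapply(seq_len(config$n_sites_per_zone), function(si) {
      site_id <- sprintf("%s_s%d", zones[zi], si)
      if (config$layout == "site_array") {
        hab <- config$habitats[(si - 1L) %% length(config$habitats) + 1L]
        data.frame(life_zone = zones[zi], site_id = site_id, habitat = hab,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(life_zone = zones[zi], site_id = site_id,
                   habitat = config$habitats, stringsAsFactors = FALSE)
      }
    }))
  }))

  ncup <- config$n_cups_per_array
  colors <- rep(config$cup_colors, length.out = ncup,
                each = max(1L, ncup %/% length(config$cup_colors)))[seq_len(ncup)]
  cups <- data.frame(cup_number = seq_len(ncup), cup_color = colors,
                     stringsAsFactors = FALSE)

  per_array <- merge(arrays, cups, by = NULL)
  per_array$cup_id <- sprintf("%s_%s_c%02d", per_array$site_id,
                              substr(per_array$habitat, 1, 1),
                              per_array$cup_number)
  slots <- merge(per_array, data.frame(season = config$seasons,
                                       stringsAsFactors = FALSE), by = NULL)
  slots$slot_id <- paste(slots$cup_id, slots$season, sep = ".")
  slots <- slots[order(match(slots$life_zone, zones), slots$site_id,
                       slots$habitat, slots$cup_number,
                       match(slots$season, config$seasons)), ]
  rownames(slots) <- NULL
  slots <- slots[, c("slot_id", "cup_id", "life_zone", "site_id", "habitat",
                     "season", "cup_number", "cup_color")]
  attr(slots, "slots_per_season") <- nrow(slots) %/% length(config$seasons)
  class(slots) <- c("cup_design", "data.frame")
  slots
}
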