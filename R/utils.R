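`%||%` <- function(a, b) if (is.null(a)) b else a

tf_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

tf_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

# Ceiling of the body-darkness channel: 0 = pure white, 222 = pure black.
DARKNESS_MAX <- 222L

# Map user-facing trait labels to specimen-table columns.
TRAITS <- c(volume = "body_volume_mm3", darkness = "darkness")

trait_column <- function(trait) {
  trait <- match.arg(trait, names(TRAITS))
  TRAITS[[trait]]
}

# Canonical life-zone ordering (low to high elevation) for tables whose
# zones match the default design; otherwise order of first appearance.
zone_levels <- function(zones_present, zone_order = NULL) {
  if (!is.null(zone_order)) return(intersect(zone_order, zones_present))
  default <- c("ponderosa", "mixed_conifer", "spruce_fir")
  if (all(zones_present %in% default)) {
    intersect(default, zones_present)
  } else {
    unique(zones_present)
  }
}
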