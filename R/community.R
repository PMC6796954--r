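# Required specimen-table columns, in interface order.
SPECIMEN_COLUMNS <- c("specimen_id", "taxon", "species_id", "life_zone",
                      "site_id", "habitat", "season", "cup_color",
                      "body_volume_mm3", "darkness")

validate_specimen_table <- function(table) {
  if (!is.data.frame(table)) tf_stop("specimen table must be a data frame")
  missing_cols <- setdiff(SPECIMEN_COLUMNS, names(table))
  if (length(missing_cols))
    tf_stop("specimen table missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(table$darkness) | table$darkness < 0 |
                 table$darkness > DARKNESS_MAX)
  if (length(bad))
    tf_stop("row %d: darkness out of [0,%d]", bad[1L], DARKNESS_MAX)
  bad <- which(!is.finite(table$body_volume_mm3) | table$body_volume_mm3 <= 0)
  if (length(bad)) tf_stop("row %d: body_volume_mm3 not > 0", bad[1L])
  invisible(table)
}

#' Group a specimen table into cup samples
#'
#' Partitions every individual into one sample per (physical cup, season,
#' taxon) -- the unit on which community-weighted means and trait ranges
#' are computed.  If the table has a `cup_id` column it identifies the
#' physical cup; otherwise the finest design unit the standard schema can
#' express, (life_zone, site_id, habitat, season, cup_color), is used.
#' Empty cups do not appear (the partition is over observed rows).
#'
#' @param table A specimen table (see [read_specimen_table()]).
#' @return Object of class `cup_samples`: list with `specimens` (the input
#'   plus a `sample_id` column) and `samples` (one row per sample:
#'   `sample_id`, `taxon`, `life_zone`, `site_id`, `habitat`, `season`,
#'   `n_individuals`).
#' @export
group_samples <- function(table) {
  validate_specimen_table(table)
  cup_key <- if ("cup_id" %in% names(table)) {
    table$cup_id
  } else {
    paste(table$life_zone, table$site_id, table$habitat, table$cup_color,
          sep = "_")
  }
  table$sample_id <- paste(cup_key, table$season, table$taxon, sep = ".")
  first <- !duplicated(table$sample_id)
  samples <- data.frame(
    sample_id = table$sample_id[first],
    taxon = table$taxon[first],
    life_zone = table$life_zone[first],
    site_id = table$site_id[first],
    habitat = table$habitat[first],
    season = table$season[first],
    stringsAsFactors = FALSE
  )
  counts <- table(table$sample_id)
  samples$n_individuals <- as.integer(counts[samples$sample_id])
  samples <- samples[order(samples$sample_id), ]
  rownames(samples) <- NULL
  structure(list(specimens = table, samples = samples), class = "cup_samples")
}

#' @export
print.cup_samples <- function(x, ...) {
  cat(sprintf("cup_samples: %d samples over %d individuals (%s)\n",
              nrow(x$samples), nrow(x$specimens),
              paste(sprintf("%s: %d", names(table(x$samples$taxon)),
                            table(x$samples$taxon)), collapse = ", ")))
  invisible(x)
}

sample_trait_values <- function(samples, trait) {
  col <- trait_column(trait)
  split(samples$specimens[[col]], samples$specimens$sample_id)
}

# Abundance-weighted species-mean trait per sample (optional CWM mode).
sample_species_mean_values <- function(samples, trait) {
  col <- trait_column(trait)
  sp <- samples$specimens
  key <- paste(sp$sample_id, sp$species_id, sep = "\r")
  sp_mean <- tapply(sp[[col]], key, mean)
  sp_n <- tapply(sp[[col]], key, length)
  sid <- sub("\r.*$", "", names(sp_mean))
  split(data.frame(mean = as.numeric(sp_mean), n = as.integer(sp_n)), sid)
}

#' Community-weighted mean trait per cup sample
#'
#' The CWM of a sample is the abundance-weighted mean trait value.  With
#' `weighting = "individual"` (default) every captured individual
#' contributes equally -- the individual-level realization of weighting
#' species means by species abundance.  With `weighting = "species_mean"`
#' the within-sample species means are weighted by the species' individual
#' counts (identical result when individuals carry their species mean).
#'
#' @param samples A `cup_samples` object.
#' @param trait `"volume"` or `"darkness"`.
#' @param weighting CWM mode, see above.
#' @return Data frame: `sample_id`, `taxon`, `life_zone`, `site_id`,
#'   `habitat`, `season`, `trait`, `cwm`, `n_individuals`.
#' @export
cwm <- function(samples, trait = c("volume", "darkness"),
                weighting = c("individual", "species_mean")) {
  trait <- match.arg(trait)
  weighting <- match.arg(weighting)
  if (!inherits(samples, "cup_samples")) tf_stop("not a cup_samples object")
  if (!nrow(samples$samples)) tf_stop("empty sample collection")
  out <- samples$samples
  vals <- if (weighting == "individual") {
    vapply(sample_trait_values(samples, trait), mean, numeric(1))
  } else {
    vapply(sample_species_mean_values(samples, trait),
           function(d) sum(d$mean * d$n) / sum(d$n), numeric(1))
  }
  out$trait <- trait
  out$cwm <- as.numeric(vals[out$sample_id])
  out[, c("sample_id", "taxon", "life_zone", "site_id", "habitat", "season",
          "trait", "cwm", "n_individuals")]
}

#' Within-sample trait range per cup sample
#'
#' `max - min` of the trait over the sample's individuals.  Samples with a
#' single individual have an undefined range: they get `NA` and
#' `range_defined = FALSE`, and are excluded from SES analysis downstream.
#'
#' @inheritParams cwm
#' @return Data frame like [cwm()] with columns `obs_range` and
#'   `range_defined` instead of `cwm`.
#' @export
trait_range <- function(samples, trait = c("volume", "darkness")) {
  trait <- match.arg(trait)
  if (!inherits(samples, "cup_samples")) tf_stop("not a cup_samples object")
  out <- samples$samples
  vals <- vapply(sample_trait_values(samples, trait),
                 function(v) if (length(v) >= 2L) max(v) - min(v) else NA_real_,
                 numeric(1))
  out$trait <- trait
  out$obs_range <- as.numeric(vals[out$sample_id])
  out$range_defined <- !is.na(out$obs_range)
  out[, c("sample_id", "taxon", "life_zone", "site_id", "habitat", "season",
          "trait", "obs_range", "range_defined", "n_individuals")]
}

#' Individual-level correlation between volume and darkness
#'
#' Pearson correlation (with two-sided test) between body volume and body
#' darkness across the individuals of one taxon; used to justify analyzing
#' the two traits independently.
#'
#' @param table A specimen table.
#' @param taxon Taxon label to subset on.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
trait_correlation <- function(table, taxon) {
  validate_specimen_table(table)
  sub <- table[table$taxon == taxon, ]
  if (nrow(sub) < 3L)
    tf_stop("need at least 3 individuals of taxon '%s'", taxon)
  if (sd(sub$body_volume_mm3) == 0 || sd(sub$darkness) == 0)
    tf_stop("undefined correlation: zero variance in a trait for taxon '%s'",
            taxon)
  ct <- cor.test(sub$body_volume_mm3, sub$darkness, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = nrow(sub))
}
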