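#' Read and validate a specimen table from CSV
#'
#' Requires the standard header (`specimen_id, taxon, species_id,
#' life_zone, site_id, habitat, season, cup_color, body_volume_mm3,
#' darkness`; an optional `cup_id` column identifies the physical cup).
#' Rows violating the trait invariants (darkness outside `[0, 222]`,
#' non-positive volume, missing labels) are rejected with a per-row reason
#' and reported via a warning; the rejected rows travel along as attribute
#' `rejected`.
#'
#' @param path Path to a CSV file.
#' @return A validated specimen data frame.
#' @export
read_specimen_table <- function(path) {
  if (!file.exists(path)) tf_stop("file not found: %s", path)
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) tf_stop("schema error reading %s: %s",
                                              path, conditionMessage(e)))
  missing_cols <- setdiff(SPECIMEN_COLUMNS, names(tab))
  if (length(missing_cols))
    tf_stop("schema error: missing column(s) %s",
            paste(missing_cols, collapse = ", "))
  if (!nrow(tab)) tf_stop("schema error: no specimen rows in %s", path)

  reasons <- rep(NA_character_, nrow(tab))
  dark_bad <- !is.finite(tab$darkness) | tab$darkness < 0 |
    tab$darkness > DARKNESS_MAX
  reasons[dark_bad] <- sprintf("darkness out of [0,%d]", DARKNESS_MAX)
  vol_bad <- is.na(reasons) &
    (!is.finite(tab$body_volume_mm3) | tab$body_volume_mm3 <= 0)
  reasons[vol_bad] <- "body_volume_mm3 not > 0"
  for (col in c("specimen_id", "taxon", "species_id", "life_zone")) {
    lab_bad <- is.na(reasons) & (is.na(tab[[col]]) | tab[[col]] == "")
    reasons[lab_bad] <- sprintf("missing %s", col)
  }

  keep <- is.na(reasons)
  rejected <- cbind(tab[!keep, , drop = FALSE],
                    data.frame(reason = reasons[!keep],
                               stringsAsFactors = FALSE))
  if (nrow(rejected))
    tf_warn("rejected %d row(s): %s", nrow(rejected),
            paste(sprintf("row %d (%s)", which(!keep), rejected$reason),
                  collapse = "; "))
  out <- tab[keep, , drop = FALSE]
  if (!nrow(out)) tf_stop("no valid specimen rows in %s", path)
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a specimen table to CSV
#'
#' Columns are written in the standard interface order, with `cup_id`
#' appended when present.
#'
#' @param table A specimen table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(table, path) {
  validate_specimen_table(table)
  cols <- c(SPECIMEN_COLUMNS, intersect("cup_id", names(table)))
  write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  # version = 2 gives a stable serialization across R >= 3.5
  saveRDS(unclass(config), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full trait-filtering pipeline
#'
#' generate (or load) -> group into cup samples -> CWM and trait ranges ->
#' SES of ranges under the richness-conditioned null model -> zone-level
#' ANOVA/Tukey summaries and intraspecific trends.  One master seed fans
#' out deterministically to per-stage child seeds, so the whole bundle is
#' reproducible and stages can be re-run independently.
#'
#' @param config A [generator_config()] (or path to a YAML/JSON config).
#' @param seed Master RNG seed (default 1).
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV plus a `run_metadata.json`.
#' @param specimens Optional pre-existing specimen table; when supplied the
#'   generator is skipped and `config` is only used for metadata.
#' @param B Null-model iterations per richness level (default 1000).
#' @param mode SES normalization tested: `"sd"` or `"paper_mean"`.
#' @param threshold Two-tailed SES significance threshold (default 1.96).
#' @param taxa Taxa to analyse (default: those present).
#' @param cwm_weighting Passed to [cwm()].
#' @return Object of class `traitfilter_run`: list with `specimens`,
#'   `samples`, `cwm_table`, `range_table`, `ses_table`,
#'   `trait_correlations`, `zone_summary`, `anova_table`, `tukey_table`,
#'   `intraspecific_table`, `metadata`.
#' @examples
#' \donttest{
#' run <- run_pipeline(generator_config(), seed = 1)
#' run$anova_table
#' }
#' @export
run_pipeline <- function(config = generator_config(), seed = 1L,
                         out_dir = NULL, specimens = NULL, B = 1000L,
                         mode = c("sd", "paper_mean"), threshold = 1.96,
                         taxa = NULL, cwm_weighting = "individual") {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_config(config)
  validate_config(config)

  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, 8L)

  if (is.null(specimens))
    specimens <- assemble_dataset(config, seed = child_seeds[1L])
  validate_specimen_table(specimens)
  taxa <- taxa %||% intersect(config$taxa, unique(specimens$taxon))
  specimens <- specimens[specimens$taxon %in% taxa, , drop = FALSE]
  if (!nrow(specimens)) tf_stop("no specimens left after taxon selection")

  samples <- group_samples(specimens)

  grids <- expand.grid(taxon = taxa, trait = names(TRAITS),
                       stringsAsFactors = FALSE)
  cwm_tab <- do.call(rbind, lapply(seq_len(nrow(grids)), function(i) {
    sub <- group_samples(specimens[specimens$taxon == grids$taxon[i], ])
    cwm(sub, grids$trait[i], weighting = cwm_weighting)
  }))
  range_tab <- do.call(rbind, lapply(seq_len(nrow(grids)), function(i) {
    sub <- group_samples(specimens[specimens$taxon == grids$taxon[i], ])
    trait_range(sub, grids$trait[i])
  }))

  ses_tab <- do.call(rbind, lapply(seq_len(nrow(grids)), function(i) {
    ses_table(samples, trait = grids$trait[i], taxon = grids$taxon[i],
              B = B, mode = mode, threshold = threshold,
              seed = child_seeds[1L + i])
  }))
  attr(ses_tab, "mode") <- mode
  attr(ses_tab, "threshold") <- threshold

  correlations <- lapply(setNames(nm = taxa), function(tx)
    tryCatch(trait_correlation(specimens, tx), error = function(e) NULL))

  zs <- zone_summary(cwm_tab, ses_tab)
  intra <- suppressWarnings(intraspecific_trends(specimens))

  metadata <- list(
    package_version = as.character(packageVersion("traitfilter")),
    seed = seed, B = B, mode = mode, threshold = threshold,
    taxa = taxa, cwm_weighting = cwm_weighting,
    config_hash = config_hash(config),
    n_specimens = nrow(specimens), n_samples = nrow(samples$samples),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  bundle <- structure(list(
    specimens = specimens, samples = samples$samples,
    cwm_table = cwm_tab, range_table = range_tab, ses_table = ses_tab,
    trait_correlations = correlations, zone_summary = zs,
    anova_table = zs$table, tukey_table = zs$tukey,
    intraspecific_table = intra, metadata = metadata
  ), class = "traitfilter_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_specimen_table(specimens, file.path(out_dir, "specimens.csv"))
    write.csv(cwm_tab, file.path(out_dir, "cwm.csv"), row.names = FALSE)
    write.csv(range_tab, file.path(out_dir, "range.csv"), row.names = FALSE)
    write.csv(ses_tab, file.path(out_dir, "ses.csv"), row.names = FALSE)
    if (!is.null(zs$table))
      write.csv(zs$table, file.path(out_dir, "anova.csv"), row.names = FALSE)
    if (!is.null(zs$tukey))
      write.csv(zs$tukey, file.path(out_dir, "tukey.csv"), row.names = FALSE)
    write.csv(intra, file.path(out_dir, "intraspecific.csv"),
              row.names = FALSE)
    jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}

#' @export
print.traitfilter_run <- function(x, ...) {
  cat(sprintf("traitfilter run (seed %s, B = %d, mode = %s)\n",
              x$metadata$seed, x$metadata$B, x$metadata$mode))
  cat(sprintf("  %d specimens in %d cup samples\n",
              x$metadata$n_specimens, x$metadata$n_samples))
  if (!is.null(x$anova_table)) {
    cat("  zone ANOVAs:\n")
    print(x$anova_table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
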