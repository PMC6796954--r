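#' One-way fixed-effects ANOVA with group summaries
#'
#' Classical one-way ANOVA of a response across life zones (or any
#' grouping), with per-group means/SDs and Tukey HSD pairwise comparisons
#' attached.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor; order of levels is kept
#'   if already a factor, else [zone_levels()] order).
#' @return Object of class `anova_oneway`: list with `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `group_sds`, `group_n`, `tukey`
#'   (data frame `group_a`, `group_b`, `diff`, `p_adj`).
#' @examples
#' anova_oneway(c(1, 2, 3, 11, 12, 13, 21, 22, 23),
#'              rep(c("a", "b", "c"), each = 3))  # F = 300 on (2, 6) df
#' @export
anova_oneway <- function(values, groups) {
  if (length(values) != length(groups))
    tf_stop("values and groups lengths differ")
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  if (!is.factor(groups))
    groups <- factor(groups, levels = zone_levels(unique(as.character(groups))))
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) tf_stop("need at least 2 groups")
  n_per <- table(groups)
  if (any(n_per < 2L)) tf_stop("every group needs at least 2 values")
  if (sd(values) == 0) tf_stop("degenerate variance: all values identical")

  fit <- aov(values ~ groups)
  at <- anova(fit)
  tk <- TukeyHSD(fit)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  structure(list(
    F = at$`F value`[1L],
    df_between = at$Df[1L],
    df_within = at$Df[2L],
    p = at$`Pr(>F)`[1L],
    group_means = setNames(as.numeric(tapply(values, groups, mean)),
                           levels(groups)),
    group_sds = setNames(as.numeric(tapply(values, groups, sd)),
                         levels(groups)),
    group_n = as.integer(n_per),
    groups = levels(groups),
    tukey = data.frame(group_a = pairs[, 1L], group_b = pairs[, 2L],
                       diff = unname(tk[, "diff"]),
                       p_adj = unname(tk[, "p adj"]),
                       stringsAsFactors = FALSE)
  ), class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  cat("  group means:",
      paste(sprintf("%s %.3g", x$groups, x$group_means), collapse = ", "), "\n")
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted p-values for every unordered pair of groups,
#' following a one-way ANOVA.
#'
#' @inheritParams anova_oneway
#' @return Data frame: `group_a`, `group_b`, `diff`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  anova_oneway(values, groups)$tukey
}

#' Zone-level ANOVA summaries of CWM and SES tables
#'
#' Runs the standard set of one-way ANOVAs with life zone as the only
#' predictor: one per (metric, taxon, trait) combination present -- with
#' both metrics, both taxa and both traits that is 8 analyses.  Cups are
#' pooled across sites, habitats and seasons as replicates by default
#' (`unit = "cup"`); `unit = "site_mean"` first averages cup values within
#' (site, season) and uses those means as replicates.
#'
#' @param cwm_table Output of [cwm()] (possibly several traits/taxa bound
#'   together), or `NULL`.
#' @param ses_table Output of [ses_table()] (possibly bound), or `NULL`.
#'   The SES value analysed is the mode the table was built under.
#' @param unit Replication unit, see above.
#' @return Object of class `zone_summary`: list with `anovas` (named list
#'   of `anova_oneway`), `table` (tidy data frame `metric`, `taxon`,
#'   `trait`, `F`, `df1`, `df2`, `p`), `zone_stats` (per-zone mean/SD/n for
#'   each response) and `tukey` (bound pairwise table).
#' @export
zone_summary <- function(cwm_table = NULL, ses_table = NULL,
                         unit = c("cup", "site_mean")) {
  unit <- match.arg(unit)
  inputs <- list()
  if (!is.null(cwm_table)) inputs$cwm <- list(tab = cwm_table, col = "cwm")
  if (!is.null(ses_table)) {
    mode <- attr(ses_table, "mode") %||% "sd"
    inputs$sesRange <- list(tab = ses_table,
                            col = if (mode == "sd") "ses_sd" else "ses_paper")
  }
  if (!length(inputs)) tf_stop("need at least one of cwm_table, ses_table")

  anovas <- list()
  rows <- list()
  zstats <- list()
  tukeys <- list()
  for (metric in names(inputs)) {
    tab <- inputs[[metric]]$tab
    col <- inputs[[metric]]$col
    for (tx in unique(tab$taxon)) {
      for (tr in unique(tab$trait)) {
        sub <- tab[tab$taxon == tx & tab$trait == tr & is.finite(tab[[col]]), ]
        key <- paste(metric, tx, tr, sep = ".")
        if (!nrow(sub)) {
          tf_warn("no data for %s; skipped", key)
          next
        }
        if (unit == "site_mean") {
          agg <- stats::aggregate(sub[[col]],
                                  by = list(life_zone = sub$life_zone,
                                            site_id = sub$site_id,
                                            season = sub$season),
                                  FUN = mean)
          vals <- agg$x
          zones <- agg$life_zone
        } else {
          vals <- sub[[col]]
          zones <- sub$life_zone
        }
        an <- tryCatch(anova_oneway(vals, zones), error = function(e) {
          tf_warn("%s: %s; skipped", key, conditionMessage(e))
          NULL
        })
        if (is.null(an)) next
        anovas[[key]] <- an
        rows[[key]] <- data.frame(metric = metric, taxon = tx, trait = tr,
                                  F = an$F, df1 = an$df_between,
                                  df2 = an$df_within, p = an$p,
                                  stringsAsFactors = FALSE)
        zstats[[key]] <- data.frame(metric = metric, taxon = tx, trait = tr,
                                    life_zone = an$groups,
                                    mean = as.numeric(an$group_means),
                                    sd = as.numeric(an$group_sds),
                                    n = an$group_n, stringsAsFactors = FALSE)
        tk <- an$tukey
        tk <- cbind(data.frame(metric = metric, taxon = tx, trait = tr,
                               stringsAsFactors = FALSE), tk)
        tukeys[[key]] <- tk
      }
    }
  }
  bind <- function(lst) {
    if (!length(lst)) return(NULL)
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  structure(list(anovas = anovas, table = bind(rows),
                 zone_stats = bind(zstats), tukey = bind(tukeys)),
            class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  cat("zone-level one-way ANOVAs (life zone as predictor)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Intraspecific trait trends along the gradient
#'
#' For every species present in at least `min_zones` life zones, tests
#' whether each trait differs among zones (one-way ANOVA) and, when the
#' test is significant at `alpha`, signs the trend by the slope of zone
#' means against elevation rank (`"+"` rising with elevation, `"-"`
#' falling, `"none"` otherwise).
#'
#' @param table A specimen table.
#' @param min_zones Minimum number of occupied zones (default 3).
#' @param alpha Significance level for assigning a direction (default 0.05).
#' @param min_per_zone Minimum individuals per occupied zone for the ANOVA
#'   to be attempted (default 2).
#' @param zone_order Optional explicit low-to-high zone ordering.
#' @return Data frame: `species_id`, `taxon`, `trait`, one `mean_<zone>`
#'   column per zone, `df`, `F`, `p`, `direction`.
#' @export
intraspecific_trends <- function(table, min_zones = 3L, alpha = 0.05,
                                 min_per_zone = 2L, zone_order = NULL) {
  validate_specimen_table(table)
  zones <- zone_levels(unique(table$life_zone), zone_order)
  zcols <- paste0("mean_", zones)

  counts <- table(table$species_id, table$life_zone)
  occ <- rowSums(counts[, zones, drop = FALSE] >= min_per_zone)
  eligible <- rownames(counts)[occ >= min_zones]
  if (!length(eligible)) {
    tf_warn("no species occupy >= %d life zones with >= %d individuals each",
            min_zones, min_per_zone)
    out <- data.frame(species_id = character(0), taxon = character(0),
                      trait = character(0), stringsAsFactors = FALSE)
    for (zc in zcols) out[[zc]] <- numeric(0)
    out$df <- integer(0); out$F <- numeric(0); out$p <- numeric(0)
    out$direction <- character(0)
    return(out)
  }

  rows <- list()
  for (sp in eligible) {
    sub <- table[table$species_id == sp, ]
    zone_n <- table(factor(sub$life_zone, levels = zones))
    test_zones <- names(zone_n)[zone_n >= min_per_zone]
    test_rows <- sub$life_zone %in% test_zones
    for (tr in names(TRAITS)) {
      vals <- sub[[trait_column(tr)]]
      zm <- tapply(vals, factor(sub$life_zone, levels = zones), mean)
      an <- tryCatch(anova_oneway(vals[test_rows], sub$life_zone[test_rows]),
                     error = function(e) NULL)
      if (is.null(an)) {
        f <- p <- NA_real_; df <- NA_integer_
      } else {
        f <- an$F; p <- an$p; df <- an$df_between
      }
      direction <- "none"
      if (!is.na(p) && p < alpha) {
        present <- which(!is.na(zm))
        slope <- coef(lm(as.numeric(zm[present]) ~ present))[2L]
        if (is.finite(slope) && slope > 0) direction <- "+"
        if (is.finite(slope) && slope < 0) direction <- "-"
      }
      row <- data.frame(species_id = sp, taxon = sub$taxon[1L], trait = tr,
                        stringsAsFactors = FALSE)
      for (zi in seq_along(zones)) row[[zcols[zi]]] <- unname(zm[zi])
      row$df <- df; row$F <- f; row$p <- p; row$direction <- direction
      rows[[paste(sp, tr)]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$trait, out$taxon, out$species_id), ]
}
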