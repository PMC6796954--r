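#' Regional pool of individual trait values
#'
#' The null model draws individuals from the regional pool: all captured
#' individuals of one taxon across the whole gradient (seasons and habitats
#' pooled), for one trait.
#'
#' @param table A specimen table.
#' @param taxon Taxon label.
#' @param trait `"volume"` or `"darkness"`.
#' @return Object of class `regional_pool`: list with `taxon`, `trait`,
#'   `specimen_id`, `values`.
#' @export
regional_pool <- function(table, taxon, trait = c("volume", "darkness")) {
  trait <- match.arg(trait)
  validate_specimen_table(table)
  sub <- table[table$taxon == taxon, ]
  if (!nrow(sub)) tf_stop("no individuals of taxon '%s' in table", taxon)
  vals <- sub[[trait_column(trait)]]
  if (any(!is.finite(vals))) tf_stop("non-finite trait values in pool")
  structure(list(taxon = taxon, trait = trait,
                 specimen_id = sub$specimen_id, values = vals),
            class = "regional_pool")
}

#' Null distribution of trait ranges at one richness level
#'
#' Distribution of the trait range of `k` individuals drawn from the
#' regional pool without replacement.  When the number of distinct subsets
#' `choose(n, k)` does not exceed `enum_cap`, the exact distribution over
#' all subsets is enumerated and flagged `exhaustive`; otherwise `B`
#' Monte-Carlo draws are taken.  `null_sd` is the population SD of the
#' null ranges.
#'
#' @param pool A `regional_pool` or a bare numeric vector of trait values.
#' @param k Individuals per draw, `2 <= k <=` pool size.
#' @param B Monte-Carlo iterations (default 1000).
#' @param enum_cap Enumerate exhaustively when `choose(n, k) <= enum_cap`.
#' @param seed Optional RNG seed for the Monte-Carlo path.
#' @return Object of class `null_distribution`: list with `trait`, `k`,
#'   `B`, `null_ranges`, `null_mean`, `null_sd`, `exhaustive`.
#' @examples
#' nd <- build_null_distribution(c(1, 2, 3, 4), k = 2)
#' nd$null_mean  # 5/3 over the six pairs
#' @export
build_null_distribution <- function(pool, k, B = 1000L, enum_cap = 10000L,
                                    seed = NULL) {
  trait <- NA_character_
  if (inherits(pool, "regional_pool")) {
    trait <- pool$trait
    pool <- pool$values
  }
  n <- length(pool)
  if (!is_count(k) || k < 2L || k > n)
    tf_stop("k must satisfy 2 <= k <= pool size (%d); got %s", n, format(k))
  if (!is_count(B)) tf_stop("B must be a count >= 1")
  if (!is.null(seed)) set.seed(seed)

  n_subsets <- choose(n, k)
  if (n_subsets <= enum_cap) {
    # sort once; the range of a subset of sorted values is last - first
    sorted <- sort(pool)
    idx <- combn(n, k)
    ranges <- sorted[idx[k, ]] - sorted[idx[1L, ]]
    exhaustive <- TRUE
  } else {
    ranges <- vapply(seq_len(B), function(i) {
      v <- pool[sample.int(n, k)]
      max(v) - min(v)
    }, numeric(1))
    exhaustive <- FALSE
  }
  m <- mean(ranges)
  structure(list(trait = trait, k = as.integer(k), B = length(ranges),
                 null_ranges = ranges, null_mean = m,
                 null_sd = sqrt(mean((ranges - m)^2)),
                 exhaustive = exhaustive),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution (k = %d, %s, %d ranges): mean %.4g, sd %.4g\n",
              x$k, if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$B, x$null_mean, x$null_sd))
  invisible(x)
}

#' Classify an SES value as an environmental-filtering signal
#'
#' Negative significant SES (observed range narrower than the null) is a
#' strong environmental filter; positive significant SES a weak filter;
#' anything below the threshold in magnitude is consistent with the null.
#'
#' @param ses Numeric SES value(s), in the normalization actually tested.
#' @param threshold Two-tailed significance threshold (default 1.96).
#' @return Character vector over `{"strong_filter", "weak_filter",
#'   "consistent_with_null"}`.
#' @export
classify_filtering <- function(ses, threshold = 1.96) {
  ifelse(abs(ses) >= threshold & ses < 0, "strong_filter",
         ifelse(abs(ses) >= threshold & ses > 0, "weak_filter",
                "consistent_with_null"))
}

#' Standardized effect size of an observed trait range
#'
#' Compares an observed within-sample trait range to its richness-matched
#' null distribution.  Two normalizations are computed: `ses_paper =
#' (obs - null_mean) / null_mean` (the formulation whose sign convention
#' the field reports) and `ses_sd = (obs - null_mean) / null_sd` (the
#' normalization under which a +/-1.96 two-tailed criterion is
#' probabilistically meaningful; the default `mode`).  Significance and the
#' filtering classification are evaluated under `mode` against `threshold`.
#'
#' @param obs_range Observed trait range (`>= 0`).
#' @param nulldist A [build_null_distribution()] result.
#' @param mode `"sd"` (default) or `"paper_mean"`: which normalization the
#'   significance rule uses.
#' @param threshold Two-tailed threshold (default 1.96).
#' @return Object of class `ses_result`: list with `obs_range`, `k`,
#'   `null_mean`, `null_sd`, `ses_paper`, `ses_sd`, `mode_used`,
#'   `significant`, `classification`.
#' @examples
#' nd <- build_null_distribution(c(1, 2, 3, 4), k = 2)
#' ses_range(3, nd, mode = "paper_mean")$ses_paper  # (3 - 5/3)/(5/3) = 0.8
#' @export
ses_range <- function(obs_range, nulldist, mode = c("sd", "paper_mean"),
                      threshold = 1.96) {
  mode <- match.arg(mode)
  if (!inherits(nulldist, "null_distribution"))
    tf_stop("nulldist must be a null_distribution")
  if (!is.finite(obs_range) || obs_range < 0)
    tf_stop("obs_range must be a finite non-negative number")
  if (mode == "paper_mean" && nulldist$null_mean <= 0)
    tf_stop("undefined SES (mode paper_mean): null mean is zero")
  if (mode == "sd" && nulldist$null_sd <= 0)
    tf_stop("undefined SES (mode sd): null SD is zero")
  centered <- obs_range - nulldist$null_mean
  ses_paper <- if (nulldist$null_mean > 0) centered / nulldist$null_mean else NA_real_
  ses_sd <- if (nulldist$null_sd > 0) centered / nulldist$null_sd else NA_real_
  tested <- if (mode == "sd") ses_sd else ses_paper
  structure(list(obs_range = obs_range, k = nulldist$k,
                 null_mean = nulldist$null_mean, null_sd = nulldist$null_sd,
                 ses_paper = ses_paper, ses_sd = ses_sd, mode_used = mode,
                 significant = abs(tested) >= threshold,
                 classification = classify_filtering(tested, threshold)),
            class = "ses_result")
}

#' Calibration of the SES decision rule under null assembly
#'
#' Assembles `n_samples` synthetic cup communities by the same process the
#' null model assumes -- `k` individuals drawn from the regional pool
#' without replacement, `k` sampled from `k_dist` -- scores each with the
#' sd-normalized SES, and returns the two-tailed rejection rate at
#' `threshold`.  Under a well-calibrated rule the rate is near the nominal
#' alpha (0.05 at 1.96), up to the skew of range statistics.
#'
#' @param pool A `regional_pool` or numeric vector of trait values.
#' @param k_dist Integer vector of cup sizes to resample from (values < 2
#'   are dropped).
#' @param n_samples Number of null communities to assemble (default 1000).
#' @param B Null-model iterations per richness level (default 1000).
#' @param threshold Two-tailed threshold (default 1.96).
#' @param seed Optional RNG seed.
#' @return List with `rejection_rate`, `n_samples`, `mean_ses`, `ses`.
#' @export
ses_null_calibration <- function(pool, k_dist, n_samples = 1000L, B = 1000L,
                                 threshold = 1.96, seed = NULL) {
  if (inherits(pool, "regional_pool")) pool <- pool$values
  if (!is.null(seed)) set.seed(seed)
  k_dist <- k_dist[k_dist >= 2L & k_dist <= length(pool)]
  if (!length(k_dist)) tf_stop("k_dist has no usable cup sizes (>= 2)")
  ks <- sample(as.integer(k_dist), n_samples, replace = TRUE)
  nulls <- lapply(setNames(nm = sort(unique(ks))), function(k)
    build_null_distribution(pool, k, B = B))
  ses <- vapply(ks, function(k) {
    v <- pool[sample.int(length(pool), k)]
    nd <- nulls[[as.character(k)]]
    (max(v) - min(v) - nd$null_mean) / nd$null_sd
  }, numeric(1))
  list(rejection_rate = mean(abs(ses) >= threshold),
       n_samples = n_samples, mean_ses = mean(ses), ses = ses)
}

#' SES of trait ranges for every eligible cup sample
#'
#' Applies the null model to each sample with a defined range (at least two
#' individuals).  Null distributions are built once per distinct richness
#' level `k` and shared across samples; the pool is per taxon over the full
#' gradient.
#'
#' @param samples A `cup_samples` object (one taxon is selected from it).
#' @param trait `"volume"` or `"darkness"`.
#' @param taxon Taxon to analyse; default: the single taxon present,
#'   error if ambiguous.
#' @param pool Optional `regional_pool` to draw from; default: built from
#'   all individuals of `taxon` in `samples`.
#' @param B,enum_cap,seed Passed to [build_null_distribution()].
#' @param mode,threshold Passed to [ses_range()].
#' @return Data frame with one row per eligible sample: `sample_id`,
#'   `taxon`, `life_zone`, `site_id`, `habitat`, `season`, `trait`, `k`,
#'   `obs_range`, `null_mean`, `null_sd`, `ses_paper`, `ses_sd`,
#'   `significant`, `classification`.  The tested mode is attached as
#'   attribute `mode`.
#' @export
ses_table <- function(samples, trait = c("volume", "darkness"), taxon = NULL,
                      pool = NULL, B = 1000L, mode = c("sd", "paper_mean"),
                      threshold = 1.96, enum_cap = 10000L, seed = NULL) {
  trait <- match.arg(trait)
  mode <- match.arg(mode)
  if (!inherits(samples, "cup_samples")) tf_stop("not a cup_samples object")
  taxa_present <- unique(samples$samples$taxon)
  if (is.null(taxon)) {
    if (length(taxa_present) != 1L)
      tf_stop("multiple taxa present (%s); specify taxon",
              paste(taxa_present, collapse = ", "))
    taxon <- taxa_present
  }
  if (is.null(pool))
    pool <- regional_pool(samples$specimens, taxon, trait)
  if (!is.null(seed)) set.seed(seed)

  rng <- trait_range(samples, trait)
  rng <- rng[rng$taxon == taxon & rng$range_defined, ]
  rng$k <- rng$n_individuals
  rng <- rng[rng$k <= length(pool$values), ]
  if (!nrow(rng)) {
    tf_warn("no eligible samples (need >= 2 individuals) for taxon '%s'", taxon)
    out <- rng[, c("sample_id", "taxon", "life_zone", "site_id", "habitat",
                   "season", "trait", "k", "obs_range")]
    out$null_mean <- out$null_sd <- out$ses_paper <- out$ses_sd <- numeric(0)
    out$significant <- logical(0)
    out$classification <- character(0)
    attr(out, "mode") <- mode
    return(out)
  }

  nulls <- lapply(setNames(nm = sort(unique(rng$k))), function(k) {
    build_null_distribution(pool, k, B = B, enum_cap = enum_cap)
  })
  res <- lapply(seq_len(nrow(rng)), function(i) {
    s <- ses_range(rng$obs_range[i], nulls[[as.character(rng$k[i])]],
                   mode = mode, threshold = threshold)
    data.frame(null_mean = s$null_mean, null_sd = s$null_sd,
               ses_paper = s$ses_paper, ses_sd = s$ses_sd,
               significant = s$significant,
               classification = s$classification, stringsAsFactors = FALSE)
  })
  out <- cbind(rng[, c("sample_id", "taxon", "life_zone", "site_id",
                       "habitat", "season", "trait", "k", "obs_range")],
               do.call(rbind, res))
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "threshold") <- threshold
  out
}
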