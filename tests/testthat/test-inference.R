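test_that("one-way ANOVA reproduces hand-computed statistics", {
  # MS_between = 300, MS_within = 1 -> F = 300 on (2, 6) df
  an <- anova_oneway(c(1, 2, 3, 11, 12, 13, 21, 22, 23),
                     rep(c("a", "b", "c"), each = 3))
  expect_equal(an$F, 300)
  expect_equal(an$df_between, 2L)
  expect_equal(an$df_within, 6L)
  expect_equal(unname(an$group_means), c(2, 12, 22))

  # identical groups: no between-group signal
  an0 <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)

  expect_error(anova_oneway(rep(5, 6), rep(c("a", "b"), each = 3)),
               "degenerate")
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "at least 2 values")

  # duplicating every observation doubles residual df, keeps group means
  x <- c(3, 5, 8, 12, 15, 11)
  g <- rep(c("lo", "hi"), each = 3)
  an1 <- anova_oneway(x, g)
  an2 <- anova_oneway(c(x, x), c(g, g))
  expect_equal(an2$group_means, an1$group_means)
  expect_gt(an2$df_within, an1$df_within)
})

test_that("Tukey HSD is conservative relative to unadjusted t tests", {
  set.seed(12)
  x <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 4))
  g <- rep(c("pp", "mc", "sf"), each = 8)
  tk <- tukey_hsd(x, g)
  expect_equal(nrow(tk), 3L)

  # oracle: pooled-SD pairwise t tests without adjustment
  pt <- stats::pairwise.t.test(x, g, p.adjust.method = "none")$p.value
  lookup <- function(a, b) {
    if (a %in% rownames(pt) && b %in% colnames(pt) && !is.na(pt[a, b]))
      return(pt[a, b])
    pt[b, a]
  }
  for (i in seq_len(nrow(tk))) {
    p_un <- lookup(tk$group_a[i], tk$group_b[i])
    expect_gte(tk$p_adj[i] + 1e-12, unname(p_un))
  }

  # three identical groups: all adjusted p near 1
  tk0 <- tukey_hsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(tk0$p_adj > 0.99))

  # one far-outlying group separates from the other two
  y <- c(rnorm(6, 0, 0.1), rnorm(6, 0.05, 0.1), rnorm(6, 50, 0.1))
  tg <- rep(c("a", "b", "c"), each = 6)
  tky <- tukey_hsd(y, tg)
  with_c <- tky$group_a == "c" | tky$group_b == "c"
  expect_lt(max(tky$p_adj[with_c]), min(tky$p_adj[!with_c]))
})

test_that("zone_summary runs the standard eight analyses", {
  spec <- assemble_dataset(tiny_config(), seed = 21)
  samples <- group_samples(spec)
  grids <- expand.grid(tx = c("bee", "fly"), tr = c("volume", "darkness"),
                       stringsAsFactors = FALSE)
  cw <- do.call(rbind, lapply(seq_len(nrow(grids)), function(i)
    cwm(group_samples(spec[spec$taxon == grids$tx[i], ]), grids$tr[i])))
  se <- do.call(rbind, lapply(seq_len(nrow(grids)), function(i)
    ses_table(samples, grids$tr[i], taxon = grids$tx[i], B = 100L,
              seed = 300 + i)))
  attr(se, "mode") <- "sd"
  zs <- zone_summary(cw, se)
  expect_equal(nrow(zs$table), 8L)
  expect_setequal(unique(zs$table$metric), c("cwm", "sesRange"))
  expect_true(all(zs$table$df1 == 2L))
  expect_true(all(zs$table$p >= 0 & zs$table$p <= 1))
  # zone stats cover every life zone for every response
  expect_equal(nrow(zs$zone_stats), 8L * 3L)
  # Tukey table has all three zone pairs per response
  expect_equal(nrow(zs$tukey), 8L * 3L)

  # site_mean aggregation uses fewer replicates but same responses
  zs2 <- zone_summary(cw, se, unit = "site_mean")
  expect_equal(nrow(zs2$table), 8L)
  expect_true(all(zs2$anovas$cwm.bee.darkness$group_n <=
                    zs$anovas$cwm.bee.darkness$group_n))
})

test_that("configured zone contrasts are recovered by the zone ANOVA", {
  # bee darkness zone means 35/35/78: a strong, detectable contrast
  spec <- assemble_dataset(generator_config(), seed = 31)
  s <- group_samples(spec[spec$taxon == "bee", ])
  cw <- cwm(s, "darkness")
  an <- anova_oneway(cw$cwm, cw$life_zone)
  expect_lt(an$p, 0.001)
  expect_gt(an$group_means[["spruce_fir"]],
            an$group_means[["ponderosa"]] + 30)

  # with no filtering and no zone contrast, the SES zone ANOVA is null
  flat_means <- list(bee = list(volume = c(302, 302, 302),
                                darkness = c(50, 50, 50)),
                     fly = list(volume = c(145, 145, 145),
                                darkness = c(30, 30, 30)))
  pvals <- vapply(1:12, function(sd_) {
    cfg0 <- generator_config(zone_trait_means = flat_means,
                             filtering_strength = list(bee = c(0, 0, 0),
                                                       fly = c(0, 0, 0)))
    sp0 <- assemble_dataset(cfg0, seed = 500 + sd_)
    s0 <- group_samples(sp0[sp0$taxon == "bee", ])
    st <- ses_table(s0, "darkness", B = 150L, seed = 900 + sd_)
    anova_oneway(st$ses_sd, st$life_zone)$p
  }, numeric(1))
  # under the null, p-values are roughly uniform: most runs non-significant
  expect_gt(mean(pvals > 0.05), 0.6)
})

test_that("intraspecific trends report direction only when significant", {
  mk_species <- function(id, means, n = 6, noise = 1, taxon = "bee",
                         seed = 1) {
    set.seed(seed)
    do.call(rbind, lapply(seq_along(means), function(zi) {
      zone <- c("ponderosa", "mixed_conifer", "spruce_fir")[zi]
      manual_specimens(pmin(pmax(rnorm(n, means[zi], noise), 0), 222),
                       life_zone = zone, species_id = id, taxon = taxon,
                       cup_id = paste0("c", zi))
    }))
  }
  rising <- mk_species("sp_rise", c(30, 60, 90), seed = 2)
  flat <- mk_species("sp_flat", c(50, 50, 50), seed = 3)
  falling <- mk_species("sp_fall", c(90, 55, 20), seed = 4)
  two_zone <- mk_species("sp_two", c(40, 70), seed = 5)
  tab <- rbind(rising, flat, falling, two_zone)
  tab$specimen_id <- sprintf("i%04d", seq_len(nrow(tab)))

  tr <- intraspecific_trends(tab)
  dk <- tr[tr$trait == "darkness", ]
  expect_false("sp_two" %in% tr$species_id)    # below min_zones
  expect_equal(dk$direction[dk$species_id == "sp_rise"], "+")
  expect_equal(dk$direction[dk$species_id == "sp_fall"], "-")
  expect_equal(dk$direction[dk$species_id == "sp_flat"], "none")
  expect_equal(dk$mean_ponderosa[dk$species_id == "sp_rise"],
               mean(rising$darkness[rising$life_zone == "ponderosa"]))

  # a significant ANOVA is required for a non-"none" direction
  expect_true(all(dk$direction[dk$p >= 0.05] == "none"))

  # nothing qualifies: empty table plus warning
  expect_warning(none <- intraspecific_trends(two_zone), "no species")
  expect_equal(nrow(none), 0L)
})
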