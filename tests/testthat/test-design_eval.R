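test_that("design summaries reduce to the sample summary and unions", {
  tab <- toy_read_table()
  # one sample at its own depth: summary equals that sample's diversity
  s <- summarise_design(tab, "site2", "A", iterations = 5, seed = 1,
                        min_reads = 1)
  expect_equal(s$n_samples, 1)
  expect_equal(s$per_sample$S_obs, 2)
  expect_equal(s$site_richness, 2)
  expect_equal(s$summary_depth, 10)

  # disjoint OTU sets union: 2 samples at site1 design A share otu1 though;
  # construct disjoint explicitly
  counts <- rbind(u1 = c(a = 1L, b = 1L, c = 1L, d = 0L, e = 0L, f = 0L,
                         g = 0L),
                  u2 = c(a = 0L, b = 0L, c = 0L, d = 2L, e = 2L, f = 2L,
                         g = 2L))
  meta <- data.frame(sample_id = c("u1", "u2"), site = "s", design = "D",
                     strategy = "unpooled", x = 0, y = 0,
                     total_reads = c(3L, 8L))
  reg <- data.frame(otu_id = letters[1:7], origin = "biological",
                    parent = letters[1:7])
  tt <- read_table(counts, meta, reg)
  s2 <- summarise_design(tt, "s", "D", min_reads = 1, iterations = 5,
                         seed = 2)
  expect_equal(s2$site_richness, 7)
  expect_gte(s2$site_richness, max(s2$per_sample$S_obs))

  expect_error(summarise_design(tab, "site9", "A"), "absent")
  # shallow samples are dropped with a warning; a stratum losing every
  # sample is an error
  expect_warning(s3 <- summarise_design(tab, "site1", "A", min_reads = 12,
                                        iterations = 5, seed = 4),
                 regexp = "below")
  expect_equal(s3$n_samples, 1)
  expect_error(suppressWarnings(summarise_design(tab, "site1", "B",
                                                 min_reads = 100)),
               "no samples left")
})

test_that("design ratios are reference / design with exclusions honoured", {
  mk <- function(site, design, S, h1) list(site_id = site,
                                           design_name = design,
                                           site_richness = S,
                                           site_hill1 = h1)
  sums <- list(mk("s1", "ref", 40, 20), mk("s1", "low", 10, 5),
               mk("s1", "sub", 2, 1), mk("s1", "zero", 0, 0))
  r <- design_ratios(sums, "ref", exclusions = "sub")
  expect_equal(r$q0_ratio[r$design == "ref"], 1)
  expect_equal(r$q0_ratio[r$design == "low"], 4)
  expect_equal(r$q1_ratio[r$design == "low"], 4)
  expect_false("sub" %in% r$design)
  expect_true(is.na(r$q0_ratio[r$design == "zero"]))
  expect_error(design_ratios(sums, "nope"), "absent")
})

test_that("denser designs dominate sparser ones in recovered richness", {
  tab <- fixture_survey()
  sums <- lapply(c("N62D0-5", "N9D0-10", "N5D0-20"), function(d)
    suppressWarnings(summarise_design(tab, "site1", d, iterations = 20,
                                      seed = 3)))
  r <- design_ratios(sums, "N62D0-5")
  expect_true(all(r$q0_ratio[r$design != "N62D0-5"] > 1))
})

test_that("site rankings and concordance behave on constructed inputs", {
  mk <- function(site, design, S) list(site_id = site, design_name = design,
                                       site_richness = S, site_hill1 = S)
  identical_sums <- c(lapply(1:3, function(i) mk(paste0("s", i), "A",
                                                 10 * i)),
                      lapply(1:3, function(i) mk(paste0("s", i), "B",
                                                 10 * i)))
  rk <- rank_sites(identical_sums)
  expect_true(all(rk$concordance == 1))
  reversed <- c(lapply(1:3, function(i) mk(paste0("s", i), "A", 10 * i)),
                lapply(1:3, function(i) mk(paste0("s", i), "B", -10 * i)))
  rk2 <- rank_sites(reversed)
  expect_equal(rk2$concordance["A", "B"], -1)
  expect_error(rank_sites(list(mk("s1", "A", 1))), "2 sites")
})

test_that("designs with many samples recover a true site gradient", {
  # 3 sites whose intensity doubles: N >= 20 designs must rank them
  hits <- 0
  for (s in 1:5) {
    pool <- make_species_pool("fungus_like", richness_total = 50,
                              seed = derive_seed(s, "rank"))
    sites <- lapply(1:3, function(i)
      realise_site(pool, 50, seed = derive_seed(s, "rs", i),
                   site_id = paste0("site", i),
                   intensity_scale = c(0.5, 1, 2)[i]))
    tab <- suppressWarnings(run_survey(sites, builtin_designs()["N40D0-5A"],
                                       "unpooled", pool, lab_config(),
                                       seed = derive_seed(s, "rv")))
    sums <- lapply(paste0("site", 1:3), function(st)
      suppressWarnings(summarise_design(tab, st, "N40D0-5A",
                                        iterations = 10, seed = s)))
    rich <- vapply(sums, `[[`, numeric(1), "site_richness")
    if (all(order(rich) == 1:3)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("the pooling effect is the depth-matched ratio", {
  tab <- self_consistent_table()
  # pooled row is literally the concatenated unpooled reads: PE = 1 exactly
  pe <- pooling_effect(tab, "site1", "D", "soil_pool", q = 0,
                       depth_fractions = 1, iterations = 5, seed = 1)
  expect_equal(pe$pe, 1)
  expect_true(pe$feasible)
  # ratio definition on a constructed pair
  pe2 <- pooling_effect(tab, "site1", "D", "soil_pool", q = 1,
                        depth_fractions = 1, iterations = 5, seed = 1)
  expect_equal(pe2$pe, 1, tolerance = 1e-10)
  expect_error(pooling_effect(tab, "site1", "D", "dna_pool"), "missing")
  # infeasible fractions are flagged, not extrapolated
  tab2 <- self_consistent_table()
  tab2$counts["pool1", ] <- as.integer(floor(tab2$counts["pool1", ] / 3))
  tab2$sample_meta$total_reads <- rowSums(tab2$counts)
  expect_warning(
    pe3 <- pooling_effect(tab2, "site1", "D", "soil_pool",
                          depth_fractions = c(0.25, 1), iterations = 5,
                          seed = 1),
    "below target")
  expect_true(is.na(pe3$pe[pe3$fraction == 1]))
  expect_false(pe3$feasible[pe3$fraction == 1])
})

test_that("pooling effect is invariant to OTU and row order", {
  tab <- fixture_survey()
  pe1 <- suppressWarnings(pooling_effect(tab, "site1", "N9D0-10",
                                         "soil_pool", 0, 1,
                                         iterations = 30, seed = 7))
  ord <- rev(seq_len(ncol(tab$counts)))
  tab2 <- tab
  tab2$counts <- tab2$counts[rev(seq_len(nrow(tab$counts))), ord]
  tab2$sample_meta <- tab2$sample_meta[rev(seq_len(nrow(tab$sample_meta))), ]
  pe2 <- suppressWarnings(pooling_effect(tab2, "site1", "N9D0-10",
                                         "soil_pool", 0, 1,
                                         iterations = 30, seed = 7))
  expect_equal(pe1$pe, pe2$pe, tolerance = 0.05)
  expect_equal(pe1$unpooled_value, pe2$unpooled_value)
})

test_that("PE rises with the depth fraction in expectation", {
  tab <- fixture_survey()
  pe <- suppressWarnings(pooling_effect(tab, "site1", "N62D0-5", "dna_pool",
                                        0, c(0.25, 0.5, 0.75, 1),
                                        iterations = 30, seed = 8))
  ok <- pe[pe$feasible, ]
  expect_true(all(diff(ok$pe) > -0.05))
})

test_that("the area-subsampling test handles geometry and the null", {
  # degenerate geometry: all samples at one point
  counts <- matrix(1L, 10, 4,
                   dimnames = list(paste0("s", 1:10), paste0("o", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:10), site = "s1",
                     design = "D", strategy = "unpooled", x = 0, y = 0,
                     total_reads = 4L)
  reg <- data.frame(otu_id = paste0("o", 1:4), origin = "biological",
                    parent = paste0("o", 1:4))
  degen <- read_table(counts, meta, reg)
  expect_error(area_subsampling_test(degen, k = 2, max_tries = 200),
               "no feasible")

  # k = 2, two samples 20 m apart on each axis: one 400 m^2 square pair
  meta2 <- meta
  meta2$x <- c(0, 20, rep(100, 8)); meta2$y <- c(0, 20, rep(100, 8))
  pair <- read_table(counts, meta2, reg)
  res <- area_subsampling_test(pair, k = 2, area_min = 300, area_max = 500,
                               n_combinations = 3, n_permutations = 19,
                               seed = 1, max_tries = 3000)
  expect_true(all(res$combinations$area == 400))
  expect_equal(res$combinations$width[1], 20)
})

test_that("the area slope is null-calibrated on one homogeneous survey", {
  pool <- make_species_pool("fungus_like", richness_total = 50,
                            preset_overrides = list(homogeneous = TRUE),
                            seed = 41)
  site <- realise_site(pool, 50, seed = 42)
  tab <- run_survey(site, builtin_designs()["N62D0-5"], "unpooled", pool,
                    lab_config(), seed = 43)
  res <- area_subsampling_test(tab, design = "N62D0-5", k = 8,
                               n_combinations = 30, n_permutations = 199,
                               seed = 44)
  expect_gte(res$n, 10)
  expect_true(res$p > 0.01) # a single seed; the rate check runs elsewhere
})
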