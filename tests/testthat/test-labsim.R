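test_that("soil pooling is the equal-mass mean of core compositions", {
  expect_equal(pool_soil(list(c(3, 1, 0))), c(0.75, 0.25, 0))
  expect_equal(pool_soil(list(c(10, 0), c(0, 10))), c(0.5, 0.5))
  # arithmetic oracle on three uneven cores
  p1 <- c(0.5, 0.3, 0.2); p2 <- c(0.1, 0.1, 0.8); p3 <- c(0, 1, 0)
  got <- pool_soil(list(p1 * 40, p2 * 10, p3 * 7))
  expect_equal(got, (p1 + p2 + p3) / 3)
  # empty cores dilute but still count in the mean
  with_zero <- pool_soil(list(c(10, 0), c(0, 0)))
  expect_equal(with_zero, c(1, 0))
  expect_error(pool_soil(list()), "empty")
  expect_error(pool_soil(list(c(0, 0), c(0, 0))), "empty")
})

test_that("DNA pooling mixes extracts with equal weight", {
  e <- c(0.2, 0.8)
  expect_equal(pool_dna(list(e, e, e)), e)
  # 62 single-species extracts: each at 1/62
  ext <- lapply(1:62, function(i) { v <- numeric(62); v[i] <- 1; v })
  expect_equal(pool_dna(ext), rep(1 / 62, 62))
  # mixing then renormalising == renormalising then mixing
  a <- c(2, 2, 0); b <- c(0, 1, 3)
  expect_equal(pool_dna(list(a, b)),
               (a / sum(a) + b / sum(b)) / 2)
  expect_error(pool_dna(list()), "empty")
})

test_that("extraction is Poisson in the templates with zero-mass safety", {
  cfg <- lab_config(templates_per_extraction = 1000)
  comp <- c(a = 0.999, b = 0.001, c = 0)
  hits <- 0L
  reps <- 4000L
  for (s in seq_len(reps)) {
    t <- extract_dna(comp, cfg, seed = s)
    expect_identical(unname(t[3]), 0L)
    if (t[2] > 0) hits <- hits + 1L
  }
  p <- 1 - exp(-1) # detection at T * p = 1
  expect_lt(abs(hits / reps - p), 3 * sqrt(p * (1 - p) / reps))
  expect_error(extract_dna(c(-0.1, 1.1), cfg), "negative")
  expect_error(extract_dna(c(0.4, 0.4), cfg), "sum to 1")
})

test_that("pooling dilutes rare templates monotonically in pool size", {
  # worst case: the species sits in one core at proportion q; detection
  # after soil pooling ~ 1 - exp(-T q / N)
  cfg <- lab_config(templates_per_extraction = 2000)
  q <- 0.01
  detect_rate <- function(N) {
    cores <- c(list(c(rare = q, common = 1 - q) * 100),
               rep(list(c(rare = 0, common = 1) * 100), N - 1))
    mix <- pool_soil(cores)
    mean(vapply(1:400, function(s)
      extract_dna(mix, cfg, seed = s)[["rare"]] > 0, logical(1)))
  }
  r2 <- detect_rate(2); r10 <- detect_rate(10); r50 <- detect_rate(50)
  expect_gt(r2, r10)
  expect_gt(r10, r50)
  expect_lt(abs(r10 - (1 - exp(-2000 * q / 10))), 0.08)
})

test_that("sequencing reproduces template proportions in the unbiased limit", {
  cfg <- lab_config(bias_sd = 0, artefact_rate = 0, chimera_coeff = 0)
  expect_identical(pcr_and_sequence(c(a = 5), depth = 0)$reads, integer(0))
  expect_error(pcr_and_sequence(c(a = 0, b = 0), config = cfg, depth = 10),
               "empty template")
  tmpl <- c(a = 60, b = 30, c = 10)
  acc <- c(a = 0, b = 0, c = 0)
  for (s in 1:200) {
    r <- pcr_and_sequence(tmpl, config = cfg, depth = 500,
                          pcr_id = "p", seed = s)
    acc <- acc + r$reads[names(acc)]
    expect_length(r$artefacts, 0)
  }
  props <- acc / sum(acc)
  expect_lt(max(abs(props - tmpl / sum(tmpl))), 0.01)
})

test_that("artefact counts are Poisson-additive across separate reactions", {
  # N shallow reactions mint ~N times the artefacts of one at equal depth
  cfg <- lab_config(bias_sd = 0, artefact_rate = 2, chimera_coeff = 0)
  tmpl <- c(a = 50, b = 50)
  n_arts <- function(depth, seed)
    length(pcr_and_sequence(tmpl, config = cfg, depth = depth,
                            pcr_id = paste0("p", seed),
                            seed = seed)$artefacts)
  many <- sum(vapply(1:300, function(s) n_arts(1000, s), numeric(1)))
  # expected 2 per reaction at depth 1000: 600 over 300 reactions
  expect_lt(abs(many - 600), 3 * sqrt(600))
  # chimera escalation raises the rate with template diversity
  cfg2 <- lab_config(bias_sd = 0, artefact_rate = 0, chimera_coeff = 1)
  even <- mean(vapply(1:100, function(s)
    length(pcr_and_sequence(c(a = 25, b = 25, c = 25, d = 25),
                            config = cfg2, depth = 1000, pcr_id = "q",
                            seed = s)$artefacts), numeric(1)))
  skewed <- mean(vapply(1:100, function(s)
    length(pcr_and_sequence(c(a = 97, b = 1, c = 1, d = 1),
                            config = cfg2, depth = 1000, pcr_id = "r",
                            seed = s)$artefacts), numeric(1)))
  expect_gt(even, skewed) # Hill1 = 4 vs ~1.2
})

test_that("surveys produce consistent, conservative, reproducible tables", {
  tab <- fixture_survey()
  m <- tab$sample_meta
  # 62 + 9 + 5 unpooled rows, one pooled row per flat design and strategy
  expect_equal(sum(m$strategy == "unpooled"), 76)
  expect_equal(sum(m$strategy == "soil_pool"), 3)
  expect_equal(sum(m$strategy == "dna_pool"), 3)
  # conservation: row sums equal recorded depths
  expect_equal(unname(rowSums(tab$counts)), m$total_reads)
  # registry covers every OTU, artefacts map to exactly one PCR
  expect_setequal(colnames(tab$counts), tab$otu_registry$otu_id)
  arts <- tab$otu_registry[tab$otu_registry$origin == "artefact", ]
  expect_true(all(arts$parent %in% m$sample_id))
  art_rows <- colSums(tab$counts[, arts$otu_id, drop = FALSE] > 0)
  expect_true(all(art_rows == 1)) # artefacts unique to their reaction
  bio <- tab$otu_registry[tab$otu_registry$origin == "biological", ]
  expect_true(all(grepl("^fungus_sp", bio$parent)))
})

test_that("hierarchical designs pool per top-level composite", {
  pool <- make_species_pool("fungus_like", richness_total = 40, seed = 3)
  site <- realise_site(pool, 50, seed = 4)
  expect_warning(
    tab <- run_survey(site, builtin_designs()["N75D0-7.5"],
                      c("unpooled", "soil_pool"), pool, lab_config(),
                      seed = 5),
    "pooled sampling only")
  expect_equal(nrow(tab$counts), 3) # one row per top-level composite
  expect_equal(sort(tab$sample_meta$composite), 1:3)
})

test_that("rerunning a survey with the same master seed is identical", {
  pool <- make_species_pool("animal_like", richness_total = 15, seed = 6)
  site <- realise_site(pool, 35, seed = 7)
  t1 <- run_survey(site, builtin_designs()["N9D0-10"],
                   c("unpooled", "dna_pool"), pool, lab_config(), seed = 8)
  t2 <- run_survey(site, builtin_designs()["N9D0-10"],
                   c("unpooled", "dna_pool"), pool, lab_config(), seed = 8)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$sample_meta, t2$sample_meta)
})
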