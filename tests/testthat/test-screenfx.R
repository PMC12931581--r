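test_that("the rare threshold is inclusive at 0.05% of total reads", {
  counts <- matrix(c(5L, 6L, 9989L), 1,
                   dimnames = list("s1", c("edge", "above", "big")))
  meta <- data.frame(sample_id = "s1", site = "x", design = "D",
                     strategy = "unpooled", total_reads = 10000L)
  reg <- data.frame(otu_id = colnames(counts), origin = "biological",
                    parent = colnames(counts))
  tab <- read_table(counts, meta, reg)
  rare <- classify_rare(tab)
  expect_true(rare[["edge"]])    # 5 / 10000 = 0.05% exactly
  expect_false(rare[["above"]])  # 0.06%
  expect_false(rare[["big"]])

  single <- read_table(matrix(10L, 1, dimnames = list("s", "only")),
                       data.frame(sample_id = "s", site = "x",
                                  design = "D", strategy = "unpooled",
                                  total_reads = 10L),
                       data.frame(otu_id = "only", origin = "biological",
                                  parent = "only"))
  expect_false(classify_rare(single)[["only"]])
})

test_that("uniqueness is per design within a site, order-invariant", {
  tab <- toy_read_table()
  u <- classify_unique(tab, "site1")
  expect_equal(unname(u["otu1"]), NA_character_) # designs A and B
  expect_equal(unname(u["otu2"]), "A")
  expect_equal(unname(u["otu3"]), "A")
  # shuffling samples changes nothing
  tab2 <- tab
  ord <- c(3, 1, 4, 2)
  tab2$counts <- tab2$counts[ord, ]
  tab2$sample_meta <- tab2$sample_meta[ord, ]
  expect_identical(classify_unique(tab2, "site1")[names(u)], u)
  expect_error(classify_unique(tab, "site2"), "2 designs")
})

test_that("global alignment yields distances and gap runs as constructed", {
  id <- align_global("ACGTACGT", "ACGTACGT")
  expect_equal(id$p_distance, 0)
  expect_equal(nrow(id$gap_runs), 0)

  expect_equal(align_global("ACGT", "AGGT")$p_distance, 0.25)

  set.seed(1)
  ref <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  qvec <- strsplit(ref, "")[[1]][-(100:124)] # internal 25-base deletion
  del <- align_global(paste(qvec, collapse = ""), ref)
  expect_equal(nrow(del$gap_runs), 1)
  expect_equal(del$gap_runs$length, 25)
  expect_equal(del$p_distance, 0)

  expect_error(align_global("ACGT", "ACNT"), "A/C/G/T")
  expect_silent(align_global("ACGT", "ACNT", iupac = TRUE))
  expect_error(align_global("", "ACGT"), "empty")
})

test_that("screening rules flag exactly their boundary cases", {
  set.seed(2)
  ref <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  rv <- strsplit(ref, "")[[1]]
  win <- list(start = 100, width = 200)
  screen <- function(q) screen_artefacts(align_global(q, ref),
                                         window_start = win$start,
                                         window = win$width)

  # 20-base gap: not a long indel; 21-base: flagged
  gap20 <- paste(rv[-(150:169)], collapse = "")
  gap21 <- paste(rv[-(150:170)], collapse = "")
  expect_false(screen(gap20)[["long_indel"]])
  expect_true(screen(gap21)[["long_indel"]])

  # one single-base indel in the window: clean; two: flagged
  one <- paste(rv[-150], collapse = "")
  two <- paste(rv[-c(150, 240)], collapse = "")
  expect_false(screen(one)[["multi_indel_window"]])
  expect_true(screen(two)[["multi_indel_window"]])
  # two single-base indels outside the window: clean
  outside <- paste(rv[-c(20, 350)], collapse = "")
  expect_false(screen(outside)[["multi_indel_window"]])

  # exactly 2% divergence: clean (strict inequality); above: flagged
  mutate_at <- function(v, pos) {
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    v
  }
  div2 <- paste(mutate_at(rv, seq(5, by = 7, length.out = 8)),
                collapse = "") # 8/400 = 2%
  div3 <- paste(mutate_at(rv, seq(5, by = 7, length.out = 12)),
                collapse = "") # 3%
  expect_false(screen(div2)[["excess_divergence"]])
  expect_true(screen(div3)[["excess_divergence"]])
  expect_false(screen(div2)[["artefact"]])
  expect_true(screen(div3)[["artefact"]])

  expect_error(screen_artefacts(align_global(ref, ref), 300, 200),
               "outside")
})

test_that("screening recovers planted artefacts perfectly", {
  registry <- data.frame(
    otu_id = c(sprintf("bio%02d", 1:12), sprintf("art%02d", 1:12)),
    origin = rep(c("biological", "artefact"), each = 12))
  fx <- make_synthetic_alignment(registry, seed = 9)
  ref <- fx$sequences[[grep("^reference", names(fx$sequences))]]
  calls <- vapply(registry$otu_id, function(id) {
    pair <- align_global(fx$sequences[[id]], ref)
    screen_artefacts(pair, fx$window_start, fx$window)[["artefact"]]
  }, logical(1))
  truth <- fx$truth$origin == "artefact"
  expect_equal(sum(calls & truth) / sum(truth), 1)   # sensitivity
  expect_equal(sum(!calls & !truth) / sum(!truth), 1) # specificity
  # the planted signature matches the triggered flag
  for (i in which(truth)) {
    pair <- align_global(fx$sequences[[registry$otu_id[i]]], ref)
    flags <- screen_artefacts(pair, fx$window_start, fx$window)
    expect_true(flags[[fx$truth$planted[i]]])
  }
  # determinism
  fx2 <- make_synthetic_alignment(registry, seed = 9)
  expect_identical(fx$sequences, fx2$sequences)
})

test_that("fasta round-trips through Biostrings", {
  fx <- make_synthetic_alignment(
    data.frame(otu_id = c("b1", "a1"),
               origin = c("biological", "artefact")), seed = 3)
  f <- tempfile(fileext = ".fasta")
  write_fasta(fx$sequences, f)
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(length(back), 3)
  expect_equal(as.character(back[[2]]), unname(fx$sequences[[2]]))
  unlink(f)
})

test_that("the artefact report computes the six statistics", {
  counts <- matrix(0L, 1, 10, dimnames = list("s1", paste0("o", 1:10)))
  counts[1, ] <- c(4000L, 3000L, 1500L, 1000L, 494L, 2L, 1L, 1L, 1L, 1L)
  meta <- data.frame(sample_id = "s1", site = "x", design = "D",
                     strategy = "unpooled", total_reads = sum(counts))
  reg <- data.frame(otu_id = paste0("o", 1:10),
                    origin = c(rep("biological", 8), "artefact", "artefact"),
                    parent = paste0("p", 1:10))
  tab <- read_table(counts, meta, reg)
  # grand total 10000; rare (<= 5 reads): o6..o10 -> 4 rare? o6=2,o7..o10=1
  rep_ <- pooling_artefact_report(tab, rare_threshold = 0.0005)
  expect_equal(rep_$n_otus, 10)
  expect_equal(rep_$n_artefacts, 2)
  expect_equal(rep_$prop_artefact, 0.2)
  expect_equal(rep_$n_rare, 5)
  expect_equal(rep_$n_rare_artefacts, 2)
  expect_equal(rep_$prop_rare_artefact, 0.4)
  # no artefacts: zero proportions
  reg2 <- reg; reg2$origin <- "biological"
  tab2 <- read_table(counts, meta, reg2)
  rep2 <- pooling_artefact_report(tab2, rare_threshold = 0.0005)
  expect_equal(rep2$prop_artefact, 0)
})

test_that("unpooled reactions out-mint the DNA pool in unique artefacts", {
  tab <- fixture_survey()
  reg <- tab$otu_registry
  art <- colnames(tab$counts) %in% reg$otu_id[reg$origin == "artefact"]
  m <- tab$sample_meta
  dense <- m$design == "N62D0-5"
  n_unp <- sum(colSums(tab$counts[m$strategy == "unpooled" & dense, art,
                                  drop = FALSE]) > 0)
  n_dna <- sum(colSums(tab$counts[m$strategy == "dna_pool" & dense, art,
                                  drop = FALSE]) > 0)
  expect_gt(n_unp, n_dna)
})
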