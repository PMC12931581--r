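# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a hand-built read table: 2 sites x 2 designs, known counts
toy_read_table <- function() {
  counts <- rbind(
    s1a1 = c(otu1 = 10L, otu2 = 5L, otu3 = 0L, art1 = 1L),
    s1a2 = c(otu1 = 4L, otu2 = 0L, otu3 = 6L, art1 = 0L),
    s1b1 = c(otu1 = 2L, otu2 = 0L, otu3 = 0L, art1 = 0L),
    s2a1 = c(otu1 = 8L, otu2 = 2L, otu3 = 0L, art1 = 0L))
  meta <- data.frame(
    sample_id = rownames(counts),
    site = c("site1", "site1", "site1", "site2"),
    design = c("A", "A", "B", "A"),
    strategy = "unpooled",
    x = c(0, 10, 5, 0), y = c(0, 10, 5, 0),
    total_reads = rowSums(counts))
  registry <- data.frame(
    otu_id = colnames(counts),
    origin = c("biological", "biological", "biological", "artefact"),
    parent = c("sp1", "sp2", "sp3", "s1a1"))
  read_table(counts, meta, registry)
}

# one small surveyed site (fungus-like), reused across analysis tests
fixture_survey <- function() {
  cached("survey", function() {
    pool <- make_species_pool("fungus_like", richness_total = 60, seed = 11)
    site <- realise_site(pool, 50, seed = 12, site_id = "site1")
    suppressWarnings(run_survey(
      site, builtin_designs()[c("N62D0-5", "N9D0-10", "N5D0-20")],
      c("unpooled", "soil_pool", "dna_pool"), pool, lab_config(),
      seed = 13))
  })
}

# deterministic read table whose pooled row is the sum of the unpooled rows
self_consistent_table <- function(n_samples = 6, n_otu = 30, seed = 5) {
  counts <- with_seed_local(seed, {
    matrix(rpois(n_samples * n_otu, 3), n_samples, n_otu,
           dimnames = list(paste0("u", seq_len(n_samples)),
                           paste0("otu", seq_len(n_otu))))
  })
  storage.mode(counts) <- "integer"
  pooled <- matrix(colSums(counts), 1, n_otu,
                   dimnames = list("pool1", colnames(counts)))
  all_counts <- rbind(counts, pooled)
  meta <- data.frame(
    sample_id = rownames(all_counts), site = "site1", design = "D",
    strategy = c(rep("unpooled", n_samples), "soil_pool"),
    x = 0, y = 0, total_reads = rowSums(all_counts))
  registry <- data.frame(otu_id = colnames(all_counts),
                         origin = "biological",
                         parent = colnames(all_counts))
  read_table(all_counts, meta, registry)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

expect_deterministic <- function(expr1, expr2) {
  expect_identical(expr1, expr2)
}
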