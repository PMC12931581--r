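#' Laboratory simulation configuration
#'
#' Parameters of the wet-lab stand-in: how many template molecules one
#' 0.2 g extraction recovers, how noisy amplification is, how artefactual
#' OTUs arise, and how sequencing depth is distributed.
#'
#' @param templates_per_extraction Expected template molecules recovered per
#'   extraction (count; the dilution bottleneck). Default 3000.
#' @param bias_sd Reaction-level sd of log amplification factors applied on
#'   top of the species' fixed `bias_factor` (dimensionless). Default 0.3.
#' @param artefact_rate Expected new artefact OTUs per 1000 reads per PCR
#'   from per-amplicon error processes. Default 0.3.
#' @param chimera_coeff Additional artefact OTUs per 1000 reads per unit of
#'   template effective diversity (Hill number of order 1): chimera formation
#'   escalates with the diversity of co-amplified templates. Default 0.15.
#' @param artefact_saturation Read depth (count) beyond which a reaction's
#'   artefact repertoire stops growing: artefact types arise during the
#'   reaction, so sequencing deeper resamples the same artefacts rather than
#'   minting new ones. Default 10000.
#' @param artefact_reads Expected reads per artefact OTU (low-abundance by
#'   construction). Default 2.
#' @param reads_mean,reads_dispersion Negative-binomial mean and size of the
#'   per-sample sequencing depth for unpooled samples. Defaults 1200 and 12
#'   (minimum depths around the hundreds, mirroring rarefaction floors of
#'   order 10^3).
#' @param pooled_depth_factor Pooled samples are sequenced deeper: their
#'   depth is negative-binomial (tighter dispersion than unpooled) with mean
#'   `pooled_depth_factor` times the design's realised summary depth (total
#'   unpooled reads), so rarefying a pooled sample to 100\% summary depth is
#'   feasible. Default 2.
#' @param capture_scale Capture-footprint multiplier used when coring (see
#'   [take_core()]). Default 20.
#' @param mass_jitter sd of lognormal jitter on per-core soil mass in soil
#'   pooling (0 = exactly equal aliquots, the default idealisation).
#' @param concentration_jitter sd of lognormal jitter on extract
#'   concentrations in DNA pooling (default 0 = equal concentrations).
#' @param norm_tol Tolerance for composition normalisation checks.
#' @return An object of class `lab_config`.
#' @export
lab_config <- function(templates_per_extraction = 3000, bias_sd = 0.3,
                       artefact_rate = 0.3, chimera_coeff = 0.15,
                       artefact_saturation = 10000, artefact_reads = 2,
                       reads_mean = 1200, reads_dispersion = 12,
                       pooled_depth_factor = 2, capture_scale = 20,
                       mass_jitter = 0, concentration_jitter = 0,
                       norm_tol = 1e-9) {
  cfg <- list(templates_per_extraction = templates_per_extraction,
              bias_sd = bias_sd, artefact_rate = artefact_rate,
              chimera_coeff = chimera_coeff,
              artefact_saturation = artefact_saturation,
              artefact_reads = artefact_reads,
              reads_mean = reads_mean, reads_dispersion = reads_dispersion,
              pooled_depth_factor = pooled_depth_factor,
              capture_scale = capture_scale, mass_jitter = mass_jitter,
              concentration_jitter = concentration_jitter,
              norm_tol = norm_tol)
  stopifnot(templates_per_extraction >= 1, bias_sd >= 0, artefact_rate >= 0,
            chimera_coeff >= 0, artefact_saturation >= 0, reads_mean > 0)
  structure(cfg, class = "lab_config")
}

as_composition <- function(x) {
  s <- sum(x)
  if (s <= 0) rep(0, length(x)) else x / s
}

#' Composite soil cores into one mixture (soil pooling)
#'
#' Equal-mass mixing: the mixture's relative abundance of each species is the
#' unweighted mean of the cores' relative abundances (a core with no
#' templates contributes a zero vector but still counts in the mean, exactly
#' as barren soil dilutes a composite). With `mass_jitter > 0`, per-core
#' weights are lognormal around equality.
#'
#' @param cores List of `core_sample` objects (or plain template vectors).
#' @param mass_jitter sd of log weights (0 = exact equal mass).
#' @param seed Seed for the jitter draw (ignored when `mass_jitter = 0`).
#' @return Numeric composition vector (sums to 1).
#' @export
pool_soil <- function(cores, mass_jitter = 0, seed = NULL) {
  if (!length(cores)) stop("empty core list")
  vecs <- lapply(cores, function(co)
    if (inherits(co, "core_sample")) co$templates else co)
  if (all(vapply(vecs, sum, numeric(1)) == 0))
    stop("all cores are empty")
  props <- lapply(vecs, as_composition)
  w <- rep(1, length(props))
  if (mass_jitter > 0)
    w <- with_seed(seed, stats::rlnorm(length(props), 0, mass_jitter))
  w <- w / sum(w)
  mix <- Reduce(`+`, Map(`*`, props, w))
  # cores may hold zero vectors, so renormalise the weighted mean
  as_composition(mix)
}

#' Mix DNA extracts into one pool (DNA pooling)
#'
#' Equal-volume, equal-concentration mixing: the unweighted mean of the
#' extracts' relative-abundance vectors. Optional lognormal concentration
#' jitter models unquantified extracts mixed by fixed volume.
#'
#' @param extracts List of template-count or composition vectors.
#' @param concentration_jitter sd of log concentrations (default 0).
#' @param seed Seed for the jitter draw.
#' @return Numeric composition vector (sums to 1; all-zero if every extract
#'   is empty).
#' @export
pool_dna <- function(extracts, concentration_jitter = 0, seed = NULL) {
  if (!length(extracts)) stop("empty extract list")
  props <- lapply(extracts, as_composition)
  w <- rep(1, length(props))
  if (concentration_jitter > 0)
    w <- with_seed(seed, stats::rlnorm(length(props), 0, concentration_jitter))
  w <- w / sum(w)
  as_composition(Reduce(`+`, Map(`*`, props, w)))
}

#' Draw the template molecules recovered by one DNA extraction
#'
#' Per-species template counts are Poisson with mean
#' `templates_per_extraction * p_s`. Species drawn at zero are lost to all
#' downstream steps — this is the dilution effect: a species present in one
#' of N pooled cores at within-core proportion q survives extraction with
#' probability about `1 - exp(-T q / N)`, decreasing in N.
#'
#' @param composition Relative-abundance vector (sums to 1, or all zero for
#'   a barren sample).
#' @param config A `lab_config`.
#' @param seed Integer seed.
#' @return Integer vector of template counts (same names as input).
#' @export
extract_dna <- function(composition, config = lab_config(), seed = NULL) {
  if (any(composition < 0)) stop("negative proportions")
  s <- sum(composition)
  if (s > 0 && abs(s - 1) > max(config$norm_tol, 1e-6))
    stop("composition must sum to 1 (got ", format(s), ")")
  with_seed(seed, {
    n <- stats::rpois(length(composition),
                      config$templates_per_extraction * composition)
    names(n) <- names(composition)
    n
  })
}

# Hill number of order 1 from a non-negative weight vector
hill1_weights <- function(w) {
  w <- w[w > 0]
  if (!length(w)) return(0)
  p <- w / sum(w)
  exp(-sum(p * log(p)))
}

#' Amplify and sequence one sample
#'
#' Biological read weights are proportional to `templates * bias_factor`
#' (species-fixed PCR bias) times a reaction-level lognormal factor of sd
#' `bias_sd`. The reaction also mints artefactual OTUs (PCR errors and
#' chimeras), each unique to this PCR: their number is Poisson with mean
#' `min(depth, artefact_saturation)/1000 * (artefact_rate + chimera_coeff *
#' Hill1(template proportions))` — the chimera term escalates with template
#' effective diversity, and the repertoire saturates in depth because
#' artefact types are created during the reaction, not by the sequencer.
#' Each artefact OTU gets a read weight equivalent to `artefact_reads`
#' expected reads. Reads are then drawn multinomially at the given depth.
#'
#' @param templates Named non-negative vector of template counts (or
#'   relative template weights, e.g. a mixed DNA-pool composition).
#' @param bias_factor Per-species amplification multipliers (defaults to 1).
#' @param config A `lab_config`.
#' @param depth Read count to draw (>= 0).
#' @param pcr_id Identifier for this reaction (used to name artefact OTUs).
#' @param seed Integer seed.
#' @return List with `reads` (named integer vector over biological species
#'   and new artefact OTUs) and `artefacts` (character vector of the new
#'   artefact OTU ids).
#' @export
pcr_and_sequence <- function(templates, bias_factor = NULL,
                             config = lab_config(), depth, pcr_id = "pcr1",
                             seed = NULL) {
  stopifnot(depth >= 0)
  if (depth == 0)
    return(list(reads = integer(0), artefacts = character(0)))
  if (sum(templates) == 0)
    stop("empty template vector with positive sequencing depth")
  if (is.null(bias_factor)) bias_factor <- rep(1, length(templates))
  with_seed(seed, {
    w <- templates * bias_factor
    if (config$bias_sd > 0)
      w <- w * stats::rlnorm(length(w), 0, config$bias_sd)
    eff_depth <- min(depth, config$artefact_saturation)
    lambda <- eff_depth / 1000 *
      (config$artefact_rate +
         config$chimera_coeff * hill1_weights(templates))
    n_art <- stats::rpois(1L, lambda)
    art_ids <- if (n_art > 0) sprintf("ART_%s_%03d", pcr_id, seq_len(n_art))
               else character(0)
    art_w <- rep(config$artefact_reads / depth * sum(w), n_art)
    all_w <- c(w, art_w)
    names(all_w) <- c(names(templates), art_ids)
    reads <- stats::rmultinom(1L, depth, all_w)[, 1L]
    list(reads = reads, artefacts = art_ids)
  })
}

# negative binomial depth draw, at least 1 read
draw_depth <- function(mean, size) {
  max(1L, stats::rnbinom(1L, mu = mean, size = size))
}

# split leaf indices 1..n into top-level composite groups
composite_groups <- function(design) {
  n <- design_leaves(design)
  k <- design_top_composites(design)
  split(seq_len(n), rep(seq_len(k), each = n / k))
}

#' Run a virtual survey: core, pool, extract, amplify, sequence
#'
#' Orchestrates one organism group's survey over sites, designs and pooling
#' strategies, producing a `read_table`. Unpooled processing yields one
#' sequenced sample per core; soil and DNA pooling yield one sample per
#' top-level composite per design and site (flat designs: one sample).
#' Designs defined for pooled sampling only (hierarchical composites, the
#' Table-1 em-dash cells) are skipped with a warning when the unpooled
#' strategy is requested. Cores whose capture volume holds no propagules
#' yield zero-read samples (failed reactions), recorded with depth 0.
#'
#' @param sites A `virtual_site` or list of them.
#' @param designs List of `design_spec` (default [builtin_designs()]).
#' @param strategies Subset of `c("unpooled", "soil_pool", "dna_pool")`.
#' @param pool The `species_pool` the sites were realised from, or a named
#'   list of pools (one per organism group) matching a list of site lists,
#'   in which case a named list of `read_table`s is returned.
#' @param config A `lab_config`.
#' @param seed Integer master seed; every reaction derives its own substream.
#' @return A `read_table` (see [read_table()]), or a named list of them.
#' @export
run_survey <- function(sites, designs = builtin_designs(),
                       strategies = c("unpooled", "soil_pool", "dna_pool"),
                       pool, config = lab_config(), seed = 1L) {
  if (inherits(sites, "virtual_site")) sites <- list(sites)
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (inherits(designs, "design_spec")) designs <- list(designs)
  if (!inherits(pool, "species_pool") && is.list(pool)) {
    stopifnot(!is.null(names(pool)))
    out <- lapply(names(pool), function(g)
      run_survey(sites[[g]], designs, strategies, pool[[g]], config,
                 derive_seed(seed, "group", g)))
    return(stats::setNames(out, names(pool)))
  }

  species_ids <- pool$species$species_id
  bias <- pool$species$bias_factor
  rows <- list(); meta <- list(); art_parent <- character(0)

  add_row <- function(reads, sample_id, site_id, design, strategy, x, y,
                      composite, arts, pcr_id) {
    rows[[length(rows) + 1L]] <<- reads
    meta[[length(meta) + 1L]] <<- data.frame(
      sample_id = sample_id, site = site_id, design = design$name,
      strategy = strategy, x = x, y = y, composite = composite,
      total_reads = sum(reads), stringsAsFactors = FALSE)
    if (length(arts))
      art_parent <<- c(art_parent, stats::setNames(rep(pcr_id, length(arts)),
                                                   arts))
  }

  for (site in sites) {
    for (design in designs) {
      positions <- place_cores(design, site,
                               derive_seed(seed, site$site_id, design$name))
      cores <- take_design_cores(site, design, positions,
                                 config$capture_scale)
      core_pos <- positions[rep(seq_len(nrow(positions)),
                                each = length(design$depth_intervals)), ]
      pooled_only <- is.na(design$unpooled_n)
      summary_depth <- 0L

      if ("unpooled" %in% strategies) {
        if (pooled_only) {
          warning("design ", design$name,
                  " is defined for pooled sampling only; skipping unpooled")
        } else {
          for (i in seq_along(cores)) {
            sid <- sprintf("%s.%s.unpooled.%02d", site$site_id, design$name, i)
            d_seed <- derive_seed(seed, sid)
            depth <- with_seed(d_seed, draw_depth(config$reads_mean,
                                                  config$reads_dispersion))
            if (sum(cores[[i]]$templates) == 0) {
              depth <- 0L
              reads <- integer(0); arts <- character(0)
            } else {
              tmpl <- extract_dna(as_composition(cores[[i]]$templates),
                                  config, derive_seed(seed, sid, "extract"))
              if (sum(tmpl) == 0) {
                depth <- 0L; reads <- integer(0); arts <- character(0)
              } else {
                res <- pcr_and_sequence(tmpl, bias, config, depth, sid,
                                        derive_seed(seed, sid, "pcr"))
                reads <- res$reads; arts <- res$artefacts
              }
            }
            summary_depth <- summary_depth + sum(reads)
            add_row(reads, sid, site$site_id, design, "unpooled",
                    core_pos$x[i], core_pos$y[i], NA_integer_, arts, sid)
          }
        }
      }
      if (summary_depth == 0L)  # pooled-only designs or no unpooled rows
        summary_depth <- design_leaves(design) * config$reads_mean

      groups <- composite_groups(design)
      pooled_mean_depth <- config$pooled_depth_factor * summary_depth /
        length(groups)

      if ("soil_pool" %in% strategies) {
        for (g in seq_along(groups)) {
          sid <- sprintf("%s.%s.soil_pool.%02d", site$site_id, design$name, g)
          mix <- tryCatch(pool_soil(cores[groups[[g]]], config$mass_jitter,
                                    derive_seed(seed, sid, "mass")),
                          error = function(e) NULL)
          depth <- with_seed(derive_seed(seed, sid, "depth"),
                             draw_depth(pooled_mean_depth,
                                        config$reads_dispersion * 4))
          if (is.null(mix)) { reads <- integer(0); arts <- character(0)
          } else {
            tmpl <- extract_dna(mix, config, derive_seed(seed, sid, "extract"))
            if (sum(tmpl) == 0) { reads <- integer(0); arts <- character(0)
            } else {
              res <- pcr_and_sequence(tmpl, bias, config, depth, sid,
                                      derive_seed(seed, sid, "pcr"))
              reads <- res$reads; arts <- res$artefacts
            }
          }
          add_row(reads, sid, site$site_id, design, "soil_pool",
                  NA_real_, NA_real_, g, arts, sid)
        }
      }

      if ("dna_pool" %in% strategies) {
        for (g in seq_along(groups)) {
          sid <- sprintf("%s.%s.dna_pool.%02d", site$site_id, design$name, g)
          extracts <- lapply(groups[[g]], function(i) {
            if (sum(cores[[i]]$templates) == 0)
              return(rep(0L, length(species_ids)))
            extract_dna(as_composition(cores[[i]]$templates), config,
                        derive_seed(seed, sid, "extract", i))
          })
          mix <- pool_dna(extracts, config$concentration_jitter,
                          derive_seed(seed, sid, "conc"))
          depth <- with_seed(derive_seed(seed, sid, "depth"),
                             draw_depth(pooled_mean_depth,
                                        config$reads_dispersion * 4))
          if (sum(mix) == 0) { reads <- integer(0); arts <- character(0)
          } else {
            # the mixed extract goes straight into the reaction: template
            # copy numbers in a DNA pool are ample, so no further Poisson
            # bottleneck beyond each core's own extraction
            res <- pcr_and_sequence(mix, bias, config, depth, sid,
                                    derive_seed(seed, sid, "pcr"))
            reads <- res$reads; arts <- res$artefacts
          }
          add_row(reads, sid, site$site_id, design, "dna_pool",
                  NA_real_, NA_real_, g, arts, sid)
        }
      }
    }
  }

  meta <- do.call(rbind, meta)
  # assemble the sparse rows into a dense samples x OTU matrix
  observed <- unique(unlist(lapply(rows, function(r) names(r)[r > 0]),
                            use.names = FALSE))
  all_ids <- c(species_ids[species_ids %in% observed],
               grep("^ART_", observed, value = TRUE))
  counts <- matrix(0L, nrow = length(rows), ncol = length(all_ids),
                   dimnames = list(meta$sample_id, all_ids))
  for (i in seq_along(rows)) {
    r <- rows[[i]]; r <- r[r > 0]
    if (length(r)) counts[i, names(r)] <- as.integer(r)
  }
  registry <- data.frame(
    otu_id = all_ids,
    origin = ifelse(grepl("^ART_", all_ids), "artefact", "biological"),
    parent = ifelse(grepl("^ART_", all_ids),
                    unname(art_parent[all_ids]), all_ids),
    stringsAsFactors = FALSE)
  read_table(counts, meta, registry)
}
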