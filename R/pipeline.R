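#' Configuration for a full virtual survey experiment
#'
#' Bundles every tunable of the simulate -> survey -> analyse -> report
#' chain with documented defaults. The configuration round-trips through
#' JSON losslessly (see [run_experiment()]'s manifest).
#'
#' @param seed Master seed; every stage derives substreams from it.
#' @param n_sites Number of virtual sites (default 3).
#' @param extent Site side length in m (default 50, i.e. 2500 m^2).
#' @param site_intensity Per-site multiplier on propagule intensity,
#'   imposing a true site-richness gradient (default `c(0.7, 1, 1.3)`).
#' @param groups Organism groups to simulate (default all three).
#' @param group_overrides Named list (per group) of preset overrides.
#' @param designs Design names from [builtin_designs()] (default all 12).
#' @param strategies Pooling strategies (default all three).
#' @param lab A `lab_config`.
#' @param rarefaction_iterations Default 1000.
#' @param depth_fractions PE depth-fraction grid (default
#'   `c(0.25, 0.5, 0.75, 1)`).
#' @param rare_threshold Rare-OTU proportion threshold (default 5e-4).
#' @param n_permutations Permutations for the composition tests
#'   (default 999).
#' @param output_dir Where [run_experiment()] writes its artefacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_sites = 3, extent = 50,
                       site_intensity = c(0.7, 1, 1.3),
                       groups = c("animal_like", "bacteria_like",
                                  "fungus_like"),
                       group_overrides = list(),
                       designs = names(builtin_designs()),
                       strategies = c("unpooled", "soil_pool", "dna_pool"),
                       lab = lab_config(),
                       rarefaction_iterations = 1000,
                       depth_fractions = c(0.25, 0.5, 0.75, 1),
                       rare_threshold = 0.0005, n_permutations = 999,
                       output_dir = "results") {
  stopifnot(length(site_intensity) == n_sites)
  structure(list(seed = seed, n_sites = n_sites, extent = extent,
                 site_intensity = site_intensity, groups = groups,
                 group_overrides = group_overrides, designs = designs,
                 strategies = strategies, lab = lab,
                 rarefaction_iterations = rarefaction_iterations,
                 depth_fractions = depth_fractions,
                 rare_threshold = rare_threshold,
                 n_permutations = n_permutations,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full virtual experiment end to end
#'
#' simulate -> survey -> diversity summaries -> design ratios and site
#' rankings -> pooling effects -> artefact/rare accounting -> composition
#' tests -> cost reports, writing every table as TSV under
#' `config$output_dir` plus a JSON run manifest with all seeds. Stages
#' abort with a stage-named error; outputs written before the failure are
#' left intact. Rerunning with the same config reproduces every output.
#'
#' @param config A `run_config`.
#' @param quiet Suppress progress messages (default FALSE).
#' @return Invisibly, a list with the in-memory artefacts (`tables`,
#'   `summaries`, `ratios`, `rankings`, `pe`, `reports`, `costs`,
#'   `manifest`).
#' @export
run_experiment <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[", ..., "]")
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  designs <- builtin_designs()[config$designs]
  out_path <- function(...) file.path(config$output_dir, paste0(...))
  tsv <- function(df, name) {
    utils::write.table(df, out_path(name, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  pools <- stage("simulate", {
    lapply(stats::setNames(config$groups, config$groups), function(g)
      make_species_pool(g, preset_overrides =
                          config$group_overrides[[g]] %||% list(),
                        seed = derive_seed(config$seed, "pool", g)))
  })
  sites <- stage("realise", {
    lapply(stats::setNames(config$groups, config$groups), function(g)
      lapply(seq_len(config$n_sites), function(i)
        realise_site(pools[[g]], config$extent,
                     seed = derive_seed(config$seed, "site", i),
                     site_id = paste0("site", i),
                     intensity_scale = config$site_intensity[i])))
  })
  tables <- stage("survey", {
    tb <- lapply(stats::setNames(config$groups, config$groups), function(g)
      run_survey(sites[[g]], designs, config$strategies, pools[[g]],
                 config$lab, derive_seed(config$seed, "survey", g)))
    for (g in config$groups) write_otu_table(tb[[g]], out_path(g))
    tb
  })

  unpooled_designs <- names(designs)[!vapply(designs, function(d)
    is.na(d$unpooled_n), logical(1))]
  site_ids <- paste0("site", seq_len(config$n_sites))

  summaries <- stage("diversity", {
    su <- list()
    for (g in config$groups) {
      su[[g]] <- list()
      for (s in site_ids) for (d in unpooled_designs) {
        su[[g]][[paste(s, d)]] <- suppressWarnings(summarise_design(
          tables[[g]], s, d, iterations = config$rarefaction_iterations,
          seed = derive_seed(config$seed, "summ", g, s, d)))
      }
      div <- do.call(rbind, lapply(su[[g]], function(x)
        data.frame(site = x$site_id, design = x$design_name,
                   n_samples = x$n_samples, depth = x$rarefaction_depth,
                   mean_richness = x$mean_richness, mean_H = x$mean_H,
                   site_richness = x$site_richness,
                   site_hill1 = x$site_hill1,
                   summary_depth = x$summary_depth)))
      tsv(div, paste0(g, "_diversity"))
    }
    su
  })

  # reference = the densest unpooled design present; subsoil-only excluded
  ref_design <- unpooled_designs[which.max(vapply(
    designs[unpooled_designs], design_leaves, integer(1)))]
  ratios <- stage("ratios", {
    rr <- lapply(stats::setNames(config$groups, config$groups), function(g)
      design_ratios(summaries[[g]], reference = ref_design,
                    exclusions = "N9D30-40"))
    for (g in config$groups) tsv(rr[[g]], paste0(g, "_ratios"))
    rr
  })

  rankings <- if (config$n_sites >= 2) stage("rankings", {
    rk <- lapply(stats::setNames(config$groups, config$groups), function(g)
      rank_sites(summaries[[g]]))
    for (g in config$groups) tsv(rk[[g]]$rankings, paste0(g, "_rankings"))
    rk
  }) else NULL

  pooled_strategies <- intersect(config$strategies,
                                 c("soil_pool", "dna_pool"))
  pe <- stage("pooling-effect", {
    res <- list()
    for (g in config$groups) for (s in site_ids)
      for (d in unpooled_designs) for (strat in pooled_strategies)
        for (q in c(0, 1)) {
          r <- tryCatch(suppressWarnings(pooling_effect(
            tables[[g]], s, d, strat, q, config$depth_fractions,
            iterations = config$rarefaction_iterations,
            seed = derive_seed(config$seed, "pe", g, s, d, strat, q))),
            error = function(e) NULL)
          if (!is.null(r)) { r$group <- g; res[[length(res) + 1]] <- r }
        }
    res <- do.call(rbind, res)
    tsv(res, "pooling_effect")
    res
  })

  reports <- stage("screening", {
    rp <- lapply(stats::setNames(config$groups, config$groups), function(g)
      pooling_artefact_report(tables[[g]],
                              rare_threshold = config$rare_threshold,
                              pe_results = pe[pe$group == g & pe$q == 0, ]))
    for (g in config$groups) tsv(rp[[g]], paste0(g, "_artefact_report"))
    rp
  })

  costs <- stage("costs", {
    cs <- list()
    for (d in names(designs)) for (strat in pooled_strategies) {
      r <- compute_costs(designs[[d]], strat, 100)
      cs[[length(cs) + 1]] <- data.frame(
        design = d, strategy = strat, n_plots = 100,
        hours_unpooled = r$hours_unpooled, hours_pooled = r$hours_pooled,
        hours_saved_pct = r$hours_saved_pct,
        chem_saved_pct = r$chem_saved_pct,
        library_saved_pct = r$library_saved_pct,
        fold_reduction = r$fold_reduction)
    }
    cs <- do.call(rbind, cs)
    tsv(cs, "cost_reports")
    cs
  })

  manifest <- stage("manifest", {
    mf <- list(package_version =
                 as.character(utils::packageVersion("pooldesign")),
               r_version = R.version.string,
               seed = config$seed,
               config = config[setdiff(names(config), "lab")],
               lab = unclass(config$lab),
               stage_seeds = list(
                 pools = vapply(config$groups, function(g)
                   derive_seed(config$seed, "pool", g), integer(1)),
                 sites = vapply(seq_len(config$n_sites), function(i)
                   derive_seed(config$seed, "site", i), integer(1)),
                 surveys = vapply(config$groups, function(g)
                   derive_seed(config$seed, "survey", g), integer(1))))
    jsonlite::write_json(mf, out_path("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    mf
  })
  say("done")
  invisible(list(tables = tables, summaries = summaries, ratios = ratios,
                 rankings = rankings, pe = pe, reports = reports,
                 costs = costs, manifest = manifest))
}
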