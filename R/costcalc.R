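#' Cost model constants for sample processing
#'
#' Throughput and per-unit cost constants: one working hour covers roughly
#' 10 DNA extractions or 40 PCR reactions (including product check and
#' purification); each sample is amplified for `markers` amplicons
#' (default 3: COI, 16S, ITS).
#'
#' @param extractions_per_hour Default 10.
#' @param pcr_reactions_per_hour Default 40.
#' @param markers Amplicons per sample (default 3).
#' @param chem_units_per_extraction,chem_units_per_pcr Relative chemical
#'   cost units (defaults 1).
#' @param library_cost_per_sample Relative library-preparation units
#'   (default 1 per sample per marker).
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(extractions_per_hour = 10, pcr_reactions_per_hour = 40,
                       markers = 3, chem_units_per_extraction = 1,
                       chem_units_per_pcr = 1, library_cost_per_sample = 1) {
  stopifnot(extractions_per_hour > 0, pcr_reactions_per_hour > 0,
            markers > 0)
  structure(list(extractions_per_hour = extractions_per_hour,
                 pcr_reactions_per_hour = pcr_reactions_per_hour,
                 markers = markers,
                 chem_units_per_extraction = chem_units_per_extraction,
                 chem_units_per_pcr = chem_units_per_pcr,
                 library_cost_per_sample = library_cost_per_sample),
            class = "cost_model")
}

#' Person-hours and consumables: pooled vs unpooled processing
#'
#' Unpooled processing extracts every physical core
#' (`n_plots * leaves(design)` extractions); pooling extracts one sample
#' per top-level composite (`n_plots * composites`, 1 composite for flat
#' designs). Soil pooling composites before extraction, so both extractions
#' and PCRs shrink; DNA pooling still extracts every core and only the PCRs
#' shrink. Hours are `extractions / 10 + PCRs / 40`; chemical and library
#' units are per extraction/PCR and per sequenced sample respectively, and
#' the saved percentages are `100 (1 - pooled / unpooled)`.
#'
#' @param design A `design_spec`.
#' @param strategy `"soil_pool"` or `"dna_pool"`.
#' @param n_plots Number of plots processed (default 100).
#' @param model A `cost_model`.
#' @return An object of class `cost_report`: list of scenario, hours and
#'   unit accounting, saved percentages and fold reduction.
#' @examples
#' r <- compute_costs(builtin_designs()[["N9D0-10"]], "soil_pool", 100)
#' round(r$chem_saved_pct, 1) # 88.9
#' @export
compute_costs <- function(design, strategy = c("soil_pool", "dna_pool"),
                          n_plots = 100, model = cost_model()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(design, "design_spec"), n_plots >= 1)
  leaves <- design_leaves(design)
  composites <- design_top_composites(design)

  ext_unpooled <- n_plots * leaves
  ext_pooled <- if (strategy == "soil_pool") n_plots * composites
                else ext_unpooled # DNA pooling still extracts every core
  pcr_unpooled <- ext_unpooled * model$markers
  pcr_pooled <- n_plots * composites * model$markers

  hours <- function(ext, pcr)
    ext / model$extractions_per_hour + pcr / model$pcr_reactions_per_hour
  chem <- function(ext, pcr)
    ext * model$chem_units_per_extraction + pcr * model$chem_units_per_pcr
  hours_unpooled <- hours(ext_unpooled, pcr_unpooled)
  hours_pooled <- hours(ext_pooled, pcr_pooled)
  chem_unpooled <- chem(ext_unpooled, pcr_unpooled)
  chem_pooled <- chem(ext_pooled, pcr_pooled)
  lib_unpooled <- n_plots * leaves * model$markers *
    model$library_cost_per_sample
  lib_pooled <- n_plots * composites * model$markers *
    model$library_cost_per_sample

  pct <- function(unp, poo) 100 * (1 - poo / unp)
  structure(list(
    design = design$name, strategy = strategy, n_plots = n_plots,
    extractions_unpooled = ext_unpooled, extractions_pooled = ext_pooled,
    pcr_unpooled = pcr_unpooled, pcr_pooled = pcr_pooled,
    hours_unpooled = hours_unpooled, hours_pooled = hours_pooled,
    hours_saved = hours_unpooled - hours_pooled,
    hours_saved_pct = pct(hours_unpooled, hours_pooled),
    chem_saved_pct = pct(chem_unpooled, chem_pooled),
    library_saved_pct = pct(lib_unpooled, lib_pooled),
    fold_reduction = chem_unpooled / chem_pooled),
    class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf(
    "%s, %s, %d plots: %.1f h -> %.1f h (%.1f saved, %.1f%%); chemicals %.1f%% saved (%.1fx); libraries %.1f%% saved\n",
    x$design, x$strategy, x$n_plots, x$hours_unpooled, x$hours_pooled,
    x$hours_saved, x$hours_saved_pct, x$chem_saved_pct, x$fold_reduction,
    x$library_saved_pct))
  invisible(x)
}

#' Break-even sequencing-depth fraction for the pooling effect
#'
#' The smallest depth fraction on the evaluated grid at which PE >= 1, plus
#' the linear interpolation of the crossing between adjacent grid points
#' (reported separately; `NA` when PE never reaches 1).
#'
#' @param pe_curve data.frame with `fraction` and `pe` (one site/design/
#'   strategy cell of [pooling_effect()] output).
#' @return List with `grid_fraction` and `interpolated` (either may be NA).
#' @export
break_even_depth <- function(pe_curve) {
  pe_curve <- pe_curve[!is.na(pe_curve$pe), , drop = FALSE]
  if (nrow(pe_curve) < 2) stop("need PE values at >= 2 fractions")
  pe_curve <- pe_curve[order(pe_curve$fraction), ]
  at <- which(pe_curve$pe >= 1)
  grid <- if (length(at)) pe_curve$fraction[at[1]] else NA_real_
  interp <- NA_real_
  if (length(at)) {
    i <- at[1]
    if (i == 1) interp <- pe_curve$fraction[1]
    else {
      f0 <- pe_curve$fraction[i - 1]; f1 <- pe_curve$fraction[i]
      p0 <- pe_curve$pe[i - 1]; p1 <- pe_curve$pe[i]
      interp <- f0 + (1 - p0) / (p1 - p0) * (f1 - f0)
    }
  }
  list(grid_fraction = grid, interpolated = interp)
}
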