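#' Construct a sampling-design specification
#'
#' A design is a number of subsample positions inside a square sampling area
#' (modelled concentric around the plot centre, side = sqrt(area)), one or
#' more depth intervals per position, a core diameter, and optionally a
#' nested compositing tree used by the pooled strategies. `composite_sizes`
#' gives the branching factors from the top level down to the leaves, e.g.
#' `c(3, 5, 5)` means 3 composites of 5 composites of 5 subsamples (75
#' leaves). `NULL` means flat: one composite of all cores.
#'
#' @param name Design code, e.g. `"N40D0-5A"`.
#' @param n_subsamples Number of core positions.
#' @param area Sampled area (m^2).
#' @param depth_intervals List of `c(top, bottom)` depth intervals (cm),
#'   half-open `[top, bottom)`.
#' @param core_diameter Core diameter (cm).
#' @param composite_sizes Integer vector of branching factors, or `NULL`.
#' @param unpooled_n Number of samples under the unpooled strategy (`NA` for
#'   designs used with pooled sampling only).
#' @param source Citation label for the design's origin.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(name, n_subsamples, area, depth_intervals,
                        core_diameter = 5, composite_sizes = NULL,
                        unpooled_n = NA_integer_, source = "") {
  stopifnot(n_subsamples >= 1, area > 0, core_diameter > 0)
  if (!is.list(depth_intervals)) depth_intervals <- list(depth_intervals)
  for (iv in depth_intervals) stopifnot(length(iv) == 2L, iv[1] < iv[2])
  if (length(depth_intervals) > 1L) {
    m <- do.call(rbind, depth_intervals)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2]))
      stop("depth intervals must not overlap")
  }
  n_leaves <- n_subsamples * length(depth_intervals)
  if (!is.null(composite_sizes)) {
    stopifnot(all(composite_sizes >= 1))
    if (prod(composite_sizes) != n_leaves)
      stop("composite tree leaves (", prod(composite_sizes),
           ") must equal n_subsamples x depth intervals (", n_leaves, ")")
  }
  structure(list(name = name, n_subsamples = as.integer(n_subsamples),
                 area = area, depth_intervals = depth_intervals,
                 core_diameter = core_diameter,
                 composite_sizes = composite_sizes,
                 unpooled_n = as.integer(unpooled_n), source = source),
            class = "design_spec")
}

#' Number of physical cores (leaves of the compositing tree) of a design
#' @param design A `design_spec`.
#' @return Integer count.
#' @export
design_leaves <- function(design) {
  design$n_subsamples * length(design$depth_intervals)
}

#' Number of top-level composites (pooled samples per site and strategy)
#' @param design A `design_spec`.
#' @return Integer count (1 for flat designs).
#' @export
design_top_composites <- function(design) {
  if (is.null(design$composite_sizes)) 1L
  else as.integer(design$composite_sizes[1L])
}

#' The twelve published soil sampling designs
#'
#' Returns the designs compared in the study, with their exact subsample
#' numbers, areas, depth ranges, core diameters and compositing trees.
#' Design codes read N<subsamples>D<top-bottom depth, cm>.
#'
#' @return Named list of `design_spec` objects.
#' @examples
#' d <- builtin_designs()
#' design_leaves(d[["N75D0-7.5"]]) # 75
#' @export
builtin_designs <- function() {
  d <- list(
    design_spec("N62D0-5",    62, 2500, c(0, 5),   5, NULL, 62,
                "Tedersoo et al., extended"),
    design_spec("N40D0-5A",   40, 2500, c(0, 5),   5, NULL, 40,
                "Tedersoo et al."),
    design_spec("N40D0-5B",   40, 1400, c(0, 5),   5, NULL, 40,
                "Tedersoo et al., reduced area"),
    design_spec("N9D0-1",      9,  900, c(0, 1),   5, NULL, 9,
                "Davison et al."),
    design_spec("N8D0-10",     8,  100, c(0, 10),  5, NULL, 8,
                "Pärtel et al."),
    design_spec("N5D0-20",     5,   16, c(0, 20),  5, NULL, 5,
                "Orgiazzi et al."),
    design_spec("N9D0-10",     9,  900, c(0, 10),  5, NULL, 9,
                "Guerra et al."),
    design_spec("N9D30-40",    9,  900, c(30, 40), 5, NULL, 9,
                "Guerra et al., subsoil"),
    design_spec("N9D0-40",     9,  900, list(c(0, 10), c(30, 40)), 5, NULL,
                18, "Guerra et al., topsoil + subsoil"),
    design_spec("N25D0-7.5",  25, 2500, c(0, 7.5), 2.5, c(5, 5), NA,
                "Delgado-Baquerizo et al."),
    design_spec("N75D0-7.5",  75, 2500, c(0, 7.5), 2.5, c(3, 5, 5), NA,
                "Delgado-Baquerizo et al., extended"),
    design_spec("N50D0-7.5",  50,  900, c(0, 7.5), 2.5, c(10, 5), NA,
                "Maestre et al."))
  stats::setNames(d, vapply(d, `[[`, character(1), "name"))
}

#' Place core positions for a design inside a site
#'
#' Positions are uniform at random within the design's square area (side
#' sqrt(area)) centred on the plot centre, with a minimum pairwise spacing of
#' `2 * core_diameter` enforced by rejection sampling. Coordinates are in
#' metres with the origin at the plot centre.
#'
#' @param design A `design_spec`.
#' @param site A `virtual_site` (the design's area must fit inside it).
#' @param seed Integer seed; layouts are deterministic given the seed.
#' @param max_tries Rejection budget per point.
#' @return data.frame with columns `position` (1..n_subsamples), `x`, `y`.
#' @export
place_cores <- function(design, site, seed = 1L, max_tries = 10000L) {
  stopifnot(inherits(design, "design_spec"), inherits(site, "virtual_site"))
  side <- sqrt(design$area)
  if (side > site$extent + 1e-9)
    stop("design area (", design$area, " m^2) exceeds site extent")
  min_dist <- 2 * design$core_diameter / 100 # cm -> m
  with_seed(derive_seed(seed, site$site_id, design$name, "place"), {
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(design$n_subsamples)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- stats::runif(1, -side / 2, side / 2)
        y <- stats::runif(1, -side / 2, side / 2)
        if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_dist^2) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place core ", i, " with spacing ", min_dist,
                    " m after ", max_tries, " tries")
      xs <- c(xs, x); ys <- c(ys, y)
    }
    data.frame(position = seq_len(design$n_subsamples), x = xs, y = ys)
  })
}

#' Extract one virtual soil core from a site
#'
#' Counts, per species, the propagule points whose horizontal distance from
#' the core centre is at most `capture_scale * diameter / 200` metres and
#' whose depth lies in the half-open interval `[top, bottom)`. With the
#' default `capture_scale = 1` this is the literal core cylinder. The survey
#' layer uses a larger capture footprint (each simulated propagule stands for
#' a colony whose DNA is recoverable in the core's neighbourhood), which
#' keeps site-level point budgets tractable; see the methods vignette.
#'
#' @param site A `virtual_site`.
#' @param x,y Core-centre coordinates (m, origin at the plot centre).
#' @param depth `c(top, bottom)` interval in cm, half-open.
#' @param diameter Core diameter (cm).
#' @param capture_scale Multiplier on the capture radius (dimensionless).
#' @return An object of class `core_sample`: list with `x`, `y`,
#'   `depth_top`, `depth_bottom`, `diameter`, `templates` (integer vector,
#'   one entry per pool species, named by species_id).
#' @export
take_core <- function(site, x, y, depth, diameter = 5, capture_scale = 1) {
  stopifnot(inherits(site, "virtual_site"))
  if (diameter <= 0) stop("diameter must be > 0")
  if (length(depth) != 2L || depth[1] >= depth[2])
    stop("degenerate depth interval")
  r <- capture_scale * diameter / 200 # cm diameter -> m radius
  p <- site$points
  # centre-origin core coordinates vs corner-origin site coordinates
  cx <- x + site$extent / 2
  cy <- y + site$extent / 2
  sel <- abs(p$x - cx) <= r & abs(p$y - cy) <= r
  if (any(sel)) {
    sel[sel] <- (p$x[sel] - cx)^2 + (p$y[sel] - cy)^2 <= r^2 &
      p$z[sel] >= depth[1] & p$z[sel] < depth[2]
  }
  templates <- tabulate(p$species[sel], nbins = site$pool$richness_total)
  names(templates) <- site$pool$species$species_id
  structure(list(x = x, y = y, depth_top = depth[1], depth_bottom = depth[2],
                 diameter = diameter, templates = templates),
            class = "core_sample")
}

#' Take all physical cores of a design at given positions
#'
#' One `core_sample` per (position, depth interval), ordered position-major
#' (all depth intervals of position 1, then position 2, ...). This ordering
#' defines the leaf order of the compositing tree.
#'
#' @param site A `virtual_site`.
#' @param design A `design_spec`.
#' @param positions data.frame from [place_cores()].
#' @param capture_scale Capture-footprint multiplier passed to [take_core()].
#' @return List of `core_sample` objects of length [design_leaves()].
#' @export
take_design_cores <- function(site, design, positions, capture_scale = 1) {
  cores <- vector("list", design_leaves(design))
  k <- 0L
  for (i in seq_len(nrow(positions))) {
    for (iv in design$depth_intervals) {
      k <- k + 1L
      cores[[k]] <- take_core(site, positions$x[i], positions$y[i], iv,
                              design$core_diameter, capture_scale)
    }
  }
  cores
}
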