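#' Summarise one design at one site on depth-standardised data
#'
#' Per-sample diversity after Monte-Carlo rarefaction to a common depth, and
#' within-site totals from the union of the design's unpooled samples.
#' The default depth policy is the near-minimum read number across the
#' stratum (the smallest per-sample depth at or above `min_reads`); samples
#' below the rarefaction depth are dropped with a warning, mirroring the
#' removal of sparsely sequenced samples.
#'
#' @param table A `read_table`.
#' @param site Site id.
#' @param design Design name.
#' @param strategy Strategy of the rows to summarise (default "unpooled").
#' @param rarefy_to `"near_min"` (default), or a numeric depth.
#' @param min_reads Samples with fewer reads are dropped (default 100).
#' @param iterations Rarefaction iterations (default 1000).
#' @param seed Integer seed.
#' @return List with `site_id`, `design_name`, `n_samples`,
#'   `rarefaction_depth`, `per_sample` (data.frame of rarefied S_obs, H,
#'   hill1, coverage), `mean_richness`, `mean_H`, `site_richness` (union of
#'   full-depth samples), `site_H`, `site_hill1`, `summary_depth` (total
#'   reads over the design's samples).
#' @export
summarise_design <- function(table, site, design, strategy = "unpooled",
                             rarefy_to = "near_min", min_reads = 100,
                             iterations = 1000, seed = NULL) {
  sub <- subset_read_table(table, site = site, design = design,
                           strategy = strategy)
  if (nrow(sub$counts) == 0) stop("design ", design, " absent at site ", site)
  depths <- sub$sample_meta$total_reads
  low <- depths < min_reads
  if (any(low)) {
    warning(sum(low), " sample(s) below ", min_reads,
            " reads dropped from ", design, " at ", site)
    sub$counts <- sub$counts[!low, , drop = FALSE]
    sub$sample_meta <- sub$sample_meta[!low, , drop = FALSE]
    depths <- depths[!low]
  }
  if (!nrow(sub$counts)) stop("no samples left after depth filtering")
  d <- if (identical(rarefy_to, "near_min")) min(depths) else rarefy_to
  per <- lapply(seq_len(nrow(sub$counts)), function(i) {
    r <- rarefy_mc(sub$counts[i, ], min(d, depths[i]), iterations,
                   if (is.null(seed)) NULL else derive_seed(seed, "rr", i))
    data.frame(sample_id = sub$sample_meta$sample_id[i], depth = depths[i],
               S_obs = r$S_obs, H = r$H, hill1 = r$hill1,
               coverage = r$coverage)
  })
  per <- do.call(rbind, per)
  union_counts <- colSums(sub$counts)
  site_div <- diversity_result(union_counts)
  list(site_id = site, design_name = design, strategy = strategy,
       n_samples = nrow(per), rarefaction_depth = d, per_sample = per,
       mean_richness = mean(per$S_obs), mean_H = mean(per$H),
       site_richness = site_div$S_obs, site_H = site_div$H,
       site_hill1 = site_div$hill1, summary_depth = sum(depths))
}

#' Richness and effective-number ratios between designs
#'
#' `ratio(design) = reference site-level value / design site-level value`,
#' per site, for Hill orders 0 (richness) and 1 (effective OTU number).
#' Designs on the exclusion list are dropped; zero denominators are flagged
#' (NA) rather than raised.
#'
#' @param summaries List of [summarise_design()] results.
#' @param reference Reference design name (e.g. the densest design).
#' @param exclusions Design names excluded from ratio calculation (e.g. a
#'   subsoil-only design).
#' @return data.frame with site, design, q0_ratio, q1_ratio.
#' @export
design_ratios <- function(summaries, reference, exclusions = character(0)) {
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(site = s$site_id, design = s$design_name,
               S = s$site_richness, hill1 = s$site_hill1)))
  if (!reference %in% df$design) stop("reference design absent")
  df <- df[!df$design %in% exclusions, , drop = FALSE]
  out <- do.call(rbind, lapply(split(df, df$site), function(d) {
    ref <- d[d$design == reference, ]
    if (!nrow(ref)) return(NULL)
    data.frame(site = d$site, design = d$design,
               q0_ratio = ifelse(d$S > 0, ref$S / d$S, NA_real_),
               q1_ratio = ifelse(d$hill1 > 0, ref$hill1 / d$hill1, NA_real_))
  }))
  rownames(out) <- NULL
  out
}

# Kendall tau-b between two rankings
kendall_tau <- function(a, b) stats::cor(a, b, method = "kendall")

#' Rank sites within each design and measure cross-design concordance
#'
#' Orders sites by site-level richness within each design (ties broken by
#' site identifier, noted in the output) and reports pairwise Kendall-tau
#' concordance of site rankings between designs.
#'
#' @param summaries List of [summarise_design()] results covering >= 2 sites.
#' @return List with `rankings` (data.frame site, design, richness, rank),
#'   `concordance` (designs x designs Kendall tau matrix), `ties` (logical).
#' @export
rank_sites <- function(summaries) {
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(site = s$site_id, design = s$design_name,
               richness = s$site_richness)))
  if (length(unique(df$site)) < 2) stop("need >= 2 sites to rank")
  ties <- FALSE
  rankings <- do.call(rbind, lapply(split(df, df$design), function(d) {
    if (anyDuplicated(d$richness)) ties <<- TRUE
    d <- d[order(-d$richness, d$site), ]
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(rankings) <- NULL
  if (ties) message("ties in site richness broken by site identifier")
  designs <- unique(rankings$design)
  conc <- matrix(NA_real_, length(designs), length(designs),
                 dimnames = list(designs, designs))
  for (i in seq_along(designs)) for (j in seq_along(designs)) {
    a <- rankings[rankings$design == designs[i], ]
    b <- rankings[rankings$design == designs[j], ]
    b <- b[match(a$site, b$site), ]
    conc[i, j] <- kendall_tau(a$rank, b$rank)
  }
  list(rankings = rankings, concordance = conc, ties = ties)
}

#' The pooling effect: pooled / unpooled diversity at matched depth
#'
#' The unpooled reference is the observed site-level value over the design's
#' unpooled samples at their full depth; the pooled value is the Monte-Carlo
#' rarefaction of the pooled sample(s) at `floor(fraction * summary depth)`,
#' where the summary depth is the design's total unpooled reads. PE > 1
#' means pooling gained OTUs, PE < 1 means it lost them. When a design has
#' several pooled samples (hierarchical composites), their counts are summed
#' before rarefaction. Fractions whose target depth exceeds the pooled reads
#' are flagged (`feasible = FALSE`, `pe = NA`) rather than extrapolated.
#'
#' @param table A `read_table`.
#' @param site Site id.
#' @param design Design name.
#' @param strategy `"soil_pool"` or `"dna_pool"`.
#' @param q Hill order, 0 or 1.
#' @param depth_fractions Fractions of the summary depth (default
#'   `c(0.25, 0.5, 0.75, 1)`).
#' @param iterations Rarefaction iterations (default 1000).
#' @param seed Integer seed.
#' @param rarefy_reference Also rarefy the unpooled side to the same
#'   fraction of its summary depth, distributing depth over samples
#'   proportionally (variant, default FALSE).
#' @return data.frame with site, design, strategy, q, fraction, depth,
#'   pooled_value, unpooled_value, pe, feasible.
#' @export
pooling_effect <- function(table, site, design,
                           strategy = c("soil_pool", "dna_pool"), q = 0,
                           depth_fractions = c(0.25, 0.5, 0.75, 1),
                           iterations = 1000, seed = NULL,
                           rarefy_reference = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(q %in% c(0, 1), all(depth_fractions > 0),
            all(depth_fractions <= 1))
  unp <- subset_read_table(table, site = site, design = design,
                           strategy = "unpooled")
  poo <- subset_read_table(table, site = site, design = design,
                           strategy = strategy)
  if (!nrow(unp$counts) || !nrow(poo$counts))
    stop("missing unpooled or ", strategy, " rows for ", design,
         " at ", site)
  summary_depth <- sum(unp$sample_meta$total_reads)
  union_unp <- colSums(unp$counts)
  pooled_counts <- colSums(poo$counts)
  pooled_total <- sum(pooled_counts)

  out <- lapply(depth_fractions, function(f) {
    d <- floor(f * summary_depth)
    feasible <- d <= pooled_total && d >= 1
    pooled_val <- unpooled_val <- NA_real_
    if (feasible) {
      r <- rarefy_mc(pooled_counts, d, iterations,
                     if (is.null(seed)) NULL else derive_seed(seed, "pe", f))
      pooled_val <- if (q == 0) r$S_obs else r$hill1
      if (rarefy_reference) {
        ru <- rarefy_mc(union_unp, d, iterations,
                        if (is.null(seed)) NULL
                        else derive_seed(seed, "peref", f))
        unpooled_val <- if (q == 0) ru$S_obs else ru$hill1
      } else {
        unpooled_val <- if (q == 0) hill_diversity(union_unp, 0)
                        else hill_diversity(union_unp, 1)
      }
    }
    data.frame(site = site, design = design, strategy = strategy, q = q,
               fraction = f, depth = d, pooled_value = pooled_val,
               unpooled_value = unpooled_val,
               pe = pooled_val / unpooled_val, feasible = feasible)
  })
  out <- do.call(rbind, out)
  if (any(!out$feasible))
    warning("pooled reads (", pooled_total, ") below target depth for ",
            "fraction(s) ", paste(out$fraction[!out$feasible],
                                  collapse = ", "), " of ", design,
            " at ", site)
  out
}

#' Rectangular area-subsampling test of the area effect on richness
#'
#' Draws subsets of `k` unpooled samples whose axis-aligned bounding
#' rectangle is near-square (`|width - length| <= aspect_tolerance`) with
#' area inside `[area_min, area_max]`, computes each subset's union OTU
#' richness, and tests the ordinary least-squares slope of richness on area
#' (with a site term when several sites are present) against a permutation
#' null that shuffles sample labels — which community sits at which
#' coordinate, within site — and recomputes every combination's richness.
#' The combinations share samples; preserving that overlap structure under
#' the null keeps the test calibrated.
#'
#' Combination sampling is rejection sampling stratified over equal-width
#' area bins so the area range is covered evenly.
#'
#' @param table A `read_table` restricted (or restrictable) to one design's
#'   unpooled samples with coordinates.
#' @param design Design name (default uses all rows present).
#' @param k Subset size (default 8).
#' @param area_min,area_max Area window in m^2 (defaults 327 and 2000).
#' @param aspect_tolerance Max |width - length| in m (default 5).
#' @param n_combinations Target combinations (default 40).
#' @param n_bins Area strata (default 5).
#' @param n_permutations Permutations for the slope p-value (default 999).
#' @param seed Integer seed.
#' @param max_tries Rejection budget (default 20000).
#' @return List with `combinations` (data.frame combination_id, site, area,
#'   width, length, richness), `slope`, `p`, `n`.
#' @export
area_subsampling_test <- function(table, design = NULL, k = 8,
                                  area_min = 327, area_max = 2000,
                                  aspect_tolerance = 5, n_combinations = 40,
                                  n_bins = 5, n_permutations = 999,
                                  seed = NULL, max_tries = 20000) {
  sub <- if (is.null(design)) subset_read_table(table, strategy = "unpooled")
         else subset_read_table(table, design = design,
                                strategy = "unpooled")
  m <- sub$sample_meta
  if (anyNA(m$x) || anyNA(m$y)) stop("samples must carry coordinates")
  combos <- list()
  with_seed(seed, {
    per_site <- split(seq_len(nrow(m)), m$site)
    bins <- seq(area_min, area_max, length.out = n_bins + 1)
    bin_count <- matrix(0L, length(per_site), n_bins,
                        dimnames = list(names(per_site), NULL))
    target <- ceiling(n_combinations / n_bins)
    tries <- 0L
    while (tries < max_tries &&
           any(bin_count < target)) {
      tries <- tries + 1L
      s <- sample(names(per_site), 1)
      idx <- per_site[[s]]
      if (length(idx) < k) next
      pick <- sample(idx, k)
      w <- diff(range(m$x[pick])); l <- diff(range(m$y[pick]))
      area <- w * l
      if (abs(w - l) > aspect_tolerance) next
      if (area < area_min || area > area_max) next
      b <- findInterval(area, bins, rightmost.closed = TRUE)
      if (bin_count[s, b] >= target) next
      bin_count[s, b] <- bin_count[s, b] + 1L
      combos[[length(combos) + 1L]] <- list(
        site = s, area = area, width = w, length = l, members = pick)
    }
  })
  if (!length(combos))
    stop("no feasible ", k, "-sample combination in the area window after ",
         max_tries, " tries (degenerate geometry?)")

  # union richness per combination via an indicator matrix product:
  # (combos x samples) %*% (samples x OTUs) counts member presences, and a
  # permutation of sample labels is a column permutation of the indicator
  pres <- (sub$counts > 0) * 1
  A <- matrix(0, length(combos), nrow(pres))
  for (ci in seq_along(combos)) A[ci, combos[[ci]]$members] <- 1
  rich_of <- function(map) rowSums(A[, order(map), drop = FALSE] %*% pres > 0)
  id_map <- seq_len(nrow(pres))
  df <- data.frame(
    combination_id = seq_along(combos),
    site = vapply(combos, `[[`, character(1), "site"),
    area = vapply(combos, `[[`, numeric(1), "area"),
    width = vapply(combos, `[[`, numeric(1), "width"),
    length = vapply(combos, `[[`, numeric(1), "length"),
    richness = rich_of(id_map))
  multi_site <- length(unique(df$site)) > 1
  slope_of <- function(rich) {
    d2 <- df; d2$richness <- rich
    f <- if (multi_site) stats::lm(richness ~ area + factor(site),
                                   data = d2)
         else stats::lm(richness ~ area, data = d2)
    stats::coef(f)[["area"]]
  }
  slope <- slope_of(df$richness)
  # null: shuffle which community sits at which coordinate (within site)
  # and recompute every combination, preserving the overlap structure
  per_site_rows <- split(seq_len(nrow(m)), m$site)
  perm <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "perm"), {
    vapply(seq_len(n_permutations), function(b) {
      map <- id_map
      for (rows in per_site_rows) map[rows] <- rows[sample.int(length(rows))]
      slope_of(rich_of(map))
    }, numeric(1))
  })
  p <- (sum(abs(perm) >= abs(slope) - 1e-12) + 1) / (n_permutations + 1)
  list(combinations = df, slope = slope, p = p, n = nrow(df))
}
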