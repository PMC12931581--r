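#!/usr/bin/env Rscript
# Stage 5 — spatial and compositional analyses of the unpooled samples.
#
# (a) Rectangular area-subsampling test within the densest design: does
#     sampling area (327-2000 m^2, near-square rectangles of 8 samples)
#     affect recovered richness? Expected: no, on these (statistically
#     homogeneous within-plot) communities.
# (b) Mantel correlogram of community distance against core distance:
#     patchy communities show positive autocorrelation at short range.
# (c) PERMANOVA of community composition across sampling designs and the
#     homogeneity of multivariate dispersion within each site.

suppressPackageStartupMessages(library(pooldesign))

seed <- 20240901L
srv <- "results/survey"
out <- "results/composition"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (g in c("animal_like", "fungus_like", "bacteria_like")) {
  tab <- read_otu_table(file.path(srv, g))

  area <- area_subsampling_test(tab, design = "N62D0-5", k = 8,
                                n_combinations = 40, n_permutations = 999,
                                seed = derive_seed(seed, "area", g))
  write.table(area$combinations,
              file.path(out, paste0(g, "_area_combinations.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: area effect on richness over %d combinations: slope %.3g, p = %.3f",
    g, area$n, area$slope, area$p))

  # distance decay among N62 topsoil cores of the median site
  sub <- subset_read_table(tab, site = "site2", design = "N62D0-5",
                           strategy = "unpooled")
  keep <- sub$sample_meta$total_reads >= 100
  D <- bray_curtis(sub$counts[keep, ])
  xy <- cbind(sub$sample_meta$x, sub$sample_meta$y)[keep, ]
  mc <- mantel_correlogram(D, xy, c(0, 5, 10, 20, 40, 80),
                           n_permutations = 199,
                           seed = derive_seed(seed, "mantel", g))
  write.table(mc, file.path(out, paste0(g, "_correlogram.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: first-class Mantel r = %.3f (adj. p = %.3f)",
    g, mc$r[1], mc$p_adj[1]))

  # composition across designs (all sites; permutations within site)
  unp <- subset_read_table(tab, strategy = "unpooled")
  keep2 <- unp$sample_meta$total_reads >= 100
  Dall <- bray_curtis(unp$counts[keep2, ])
  pm <- permanova(Dall, factor(unp$sample_meta$design[keep2]),
                  strata = factor(unp$sample_meta$site[keep2]),
                  n_permutations = 499,
                  seed = derive_seed(seed, "permanova", g))
  message(sprintf(
    "%s: PERMANOVA design effect F(%d,%d) = %.2f, R2 = %.3f, p = %.3f",
    g, pm$df[1], pm$df[2], pm$pseudo_F, pm$R2, pm$p))

  # beta-diversity comparability of two designs at one site: do the dense
  # and the small topsoil design spread samples equally in community space?
  two <- subset_read_table(tab, site = "site2",
                           design = c("N62D0-5", "N9D0-10"),
                           strategy = "unpooled")
  keep3 <- two$sample_meta$total_reads >= 100
  disp <- dispersion_homogeneity(bray_curtis(two$counts[keep3, ]),
                                 factor(two$sample_meta$design[keep3]),
                                 n_permutations = 199,
                                 seed = derive_seed(seed, "disp", g))
  message(sprintf(
    "%s: dispersion N62D0-5 %.3f vs N9D0-10 %.3f (homogeneity p = %.2f)",
    g, disp$group_dispersion[["N62D0-5"]],
    disp$group_dispersion[["N9D0-10"]], disp$p))
}
message("wrote ", out)
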