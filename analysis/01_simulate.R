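#!/usr/bin/env Rscript
# Stage 1 — build the virtual study system.
#
# Three 2500 m^2 forest-soil plots with a true richness gradient, three
# organism groups (animal-, fungus-, bacteria-like) with group-typical
# richness, patchiness and vertical stratification. Writes the species
# pools and propagule point patterns so later stages (and readers) can
# inspect exactly what "truth" the surveys sample from.

suppressPackageStartupMessages(library(pooldesign))

seed <- 20240901L
out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

groups <- c("animal_like", "fungus_like", "bacteria_like")
site_intensity <- c(0.7, 1, 1.3)

for (g in groups) {
  pool <- make_species_pool(g, seed = derive_seed(seed, "pool", g))
  write_species_pool(pool, file.path(out, paste0(g, "_pool.tsv")))
  message(g, ": ", pool$richness_total, " species, ",
          round(100 * pool$subsoil_unique_fraction, 1),
          "% subsoil specialists")
  for (i in 1:3) {
    site <- realise_site(pool, 50, seed = derive_seed(seed, "site", i),
                         site_id = paste0("site", i),
                         intensity_scale = site_intensity[i])
    message("  site", i, " (intensity ", site_intensity[i], "): ",
            nrow(site$points), " propagules, ",
            length(unique(site$points$species)), " species present")
    # point patterns are large; keep only the species-poor group on disk
    if (g == "animal_like")
      write_site_points(site, file.path(out, paste0(g, "_site", i,
                                                    "_points.tsv")))
  }
}
message("wrote ", out)
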