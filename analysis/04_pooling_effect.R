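#!/usr/bin/env Rscript
# Stage 4 — the pooling effect across designs, strategies and depths.
#
# PE = pooled / unpooled diversity with the pooled sample rarefied at a
# fraction of the design's summary sequencing depth (total unpooled
# reads). PE > 1 means pooling gained OTUs. Also reports the break-even
# sequencing-depth fraction per design and strategy.

suppressPackageStartupMessages(library(pooldesign))

seed <- 20240901L
srv <- "results/survey"
out <- "results/pooling"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

groups <- c("animal_like", "fungus_like", "bacteria_like")
unpooled_designs <- names(Filter(function(d) !is.na(d$unpooled_n),
                                 builtin_designs()))
fractions <- c(0.25, 0.5, 0.75, 1)

all_pe <- list()
for (g in groups) {
  tab <- read_otu_table(file.path(srv, g))
  for (s in paste0("site", 1:3)) for (dn in unpooled_designs)
    for (strat in c("soil_pool", "dna_pool")) for (q in c(0, 1)) {
      pe <- tryCatch(suppressWarnings(pooling_effect(
        tab, s, dn, strat, q, fractions, iterations = 1000,
        seed = derive_seed(seed, "pe", g, s, dn, strat, q))),
        error = function(e) NULL)
      if (!is.null(pe)) { pe$group <- g; all_pe[[length(all_pe) + 1]] <- pe }
    }
}
pe <- do.call(rbind, all_pe)
write.table(pe, file.path(out, "pooling_effect.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

full <- pe[pe$fraction == 1 & pe$q == 0 & pe$feasible, ]
agg <- aggregate(pe ~ group + design, full, stats::median)
for (g in groups) {
  a <- agg[agg$group == g, ]
  dense <- a$pe[a$design %in% c("N62D0-5", "N40D0-5A", "N40D0-5B")]
  small <- a$pe[a$design %in% c("N9D0-10", "N9D0-1", "N5D0-20")]
  message(sprintf(
    "%s: median PE(100%%, q=0) dense designs %.2f | small designs %.2f",
    g, stats::median(dense), stats::median(small)))
}

be <- list()
for (g in groups) for (dn in unique(pe$design))
  for (strat in c("soil_pool", "dna_pool")) {
    curve <- pe[pe$group == g & pe$design == dn & pe$strategy == strat &
                  pe$q == 0 & pe$site == "site2", ]
    if (sum(!is.na(curve$pe)) >= 2) {
      b <- break_even_depth(curve)
      be[[length(be) + 1]] <- data.frame(
        group = g, design = dn, strategy = strat,
        grid_fraction = b$grid_fraction, interpolated = b$interpolated)
    }
  }
be <- do.call(rbind, be)
write.table(be, file.path(out, "break_even.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", out)
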