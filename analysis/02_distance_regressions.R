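#!/usr/bin/env Rscript

# Stage 2: drift signal along the migration path.
#
# Regresses genome-wide and per-panel average heterozygosity and average
# risk-allele frequency on distance from the origin, over all populations
# and over two subsets (origin-proximal third excluded / only), mirroring
# the out-of-Africa analysis where African populations are excluded or
# isolated. Reports how panel slopes compare with the genome-wide drift
# baseline.
#
# Reads scratch/synthetic/, writes results/tables/distance_regressions.tsv.

suppressMessages(library(alleleclim))

inp <- "scratch/synthetic"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mat <- read_frequency_matrix(file.path(inp, "frequency_matrix.tsv"))
panel <- utils::read.delim(file.path(inp, "populations.tsv"))
climate <- read_climate(file.path(inp, "climate.tsv"))
sets <- read_risk_sets(file.path(inp, "risk_sets.tsv"), matrix = mat)

predictors <- predictor_table(panel, climate)
baseline <- genomewide_baseline(mat)
dist_only <- predictors[, c("population", "distance_km")]

base_fit <- ols(baseline$avg_het_all, predictors$distance_km,
                "baseline_het", "distance_km")
cat(sprintf("genome-wide heterozygosity on distance: slope %.3e per km, R^2 %.3f\n",
            base_fit$slope, base_fit$r_squared))

proximal <- panel$population[seq_len(20)]        # first third of the chain
subsets <- list(excl_proximal = setdiff(panel$population, proximal),
                only_proximal = proximal)

rows <- list(cbind(disease = "genome_wide", subset = "all", base_fit))
for (s in sets) {
  prof <- allelic_profile(mat, s, baseline = baseline)
  for (stat in c("heterozygosity", "risk_freq")) {
    rows[[length(rows) + 1L]] <-
      cbind(disease = s$disease, subset = "all",
            regress_panel(prof, dist_only, stat, adjusted = FALSE))
    for (nm in names(subsets)) {
      rows[[length(rows) + 1L]] <-
        cbind(disease = s$disease, subset = nm,
              regress_panel(prof, dist_only, stat, adjusted = FALSE,
                            subset = subsets[[nm]]))
    }
  }
}
tab <- do.call(rbind, rows)
write_tsv(tab, file.path(out, "distance_regressions.tsv"))

het_all <- tab[tab$response == "heterozygosity" & tab$subset == "all", ]
steepest <- het_all[which.min(het_all$slope), ]
cat(sprintf("steepest panel heterozygosity decline: %s (slope %.3e, r %.2f)\n",
            steepest$disease, steepest$slope, steepest$r))
cat(sprintf("%d regressions written to %s\n", nrow(tab),
            file.path(out, "distance_regressions.tsv")))
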