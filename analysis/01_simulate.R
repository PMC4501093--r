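#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study world.
#
# Simulates a 60-population serial-founder chain (20,000 SNPs, diploid
# effective size 500, one founding event per step, 400 km between
# neighbouring populations), a nine-variable climate table partially
# correlated with migration distance, and 21 disease risk-SNP panels with
# the standard panel sizes (7-41 SNPs). One panel ("type_2_diabetes", 15
# SNPs) is left neutral on purpose; a 22nd panel ("cline_disease", 15
# SNPs) carries an injected frequency cline on winter humidity
# (beta = 0.1 per SD) so later stages have a known positive control.
#
# Writes TSVs under scratch/synthetic/ (bulky, regenerable inputs).

suppressMessages(library(alleleclim))

seed <- 20240101L
out <- "scratch/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- founder_config(n_populations = 60L, n_snps = 20000L,
                      effective_size = 500L, seed = seed)
sim <- simulate_serial_founder(cfg)
climate <- generate_climate(sim$panel, seed = seed)

set.seed(seed)
cline_ids <- sample(rownames(sim$matrix), 15)
matrix_final <- inject_cline(sim$matrix, climate,
                             cline_spec(cline_ids, "winter_humidity",
                                        beta = 0.1),
                             seed = seed)

sizes <- disease_panel_sizes()
sets <- make_risk_sets(matrix_final, c(unname(sizes), 15L),
                       labels = c(names(sizes), "cline_disease"),
                       cline_assignments = list(cline_disease = cline_ids),
                       seed = seed)

write_frequency_matrix(matrix_final, file.path(out, "frequency_matrix.tsv"))
write_tsv(sim$panel, file.path(out, "populations.tsv"))
write_tsv(climate, file.path(out, "climate.tsv"))
write_risk_sets(sets, file.path(out, "risk_sets.tsv"))

het <- colMeans(2 * unclass(matrix_final) * (1 - unclass(matrix_final)))
cat(sprintf("simulated %d SNPs x %d populations\n", nrow(matrix_final),
            ncol(matrix_final)))
cat(sprintf("mean heterozygosity: %.4f (origin) -> %.4f (chain end)\n",
            het[1], het[length(het)]))
cat(sprintf("%d risk panels written (sizes %d-%d), cline panel on winter_humidity\n",
            length(sets), min(sizes), max(sizes)))
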