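#!/usr/bin/env Rscript
# Stage 1: generate the synthetic hindgut study.
#
# Emulates the downstream inputs of a donkey hindgut MAG survey: 9 genome
# bins in 3 planted species clusters (within-cluster ANI ~99.5%, between
# ~81%), a 20,000-row best-hit table in which only ~0.3% of proteins match
# the database above 95% identity, and relative abundances for 26 donkeys x
# 3 hindgut segments (cecum C, ventral colon VC, dorsal colon DC) carrying
# two planted co-occurrence blocks and 10 MAGs shifted up in the cecum.

suppressPackageStartupMessages(library(hindgutMAG))

seed <- 11L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(
  seed = seed, n_clusters = 3, genomes_per_cluster = 3,
  genome_length = 30000, within_divergence = 0.0025,
  between_divergence = 0.10, n_samples = 26, n_mags = 60, noise_sd = 0.3,
  block_spec = list(list(members = sprintf("MAG%04d", 1:5), strength = 1.0),
                    list(members = sprintf("MAG%04d", 11:14), strength = 0.95)),
  group_effects = lapply(sprintf("MAG%04d", 21:30), function(m)
    list(mag = m, group = "C", lfc = 1.5)))

gs <- generate_genome_set(cfg)
write_genome_set(gs$genomes, file.path(out, "genomes"))
cat(sprintf("generated %d genomes in %d planted clusters\n",
            length(gs$genomes), length(unique(gs$clusters))))

hits <- generate_hit_table(20000, frac_known = 0.003, seed = seed,
                           n_mags = 60)
write_hit_table(hits, file.path(out, "hits.tsv"))
cat(sprintf("hit table: %d records, %d planted in the known stratum\n",
            nrow(hits), sum(hits$planted_known)))

am <- generate_abundance_matrix(cfg)
write_abundance(am$abundance, file.path(out, "abundance.tsv"))
write_groups(am$groups, file.path(out, "groups.tsv"))
jsonlite::write_json(c(list(clusters = as.list(gs$clusters)), am$truth),
                     file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("abundance matrix: %d samples x %d MAGs; %d planted blocks, %d shifted MAGs\n",
            nrow(am$abundance), ncol(am$abundance),
            length(am$truth$blocks), length(am$truth$shifted)))
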