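#!/usr/bin/env Rscript
# Simulate the family-based breeding program (desk scale), write its tables,
# and run the genotype-processing front end: assay observation, two-level QC
# and genotype-based parentage assignment for the newest year class.
#
# Usage: Rscript analysis/01_simulate_program.R [seed]

library(salmogs)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

# Desk-scale rendition of the program: 2 chromosomes stand in for the genome,
# 5000 markers for the ~45K standard set, 40 families/400 sampled presmolt per
# year class for the 200/8000 of the full program. Structure (partial
# factorial mating, 15% repeat spawners, 3/8 freshwater candidate split,
# male/female spawning ages) follows the program description.
cfg <- sim_config(
  n_chromosomes = 2, chrom_length_bp = 5e7, n_markers = 5000, n_qtl = 300,
  n_founders = 120, families_per_year = 40, pool_per_family = 30,
  progeny_genotyped_per_year = 400, n_year_classes = 3, seed = seed
)
tm <- saltas_trait_model()

message("Simulating a ", cfg$n_year_classes, "-year-class genomic program ...")
sim <- simulate_breeding_cycle(cfg, tm, scheme = "genomic", evaluate_both = TRUE)

write_pedigree(sim$pedigree, "results/pedigree.csv")
write_phenotypes(sim$phenotypes, "results/phenotypes.csv")
write_marker_map(sim$map, "results/marker_map.tsv")
utils::write.csv(sim$genetic_trend, "results/genetic_trend.csv", row.names = FALSE)
bv <- do.call(rbind, sim$bv_history)
utils::write.csv(bv, "results/breeding_values.csv", row.names = FALSE)

## Genotype-processing front end for the newest year class (two-tier scheme):
## candidates observed on a sparse assay with GBS-like dropout, parents at
## full density.
yc <- cfg$n_year_classes
new_ids <- sim$pedigree$id[sim$pedigree$birth_year == yc]
parents <- unique(c(sim$selections[[yc]]$sires, sim$selections[[yc]]$dams))
ld_markers <- sim$map$marker_id[seq(1, nrow(sim$map), length.out = 300)]
assay <- simulate_assay(sim$genotypes[new_ids, ], ld_markers,
                        missing_rate = 0.05, error_rate = 0.002,
                        seed = seed + 1L)

# basic QC (markers only) ahead of parentage, as in the production workflow
basic <- qc_filter(assay[, ld_markers], mode = "basic")
message("Basic QC removed ", nrow(basic$report$markers_removed), " of ",
        length(ld_markers), " assay markers; no individuals removed.")

meta <- data.frame(id = parents,
                   sex = sim$pedigree$sex[match(parents, sim$pedigree$id)])
pa <- assign_parentage(basic$genotypes,
                       sim$genotypes[parents, colnames(basic$genotypes)],
                       meta, max_mismatch_rate = 0.05)
truth <- sim$pedigree[match(rownames(basic$genotypes), sim$pedigree$id), ]
correct <- mean(pa$sire == truth$sire & pa$dam == truth$dam, na.rm = TRUE)
message(sprintf("Parentage: %d/%d assigned, %.1f%% of assignments correct.",
                sum(pa$assigned), nrow(pa), 100 * correct))
utils::write.csv(pa, "results/parentage.csv", row.names = FALSE)

# full QC for the evaluation path
full <- qc_filter(sim$genotypes, mode = "full")
message("Full QC on the standard set removed ",
        nrow(full$report$markers_removed), " markers and ",
        nrow(full$report$individuals_removed), " individuals.")

trend <- genetic_gain(
  data.frame(year_class = rep(sim$genetic_trend$year_class, 1),
             trait = sim$genetic_trend$trait, value = sim$genetic_trend$mean_tbv),
  genetic_sds = sim$genetic_sds
)
message("True index-trait gains (genetic SD / year):")
print(trend$gains)
utils::write.csv(trend$gains, "results/true_gain_rates.csv", row.names = FALSE)
message("Wrote results/pedigree.csv, phenotypes.csv, marker_map.tsv, ",
        "breeding_values.csv, parentage.csv, genetic_trend.csv, true_gain_rates.csv")
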