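#!/usr/bin/env Rscript

# Step 1 -- generate the synthetic study dataset.
#
# Emulates the study design: 14 taxa on a 5-Myr ultrametric tree, five
# organs x two sexes x three replicates of negative-binomial RNA-seq
# counts whose log2 means drift along the tree, planted sex-biased genes
# (30% of genes in gonads, 1% in somatic organs), per-species genotypes
# with fixed X/Y-divergent sites on each species' sex-chromosome linkage
# groups, coding-sequence pairs with log-normal target dN/dS, and
# Brownian traits. Everything is written under results/data/ together
# with the truth tables used by later steps.

suppressMessages(library(sbgevol))

seed <- 42L
cfg <- sim_config(n_genes = 800, seed = seed)
dir.create("results", showWarnings = FALSE)

message("simulating dataset (", cfg$n_species, " species, ",
        cfg$n_genes, " genes, seed ", seed, ") ...")
ds <- simulate_dataset(cfg)
write_dataset(ds, "results/data")

n_sbg <- nrow(ds$truth)
message("planted sex-bias entries (gene x species x organ): ", n_sbg)
message("species with sex chromosomes: ",
        sum(lengths(ds$sex_chromosomes) > 0), " of ", cfg$n_species)
message("wrote results/data/ (counts, metadata, GFF3, VCFs, tree, traits, truth)")
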