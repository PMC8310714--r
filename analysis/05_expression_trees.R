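#!/usr/bin/env Rscript

# Step 5 -- expression phylogenies and rates of expression evolution.
#
# Builds neighbour-joining trees from 1 - Spearman rho distances between
# species' mean expression profiles, separately for FBG / MBG / unbiased
# gene classes per organ (FBGs profiled in females, MBGs in males), adds
# gene bootstraps for the gonad trees, and compares: root-to-tip
# divergence across classes (Kruskal-Wallis), RF distance to the species
# tree, the decay of expression correlation with divergence time, and
# per-linkage-group correlation distributions.

suppressMessages(library(sbgevol))

counts <- filter_low_count_genes(read_counts("results/data/counts.tsv"))
meta <- read_metadata("results/data/metadata.tsv", counts)
tree <- read_species_tree("results/data/tree.nwk",
                          species = sort(unique(meta$species)))
ann <- read_annotation("results/data/annotation.gff3")
bias <- read.delim("results/sex_bias.tsv", comment.char = "#")
norm <- tmm_normalize(counts)$normalized
outgroup <- tree$tip.label[1]

rtt_rows <- list(); rf_rows <- list(); trees <- list()
for (org in sort(unique(meta$organ))) {
  for (cls in c("FBG", "MBG", "unbiased")) {
    genes <- unique(bias$gene_id[bias$organ == org & bias$direction == cls])
    if (length(genes) < 5) next
    sx <- switch(cls, FBG = "F", MBG = "M", "both")
    prof <- mean_expression_profiles(norm, meta, org, sx, genes = genes)
    tr <- nj_tree(spearman_distance_matrix(prof))
    trees[[paste(org, cls, sep = "_")]] <- tr
    rooted <- root_expression_tree(tr, outgroup)
    rtt <- root_to_tip_lengths(rooted)
    rtt_rows[[length(rtt_rows) + 1L]] <-
      data.frame(organ = org, class = cls, species = names(rtt),
                 root_to_tip = unname(rtt))
    rf_rows[[length(rf_rows) + 1L]] <-
      data.frame(organ = org, class = cls,
                 rf = rf_distance(tr, tree)$rf,
                 rf_normalized = rf_distance(tr, tree)$normalized)
  }
}
rtt <- do.call(rbind, rtt_rows)
write.table(rtt, "results/root_to_tip.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(do.call(rbind, rf_rows), "results/rf_to_species_tree.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
ape::write.tree(do.call(c, trees), "results/expression_trees.nwk",
                tree.names = TRUE)

g_rtt <- rtt[rtt$organ == "gonad", ]
kw <- kruskal_wallis(g_rtt$root_to_tip, g_rtt$class)
message(sprintf(
  "gonad root-to-tip by class: medians FBG %.3f / MBG %.3f / unbiased %.3f (KW p = %.3g)",
  median(g_rtt$root_to_tip[g_rtt$class == "FBG"]),
  median(g_rtt$root_to_tip[g_rtt$class == "MBG"]),
  median(g_rtt$root_to_tip[g_rtt$class == "unbiased"]), kw$p))

# bootstrap support for the gonad unbiased tree (the largest gene set)
genes_ub <- unique(bias$gene_id[bias$organ == "gonad" &
                                  bias$direction == "unbiased"])
prof_ub <- mean_expression_profiles(norm, meta, "gonad", "both",
                                    genes = genes_ub)
bs <- bootstrap_supports(prof_ub, n_boot = 200, seed = 7)
message(sprintf("gonad unbiased tree: mean internal bootstrap support %.2f",
                mean(bs$support[-1])))

# expression similarity vs divergence time, per class, in the gonad
for (cls in c("FBG", "MBG", "unbiased")) {
  genes <- unique(bias$gene_id[bias$organ == "gonad" &
                                 bias$direction == cls])
  if (length(genes) < 5) next
  sx <- switch(cls, FBG = "F", MBG = "M", "both")
  prof <- mean_expression_profiles(norm, meta, "gonad", sx, genes = genes)
  reg <- divergence_regression(log2(prof + 1), tree)
  rate <- expression_rate(reg$pairs$rho, reg$pairs$t)
  message(sprintf(
    "gonad %-8s: slope(rho~t) = %.4f (cor p = %.3g), median rate (1-rho)/t = %.4f / Myr",
    cls, reg$slope, reg$p, median(rate)))
}

# per-LG correlation distributions across taxa (male + female profiles)
prof_all <- mean_expression_profiles(norm, meta, "gonad", "both")
lg <- ann$lg[match(rownames(prof_all), ann$gene_id)]
pl <- per_lg_correlation(prof_all, lg)
write.table(pl$per_lg, "results/per_lg_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("across-LG Kruskal-Wallis on pairwise rho: p = %.3g",
                pl$kruskal$p.value))
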