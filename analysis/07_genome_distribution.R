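#!/usr/bin/env Rscript

# Step 7 -- genomic distribution of sex bias and sequence statistics.
#
# Per species: a one-sided Fisher screen for feminized / masculinized
# linkage groups in the gonad (tested in the direction of the observed
# MBG - FBG difference), and Mann-Whitney comparisons of intersex Fst,
# pi and Tajima's D between each species' sex-chromosome LGs and all
# autosomes pooled, per gene class.

suppressMessages(library(sbgevol))

ann <- read_annotation("results/data/annotation.gff3")
meta <- read_metadata("results/data/metadata.tsv")
bias <- read.delim("results/sex_bias.tsv", comment.char = "#")
popgen <- read.delim("results/popgen_gene_stats.tsv", comment.char = "#")
gene_lg <- setNames(ann$lg, ann$gene_id)
species <- sort(unique(meta$species))
sexchr <- default_sex_chromosomes(species)

enr <- list()
for (sp in species) {
  bt <- bias[bias$species == sp & bias$organ == "gonad", ]
  if (nrow(bt) == 0) next
  e <- lg_enrichment(bt, gene_lg)
  e$species <- sp
  enr[[sp]] <- e
}
enr <- do.call(rbind, c(enr, make.row.names = FALSE))
write.table(enr, "results/lg_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- enr[enr$padj < 0.05, ]
message("LG enrichment screen: ", nrow(sig), " significant LG x species (",
        sum(sig$direction == "feminized"), " feminized, ",
        sum(sig$direction == "masculinized"), " masculinized)")

cmp <- list()
for (sp in species) {
  sl <- sexchr[[sp]]
  if (length(sl) == 0) next
  bt <- bias[bias$species == sp & bias$organ == "gonad", ]
  gs <- popgen[popgen$species == sp, ]
  for (statc in c("fst", "pi", "tajimas_d")) {
    r <- sexchr_vs_autosome_compare(gs, bt, sl, statc)
    if (nrow(r) == 0) next
    r$species <- sp
    r$statistic <- statc
    cmp[[length(cmp) + 1L]] <- r
  }
}
cmp <- do.call(rbind, c(cmp, make.row.names = FALSE))
write.table(cmp, "results/sexchr_vs_autosomes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fst <- cmp[cmp$statistic == "fst", ]
message(sprintf(
  "intersex Fst, sex chromosomes vs autosomes: median elevation %.3f; %d of %d class comparisons p < 0.01",
  median(fst$median_sex - fst$median_auto), sum(fst$p < 0.01), nrow(fst)))
pi_c <- cmp[cmp$statistic == "pi", ]
message(sprintf("pi comparisons significant at 0.05: %d of %d",
                sum(pi_c$p < 0.05), nrow(pi_c)))
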