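#!/usr/bin/env Rscript

# Step 3 -- intersex population-genetic statistics per gene and species.
#
# Reads each species' VCF, applies the site filters (>= 3 covered
# individuals, total depth >= 3; additionally >= 2 covered individuals
# per sex for Fst), and computes per-gene intersex Hudson Fst as the
# ratio of sums of the alpha / alpha+beta components, coverage-corrected
# nucleotide diversity, segregating sites and Tajima's D.

suppressMessages(library(sbgevol))

ann <- read_annotation("results/data/annotation.gff3")
meta <- read_metadata("results/data/metadata.tsv")
vcfs <- list.files("results/data", pattern = "^genotypes_.*\\.vcf$",
                   full.names = TRUE)

res <- list()
for (path in vcfs) {
  sp <- sub("genotypes_(.*)\\.vcf", "\\1", basename(path))
  v <- read_vcf_genotypes(path)
  sex <- substr(sub(paste0(sp, "_"), "", v$samples), 1, 1)
  st <- popgen_gene_stats(v$gt, v$depth, sex, v$site_pos, ann)
  st$species <- sp
  res[[sp]] <- st
}
stats <- do.call(rbind, c(res, make.row.names = FALSE))
write.table(stats, "results/popgen_gene_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("per-gene stats for ", length(res), " species, ",
        nrow(stats), " rows")
sexchr <- default_sex_chromosomes(sort(unique(meta$species)))
onxy <- mapply(function(lg, sp) lg %in% sexchr[[sp]], stats$lg,
               stats$species)
message(sprintf("median intersex Fst: sex-linked LGs %.3f vs autosomes %.3f",
                median(stats$fst[onxy], na.rm = TRUE),
                median(stats$fst[!onxy], na.rm = TRUE)))
message(sprintf("mean Tajima's D (all genes): %.3f",
                mean(stats$tajimas_d, na.rm = TRUE)))
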