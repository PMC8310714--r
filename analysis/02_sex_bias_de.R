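#!/usr/bin/env Rscript

# Step 2 -- call sex-biased genes per species and organ.
#
# Reads the files written by step 1 back through the package's readers,
# filters no-count genes, runs QC flagging, then the negative-binomial
# Wald test per species x organ with BH adjustment; assigns bias
# directions (|LFC| > 2, padj < 0.05) and categories (low/mid/high/
# extreme), summarizes cross-species sharing, and scores the calls
# against the planted truth.

suppressMessages(library(sbgevol))

counts <- read_counts("results/data/counts.tsv")
meta <- read_metadata("results/data/metadata.tsv", counts)
counts <- filter_low_count_genes(counts)
message("genes after count filter: ", nrow(counts))

qc <- qc_flag_samples(counts, meta)
message("QC flags: ", nrow(qc))
write.table(qc, "results/qc_flags.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

de <- call_sex_bias_all(counts, meta)
bias <- de$table
write.table(bias, "results/sex_bias.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tab <- table(bias$organ[bias$direction != "unbiased"],
             bias$direction[bias$direction != "unbiased"])
message("sex-biased calls by organ:")
print(tab)

truth <- read.delim("results/data/truth_sbg.tsv", comment.char = "#")
key <- function(d) paste(d$gene_id, d$species, d$organ)
called <- bias[bias$direction != "unbiased", ]
sens <- mean(key(truth) %in% key(called))
fdr <- if (nrow(called)) mean(!key(called) %in% key(truth)) else 0
message(sprintf("recovery vs planted truth: sensitivity %.3f, FDR %.3f",
                sens, fdr))

sharing <- shared_sbg_sets(bias)
write.table(sharing, "results/sbg_sharing.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("fraction of SBGs shared across >= 2 species, by organ/direction:")
print(sharing)
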