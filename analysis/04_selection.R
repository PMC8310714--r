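#!/usr/bin/env Rscript

# Step 4 -- selection on sequence (NG86 dN/dS) and expression (delta-x).
#
# dN/dS per gene from the reference/derived CDS pairs; delta-x per gene
# and species in the gonad against the most basal species as ancestral
# proxy, on log2(TPM + 1) with the pooled replicate SD as denominator;
# candidates under putative positive selection at both levels are their
# intersection (|delta-x| > 1 and dN/dS > 1).

suppressMessages(library(sbgevol))

ann <- read_annotation("results/data/annotation.gff3")
counts <- filter_low_count_genes(read_counts("results/data/counts.tsv"))
meta <- read_metadata("results/data/metadata.tsv", NULL)
tree <- read_species_tree("results/data/tree.nwk")

ref <- seqinr::read.fasta("results/data/cds_ref.fasta", as.string = TRUE,
                          forceDNAtolower = FALSE)
der <- seqinr::read.fasta("results/data/cds_derived.fasta", as.string = TRUE,
                          forceDNAtolower = FALSE)
dnds <- do.call(rbind, lapply(names(ref), function(g)
  cbind(data.frame(gene_id = g, species = "all"),
        ng86_dnds(as.character(ref[[g]]), as.character(der[[g]])))))
write.table(dnds, "results/dnds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
truth_w <- read.delim("results/data/truth_omega.tsv", comment.char = "#")
m <- merge(dnds, truth_w, by = "gene_id")
ok <- !is.na(m$omega.x)
message(sprintf(
  "dN/dS: %d genes, cor(estimated, target omega) = %.3f",
  nrow(dnds), cor(m$omega.x[ok], m$omega.y[ok], method = "spearman")))

tpm <- tpm_from_counts(counts,
                       ann$length[match(rownames(counts), ann$gene_id)])
ref_sp <- tree$tip.label[1]
dx <- list()
for (sp in setdiff(sort(unique(meta$species)), ref_sp)) {
  f_cols <- meta$sample_id[meta$species == sp & meta$organ == "gonad"]
  r_cols <- meta$sample_id[meta$species == ref_sp & meta$organ == "gonad"]
  dval <- vapply(rownames(counts), function(g)
    delta_x(tpm[g, f_cols], tpm[g, r_cols])$delta_x, numeric(1))
  dx[[sp]] <- data.frame(gene_id = rownames(counts), species = sp,
                         organ = "gonad", delta_x = unname(dval))
}
dx <- do.call(rbind, c(dx, make.row.names = FALSE))
write.table(dx, "results/delta_x.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
frac_dir <- mean(abs(dx$delta_x) > 1, na.rm = TRUE)
message(sprintf(
  "delta-x: %.1f%% of gene x species values beyond +/-1 (directional)",
  100 * frac_dir))

joint <- joint_candidates(within(dx, species <- "all"), dnds,
                          annotation = ann)
write.table(joint, "results/joint_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("joint expression + sequence candidates: ",
        length(unique(joint$gene_id)), " genes")
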