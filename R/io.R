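# Readers and writers for the pipeline's file dialects: TSV tables with a
# config-hash comment line, GFF3 gene annotation, VCF v4.2 genotypes,
# newick trees. Validation happens at load so downstream code can assume
# the type invariants.

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

write_tsv_hashed <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a gene x sample count matrix
#'
#' TSV dialect: first column `gene_id`, remaining columns one per sample.
#'
#' @param path TSV file.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_any(path)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids in ", path, ": ",
         df$gene_id[duplicated(df$gene_id)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#' @param counts Gene x sample matrix.
#' @param path Output TSV.
#' @param hash Optional config hash for the header comment.
#' @export
write_counts <- function(counts, path, hash = NULL) {
  write_tsv_hashed(data.frame(gene_id = rownames(counts), counts,
                              check.names = FALSE), path, hash)
}

#' Read sample metadata
#'
#' @param path TSV with columns sample_id, species, sex, organ, replicate.
#' @param counts Optional count matrix to cross-validate sample ids.
#' @return data.frame.
#' @export
read_metadata <- function(path, counts = NULL) {
  md <- read_tsv_any(path)
  need <- c("sample_id", "species", "sex", "organ", "replicate")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids: ", md$sample_id[duplicated(md$sample_id)][1])
  if (!all(md$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (!is.null(counts) && !setequal(colnames(counts), md$sample_id))
    stop("metadata sample ids do not match count matrix columns")
  md
}

#' Write gene annotation as GFF3
#'
#' One `gene` feature per row, 1-based inclusive coordinates, `ID=` holding
#' the gene id.
#'
#' @param annotation data.frame with gene_id, lg, start, end.
#' @param path Output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsbgevol\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     annotation$lg, annotation$start, annotation$end,
                     annotation$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Keeps `gene` features; the gene id is taken from the `ID` attribute.
#'
#' @param path GFF3 file (1-based inclusive).
#' @return data.frame: gene_id, lg, start, end, length.
#' @export
read_annotation <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  f <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9)
  if (length(bad))
    stop("malformed GFF3 record at data line ", bad[1])
  f <- do.call(rbind, f)
  f <- f[f[, 3] == "gene", , drop = FALSE]
  ids <- sub(".*ID=([^;]+).*", "\\1", f[, 9])
  start <- as.integer(f[, 4]); end <- as.integer(f[, 5])
  if (any(is.na(start)) || any(is.na(end)) || any(end < start))
    stop("coordinate violation in ", path)
  ann <- data.frame(gene_id = ids, lg = f[, 1], start = start, end = end,
                    length = end - start + 1L)
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene ids in annotation: ",
         ann$gene_id[duplicated(ann$gene_id)][1])
  ann
}

#' Write per-species genotypes as VCF v4.2
#'
#' Biallelic A/T placeholder alleles with GT and DP per sample; missing
#' sites written as `./.`.
#'
#' @param geno One species' element of [simulate_genotypes()] output.
#' @param path Output file.
#' @export
write_vcf <- function(geno, path) {
  n_ind <- ncol(geno$gt)
  gt_str <- matrix("./.", nrow(geno$gt), n_ind)
  gt_str[!is.na(geno$gt) & geno$gt == 0L] <- "0/0"
  gt_str[!is.na(geno$gt) & geno$gt == 1L] <- "0/1"
  gt_str[!is.na(geno$gt) & geno$gt == 2L] <- "1/1"
  cells <- matrix(paste(gt_str, geno$depth, sep = ":"), nrow(geno$gt), n_ind)
  body <- paste(geno$site_pos$lg, geno$site_pos$pos, ".", "A", "T", ".",
                "PASS", ".", "GT:DP",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno$gt)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes with depth from a VCF
#'
#' @param path VCF v4.2 with GT (and optionally DP) per sample.
#' @param sex Optional named vector mapping sample -> "M"/"F"; when given,
#'   returned in column order.
#' @return List: `gt` (sites x samples dosage matrix, NA = missing),
#'   `depth`, `site_pos` (lg, pos), `samples`, `sex`.
#' @export
read_vcf_genotypes <- function(path, sex = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  alleles <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(z) {
      z <- suppressWarnings(as.integer(z))
      if (anyNA(z)) NA_integer_ else sum(z)
    }, integer(1))
  }
  gt <- apply(gt_raw, 2, alleles)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(gt_raw))
  dimnames(gt) <- dimnames(gt_raw)
  dp_raw <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                     error = function(e) NULL)
  depth <- if (is.null(dp_raw)) {
    d <- matrix(1, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    d[is.na(gt)] <- 0
    d
  } else {
    dp_raw[is.na(dp_raw)] <- 0
    dp_raw
  }
  site_pos <- data.frame(lg = vcfR::getCHROM(v),
                         pos = as.integer(vcfR::getPOS(v)))
  samples <- colnames(gt)
  sx <- NULL
  if (!is.null(sex)) {
    missing <- setdiff(samples, names(sex))
    if (length(missing))
      stop("no sex assignment for sample(s): ",
           paste(missing, collapse = ", "))
    sx <- unname(sex[samples])
  }
  list(gt = gt, depth = depth, site_pos = site_pos, samples = samples,
       sex = sx)
}

#' Read a newick species tree
#'
#' @param path Newick file.
#' @param species Optional species set the tips must match.
#' @return [ape::phylo].
#' @export
read_species_tree <- function(path, species = NULL) {
  tr <- ape::read.tree(path)
  if (!is.null(species)) {
    extra <- setdiff(tr$tip.label, species)
    miss <- setdiff(species, tr$tip.label)
    if (length(extra) || length(miss))
      stop("tree tips do not match species set; unexpected: [",
           paste(extra, collapse = ", "), "], missing: [",
           paste(miss, collapse = ", "), "]")
  }
  tr
}

#' Read per-species traits
#'
#' @param path TSV with a `species` column plus numeric trait columns.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  tr <- read_tsv_any(path)
  if (!"species" %in% names(tr)) stop("traits need a 'species' column")
  if (anyDuplicated(tr$species)) stop("duplicate species in traits")
  tr
}

#' Write a simulated dataset to a directory
#'
#' Emits counts.tsv, metadata.tsv, annotation.gff3, genotypes_<sp>.vcf,
#' tree.nwk, traits.tsv, truth_sbg.tsv, truth_omega.tsv, cds_<ref|derived>.fasta
#' and manifest.json (config + seed + config hash).
#'
#' @param dataset A `"sim_dataset"` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(dataset$config))
  write_counts(dataset$counts, file.path(dir, "counts.tsv"), hash)
  write_tsv_hashed(dataset$metadata, file.path(dir, "metadata.tsv"), hash)
  write_annotation_gff3(dataset$annotation, file.path(dir, "annotation.gff3"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_tsv_hashed(dataset$traits, file.path(dir, "traits.tsv"), hash)
  write_tsv_hashed(dataset$truth, file.path(dir, "truth_sbg.tsv"), hash)
  write_tsv_hashed(data.frame(gene_id = names(dataset$cds$omega),
                              omega = unname(dataset$cds$omega)),
                   file.path(dir, "truth_omega.tsv"), hash)
  seqinr::write.fasta(as.list(dataset$cds$ref), names(dataset$cds$ref),
                      file.path(dir, "cds_ref.fasta"))
  seqinr::write.fasta(as.list(dataset$cds$derived),
                      names(dataset$cds$derived),
                      file.path(dir, "cds_derived.fasta"))
  for (sp in names(dataset$genotypes))
    write_vcf(dataset$genotypes[[sp]],
              file.path(dir, paste0("genotypes_", sp, ".vcf")))
  jsonlite::write_json(list(config = unclass(dataset$config),
                            config_hash = hash),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
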