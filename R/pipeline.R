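# End-to-end pipeline: glue that runs sex-bias calling across all species
# and organs, assembles profile matrices and state matrices, and the
# orchestrator that executes every stage on a (simulated or loaded)
# dataset, writing tables and a reproducibility manifest.

#' Call sex bias for every species x organ
#'
#' Runs [test_sex_bias()] per species and organ; groups with fewer than two
#' replicates of either sex are skipped and reported.
#'
#' @param counts Gene x sample raw counts (all samples).
#' @param metadata Sample metadata (see [read_metadata()]).
#' @param alpha,lfc_threshold,pseudo_count Passed to [test_sex_bias()].
#' @return List: `table` (stacked data.frame with species and organ
#'   columns), `skipped` (data.frame: species, organ, reason).
#' @export
call_sex_bias_all <- function(counts, metadata, alpha = 0.05,
                              lfc_threshold = 2, pseudo_count = 0.5) {
  res <- list()
  skipped <- list()
  for (sp in unique(metadata$species)) {
    for (org in unique(metadata$organ)) {
      sel <- metadata$species == sp & metadata$organ == org
      if (!any(sel)) next
      sx <- metadata$sex[sel]
      if (sum(sx == "M") < 2 || sum(sx == "F") < 2) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(species = sp, organ = org,
                     reason = "fewer than two replicates per sex")
        next
      }
      tab <- test_sex_bias(counts[, metadata$sample_id[sel], drop = FALSE],
                           sx, alpha = alpha,
                           lfc_threshold = lfc_threshold,
                           pseudo_count = pseudo_count)
      tab$species <- sp
      tab$organ <- org
      res[[length(res) + 1L]] <- tab
    }
  }
  list(
    table = if (length(res)) do.call(rbind, res) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped)
    else data.frame(species = character(), organ = character(),
                    reason = character())
  )
}

#' Mean expression profiles per species
#'
#' Averages TMM-normalized counts over replicates, per species, for one
#' organ and sex (or averaging both sexes).
#'
#' @param normalized Gene x sample normalized matrix.
#' @param metadata Sample metadata.
#' @param organ Organ to profile.
#' @param sex "M", "F", or "both" (sex-averaged).
#' @param genes Optional gene subset (e.g. one bias class).
#' @return Genes x species matrix.
#' @export
mean_expression_profiles <- function(normalized, metadata, organ,
                                     sex = "both", genes = NULL) {
  sel <- metadata$organ == organ
  if (sex != "both") sel <- sel & metadata$sex == sex
  md <- metadata[sel, , drop = FALSE]
  if (nrow(md) == 0) stop("no samples for organ ", organ)
  m <- normalized[, md$sample_id, drop = FALSE]
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  sp <- sort(unique(md$species))
  out <- vapply(sp, function(s)
    rowMeans(m[, md$sample_id[md$species == s], drop = FALSE]),
    numeric(nrow(m)))
  colnames(out) <- sp
  out
}

#' Gene x species bias-state matrix for one organ
#'
#' Converts a stacked sex-bias table into the 3-state character matrix the
#' Mk model consumes; species x organ combinations absent from the table
#' (skipped groups) become NA (missing, integrated out).
#'
#' @param bias_table Stacked table from [call_sex_bias_all()].
#' @param organ Organ label.
#' @param species Full species set (columns).
#' @return Character matrix genes x species with "U"/"FBG"/"MBG"/NA.
#' @export
bias_state_matrix <- function(bias_table, organ, species) {
  bt <- bias_table[bias_table$organ == organ, , drop = FALSE]
  genes <- sort(unique(bt$gene_id))
  m <- matrix(NA_character_, length(genes), length(species),
              dimnames = list(genes, species))
  for (sp in intersect(species, unique(bt$species))) {
    rows <- bt[bt$species == sp, , drop = FALSE]
    st <- ifelse(rows$direction == "unbiased", "U", rows$direction)
    m[match(rows$gene_id, genes), sp] <- st
  }
  m
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated dataset:
#' simulate, sex-bias calling (de), population genetics (popgen), selection
#' statistics (molevol), expression phylogenies (exprtree), ancestral
#' reconstruction and turnover counting (ancestral), genomic-distribution
#' tests (enrich). All tables are written under `outdir` with the config
#' hash in a header comment; a manifest with per-file checksums is written
#' at the end. A fixed config seed makes the run byte-identical.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param stages Character vector of stages to run (dependencies are not
#'   auto-enabled; disabling an upstream stage skips dependents with a
#'   logged reason).
#' @param focal_organ Organ used for the popgen/molevol/ancestral contrasts
#'   (default "gonad").
#' @return The manifest (list), invisibly; also written as manifest.json.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = c("simulate", "de", "popgen", "molevol",
                                    "exprtree", "ancestral", "enrich"),
                         focal_organ = "gonad") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  written <- character()
  log_lines <- character()
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv_hashed(df, p, hash)
    written <<- c(written, p)
  }
  if (!"simulate" %in% stages)
    stop("pre-flight: the simulate stage is required as data source")
  note("stage simulate: seed ", config$seed)
  ds <- simulate_dataset(config)
  write_dataset(ds, file.path(outdir, "data"))
  written <- c(written, list.files(file.path(outdir, "data"),
                                   full.names = TRUE))
  counts <- filter_low_count_genes(ds$counts)
  note("gene filter: ", nrow(ds$counts), " -> ", nrow(counts), " genes")

  bias <- NULL
  if ("de" %in% stages) {
    norm <- tmm_normalize(counts)$normalized
    qc <- qc_flag_samples(counts, ds$metadata)
    emit(qc, "qc_flags.tsv")
    de <- call_sex_bias_all(counts, ds$metadata)
    bias <- de$table
    emit(bias, "sex_bias.tsv")
    emit(de$skipped, "sex_bias_skipped.tsv")
    note("stage de: ", sum(bias$direction != "unbiased"), " biased calls")
    emit(shared_sbg_sets(bias), "sbg_sharing.tsv")
  }

  popgen <- NULL
  if ("popgen" %in% stages) {
    res <- list()
    for (sp in names(ds$genotypes)) {
      g <- ds$genotypes[[sp]]
      st <- popgen_gene_stats(g$gt, g$depth, g$sex, g$site_pos,
                              ds$annotation)
      st$species <- sp
      res[[sp]] <- st
    }
    popgen <- do.call(rbind, c(res, make.row.names = FALSE))
    emit(popgen, "popgen_gene_stats.tsv")
    note("stage popgen: ", nrow(popgen), " gene x species rows")
  }

  dnds <- NULL
  if ("molevol" %in% stages) {
    gene_ids <- names(ds$cds$ref)
    dnds <- do.call(rbind, lapply(gene_ids, function(g) {
      r <- ng86_dnds(ds$cds$ref[[g]], ds$cds$derived[[g]])
      cbind(data.frame(gene_id = g), r)
    }))
    emit(dnds, "dnds.tsv")
    tpm <- tpm_from_counts(counts,
                           ds$annotation$length[match(rownames(counts),
                                                      ds$annotation$gene_id)])
    ref_sp <- ds$tree$tip.label[1]
    md <- ds$metadata
    dx <- list()
    for (sp in setdiff(ds$tree$tip.label, ref_sp)) {
      f_cols <- md$sample_id[md$species == sp & md$organ == focal_organ]
      r_cols <- md$sample_id[md$species == ref_sp & md$organ == focal_organ]
      if (length(f_cols) < 2 || length(r_cols) < 2) next
      dval <- vapply(rownames(counts), function(g)
        delta_x(tpm[g, f_cols], tpm[g, r_cols])$delta_x, numeric(1))
      dx[[sp]] <- data.frame(gene_id = rownames(counts), species = sp,
                             organ = focal_organ, delta_x = unname(dval))
    }
    dx <- do.call(rbind, c(dx, make.row.names = FALSE))
    emit(dx, "delta_x.tsv")
    dnds$species <- "all"   # one derived sequence per gene in the simulation
    joint <- joint_candidates(
      within(dx, species <- "all"), dnds, annotation = ds$annotation)
    emit(joint, "joint_candidates.tsv")
    note("stage molevol: ", nrow(joint), " joint candidates")
  }

  if ("exprtree" %in% stages && !is.null(bias)) {
    norm <- tmm_normalize(counts)$normalized
    trees <- list()
    rtt <- list()
    for (org in unique(ds$metadata$organ)) {
      for (cls in c("FBG", "MBG", "unbiased")) {
        cls_genes <- unique(bias$gene_id[bias$organ == org &
                                           bias$direction == cls])
        if (length(cls_genes) < 5) next
        sxx <- if (cls == "FBG") "F" else if (cls == "MBG") "M" else "both"
        prof <- mean_expression_profiles(norm, ds$metadata, org, sxx,
                                         genes = cls_genes)
        if (ncol(prof) < 3) next
        tr <- nj_tree(spearman_distance_matrix(prof))
        rooted <- root_expression_tree(tr, outgroup = ds$tree$tip.label[1])
        trees[[paste(org, cls, sep = "_")]] <- tr
        rtt[[length(rtt) + 1L]] <- data.frame(
          organ = org, class = cls, species = names(root_to_tip_lengths(rooted)),
          root_to_tip = unname(root_to_tip_lengths(rooted)),
          rf_to_species_tree = rf_distance(tr, ds$tree)$rf)
      }
    }
    if (length(trees)) {
      tre_path <- file.path(outdir, "expression_trees.nwk")
      ape::write.tree(do.call(c, trees), tre_path, tree.names = TRUE)
      written <- c(written, tre_path)
      emit(do.call(rbind, rtt), "root_to_tip.tsv")
      note("stage exprtree: ", length(trees), " class trees")
    }
  }

  if ("ancestral" %in% stages && !is.null(bias)) {
    states <- bias_state_matrix(bias, focal_organ, ds$tree$tip.label)
    fit <- fit_mk_equal_rates(states, ds$tree)
    anc <- joint_ancestral_states(states, ds$tree, fit$q)
    turn <- count_turnovers(anc, ds$tree)
    emit(turn$branches, "turnovers_branches.tsv")
    emit(turn$nodes, "turnovers_nodes.tsv")
    note("stage ancestral: q = ", signif(fit$q, 4))
    term <- turn$branches[turn$branches$child_label %in% ds$tree$tip.label, ]
    tot <- term$gains_MBG + term$losses_MBG + term$gains_FBG + term$losses_FBG
    resp <- stats::setNames(tot, term$child_label)
    pg <- lapply(c("sperm_competition", "dimorphism",
                   "sexchr_differentiation"), function(tr_name) {
      trv <- stats::setNames(ds$traits[[tr_name]], ds$traits$species)
      fitp <- pgls_trait_association(resp, trv, ds$tree)
      co <- fitp$coefficients[fitp$coefficients$term == "x", , drop = FALSE]
      data.frame(trait = tr_name, slope = co$estimate, se = co$se, p = co$p)
    })
    emit(do.call(rbind, pg), "pgls_traits.tsv")
  } else if ("ancestral" %in% stages) {
    note("stage ancestral skipped: requires de stage output")
  }

  if ("enrich" %in% stages && !is.null(bias)) {
    gene_lg <- stats::setNames(ds$annotation$lg, ds$annotation$gene_id)
    enr <- list()
    for (sp in unique(bias$species)) {
      bt <- bias[bias$species == sp & bias$organ == focal_organ, ]
      if (nrow(bt) == 0) next
      e <- lg_enrichment(bt, gene_lg)
      e$species <- sp
      enr[[sp]] <- e
    }
    emit(do.call(rbind, c(enr, make.row.names = FALSE)), "lg_enrichment.tsv")
    if (!is.null(popgen)) {
      cmp <- list()
      for (sp in names(ds$sex_chromosomes)) {
        sl <- ds$sex_chromosomes[[sp]]
        if (length(sl) == 0) next
        bt <- bias[bias$species == sp & bias$organ == focal_organ, ]
        gs <- popgen[popgen$species == sp, ]
        for (statc in c("fst", "pi", "tajimas_d")) {
          r <- sexchr_vs_autosome_compare(gs, bt, sl, statc)
          if (nrow(r) == 0) next
          r$species <- sp
          r$statistic <- statc
          cmp[[length(cmp) + 1L]] <- r
        }
      }
      if (length(cmp))
        emit(do.call(rbind, c(cmp, make.row.names = FALSE)),
             "sexchr_vs_autosomes.tsv")
    } else {
      note("enrich: popgen disabled, sex-chromosome Fst comparison skipped")
    }
    note("stage enrich done")
  }

  log_path <- file.path(outdir, "run.log")
  writeLines(log_lines, log_path)
  manifest <- list(
    tool = "sbgevol",
    version = as.character(utils::packageVersion("sbgevol")),
    config_hash = hash, seed = config$seed,
    stages = stages,
    checksums = local({
      cs <- tools::md5sum(sort(c(written, log_path)))
      names(cs) <- substring(names(cs), nchar(outdir) + 2L)
      as.list(cs)
    })
  )
  mpath <- file.path(outdir, "manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, mpath)   # atomic at run end
  invisible(manifest)
}
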