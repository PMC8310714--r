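# Synthetic-data generator emulating the study design: an ultrametric
# species tree, per-species x sex x organ RNA-seq counts whose log2 means
# drift as Brownian motion along the tree with planted sex-biased genes,
# per-species genotypes with an XY-divergent region, in-frame coding
# sequence pairs with controlled dN/dS, and per-species traits. Every
# planted signal is recorded in truth tables so downstream stages can be
# scored without external data.

#' Simulation configuration
#'
#' Builds a validated configuration list with defaults chosen to emulate
#' the study design: 14 taxa on a 5-Myr ultrametric tree, two sexes by five
#' organs by three replicates, negative-binomial counts with gene-wise
#' dispersion, a high sex-bias fraction in gonads and a low one in soma,
#' an XY-divergent region on the species' sex-chromosome linkage groups,
#' and log-normal library sizes (CV 0.3).
#'
#' @param n_species Number of taxa (>= 2).
#' @param tree_mode "yule" (simulated birth tree scaled to `tree_height`)
#'   or "fixed_newick" (use `fixed_newick` unchanged).
#' @param fixed_newick Newick string when `tree_mode = "fixed_newick"`.
#' @param tree_height Root age in Myr for simulated trees.
#' @param organs Organ labels.
#' @param replicates_per_sex_organ Replicates per species x sex x organ
#'   (>= 2).
#' @param n_genes Number of genes.
#' @param n_lgs Number of linkage groups genes are spread over.
#' @param base_mean,base_sd Gene baseline log2 expression distribution.
#' @param nb_dispersion_meanlog,nb_dispersion_sdlog Log-normal gene-wise NB
#'   dispersion.
#' @param brownian_rate Per-organ Brownian variance of log2 expression per
#'   Myr (scalar or named per organ).
#' @param sbg_rate_multiplier Brownian-rate multiplier for planted SBGs
#'   (elevated expression divergence).
#' @param sbg_fraction_per_organ Fraction of genes planted as sex-biased,
#'   named per organ (scalar recycled).
#' @param sbg_lfc_mixture Mixing weights over the bias categories
#'   low/mid/high/extreme for planted |LFC| values.
#' @param evolve_bias_states Evolve the 3-state bias character along the
#'   tree with rate `bias_q` instead of planting the same bias in every
#'   species.
#' @param bias_q Transition rate when `evolve_bias_states = TRUE`.
#' @param library_size_mean Mean library-scaling factor (log-normal, CV
#'   0.3).
#' @param n_sites_per_gene Gene length in bases (multiple of 3).
#' @param n_ind_per_sex Genotyped individuals per sex and species.
#' @param theta Population-scaled mutation rate per site.
#' @param xy_fraction Fraction of sex-chromosome sites fixed X/Y divergent.
#' @param mean_depth Mean sequencing depth per site and individual.
#' @param coverage_dropout Per-site per-individual missingness probability.
#' @param omega_meanlog,omega_sdlog Log-normal distribution of per-gene
#'   dN/dS targets.
#' @param seq_divergence Per-site proposal probability for the codon
#'   substitution process.
#' @param seed Integer seed; fully determines all outputs.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 14, tree_mode = c("yule", "fixed_newick"),
                       fixed_newick = NULL, tree_height = 5,
                       organs = c("gonad", "brain", "liver", "gill", "jaw"),
                       replicates_per_sex_organ = 3,
                       n_genes = 1000, n_lgs = 22,
                       base_mean = 5, base_sd = 2,
                       nb_dispersion_meanlog = log(0.1),
                       nb_dispersion_sdlog = 0.5,
                       brownian_rate = 0.05,
                       sbg_rate_multiplier = 3,
                       sbg_fraction_per_organ = c(gonad = 0.3, brain = 0.01,
                                                  liver = 0.01, gill = 0.01,
                                                  jaw = 0.01),
                       sbg_lfc_mixture = c(low = 0.25, mid = 0.35,
                                           high = 0.25, extreme = 0.15),
                       evolve_bias_states = FALSE, bias_q = 0.5,
                       library_size_mean = 1, n_sites_per_gene = 300,
                       n_ind_per_sex = 3, theta = 0.01, xy_fraction = 0.3,
                       mean_depth = 10, coverage_dropout = 0.1,
                       omega_meanlog = log(0.2), omega_sdlog = 0.5,
                       seq_divergence = 0.05, seed = 1) {
  tree_mode <- match.arg(tree_mode)
  if (n_species < 2) stop("invalid config: n_species must be >= 2")
  if (replicates_per_sex_organ < 2)
    stop("invalid config: need a minimum of two replicates per sex")
  if (length(organs) == 0) stop("invalid config: organ list is empty")
  if (n_sites_per_gene %% 3 != 0)
    stop("invalid config: gene length must be a multiple of 3")
  if (any(sbg_fraction_per_organ < 0 | sbg_fraction_per_organ > 1))
    stop("invalid config: sbg fractions must lie in [0, 1]")
  if (xy_fraction < 0 || xy_fraction > 1)
    stop("invalid config: xy_fraction must lie in [0, 1]")
  if (coverage_dropout < 0 || coverage_dropout > 1)
    stop("invalid config: coverage_dropout must lie in [0, 1]")
  if (length(brownian_rate) == 1)
    brownian_rate <- stats::setNames(rep(brownian_rate, length(organs)),
                                     organs)
  if (length(sbg_fraction_per_organ) == 1)
    sbg_fraction_per_organ <- stats::setNames(
      rep(sbg_fraction_per_organ, length(organs)), organs)
  missing_org <- setdiff(organs, names(sbg_fraction_per_organ))
  if (length(missing_org))
    sbg_fraction_per_organ[missing_org] <- 0.01
  missing_org <- setdiff(organs, names(brownian_rate))
  if (length(missing_org)) brownian_rate[missing_org] <- 0.05
  structure(list(
    n_species = n_species, tree_mode = tree_mode,
    fixed_newick = fixed_newick, tree_height = tree_height,
    organs = organs,
    replicates_per_sex_organ = replicates_per_sex_organ,
    n_genes = n_genes, n_lgs = n_lgs,
    base_mean = base_mean, base_sd = base_sd,
    nb_dispersion_meanlog = nb_dispersion_meanlog,
    nb_dispersion_sdlog = nb_dispersion_sdlog,
    brownian_rate = brownian_rate[organs],
    sbg_rate_multiplier = sbg_rate_multiplier,
    sbg_fraction_per_organ = sbg_fraction_per_organ[organs],
    sbg_lfc_mixture = sbg_lfc_mixture / sum(sbg_lfc_mixture),
    evolve_bias_states = evolve_bias_states, bias_q = bias_q,
    library_size_mean = library_size_mean,
    n_sites_per_gene = n_sites_per_gene,
    n_ind_per_sex = n_ind_per_sex, theta = theta,
    xy_fraction = xy_fraction, mean_depth = mean_depth,
    coverage_dropout = coverage_dropout,
    omega_meanlog = omega_meanlog, omega_sdlog = omega_sdlog,
    seq_divergence = seq_divergence, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate (or parse) the species tree
#'
#' @param config A [sim_config()].
#' @return Ultrametric rooted [ape::phylo] with `n_species` tips labelled
#'   `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(config) {
  if (config$tree_mode == "fixed_newick") {
    if (is.null(config$fixed_newick)) stop("fixed_newick not supplied")
    return(ape::read.tree(text = config$fixed_newick))
  }
  set.seed(config$seed + 101L)
  tr <- ape::rphylo(config$n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * config$tree_height / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
  tr
}

#' Gene annotation for the synthetic genome
#'
#' Genes are dealt round-robin onto `n_lgs` linkage groups and placed
#' end-to-end with a fixed spacer; coordinates are 1-based inclusive.
#'
#' @param config A [sim_config()].
#' @return data.frame: `gene_id`, `lg`, `start`, `end`, `length`.
#' @export
simulate_annotation <- function(config) {
  gene_id <- sprintf("gene%05d", seq_len(config$n_genes))
  lg <- paste0("LG", (seq_len(config$n_genes) - 1L) %% config$n_lgs + 1L)
  idx_on_lg <- stats::ave(seq_len(config$n_genes), lg, FUN = seq_along)
  spacer <- 100L
  start <- (idx_on_lg - 1L) * (config$n_sites_per_gene + spacer) + 1L
  data.frame(gene_id = gene_id, lg = lg, start = start,
             end = start + config$n_sites_per_gene - 1L,
             length = config$n_sites_per_gene)
}

#' Default sex-chromosome systems for the synthetic taxa
#'
#' Emulates the study layout of XY systems: the first species carries an
#' old full-length XY on LG19, the next five a fused LG5/LG19 system, the
#' seventh an LG11/LG15 system, and the remaining species have no known
#' sex chromosome.
#'
#' @param species Character vector of species labels.
#' @return Named list of character vectors of sex-linked LG ids.
#' @export
default_sex_chromosomes <- function(species) {
  out <- stats::setNames(vector("list", length(species)), species)
  for (i in seq_along(species)) {
    out[[i]] <- if (i == 1) "LG19"
    else if (i <= 6) c("LG5", "LG19")
    else if (i == 7) c("LG11", "LG15")
    else character(0)
  }
  out
}

#' Simulate the 3-state bias character along the tree
#'
#' Evolves "U"/"FBG"/"MBG" under the equal-rates Mk model with rate `q`
#' from a uniform root state, returning tip states and the true per-branch
#' transition history.
#'
#' @param tree [ape::phylo].
#' @param q Transition rate per unit branch length.
#' @param n_genes Number of independent characters.
#' @param seed Integer seed.
#' @return List: `tip_states` (genes x species matrix), `node_states`
#'   (genes x all-nodes matrix, postorder node numbering as in
#'   [joint_ancestral_states()]).
#' @export
sim_bias_states <- function(tree, q, n_genes, seed = 1) {
  set.seed(seed)
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  st <- matrix(NA_integer_, n_genes, n_all)
  root <- n_tip + 1L
  st[, root] <- sample.int(3, n_genes, replace = TRUE)
  for (e in rev(seq_len(nrow(tree$edge)))) {   # root-to-tip order
    P <- mk3_pmat(q, tree$edge.length[e])
    parent_state <- st[, tree$edge[e, 1]]
    u <- stats::runif(n_genes)
    cum <- t(apply(P, 1, cumsum))
    child <- integer(n_genes)
    for (s in 1:3) {
      rows <- parent_state == s
      child[rows] <- 1L + rowSums(outer(u[rows], cum[s, ], ">"))
    }
    st[, tree$edge[e, 2]] <- child
  }
  out <- matrix(BIAS_STATES[st], n_genes, n_all)
  colnames(out) <- c(tree$tip.label, paste0("node", (n_tip + 1L):n_all))
  list(tip_states = out[, tree$tip.label, drop = FALSE], node_states = out)
}

# draw a planted |LFC| from the category mixture
draw_lfc <- function(n, mixture) {
  bins <- rbind(low = c(2.05, 2.6), mid = c(2.6, 4.1),
                high = c(4.1, 6.5), extreme = c(6.5, 10))
  cat <- sample(rownames(bins), n, replace = TRUE, prob = mixture[rownames(bins)])
  stats::runif(n, bins[cat, 1], bins[cat, 2])
}

#' Simulate expression counts along the species tree
#'
#' Per organ, each gene's log2 baseline evolves as Brownian motion along
#' the tree (per-organ rate; planted SBGs get `sbg_rate_multiplier` times
#' the rate); planted SBGs add their LFC to one sex; counts are drawn
#' negative-binomial around `2^logmean` times a log-normal library factor,
#' with log-normal gene-wise dispersion.
#'
#' @param config A [sim_config()].
#' @param tree The species tree from [simulate_tree()].
#' @return List: `counts` (gene x sample integer matrix), `metadata`
#'   (sample_id, species, sex, organ, replicate), `truth` (data.frame of
#'   planted gene x species x organ biases with true LFC), `bias_states`
#'   (when `evolve_bias_states`, the true tip/node states per organ).
#' @export
simulate_expression_counts <- function(config, tree) {
  if (is.null(tree$tip.label)) stop("tree tips must be labelled")
  set.seed(config$seed + 202L)
  species <- tree$tip.label
  n_sp <- length(species)
  ng <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(ng))
  C <- ape::vcv(tree)[species, species]
  U <- chol(C + diag(1e-10, n_sp))
  phi <- stats::rlnorm(ng, config$nb_dispersion_meanlog,
                       config$nb_dispersion_sdlog)
  reps <- config$replicates_per_sex_organ
  meta <- expand.grid(replicate = seq_len(reps), sex = c("F", "M"),
                      organ = config$organs, species = species,
                      stringsAsFactors = FALSE)
  meta$sample_id <- with(meta, paste(species, organ, sex, replicate, sep = "_"))
  meta <- meta[, c("sample_id", "species", "sex", "organ", "replicate")]
  lib_sdlog <- sqrt(log(1 + 0.3^2))     # CV 0.3
  libfac <- stats::rlnorm(nrow(meta),
                          log(config$library_size_mean) - lib_sdlog^2 / 2,
                          lib_sdlog)
  counts <- matrix(0L, ng, nrow(meta),
                   dimnames = list(gene_id, meta$sample_id))
  truth <- list()
  bias_states <- list()
  for (org in config$organs) {
    base <- stats::rnorm(ng, config$base_mean, config$base_sd)
    frac <- config$sbg_fraction_per_organ[[org]]
    n_sbg <- floor(frac * ng)
    sbg_idx <- if (n_sbg > 0) sort(sample.int(ng, n_sbg)) else integer(0)
    lfc <- numeric(ng)
    dir_sex <- rep(NA_character_, ng)
    if (n_sbg > 0) {
      lfc[sbg_idx] <- draw_lfc(n_sbg, config$sbg_lfc_mixture)
      dir_sex[sbg_idx] <- sample(c("M", "F"), n_sbg, replace = TRUE)
    }
    # which species carry the bias for each gene
    if (config$evolve_bias_states) {
      bs <- sim_bias_states(tree, config$bias_q, ng,
                            seed = config$seed + 303L + match(org, config$organs))
      bias_states[[org]] <- bs
      biased_in <- bs$tip_states != "U"
      dir_mat <- matrix(NA_character_, ng, n_sp,
                        dimnames = list(gene_id, species))
      dir_mat[bs$tip_states == "MBG"] <- "M"
      dir_mat[bs$tip_states == "FBG"] <- "F"
      lfc_evo <- numeric(ng)
      lfc_evo[rowSums(biased_in) > 0] <-
        draw_lfc(sum(rowSums(biased_in) > 0), config$sbg_lfc_mixture)
      lfc_mat <- matrix(lfc_evo, ng, n_sp,
                        dimnames = list(gene_id, species)) * biased_in
    } else {
      dir_mat <- matrix(dir_sex, ng, n_sp, dimnames = list(gene_id, species))
      lfc_mat <- matrix(lfc, ng, n_sp, dimnames = list(gene_id, species))
    }
    rate <- config$brownian_rate[[org]]
    rate_gene <- rep(rate, ng)
    elevated <- if (config$evolve_bias_states)
      rowSums(lfc_mat > 0) > 0 else lfc > 0
    rate_gene[elevated] <- rate * config$sbg_rate_multiplier
    Z <- matrix(stats::rnorm(ng * n_sp), ng, n_sp)
    dev <- (Z %*% U) * sqrt(rate_gene)
    colnames(dev) <- species
    for (sp in species) {
      for (sx in c("F", "M")) {
        logmu <- base + dev[, sp]
        add <- lfc_mat[, sp] * (dir_mat[, sp] == sx)
        add[is.na(add)] <- 0
        logmu <- logmu + add
        cols <- which(meta$organ == org & meta$species == sp & meta$sex == sx)
        for (j in cols) {
          mu <- pmax(2^logmu * libfac[j], 1e-8)
          counts[, j] <- stats::rnbinom(ng, mu = mu, size = 1 / phi)
        }
      }
    }
    tr_rows <- which(lfc_mat > 0 & !is.na(dir_mat), arr.ind = TRUE)
    if (nrow(tr_rows) > 0)
      truth[[org]] <- data.frame(
        gene_id = gene_id[tr_rows[, 1]],
        species = species[tr_rows[, 2]],
        organ = org,
        direction = ifelse(dir_mat[tr_rows] == "M", "MBG", "FBG"),
        lfc = lfc_mat[tr_rows] * ifelse(dir_mat[tr_rows] == "M", 1, -1))
  }
  storage.mode(counts) <- "integer"
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
  else data.frame(gene_id = character(), species = character(),
                  organ = character(), direction = character(),
                  lfc = numeric())
  list(counts = counts, metadata = meta, truth = truth,
       bias_states = bias_states, dispersion = phi)
}

#' Simulate per-species genotypes with an XY-divergent region
#'
#' Every position of every gene is a potential site: autosomal sites are
#' segregating with probability `theta * a1(2n)` with a neutral (1/i)
#' frequency spectrum and sex-independent binomial genotypes; on the
#' species' sex-chromosome linkage groups, a fraction `xy_fraction` of
#' sites is fixed X/Y divergent (all males heterozygous, all females
#' homozygous reference). Depth is Poisson with dropout; a site is missing
#' in an individual at depth 0.
#'
#' @param config A [sim_config()].
#' @param annotation From [simulate_annotation()].
#' @param sex_chromosomes Named list (per species) of sex-linked LG ids.
#' @param species Species labels to simulate.
#' @return Named list per species: `gt` (sites x individuals dosage, NA =
#'   missing), `depth`, `sex`, `site_pos` (data.frame lg, pos),
#'   `truth_divergent` (logical per site).
#' @export
simulate_genotypes <- function(config, annotation, sex_chromosomes,
                               species = names(sex_chromosomes)) {
  bad <- setdiff(unique(unlist(sex_chromosomes)), unique(annotation$lg))
  if (length(bad) > 0)
    stop("config error: sex-linked LG not in annotation: ",
         paste(bad, collapse = ", "))
  set.seed(config$seed + 404L)
  n_ind <- 2L * config$n_ind_per_sex
  sex <- rep(c("M", "F"), each = config$n_ind_per_sex)
  site_pos <- data.frame(
    lg = rep(annotation$lg, annotation$length),
    pos = unlist(lapply(seq_len(nrow(annotation)), function(i)
      annotation$start[i]:annotation$end[i]))
  )
  n_sites <- nrow(site_pos)
  a1 <- sum(1 / seq_len(2 * n_ind - 1))
  p_seg <- min(1, config$theta * a1)
  sfs_class <- seq_len(2 * n_ind - 1)
  sfs_w <- 1 / sfs_class
  out <- list()
  for (sp in species) {
    seg <- stats::runif(n_sites) < p_seg
    p <- numeric(n_sites)
    p[seg] <- sample(sfs_class, sum(seg), replace = TRUE, prob = sfs_w) /
      (2 * n_ind)
    gt <- matrix(0L, n_sites, n_ind)
    if (any(seg))
      gt[seg, ] <- stats::rbinom(sum(seg) * n_ind, 2, rep(p[seg], n_ind))
    divergent <- rep(FALSE, n_sites)
    sex_lgs <- sex_chromosomes[[sp]]
    if (length(sex_lgs) > 0 && config$xy_fraction > 0) {
      on_sex <- site_pos$lg %in% sex_lgs
      divergent <- on_sex & stats::runif(n_sites) < config$xy_fraction
      gt[divergent, sex == "M"] <- 1L
      gt[divergent, sex == "F"] <- 0L
    }
    depth <- matrix(stats::rpois(n_sites * n_ind, config$mean_depth),
                    n_sites, n_ind)
    drop <- matrix(stats::runif(n_sites * n_ind) < config$coverage_dropout,
                   n_sites, n_ind)
    depth[drop] <- 0L
    gt[depth == 0] <- NA_integer_
    colnames(gt) <- colnames(depth) <-
      paste0(sp, "_", sex, rep(seq_len(config$n_ind_per_sex), times = 2))
    out[[sp]] <- list(gt = gt, depth = depth, sex = sex,
                      site_pos = site_pos, truth_divergent = divergent)
  }
  out
}

NON_STOP_CODONS <- NULL  # populated lazily in simulate_coding_sequences

#' Simulate reference/derived coding sequence pairs
#'
#' Builds for each gene a random in-frame reference CDS (no stop codons)
#' and a derived sequence produced by a codon substitution process with a
#' per-gene target dN/dS: proposed single-nucleotide changes are accepted
#' with probability proportional to 1 (synonymous) vs omega (nonsynonymous,
#' for omega <= 1; the ratio is inverted above 1), and changes creating a
#' stop codon are rejected.
#'
#' @param config A [sim_config()].
#' @param omega Optional per-gene target dN/dS vector; drawn log-normal by
#'   default.
#' @return List: `ref` and `derived` (named character vectors of CDS),
#'   `omega` (true targets).
#' @export
simulate_coding_sequences <- function(config, omega = NULL) {
  set.seed(config$seed + 505L)
  ng <- config$n_genes
  n_codon <- config$n_sites_per_gene / 3
  if (is.null(omega))
    omega <- stats::rlnorm(ng, config$omega_meanlog, config$omega_sdlog)
  stopifnot(length(omega) == ng)
  aa_tab <- codon_table()
  good <- names(aa_tab)[aa_tab != "*"]
  gene_id <- sprintf("gene%05d", seq_len(ng))
  nts <- c("A", "C", "G", "T")
  ref <- derived <- character(ng)
  for (g in seq_len(ng)) {
    codons <- sample(good, n_codon, replace = TRUE)
    seq_ref <- paste(codons, collapse = "")
    chars <- strsplit(seq_ref, "")[[1]]
    w <- omega[g]
    acc_syn <- min(1, 1 / w)
    acc_non <- min(1, w)
    hit <- which(stats::runif(length(chars)) < config$seq_divergence)
    for (pos in hit) {
      alt <- sample(setdiff(nts, chars[pos]), 1)
      cstart <- pos - (pos - 1) %% 3
      old_codon <- paste(chars[cstart:(cstart + 2)], collapse = "")
      newc <- chars
      newc[pos] <- alt
      new_codon <- paste(newc[cstart:(cstart + 2)], collapse = "")
      if (aa_tab[[new_codon]] == "*") next
      syn <- aa_tab[[new_codon]] == aa_tab[[old_codon]]
      if (stats::runif(1) < (if (syn) acc_syn else acc_non))
        chars[pos] <- alt
    }
    ref[g] <- seq_ref
    derived[g] <- paste(chars, collapse = "")
  }
  names(ref) <- names(derived) <- gene_id
  list(ref = ref, derived = derived, omega = stats::setNames(omega, gene_id))
}

#' Simulate per-species traits
#'
#' Sperm-competition rank, sexual-dimorphism degree and sex-chromosome
#' differentiation degree, each a Brownian component along the tree plus
#' independent Gaussian noise (so phylogenetically controlled regressions
#' have recoverable structure).
#'
#' @param config A [sim_config()].
#' @param tree Species tree.
#' @param bm_sd,noise_sd Scales of the two components.
#' @return data.frame: `species`, `sperm_competition`, `dimorphism`,
#'   `sexchr_differentiation`.
#' @export
simulate_traits <- function(config, tree, bm_sd = 1, noise_sd = 0.3) {
  set.seed(config$seed + 606L)
  one <- function() {
    x <- ape::rTraitCont(tree, model = "BM", sigma = bm_sd)
    x + stats::rnorm(length(x), 0, noise_sd)
  }
  data.frame(species = tree$tip.label,
             sperm_competition = unname(one()[tree$tip.label]),
             dimorphism = unname(one()[tree$tip.label]),
             sexchr_differentiation = unname(one()[tree$tip.label]))
}

#' Simulate the full labelled dataset
#'
#' Orchestrates tree, annotation, counts, genotypes, coding sequences and
#' traits under one seed.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_dataset"`: `config`, `tree`, `annotation`,
#'   `counts`, `metadata`, `truth`, `bias_states`, `genotypes`,
#'   `sex_chromosomes`, `cds`, `traits`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- simulate_tree(config)
  annotation <- simulate_annotation(config)
  expr <- simulate_expression_counts(config, tree)
  sexchr <- lapply(default_sex_chromosomes(tree$tip.label),
                   intersect, unique(annotation$lg))
  genotypes <- simulate_genotypes(config, annotation, sexchr)
  cds <- simulate_coding_sequences(config)
  traits <- simulate_traits(config, tree)
  structure(list(config = config, tree = tree, annotation = annotation,
                 counts = expr$counts, metadata = expr$metadata,
                 truth = expr$truth, bias_states = expr$bias_states,
                 dispersion = expr$dispersion,
                 genotypes = genotypes, sex_chromosomes = sexchr,
                 cds = cds, traits = traits),
            class = "sim_dataset")
}
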