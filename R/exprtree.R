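# Expression phylogenies: 1 - Spearman rho distances between species'
# mean expression profiles, neighbour-joining trees with gene bootstraps,
# root-to-tip divergence, Robinson-Foulds comparison to the species tree,
# and divergence-time regressions.

#' Spearman-correlation distance matrix between expression profiles
#'
#' Distance between two species' mean expression profiles is `1 - rho`
#' (Spearman's rank correlation, average ranks for ties), giving values in
#' `[0, 2]`.
#'
#' @param profiles Numeric matrix, genes x species (columns are the units to
#'   be related).
#' @return A symmetric `dist`-compatible matrix with zero diagonal.
#' @export
spearman_distance_matrix <- function(profiles) {
  if (ncol(profiles) < 2) stop("need at least 2 profiles")
  if (nrow(profiles) < 3) stop("need at least 3 genes to rank")
  const <- apply(profiles, 2, function(x) length(unique(x)) == 1)
  if (any(const))
    stop("constant profile (all ranks tied) for: ",
         paste(colnames(profiles)[const], collapse = ", "))
  1 - stats::cor(profiles, method = "spearman")
}

#' Neighbour-joining expression tree
#'
#' Builds an unrooted NJ tree from a distance matrix. Negative branch
#' lengths (which NJ can produce on noisy, non-additive matrices) are set to
#' zero and the deficit transferred to the adjacent descendant branches so
#' path lengths through the node are preserved as far as possible. On an
#' additive matrix the generating topology and branch lengths are recovered
#' exactly.
#'
#' @param d Symmetric distance matrix (>= 3 taxa, finite entries).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("non-finite distances")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    child <- tr$edge[e, 2]
    down <- which(tr$edge[, 1] == child)
    if (length(down) > 0)
      tr$edge.length[down] <- tr$edge.length[down] + deficit
    tr$edge.length[down][tr$edge.length[down] < 0] <- 0
  }
  tr
}

#' Bootstrap supports for an expression tree
#'
#' Resamples genes (rows of the profile matrix) with replacement, rebuilds
#' the NJ tree per replicate and reports, for each internal split of the
#' observed tree, the fraction of replicate trees containing that split.
#'
#' @param profiles Genes x species matrix.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `tree` (the observed NJ tree), `support` (per internal
#'   edge, in `[0, 1]`), and `n_boot`.
#' @export
bootstrap_supports <- function(profiles, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- nj_tree(spearman_distance_matrix(profiles))
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(profiles), replace = TRUE)
    boots[[b]] <- nj_tree(spearman_distance_matrix(profiles[idx, , drop = FALSE]))
  }
  cnt <- ape::prop.clades(obs, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  list(tree = obs, support = cnt / n_boot, n_boot = n_boot)
}

#' Root-to-tip path lengths
#'
#' Cumulative branch length from the root to every tip of a rooted tree, the
#' per-species measure of accumulated expression divergence.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @return Named numeric vector, one entry per tip.
#' @export
root_to_tip_lengths <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  nd <- ape::node.depth.edgelength(tree)
  stats::setNames(nd[seq_along(tree$tip.label)], tree$tip.label)
}

#' Root an expression tree for root-to-tip comparisons
#'
#' Roots at the given outgroup tip if supplied and present, otherwise by
#' midpoint rooting.
#'
#' @param tree Unrooted [ape::phylo].
#' @param outgroup Optional tip label.
#' @return Rooted tree.
#' @export
root_expression_tree <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup) && outgroup %in% tree$tip.label)
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  else phangorn::midpoint(tree)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the nontrivial bipartitions present in exactly one of the two
#' trees (identical tip sets required), plus a normalized variant dividing
#' by the total number of nontrivial splits in both trees.
#'
#' @param tree_a,tree_b [ape::phylo] trees over the same tips.
#' @return List with `rf` (integer) and `normalized`.
#' @export
rf_distance <- function(tree_a, tree_b) {
  diff <- setdiff(tree_a$tip.label, tree_b$tip.label)
  diff2 <- setdiff(tree_b$tip.label, tree_a$tip.label)
  if (length(diff) || length(diff2))
    stop("tip sets differ: ", paste(c(diff, diff2), collapse = ", "))
  ua <- ape::unroot(tree_a)
  ub <- ape::unroot(tree_b)
  rf <- phangorn::RF.dist(ua, ub, check.labels = TRUE)
  n_splits <- function(tr) max(0L, tr$Nnode - 1L)  # nontrivial splits, unrooted
  tot <- n_splits(ua) + n_splits(ub)
  list(rf = rf, normalized = if (tot > 0) rf / tot else 0)
}

#' Pairwise divergence times from an ultrametric species tree
#'
#' @param tree Ultrametric [ape::phylo] with branch lengths in time units.
#' @return Symmetric matrix of tip-to-tip path lengths (twice the MRCA age).
#' @export
divergence_times <- function(tree) ape::cophenetic.phylo(tree)

#' Expression similarity versus divergence time
#'
#' Correlates pairwise Spearman's rho of expression profiles with pairwise
#' divergence times from the time-calibrated species tree, and fits a
#' least-squares line (the divergence-time regression of expression
#' similarity).
#'
#' @param profiles Genes x species matrix (one gene class / organ / sex).
#' @param species_tree Ultrametric [ape::phylo]; tips must cover the
#'   profile columns.
#' @return List with `pairs` (data.frame: species_i, species_j, rho, t),
#'   `slope`, `intercept`, `cor` (Spearman of rho with t) and `p` (NA with
#'   fewer than 3 pairs).
#' @export
divergence_regression <- function(profiles, species_tree) {
  sp <- colnames(profiles)
  if (!all(sp %in% species_tree$tip.label))
    stop("profile species missing from tree")
  rho <- stats::cor(profiles, method = "spearman")
  tt <- divergence_times(species_tree)[sp, sp]
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  pairs <- data.frame(
    species_i = sp[idx[, 1]], species_j = sp[idx[, 2]],
    rho = rho[idx], t = tt[idx]
  )
  out <- list(pairs = pairs, slope = NA_real_, intercept = NA_real_,
              cor = NA_real_, p = NA_real_)
  if (nrow(pairs) >= 2 && stats::var(pairs$t) > 0) {
    fit <- stats::lm(rho ~ t, data = pairs)
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
  }
  if (nrow(pairs) >= 3 && stats::var(pairs$t) > 0 &&
      stats::var(pairs$rho) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(pairs$rho, pairs$t, method = "spearman"))
    out$cor <- unname(ct$estimate)
    out$p <- ct$p.value
  }
  out
}

#' Rate of expression change
#'
#' `(1 - rho) / t`: expression distance accumulated per unit divergence
#' time (e.g. per Myr).
#'
#' @param rho Spearman correlation between the two species' profiles.
#' @param t Divergence time (> 0).
#' @return The rate; `NA` when `t <= 0`.
#' @export
expression_rate <- function(rho, t) {
  out <- (1 - rho) / t
  out[t <= 0] <- NA_real_
  out
}

#' Per-linkage-group expression correlations
#'
#' Computes, separately for each linkage group, all pairwise between-species
#' Spearman correlations of mean expression, then compares the correlation
#' distributions across linkage groups with a Kruskal-Wallis test.
#'
#' @param profiles Genes x species matrix.
#' @param gene_lg Linkage-group label per gene (row).
#' @param min_genes Minimum genes per LG to be included (default 3).
#' @return List with `per_lg` (data.frame: lg, species_i, species_j, rho),
#'   `kruskal` (htest or NULL with a single LG), `excluded_lgs`.
#' @export
per_lg_correlation <- function(profiles, gene_lg, min_genes = 3) {
  stopifnot(nrow(profiles) == length(gene_lg))
  lgs <- split(seq_len(nrow(profiles)), gene_lg)
  small <- names(lgs)[lengths(lgs) < min_genes]
  lgs <- lgs[lengths(lgs) >= min_genes]
  res <- lapply(names(lgs), function(lg) {
    rho <- stats::cor(profiles[lgs[[lg]], , drop = FALSE],
                      method = "spearman")
    idx <- which(upper.tri(rho), arr.ind = TRUE)
    data.frame(lg = lg,
               species_i = colnames(rho)[idx[, 1]],
               species_j = colnames(rho)[idx[, 2]],
               rho = rho[idx])
  })
  per_lg <- do.call(rbind, res)
  kw <- if (length(lgs) >= 2)
    stats::kruskal.test(per_lg$rho, factor(per_lg$lg)) else NULL
  list(per_lg = per_lg, kruskal = kw, excluded_lgs = small)
}
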