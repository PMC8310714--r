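# Independent oracles and small fixture builders used across the suite.
# These deliberately recompute quantities by brute force (enumeration,
# hand-rolled formulas, numerical matrix exponentials) so they do not share
# code paths with the package implementation.

# brute-force per-gene Hudson Fst from raw genotypes: per-site allele
# frequencies by sex, moment components, ratio of sums
oracle_gene_fst <- function(gt, sex, use_sites = seq_len(nrow(gt))) {
  num <- den <- 0
  for (s in use_sites) {
    gm <- gt[s, sex == "M"]; gf <- gt[s, sex == "F"]
    gm <- gm[!is.na(gm)]; gf <- gf[!is.na(gf)]
    n1 <- 2 * length(gm); n2 <- 2 * length(gf)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(gm) / n1; p2 <- sum(gf) / n2
    a <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    b <- p1 * (1 - p2) + p2 * (1 - p1)
    num <- num + a
    den <- den + a + b
  }
  if (den == 0) NA_real_ else num / den
}

# pairwise-difference pi at a site by explicit haplotype enumeration
oracle_site_pi <- function(d, n) {
  hap <- c(rep(1, d), rep(0, n - d))
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + (hap[i] != hap[j])
  tot / choose(n, 2)
}

# 3-state equal-rates transition matrix via numerical eigen-decomposition
# (independent of the closed-form expression in the package)
oracle_mk3_P <- function(q, t) {
  Q <- matrix(q, 3, 3); diag(Q) <- -2 * q
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# total likelihood / best joint assignment by enumeration over all
# internal-state combinations; states are indices 1..3 matching
# c("U", "FBG", "MBG"); tip_states indexed in postorder tip order, NA = missing
oracle_mk3_enumerate <- function(tree, tip_states_idx, q) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  combos <- as.matrix(expand.grid(rep(list(1:3), tree$Nnode)))
  lik <- numeric(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    assign_full <- c(rep(NA_integer_, n_tip), combos[k, ])
    pr <- 1 / 3
    for (e in seq_len(nrow(tree$edge))) {
      p <- assign_full[tree$edge[e, 1]]
      ch <- tree$edge[e, 2]
      P <- oracle_mk3_P(q, tree$edge.length[e])
      if (ch <= n_tip) {
        st <- tip_states_idx[tree$tip.label[ch]]
        pr <- pr * if (is.na(st)) 1 else P[p, st]
      } else pr <- pr * P[p, assign_full[ch]]
    }
    lik[k] <- pr
  }
  list(total = sum(lik), best = combos[which.max(lik), ], liks = lik,
       combos = combos)
}

# nontrivial bipartitions of an unrooted tree as canonical strings
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n_tip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character()
  for (p in parts) {
    side <- sort(labs[p])
    if (length(side) <= 1 || length(side) >= n_tip - 1) next
    other <- setdiff(tips, side)
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  unique(out)
}

oracle_rf <- function(a, b) {
  pa <- oracle_bipartitions(a)
  pb <- oracle_bipartitions(b)
  length(setdiff(pa, pb)) + length(setdiff(pb, pa))
}

# small genotype fixture: explicit dosage matrix with full coverage
toy_genotypes <- function(gt_rows, sex, depth_value = 10) {
  gt <- do.call(rbind, gt_rows)
  depth <- matrix(depth_value, nrow(gt), ncol(gt))
  depth[is.na(gt)] <- 0
  list(gt = gt, depth = depth, sex = sex)
}
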