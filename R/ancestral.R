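# Ancestral reconstruction of sex-bias states: a 3-state equal-rates Mk
# model fitted by maximum likelihood (Felsenstein pruning), joint
# (max-product) reconstruction of internal-node states, branch-wise
# counting of gains and losses of male- and female-biased status, and
# phylogenetically controlled trait regression.

BIAS_STATES <- c("U", "FBG", "MBG")  # tie-break order: U first, then FBG

# P(t) for the 3-state equal-rates model: off-diagonal rate q.
mk3_pmat <- function(q, t) {
  e <- exp(-3 * q * t)
  p_same <- 1 / 3 + 2 / 3 * e
  p_diff <- 1 / 3 - 1 / 3 * e
  m <- matrix(p_diff, 3, 3)
  diag(m) <- p_same
  m
}

# tip partial-likelihood matrices (genes x 3) in tree tip order;
# missing states (NA) become uniform (1,1,1) rows.
mk3_tip_partials <- function(states, tree) {
  sp <- tree$tip.label
  if (!all(sp %in% colnames(states)))
    stop("state matrix lacks species: ",
         paste(setdiff(sp, colnames(states)), collapse = ", "))
  lapply(sp, function(s) {
    st <- states[, s]
    m <- matrix(1, nrow(states), 3, dimnames = list(NULL, BIAS_STATES))
    known <- !is.na(st)
    m[known, ] <- 0
    m[cbind(which(known), match(st[known], BIAS_STATES))] <- 1
    m
  })
}

# summed log-likelihood across genes by pruning; partials rescaled per node
# to avoid underflow.
mk3_loglik <- function(q, tree, tip_partials) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  n_gene <- nrow(tip_partials[[1]])
  partial <- vector("list", n_tip + n_node)
  partial[seq_len(n_tip)] <- tip_partials
  logscale <- numeric(n_gene)
  # postorder guarantees a child's partial is complete before the edge to
  # its parent is visited; messages are accumulated per edge
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    P <- mk3_pmat(q, tree$edge.length[e])
    msg <- partial[[child]] %*% t(P)
    acc <- if (is.null(partial[[p]])) msg else partial[[p]] * msg
    sc <- pmax(apply(acc, 1, max), .Machine$double.xmin)
    logscale <- logscale + log(sc)
    partial[[p]] <- acc / sc
  }
  root <- n_tip + 1L
  sum(log(partial[[root]] %*% rep(1 / 3, 3)) + logscale)
}

#' Fit the equal-rates Mk model of sex-bias evolution
#'
#' Maximizes the pruning log-likelihood of a single symmetric transition
#' rate q for the 3-state character {unbiased, FBG, MBG} over all genes
#' jointly on the species tree. Missing species entries are integrated out
#' with uniform tip partial likelihoods.
#'
#' @param states Character matrix genes x species with entries in
#'   `c("U", "FBG", "MBG")` or `NA` for missing.
#' @param tree [ape::phylo] with positive branch lengths.
#' @param q_max Upper search bound (default scaled to tree height).
#' @return List: `q`, `loglik`, `convergence` ("ok" or "boundary"),
#'   `n_genes`.
#' @export
fit_mk_equal_rates <- function(states, tree, q_max = NULL) {
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("tree must have positive branch lengths")
  if (nrow(states) < 1) stop("need at least one gene")
  tp <- mk3_tip_partials(states, tree)
  height <- max(ape::node.depth.edgelength(tree))
  if (is.null(q_max)) q_max <- 100 / height
  # monomorphic data: likelihood maximized at the q = 0 boundary
  mono <- all(apply(states, 1, function(x) length(unique(stats::na.omit(x))) <= 1))
  if (mono)
    return(list(q = 0, loglik = mk3_loglik(1e-12, tree, tp),
                convergence = "boundary", n_genes = nrow(states)))
  opt <- stats::optimize(function(q) mk3_loglik(q, tree, tp),
                         interval = c(0, q_max),
                         maximum = TRUE, tol = 1e-8 * q_max)
  conv <- if (opt$maximum < 1e-6 * q_max || opt$maximum > 0.999 * q_max)
    "boundary" else "ok"
  list(q = opt$maximum, loglik = opt$objective, convergence = conv,
       n_genes = nrow(states))
}

#' Joint ancestral reconstruction of sex-bias states
#'
#' For every gene, finds the jointly most probable assignment of states to
#' the internal nodes by max-product dynamic programming over the tree
#' (fitted rate q, uniform root prior). Ties are broken towards "U", then
#' "FBG", then "MBG".
#'
#' @param states Character matrix genes x species (see
#'   [fit_mk_equal_rates()]).
#' @param tree [ape::phylo].
#' @param q Fitted transition rate.
#' @return Character matrix genes x nodes (columns: tips in tip order, then
#'   internal nodes "node<N>"; tip columns echo the observed states, with
#'   missing tips assigned their most probable state).
#' @export
joint_ancestral_states <- function(states, tree, q) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  n_gene <- nrow(states)
  tp <- mk3_tip_partials(states, tree)
  logtp <- lapply(tp, function(m) ifelse(m > 0, 0, -Inf))
  V <- vector("list", n_all)
  V[seq_len(n_tip)] <- logtp
  ptr <- vector("list", nrow(tree$edge))   # genes x 3: best child state per parent state
  q <- max(q, 1e-12)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    logP <- log(mk3_pmat(q, tree$edge.length[e]))
    best <- matrix(0, n_gene, 3)
    arg <- matrix(0L, n_gene, 3)
    for (j in 1:3) {
      cand <- sweep(V[[child]], 2, logP[j, ], "+")
      arg[, j] <- max.col(cand, ties.method = "first")
      best[, j] <- cand[cbind(seq_len(n_gene), arg[, j])]
    }
    ptr[[e]] <- arg
    V[[p]] <- if (is.null(V[[p]])) best else V[[p]] + best
  }
  root <- n_tip + 1L
  assign_state <- matrix(0L, n_gene, n_all)
  assign_state[, root] <- max.col(V[[root]], ties.method = "first")
  for (e in rev(seq_len(nrow(tree$edge)))) {   # preorder on postorder-sorted edges
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    assign_state[, child] <- ptr[[e]][cbind(seq_len(n_gene),
                                            assign_state[, parent])]
  }
  out <- matrix(BIAS_STATES[assign_state], n_gene, n_all)
  colnames(out) <- c(tree$tip.label, paste0("node", (n_tip + 1L):n_all))
  rownames(out) <- rownames(states)
  out
}

#' Count gains and losses of sex-biased status per branch
#'
#' Compares parent and child states on every branch, per gene: a child
#' becoming MBG from any other state is a gain of MBG; an MBG parent whose
#' child is not MBG is a loss of MBG (so a direct MBG -> FBG flip counts as
#' one loss of MBG plus one gain of FBG); symmetrically for FBG. Also
#' tallies reconstructed MBG/FBG gene counts per internal node.
#'
#' @param node_states Genes x nodes matrix from [joint_ancestral_states()].
#' @param tree The same tree (will be put in postorder to match columns).
#' @return List: `branches` (data.frame per edge: parent, child,
#'   child_label, gains_MBG, losses_MBG, gains_FBG, losses_FBG), `nodes`
#'   (data.frame per internal node: n_MBG, n_FBG, n_U).
#' @export
count_turnovers <- function(node_states, tree) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  lab <- colnames(node_states)
  branches <- data.frame(
    parent = tree$edge[, 1], child = tree$edge[, 2],
    child_label = lab[tree$edge[, 2]],
    gains_MBG = 0L, losses_MBG = 0L, gains_FBG = 0L, losses_FBG = 0L
  )
  for (e in seq_len(nrow(tree$edge))) {
    p <- node_states[, tree$edge[e, 1]]
    c_ <- node_states[, tree$edge[e, 2]]
    branches$gains_MBG[e] <- sum(p != "MBG" & c_ == "MBG")
    branches$losses_MBG[e] <- sum(p == "MBG" & c_ != "MBG")
    branches$gains_FBG[e] <- sum(p != "FBG" & c_ == "FBG")
    branches$losses_FBG[e] <- sum(p == "FBG" & c_ != "FBG")
  }
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  nodes <- data.frame(
    node = lab[internal],
    n_MBG = colSums(node_states[, internal, drop = FALSE] == "MBG"),
    n_FBG = colSums(node_states[, internal, drop = FALSE] == "FBG"),
    n_U = colSums(node_states[, internal, drop = FALSE] == "U")
  )
  list(branches = branches, nodes = nodes)
}

#' Phylogenetically controlled trait regression (PGLS)
#'
#' Fits `response ~ trait` by generalized least squares with a Brownian
#' covariance structure derived from the species tree (shared root-to-MRCA
#' path lengths), maximum-likelihood fit. Used to ask whether per-species
#' turnover counts on terminal branches track traits such as sperm
#' competition rank.
#'
#' @param response Named numeric vector (names = species / tree tips), e.g.
#'   terminal-branch turnover counts.
#' @param trait Named numeric vector over the same species.
#' @param tree [ape::phylo] containing those species as tips.
#' @return List: `coefficients` (data.frame: term, estimate, se, t, p),
#'   `fit` (the gls object), `n`.
#' @export
pgls_trait_association <- function(response, trait, tree) {
  sp <- intersect(names(response), names(trait))
  sp <- intersect(sp, tree$tip.label)
  sp <- sp[!is.na(response[sp]) & !is.na(trait[sp])]
  if (length(sp) < 4) stop("need >= 4 species with complete data")
  if (stats::var(trait[sp]) == 0) stop("trait is constant: slope undefined")
  tr <- ape::keep.tip(tree, sp)
  dat <- data.frame(species = sp, y = as.numeric(response[sp]),
                    x = as.numeric(trait[sp]))
  fit <- nlme::gls(y ~ x, data = dat,
                   correlation = ape::corBrownian(phy = tr, form = ~species),
                   method = "ML")
  tt <- summary(fit)$tTable
  list(coefficients = data.frame(term = rownames(tt),
                                 estimate = tt[, "Value"],
                                 se = tt[, "Std.Error"],
                                 t = tt[, "t-value"],
                                 p = tt[, "p-value"],
                                 row.names = NULL),
       fit = fit, n = length(sp))
}
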