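# Mk equal-rates fitting, joint ancestral states, turnover counting, PGLS.

idx_of <- function(x) match(x, c("U", "FBG", "MBG"))

test_that("pruning likelihood equals exhaustive enumeration on small trees", {
  trees <- list(
    ape::read.tree(text = "((A:0.3,B:0.5):0.4,(C:0.2,D:0.6):0.3);"),
    ape::read.tree(text = "(((A:0.2,B:0.2):0.2,(C:0.3,D:0.1):0.4):0.3,(E:0.5,F:0.2):0.4);")
  )
  set.seed(15)
  for (tr in trees) {
    n <- length(tr$tip.label)
    for (q in c(0.2, 0.9)) {
      states <- matrix(sample(c("U", "FBG", "MBG", NA), 3 * n, replace = TRUE,
                              prob = c(0.3, 0.3, 0.3, 0.1)),
                       3, n, dimnames = list(NULL, tr$tip.label))
      ll <- sbgevol:::mk3_loglik(q, tr, sbgevol:::mk3_tip_partials(states, tr))
      enum <- sum(vapply(1:3, function(g) {
        log(oracle_mk3_enumerate(tr, setNames(idx_of(states[g, ]),
                                              colnames(states)), q)$total)
      }, numeric(1)))
      expect_equal(ll, enum, tolerance = 1e-10)
    }
  }
})

test_that("joint reconstruction equals the enumeration argmax", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.5):0.4,(C:0.2,D:0.6):0.3);")
  set.seed(16)
  for (rep in 1:10) {
    states <- matrix(sample(c("U", "FBG", "MBG"), 4, replace = TRUE), 1, 4,
                     dimnames = list(NULL, tr$tip.label))
    q <- runif(1, 0.1, 1)
    anc <- joint_ancestral_states(states, tr, q)
    enum <- oracle_mk3_enumerate(tr, setNames(idx_of(states[1, ]),
                                              colnames(states)), q)
    # compare joint probabilities, not labels, so ties cannot misfire
    tr_post <- stats::reorder(tr, "postorder")
    got_idx <- idx_of(anc[1, paste0("node", 5:7)])
    pick <- apply(enum$combos, 1, function(z) all(z == got_idx))
    expect_equal(max(enum$liks), enum$liks[pick], tolerance = 1e-10)
  }
})

test_that("unanimous tips reconstruct as the same state; huge q ties go to U", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- matrix("MBG", 2, 4, dimnames = list(NULL, tr$tip.label))
  anc <- joint_ancestral_states(states, tr, 0.3)
  expect_true(all(anc == "MBG"))
  # q -> infinity: transition matrix flat, tie broken towards U
  anc_flat <- joint_ancestral_states(states, tr, 1e8)
  expect_true(all(anc_flat[, paste0("node", 5:7)] == "U"))
  # 3 MBG tips vs 1 unbiased, small q: root reconstructs MBG
  st2 <- matrix(c("MBG", "MBG", "MBG", "U"), 1, 4,
                dimnames = list(NULL, tr$tip.label))
  anc2 <- joint_ancestral_states(st2, tr, 0.05)
  expect_equal(unname(anc2[1, "node5"]), "MBG")
})

test_that("the ML rate is recovered and scales inversely with branch lengths", {
  cfg <- sim_config(n_species = 10, seed = 17)
  tree <- simulate_tree(cfg)
  bs <- sim_bias_states(tree, q = 0.5, n_genes = 1200, seed = 18)
  fit <- fit_mk_equal_rates(bs$tip_states, tree)
  expect_equal(fit$q, 0.5, tolerance = 0.15)
  expect_equal(fit$convergence, "ok")
  # time-rate scaling identity
  tree_k <- tree
  tree_k$edge.length <- 4 * tree_k$edge.length
  fit_k <- fit_mk_equal_rates(bs$tip_states, tree_k)
  expect_equal(fit_k$q, fit$q / 4, tolerance = 1e-3)
  # monomorphic data pin q at the boundary
  mono <- matrix("U", 5, 10, dimnames = list(NULL, tree$tip.label))
  fit0 <- fit_mk_equal_rates(mono, tree)
  expect_equal(fit0$q, 0)
  expect_equal(fit0$convergence, "boundary")
})

test_that("turnover counting applies the gain/loss rules and telescopes along paths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  # columns: A, B, C, node4 (root), node5
  ns <- matrix(c("MBG", "U", "FBG", "U", "MBG"), 1, 5,
               dimnames = list("g1", c("A", "B", "C", "node4", "node5")))
  turn <- count_turnovers(ns, tr)
  br <- turn$branches
  # root -> C stays U->FBG: gain FBG; root -> node5 U->MBG: gain MBG;
  # node5 -> A MBG->MBG: nothing; node5 -> B MBG->U: loss MBG
  expect_equal(sum(br$gains_MBG), 1)
  expect_equal(sum(br$losses_MBG), 1)
  expect_equal(sum(br$gains_FBG), 1)
  expect_equal(sum(br$losses_FBG), 0)
  expect_equal(br$losses_MBG[br$child_label == "B"], 1)
  # MBG -> FBG counts one loss and one gain on the same branch
  ns2 <- matrix(c("FBG", "MBG", "MBG", "MBG", "MBG"), 1, 5,
                dimnames = list("g1", c("A", "B", "C", "node4", "node5")))
  br2 <- count_turnovers(ns2, tr)$branches
  expect_equal(br2$losses_MBG[br2$child_label == "A"], 1)
  expect_equal(br2$gains_FBG[br2$child_label == "A"], 1)
  # path telescoping: per tip, gains - losses along the root path equals
  # the indicator change from root to tip, per direction
  cfg <- sim_config(n_species = 8, seed = 19)
  tree <- simulate_tree(cfg)
  bs <- sim_bias_states(tree, q = 0.4, n_genes = 50, seed = 20)
  tpost <- stats::reorder(tree, "postorder")
  tt <- count_turnovers(bs$node_states, tpost)
  root_lab <- paste0("node", length(tpost$tip.label) + 1)
  for (tip in tpost$tip.label) {
    path <- character()
    node <- which(tpost$tip.label == tip)
    repeat {
      e <- which(tpost$edge[, 2] == node)
      if (length(e) == 0) break
      path <- c(path, e)
      node <- tpost$edge[e, 1]
    }
    e_idx <- as.integer(path)
    for (dir in c("MBG", "FBG")) {
      net <- sum(tt$branches[e_idx, paste0("gains_", dir)]) -
        sum(tt$branches[e_idx, paste0("losses_", dir)])
      expected <- sum(bs$node_states[, tip] == dir) -
        sum(bs$node_states[, root_lab] == dir)
      expect_equal(net, expected)
    }
  }
  # reconstruction recovers true transition counts under strong signal
  bs_low <- sim_bias_states(tree, q = 0.05, n_genes = 200, seed = 21)
  fit <- fit_mk_equal_rates(bs_low$tip_states, tree)
  anc <- joint_ancestral_states(bs_low$tip_states, tree, fit$q)
  got <- count_turnovers(anc, tree)$branches
  truth <- count_turnovers(bs_low$node_states, tpost)$branches
  tot_got <- sum(got$gains_MBG + got$losses_MBG + got$gains_FBG + got$losses_FBG)
  tot_true <- sum(truth$gains_MBG + truth$losses_MBG +
                    truth$gains_FBG + truth$losses_FBG)
  expect_equal(tot_got, tot_true, tolerance = 0.25)
})

test_that("PGLS equals OLS on a star tree and recovers a planted slope", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(22)
  x <- setNames(rnorm(6), star$tip.label)
  y <- setNames(2 * x + rnorm(6, sd = 0.5), star$tip.label)
  fit <- pgls_trait_association(y, x, star)
  ols <- lm(y ~ x)
  expect_equal(fit$coefficients$estimate,
               unname(coef(ols)), tolerance = 1e-6)
  expect_error(pgls_trait_association(y, setNames(rep(1, 6), names(x)), star),
               "constant")
  # recovery: response = 2 * trait + Brownian noise on a real tree
  cfg <- sim_config(n_species = 12, seed = 23)
  tree <- simulate_tree(cfg)
  hits <- 0
  n_rep <- 25
  for (r in 1:n_rep) {
    set.seed(100 + r)
    trait <- setNames(rnorm(12), tree$tip.label)
    noise <- ape::rTraitCont(tree, sigma = 0.4)
    y <- 2 * trait + noise[tree$tip.label]
    f <- pgls_trait_association(y, trait, tree)
    co <- f$coefficients[f$coefficients$term == "x", ]
    ci <- co$estimate + c(-1, 1) * qt(0.975, f$n - 2) * co$se
    if (ci[1] <= 2 && 2 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})
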