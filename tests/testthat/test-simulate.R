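# The synthetic-data generator: determinism, planted signals, degenerate
# configurations.

test_that("tree simulation honours the mode, tip count and seed", {
  cfg_fix <- sim_config(tree_mode = "fixed_newick",
                        fixed_newick = "((A:1,B:1):1,C:2);")
  tr <- simulate_tree(cfg_fix)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)
  cfg <- sim_config(n_species = 14, seed = 1)
  t1 <- simulate_tree(cfg)
  expect_equal(length(t1$tip.label), 14)
  rtt <- ape::node.depth.edgelength(t1)[1:14]
  expect_equal(rtt, rep(cfg$tree_height, 14), tolerance = 1e-8)  # ultrametric
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(sim_config(n_species = 1), "n_species")
  expect_error(sim_config(replicates_per_sex_organ = 1), "two replicates")
})

test_that("a null configuration produces equal sex means", {
  cfg <- sim_config(n_species = 3, organs = "gonad", n_genes = 150,
                    sbg_fraction_per_organ = c(gonad = 0),
                    nb_dispersion_meanlog = log(1e-4),
                    nb_dispersion_sdlog = 1e-4,
                    brownian_rate = 1e-12,
                    replicates_per_sex_organ = 30, seed = 41)
  sim <- simulate_expression_counts(cfg, simulate_tree(cfg))
  md <- sim$metadata
  expect_equal(nrow(sim$truth), 0)
  m <- rowMeans(sim$counts[, md$sample_id[md$sex == "M"]])
  f <- rowMeans(sim$counts[, md$sample_id[md$sex == "F"]])
  keep <- (m + f) / 2 > 20
  expect_lt(median(abs(log2((m[keep] + 0.5) / (f[keep] + 0.5)))), 0.15)
})

test_that("planted fold changes are realized at large replicate numbers", {
  cfg <- sim_config(n_species = 2, organs = "gonad", n_genes = 300,
                    sbg_fraction_per_organ = c(gonad = 0.2),
                    replicates_per_sex_organ = 50, seed = 42)
  sim <- simulate_expression_counts(cfg, simulate_tree(cfg))
  md <- sim$metadata
  sel_m <- md$sample_id[md$species == "sp01" & md$sex == "M"]
  sel_f <- md$sample_id[md$species == "sp01" & md$sex == "F"]
  truth <- sim$truth[sim$truth$species == "sp01", ]
  emp <- log2((rowMeans(sim$counts[truth$gene_id, sel_m]) + 0.5) /
                (rowMeans(sim$counts[truth$gene_id, sel_f]) + 0.5))
  expect_lt(median(abs(emp - truth$lfc)), 0.2)
  expect_true(all(sign(emp[abs(truth$lfc) > 3]) ==
                    sign(truth$lfc[abs(truth$lfc) > 3])))
})

test_that("between-tip expression correlation decays with divergence on average", {
  # Monte-Carlo over seeds: corr(rho_ij, t_ij) < 0 on average
  cors <- vapply(1:20, function(s) {
    cfg <- sim_config(n_species = 6, organs = "gonad", n_genes = 150,
                      sbg_fraction_per_organ = c(gonad = 0),
                      brownian_rate = 0.3,
                      replicates_per_sex_organ = 2, seed = 500 + s)
    tree <- simulate_tree(cfg)
    sim <- simulate_expression_counts(cfg, tree)
    prof <- mean_expression_profiles(sim$counts, sim$metadata, "gonad")
    rho <- cor(log2(prof + 1), method = "spearman")
    tt <- divergence_times(tree)[colnames(rho), colnames(rho)]
    cor(rho[upper.tri(rho)], tt[upper.tri(tt)])
  }, numeric(1))
  expect_lt(mean(cors), -0.2)
})

test_that("genotype simulation enforces the XY construction and dropout", {
  cfg <- sim_config(n_species = 2, n_genes = 30, n_lgs = 20,
                    xy_fraction = 1, coverage_dropout = 0, seed = 43)
  ann <- simulate_annotation(cfg)
  gen <- simulate_genotypes(cfg, ann, list(spA = "LG19", spB = character(0)))
  g <- gen$spA
  onxy <- g$site_pos$lg == "LG19"
  expect_true(all(g$truth_divergent[onxy]))
  gm <- g$gt[onxy, g$sex == "M"]   # covered calls only: depth 0 is missing
  gf <- g$gt[onxy, g$sex == "F"]
  expect_true(all(gm[!is.na(gm)] == 1L))
  expect_true(all(gf[!is.na(gf)] == 0L))
  # full dropout fails every site downstream
  cfg_d <- sim_config(n_species = 2, n_genes = 10, coverage_dropout = 1,
                      seed = 44)
  ann_d <- simulate_annotation(cfg_d)
  gen_d <- simulate_genotypes(cfg_d, ann_d, list(spA = character(0)))
  gd <- gen_d$spA
  st <- popgen_gene_stats(gd$gt, gd$depth, gd$sex, gd$site_pos, ann_d)
  expect_true(all(st$n_covered_sites == 0))
  expect_true(all(is.na(st$fst)))
  # unknown sex-linked LG is rejected
  expect_error(simulate_genotypes(cfg, ann, list(spA = "LG99")), "LG99")
})

test_that("XY-region Fst exceeds the autosomal mean across seeds", {
  diffs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_species = 2, n_genes = 40, n_lgs = 8,
                      organs = "gonad", xy_fraction = 0.15,
                      theta = 0.03, seed = 600 + s)
    ann <- simulate_annotation(cfg)
    gen <- simulate_genotypes(cfg, ann, list(spA = "LG5"))
    g <- gen$spA
    st <- popgen_gene_stats(g$gt, g$depth, g$sex, g$site_pos, ann)
    mean(st$fst[st$lg == "LG5"], na.rm = TRUE) -
      mean(st$fst[st$lg != "LG5"], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("the evolved bias character matches the recorded history", {
  cfg <- sim_config(n_species = 8, seed = 45)
  tree <- simulate_tree(cfg)
  bs1 <- sim_bias_states(tree, 0.5, 100, seed = 9)
  bs2 <- sim_bias_states(tree, 0.5, 100, seed = 9)
  expect_identical(bs1, bs2)
  expect_true(all(bs1$node_states %in% c("U", "FBG", "MBG")))
  expect_equal(bs1$tip_states, bs1$node_states[, tree$tip.label])
  # very low rate: tips nearly always inherit the root state
  bs_low <- sim_bias_states(tree, 1e-6, 200, seed = 10)
  agree <- rowSums(bs_low$tip_states ==
                     bs_low$node_states[, "node9"]) == 8
  expect_gt(mean(agree), 0.99)
})

test_that("the full dataset is byte-reproducible under one seed", {
  cfg <- sim_config(n_species = 4, n_genes = 60, organs = c("gonad", "liver"),
                    seed = 46)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$cds, d2$cds)
  expect_identical(d1$truth, d2$truth)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  # annotation covers every gene in the counts exactly once
  expect_setequal(rownames(d1$counts), d1$annotation$gene_id)
  expect_equal(anyDuplicated(d1$annotation$gene_id), 0)
})
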