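# Normalization, QC and sex-bias calling.

test_that("the count filter keeps any gene with total >= 1", {
  m <- matrix(c(0, 0, 0,   1, 0, 0,   4, 3, 3), 3, byrow = TRUE,
              dimnames = list(c("zero", "one", "ten"), c("s1", "s2", "s3")))
  f <- filter_low_count_genes(m)
  expect_equal(rownames(f), c("one", "ten"))   # total 1 is not < 1
  expect_warning(filter_low_count_genes(m[1, , drop = FALSE]), "no gene")
})

test_that("TMM factors behave on identity, doubling and degenerate inputs", {
  set.seed(24)
  a <- rpois(200, 40)
  m_id <- cbind(s1 = a, s2 = a, s3 = a)
  rownames(m_id) <- sprintf("g%03d", 1:200)
  f <- tmm_normalize(m_id)
  expect_equal(unname(f$factors), rep(1, 3), tolerance = 1e-12)
  expect_equal(exp(mean(log(f$factors))), 1, tolerance = 1e-12)
  # doubled library: normalized counts coincide
  m2 <- cbind(A = a, B = 2L * a)
  rownames(m2) <- rownames(m_id)
  n2 <- tmm_normalize(m2)$normalized
  expect_equal(n2[, "A"], n2[, "B"], tolerance = 1e-10)
  # single sample
  f1 <- tmm_normalize(m_id[, 1, drop = FALSE])
  expect_equal(unname(f1$factors), 1)
  # zero-count sample is refused by name
  m0 <- m_id; m0[, 2] <- 0L
  expect_error(tmm_normalize(m0), "s2")
})

test_that("bias categories hit the printed bin boundaries", {
  expect_equal(assign_bias_category(c(2, 2.5, 2.6, 4.1, 6.5)),
               c("none", "low", "mid", "high", "extreme"))
  expect_equal(assign_bias_category(-3), "mid")       # applied to |LFC|
  expect_equal(assign_bias_category(2.0000001), "low")
  expect_equal(assign_bias_category(100), "extreme")
})

test_that("sex-label swap flips every LFC and preserves p-values", {
  cfg <- sim_config(n_species = 2, organs = "gonad", n_genes = 400,
                    replicates_per_sex_organ = 3, seed = 25)
  sim <- simulate_expression_counts(cfg, simulate_tree(cfg))
  md <- sim$metadata
  sel <- md$species == "sp01"
  cts <- sim$counts[, md$sample_id[sel]]
  sx <- md$sex[sel]
  t1 <- test_sex_bias(cts, sx)
  t2 <- test_sex_bias(cts, ifelse(sx == "M", "F", "M"))
  expect_equal(t1$lfc, -t2$lfc, tolerance = 1e-12)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  expect_equal(t1$padj, t2$padj, tolerance = 1e-12)
  # direction/category invariants hold row-wise
  called <- t1$direction != "unbiased"
  expect_true(all(t1$padj[called] < 0.05))
  expect_true(all(abs(t1$lfc[called]) > 2))
  expect_true(all(t1$category[!called] == "none"))
  expect_true(all(t1$category[called] != "none"))
  expect_error(test_sex_bias(cts, rep(c("M", "F"), c(1, 5))), "two replicates")
})

test_that("planted sex bias is recovered and the null stays calibrated", {
  # power: large replicate number, mid-or-stronger planted LFCs
  cfg <- sim_config(n_species = 2, organs = "gonad", n_genes = 800,
                    sbg_fraction_per_organ = c(gonad = 0.1),
                    sbg_lfc_mixture = c(low = 0, mid = 0.5, high = 0.3,
                                        extreme = 0.2),
                    replicates_per_sex_organ = 50, seed = 26)
  sim <- simulate_expression_counts(cfg, simulate_tree(cfg))
  md <- sim$metadata
  sel <- md$species == "sp01"
  tab <- test_sex_bias(sim$counts[, md$sample_id[sel]], md$sex[sel])
  truth <- sim$truth[sim$truth$species == "sp01", ]
  called <- tab$gene_id[tab$direction != "unbiased"]
  expect_gte(mean(truth$gene_id %in% called), 0.9)
  expect_lte(mean(!called %in% truth$gene_id), 0.1)
  # empirical LFC close to the planted value at 50 replicates
  norm <- tmm_normalize(filter_low_count_genes(sim$counts[, md$sample_id[sel]]))$normalized
  sub <- truth[match(intersect(truth$gene_id, rownames(norm)), truth$gene_id), ]
  sxx <- md$sex[sel]
  emp <- log2((rowMeans(norm[sub$gene_id, sxx == "M"]) + 0.5) /
                (rowMeans(norm[sub$gene_id, sxx == "F"]) + 0.5))
  expect_lt(median(abs(emp - sub$lfc)), 0.3)
  # null calibration at the study replicate number
  cfg0 <- sim_config(n_species = 2, organs = "gonad", n_genes = 2000,
                     sbg_fraction_per_organ = c(gonad = 0), seed = 27)
  sim0 <- simulate_expression_counts(cfg0, simulate_tree(cfg0))
  md0 <- sim0$metadata
  sel0 <- md0$species == "sp01"
  tab0 <- test_sex_bias(sim0$counts[, md0$sample_id[sel0]], md0$sex[sel0])
  se <- sqrt(0.05 * 0.95 / sum(!is.na(tab0$p)))
  expect_lte(mean(tab0$p < 0.05, na.rm = TRUE), 0.05 + 3 * se)
  expect_equal(sum(tab0$direction != "unbiased"), 0)
})

test_that("BH adjustment is the step-up procedure and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(28)
  for (i in 1:10) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("QC flags low-signal, sex-swapped and organ-misplaced samples", {
  cfg <- sim_config(n_species = 2, organs = c("gonad", "liver"),
                    n_genes = 400, replicates_per_sex_organ = 4,
                    sbg_fraction_per_organ = c(gonad = 0.4, liver = 0.4),
                    sbg_lfc_mixture = c(low = 0, mid = 0, high = 0.5,
                                        extreme = 0.5), seed = 29)
  sim <- simulate_expression_counts(cfg, simulate_tree(cfg))
  counts <- sim$counts
  md <- sim$metadata
  clean <- qc_flag_samples(counts, md)
  expect_equal(nrow(clean), 0)
  # all-zero sample
  c2 <- counts
  c2[, 3] <- 0L
  fl <- qc_flag_samples(c2, md)
  expect_true(any(fl$sample_id == colnames(c2)[3] & fl$flag == "low_signal"))
  # a male sample generated under the female model: swap its label
  md_sw <- md
  f_samp <- md$sample_id[md$species == "sp01" & md$organ == "gonad" &
                           md$sex == "F"][1]
  md_sw$sex[md_sw$sample_id == f_samp] <- "M"
  fl2 <- qc_flag_samples(counts, md_sw)
  expect_true(any(fl2$sample_id == f_samp & fl2$flag == "sex_mismatch"))
})

test_that("sharing summaries enumerate shared and specific SBGs", {
  bt <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3"),
    species = c("A", "A", "B", "B"),
    organ = "gonad",
    direction = "MBG"
  )
  s <- shared_sbg_sets(bt)
  expect_equal(s$n_shared, 1)        # g2
  expect_equal(s$n_specific, 2)      # g1, g3
  expect_equal(s$fraction_shared, 1 / 3)
  # identical sets across species
  bt2 <- data.frame(gene_id = rep(c("g1", "g2"), 3),
                    species = rep(c("A", "B", "C"), each = 2),
                    organ = "gonad", direction = "FBG")
  expect_equal(shared_sbg_sets(bt2)$fraction_shared, 1)
  # disjoint sets
  bt3 <- data.frame(gene_id = c("g1", "g2"), species = c("A", "B"),
                    organ = "gonad", direction = "MBG")
  expect_equal(shared_sbg_sets(bt3)$fraction_shared, 0)
})

test_that("the variance sanity check reports rho and degeneracies", {
  sbg <- data.frame(species = rep(c("A", "B", "C", "D"), 2),
                    organ = rep(c("gonad", "liver"), each = 4),
                    n_sbg = c(10, 20, 30, 40, 1, 2, 3, 4))
  mv <- data.frame(species = rep(c("A", "B", "C", "D"), 2),
                   organ = rep(c("gonad", "liver"), each = 4),
                   med_var = c(1, 2, 3, 4, 4, 3, 2, 1))
  out <- expression_variance_check(sbg, mv)
  expect_equal(out$rho[out$scope == "gonad"], 1)
  expect_equal(out$rho[out$scope == "liver"], -1)
  # constant variance: rho undefined
  mv0 <- mv; mv0$med_var <- 1
  out0 <- expression_variance_check(sbg, mv0)
  expect_true(all(is.na(out0$rho)))
})
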