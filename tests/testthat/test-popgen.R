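# Population-genetic statistics: Hudson Fst components, ratio-of-sums
# aggregation, pi, Tajima's D, SFS, site filters.

test_that("Hudson alpha/beta match the moment formulas on worked cases", {
  # fixed difference
  ab <- hudson_alpha_beta(1, 10, 0, 10)
  expect_equal(ab$alpha, 1)
  expect_equal(ab$beta, 1)
  # identical intermediate frequencies: negative alpha
  ab <- hudson_alpha_beta(0.5, 10, 0.5, 10)
  expect_equal(ab$alpha, -1 / 18, tolerance = 1e-12)
  expect_equal(ab$beta, 0.5)
  # XY-divergent site pattern: males 0.5, females 0
  ab <- hudson_alpha_beta(0.5, 10, 0, 10)
  expect_equal(ab$alpha, 0.25 - 0.25 / 9, tolerance = 1e-12)
  expect_equal(ab$beta, 0.5)
  expect_equal(ab$alpha / (ab$alpha + ab$beta), 0.30769, tolerance = 1e-4)
})

test_that("alpha/beta are symmetric in the two groups and reject bad input", {
  set.seed(1)
  for (i in 1:20) {
    p1 <- runif(1); p2 <- runif(1)
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    a <- hudson_alpha_beta(p1, n1, p2, n2)
    b <- hudson_alpha_beta(p2, n2, p1, n1)
    expect_equal(a$alpha, b$alpha, tolerance = 1e-12)
    expect_equal(a$beta, b$beta, tolerance = 1e-12)
  }
  expect_true(is.na(hudson_alpha_beta(0.5, 1, 0.5, 10)$alpha))
  expect_error(hudson_alpha_beta(1.2, 10, 0, 10), "\\[0, 1\\]")
})

test_that("per-gene Fst is the ratio of sums, including negative alpha", {
  expect_equal(gene_fst_ratio_of_sums(c(1, -1 / 18), c(1, 0.5)),
               (1 - 1 / 18) / (1 - 1 / 18 + 1.5), tolerance = 1e-12)
  expect_equal(gene_fst_ratio_of_sums(1, 1), 0.5)  # single fixed-ratio site
  expect_true(is.na(gene_fst_ratio_of_sums(numeric(0), numeric(0))))
  expect_true(is.na(gene_fst_ratio_of_sums(c(0.5, -0.5), c(-0.25, 0.25))))
})

test_that("site pi equals pairwise-difference enumeration and is symmetric", {
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(2, 4), oracle_site_pi(2, 4), tolerance = 1e-12)
  expect_equal(site_pi(2, 4), 2 / 3, tolerance = 1e-12)
  for (n in c(4, 6, 9)) {
    pis <- site_pi(0:n, rep(n, n + 1))
    expect_equal(pis, site_pi(n:0, rep(n, n + 1)))      # allele relabelling
    expect_equal(which.max(pis) - 1,
                 if (n %% 2 == 0) n / 2 else (n - 1) / 2) # maximized near n/2
    for (d in 0:n) expect_equal(pis[d + 1], oracle_site_pi(d, n),
                                tolerance = 1e-12)
  }
})

test_that("coverage-corrected gene pi divides by covered sites", {
  expect_equal(gene_pi_corrected(c(1, 0.6667), 100), 1.6667 / 100)
  expect_equal(gene_pi_corrected(numeric(0), 50), 0)
  # halving the denominator doubles the value
  expect_equal(gene_pi_corrected(c(0.5, 0.3), 40),
               2 * gene_pi_corrected(c(0.5, 0.3), 80))
  expect_true(is.na(gene_pi_corrected(numeric(0), 0)))
})

test_that("Tajima's D reproduces the hand-evaluated 1989 worked example", {
  # n = 4 copies, derived counts {1, 1, 2}
  pi_total <- oracle_site_pi(1, 4) + oracle_site_pi(1, 4) + oracle_site_pi(2, 4)
  expect_equal(pi_total, 5 / 3, tolerance = 1e-12)
  expect_equal(tajimas_d(3, pi_total, 4), 0.168, tolerance = 1e-2)
  expect_equal(tajimas_d(3, pi_total, 4), 0.1676558, tolerance = 1e-6)
  expect_true(is.na(tajimas_d(0, 0, 4)))
  # excess singletons drive D negative
  S <- 40
  pi_sing <- S * oracle_site_pi(1, 20)
  expect_lt(tajimas_d(S, pi_sing, 20), 0)
})

test_that("SFS counting and folding behave as expected", {
  sfs <- build_sfs(c(1, 1, 2), 4)
  expect_equal(unname(sfs), c(0, 2, 1, 0, 0))
  expect_equal(unname(build_sfs(3, 4, folded = TRUE)), c(0, 1, 0))
  set.seed(2)
  d <- sample(0:8, 50, replace = TRUE)
  expect_equal(sum(build_sfs(d, 8, folded = TRUE)), sum(build_sfs(d, 8)))
})

test_that("site filters implement the coverage rules", {
  sites <- data.frame(n_ind = c(2, 3, 6), depth = c(10, 10, 30),
                      n_male = c(1, 1, 3), n_female = c(1, 2, 3))
  f <- apply_site_filters(sites)
  expect_equal(f$keep_general, c(FALSE, TRUE, TRUE))  # <3 individuals drops
  expect_equal(f$keep_fst, c(FALSE, FALSE, TRUE))     # <2 per sex drops
  low_depth <- apply_site_filters(data.frame(n_ind = 5, depth = 2,
                                             n_male = 2, n_female = 3))
  expect_false(low_depth$keep_general)
})

test_that("per-gene stats equal brute-force recomputation on toy genes", {
  sex <- c("M", "M", "M", "F", "F", "F")
  # gene 1: 4 sites incl. a fixed difference and a shared polymorphism;
  # gene 2: 3 sites with one missing genotype
  rows <- list(
    c(1L, 1L, 1L, 0L, 0L, 0L),   # males het at XY-like site
    c(2L, 2L, 2L, 0L, 0L, 0L),   # fixed difference
    c(1L, 0L, 1L, 1L, 0L, 1L),   # sex-independent polymorphism
    c(0L, 0L, 0L, 0L, 0L, 0L),   # invariant
    c(1L, NA, 0L, 1L, 1L, 0L),
    c(2L, 1L, 0L, 2L, 1L, 0L),
    c(0L, 0L, 1L, 0L, 0L, 0L)
  )
  g <- toy_genotypes(rows, sex)
  site_pos <- data.frame(lg = "LG1", pos = c(1:4, 11:13))
  ann <- data.frame(gene_id = c("gA", "gB"), lg = "LG1",
                    start = c(1L, 11L), end = c(10L, 20L))
  st <- popgen_gene_stats(g$gt, g$depth, g$sex, site_pos, ann)
  expect_equal(st$fst[1], oracle_gene_fst(g$gt, sex, 1:4), tolerance = 1e-10)
  expect_equal(st$fst[2], oracle_gene_fst(g$gt, sex, 5:7), tolerance = 1e-10)
  # pi oracle: sum of per-site pairwise-difference pi over covered sites
  pi_a <- sum(vapply(1:4, function(s) oracle_site_pi(sum(g$gt[s, ]), 12),
                     numeric(1))) / 4
  expect_equal(st$pi[1], pi_a, tolerance = 1e-10)
  expect_equal(st$n_covered_sites, c(4L, 3L))
  expect_equal(st$S, c(3L, 3L))
  # Tajima's D for gene A: three variant sites at full coverage, n = 12
  piv <- oracle_site_pi(3, 12) + oracle_site_pi(6, 12) + oracle_site_pi(4, 12)
  expect_equal(st$tajimas_d[1], tajimas_d(3, piv, 12), tolerance = 1e-10)
})

test_that("autosomal simulated sites give near-zero mean Fst and XY sites exceed it", {
  cfg <- sim_config(n_species = 2, n_genes = 40, n_lgs = 20,
                    organs = "gonad", theta = 0.05, coverage_dropout = 0,
                    seed = 5)
  ann <- simulate_annotation(cfg)
  sexchr <- list(spA = "LG19", spB = character(0))
  gen <- simulate_genotypes(cfg, ann, sexchr)
  for (sp in names(gen)) {
    g <- gen[[sp]]
    st <- popgen_gene_stats(g$gt, g$depth, g$sex, g$site_pos, ann)
    auto <- st$fst[!st$lg %in% "LG19"]
    expect_lt(abs(mean(auto, na.rm = TRUE)), 0.05)
    if (sp == "spA") {
      xy <- st$fst[st$lg %in% "LG19"]
      expect_gt(mean(xy, na.rm = TRUE), mean(auto, na.rm = TRUE) + 0.1)
    }
  }
})
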