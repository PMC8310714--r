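#' Hudson's per-site Fst components
#'
#' Computes the between-population variance component alpha and the total
#' heterozygosity component beta of Hudson's Fst estimator from sample allele
#' frequencies, using the method-of-moments form. alpha may be negative;
#' negative values are retained, not clamped.
#'
#' @param p1,p2 Sample allele frequencies in the two groups (here typically
#'   males and females), in `[0, 1]`. Vectorized.
#' @param n1,n2 Number of allele copies sampled per group (2 x covered
#'   diploid individuals). Must be >= 2.
#' @return A data.frame with columns `alpha` and `beta`, one row per site.
#'   Sites with `n1 < 2` or `n2 < 2` get `NA` in both columns.
#' @examples
#' hudson_alpha_beta(0.5, 10, 0, 10)  # XY-divergent site pattern
#' @export
hudson_alpha_beta <- function(p1, n1, p2, n2) {
  stopifnot(length(p1) == length(p2), length(n1) %in% c(1L, length(p1)),
            length(n2) %in% c(1L, length(p2)))
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  n1 <- rep_len(n1, length(p1))
  n2 <- rep_len(n2, length(p2))
  ok <- n1 >= 2 & n2 >= 2
  alpha <- beta <- rep(NA_real_, length(p1))
  alpha[ok] <- (p1[ok] - p2[ok])^2 -
    p1[ok] * (1 - p1[ok]) / (n1[ok] - 1) -
    p2[ok] * (1 - p2[ok]) / (n2[ok] - 1)
  beta[ok] <- p1[ok] * (1 - p2[ok]) + p2[ok] * (1 - p1[ok])
  data.frame(alpha = alpha, beta = beta)
}

#' Per-gene Fst as a ratio of sums
#'
#' Aggregates per-site Hudson components over the sites of a gene as
#' `sum(alpha) / sum(alpha + beta)`. Summing before dividing shrinks noisy
#' per-site ratios towards the regional value. Negative-alpha sites are
#' included in both sums.
#'
#' @param alpha,beta Per-site component vectors (as from
#'   [hudson_alpha_beta()]); `NA` sites are dropped.
#' @return The per-gene Fst, or `NA` if no usable site remains or the
#'   denominator is zero.
#' @export
gene_fst_ratio_of_sums <- function(alpha, beta) {
  keep <- !is.na(alpha) & !is.na(beta)
  if (!any(keep)) return(NA_real_)
  denom <- sum(alpha[keep] + beta[keep])
  if (denom == 0) return(NA_real_)
  sum(alpha[keep]) / denom
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site pi from allele counts: the expected number of pairwise
#' differences among the `n` sampled copies, `2 d (n - d) / (n (n - 1))`.
#'
#' @param d Derived (or minor) allele count, `0 <= d <= n`. Vectorized.
#' @param n Total allele copies sampled, `n >= 2`.
#' @return Per-site pi; `NA` where `n < 2`.
#' @export
site_pi <- function(d, n) {
  n <- rep_len(n, length(d))
  if (any(d < 0 | d > n, na.rm = TRUE)) stop("need 0 <= d <= n")
  out <- rep(NA_real_, length(d))
  ok <- !is.na(d) & n >= 2
  out[ok] <- 2 * d[ok] * (n[ok] - d[ok]) / (n[ok] * (n[ok] - 1))
  out
}

#' Coverage-corrected per-gene nucleotide diversity
#'
#' Divides the summed variant-site pi by the number of covered sites
#' (variant plus invariant), so genes with uneven RNA-seq coverage are
#' comparable: invariant covered sites contribute 0 to the numerator and 1
#' to the denominator.
#'
#' @param site_pis Per-variant-site pi values for the gene.
#' @param n_covered_sites Total covered sites in the gene (>= number of
#'   variant sites).
#' @return Per-site gene pi, or `NA` if `n_covered_sites` is 0.
#' @export
gene_pi_corrected <- function(site_pis, n_covered_sites) {
  if (n_covered_sites == 0) return(NA_real_)
  if (n_covered_sites < sum(!is.na(site_pis)))
    stop("covered sites cannot be fewer than variant sites")
  sum(site_pis, na.rm = TRUE) / n_covered_sites
}

# Tajima (1989) normalizing constants for sample size n (allele copies).
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' The standardized difference between the pairwise-diversity estimator of
#' theta (total pi over the gene's variant sites) and the Watterson
#' segregating-sites estimator `S / a1`, with the 1989 variance constants.
#' Negative values indicate an excess of rare variants.
#'
#' @param S Number of segregating sites.
#' @param pi_total Sum of per-site pi over the gene's variant sites.
#' @param n Allele copies sampled (constant across sites; down-sample first
#'   if coverage varies).
#' @return D, or `NA` when `S = 0` or the variance term is non-positive.
#' @export
tajimas_d <- function(S, pi_total, n) {
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_total - S / k$a1) / sqrt(v)
}

#' Site frequency spectrum
#'
#' Histogram of derived-allele counts (unfolded) or minor-allele counts
#' (folded, `d -> min(d, n - d)`) over variant sites with a common sample
#' size `n`.
#'
#' @param d Per-site derived allele counts.
#' @param n Allele copies sampled.
#' @param folded Fold the spectrum (use when ancestral states are unknown).
#' @return Named integer vector; unfolded has classes `0..n`, folded
#'   `0..floor(n/2)`.
#' @export
build_sfs <- function(d, n, folded = FALSE) {
  stopifnot(all(d >= 0 & d <= n))
  if (folded) d <- pmin(d, n - d)
  k <- if (folded) floor(n / 2) else n
  tab <- tabulate(d + 1L, nbins = k + 1L)
  names(tab) <- 0:k
  tab
}

# Hypergeometric expectation of the derived count when down-sampling from
# n_from to n_to copies; used to put sites with uneven coverage on a common
# sample size before Tajima's D.
downsample_d <- function(d, n_from, n_to) d * n_to / n_from

#' Site filters for population-genetic statistics
#'
#' Applies the study's site inclusion rules to a per-site coverage table:
#' the general stream keeps sites covered in at least `min_ind` individuals
#' with total depth at least `min_depth`; the Fst-eligible stream
#' additionally requires at least `min_per_sex` covered individuals in each
#' sex.
#'
#' @param sites data.frame with columns `n_ind` (covered individuals),
#'   `depth` (total depth), `n_male`, `n_female` (covered individuals per
#'   sex).
#' @param min_ind,min_depth,min_per_sex Filter thresholds (defaults 3, 3, 2).
#' @return The input with logical columns `keep_general` and `keep_fst`.
#' @export
apply_site_filters <- function(sites, min_ind = 3L, min_depth = 3L,
                               min_per_sex = 2L) {
  need <- c("n_ind", "depth", "n_male", "n_female")
  if (!all(need %in% names(sites)))
    stop("sites must have columns: ", paste(need, collapse = ", "))
  sites$keep_general <- sites$n_ind >= min_ind & sites$depth >= min_depth
  sites$keep_fst <- sites$keep_general &
    sites$n_male >= min_per_sex & sites$n_female >= min_per_sex
  sites
}

#' Per-gene population-genetic statistics from genotypes
#'
#' The per-species workhorse: takes a genotype matrix (rows = sites, 0/1/2
#' alternate-allele dosages, NA = not covered), per-site per-individual
#' depths, individual sex labels and a gene annotation, applies the site
#' filters and returns intersex Fst (ratio of sums of Hudson components),
#' coverage-corrected pi, segregating sites and Tajima's D per gene.
#'
#' @param gt Integer matrix sites x individuals of allele dosages (0, 1, 2,
#'   or NA when the site is missing in that individual).
#' @param depth Matrix of the same shape with per-individual site depth.
#' @param sex Character vector ("M"/"F") per individual (column).
#' @param site_pos data.frame with `lg` and `pos` per site (rows align with
#'   `gt`).
#' @param annotation data.frame with `gene_id`, `lg`, `start`, `end`
#'   (1-based inclusive).
#' @param min_ind,min_depth,min_per_sex Site filter thresholds.
#' @return data.frame per gene: `gene_id`, `lg`, `fst`, `sum_alpha`,
#'   `sum_alpha_beta`, `pi`, `S`, `tajimas_d`, `n_fst_sites`,
#'   `n_covered_sites`.
#' @export
popgen_gene_stats <- function(gt, depth, sex, site_pos, annotation,
                              min_ind = 3L, min_depth = 3L, min_per_sex = 2L) {
  stopifnot(nrow(gt) == nrow(site_pos), ncol(gt) == length(sex),
            all(dim(gt) == dim(depth)))
  covered <- !is.na(gt) & depth >= 1
  is_m <- sex == "M"
  cover_tab <- data.frame(
    n_ind = rowSums(covered),
    depth = rowSums(depth * covered),
    n_male = rowSums(covered[, is_m, drop = FALSE]),
    n_female = rowSums(covered[, !is_m, drop = FALSE])
  )
  cover_tab <- apply_site_filters(cover_tab, min_ind, min_depth, min_per_sex)

  gt_use <- gt
  gt_use[!covered] <- NA
  d_all <- rowSums(gt_use, na.rm = TRUE)
  n_all <- 2L * cover_tab$n_ind
  gm <- gt_use[, is_m, drop = FALSE]
  gf <- gt_use[, !is_m, drop = FALSE]
  d_m <- rowSums(gm, na.rm = TRUE); n_m <- 2L * cover_tab$n_male
  d_f <- rowSums(gf, na.rm = TRUE); n_f <- 2L * cover_tab$n_female

  ab <- hudson_alpha_beta(ifelse(n_m > 0, d_m / n_m, NA),
                          n_m,
                          ifelse(n_f > 0, d_f / n_f, NA),
                          n_f)
  pi_site <- site_pi(d_all, n_all)
  variant <- !is.na(d_all) & d_all > 0 & d_all < n_all

  site_gene <- map_sites_to_genes(site_pos, annotation)
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    in_gene <- which(site_gene == i)
    gen <- in_gene[cover_tab$keep_general[in_gene]]
    fst_ok <- in_gene[cover_tab$keep_fst[in_gene]]
    n_cov <- length(gen)
    var_sites <- gen[variant[gen]]
    S <- length(var_sites)
    pi_gene <- if (n_cov > 0)
      gene_pi_corrected(pi_site[var_sites], n_cov) else NA_real_
    taj <- NA_real_
    if (S > 0) {
      # common sample size: gene-wise minimum; hypergeometric expectation
      n_min <- min(n_all[var_sites])
      if (n_min >= 4) {
        d_ds <- downsample_d(d_all[var_sites], n_all[var_sites], n_min)
        taj <- tajimas_d(S, sum(site_pi(d_ds, n_min)), n_min)
      }
    }
    data.frame(
      gene_id = g$gene_id, lg = g$lg,
      fst = gene_fst_ratio_of_sums(ab$alpha[fst_ok], ab$beta[fst_ok]),
      sum_alpha = sum(ab$alpha[fst_ok], na.rm = TRUE),
      sum_alpha_beta = sum(ab$alpha[fst_ok] + ab$beta[fst_ok], na.rm = TRUE),
      pi = pi_gene, S = S, tajimas_d = taj,
      n_fst_sites = length(fst_ok), n_covered_sites = n_cov
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# first-match (sorted order) site -> gene interval assignment; overlapping
# genes resolve to the earlier gene on the linkage group.
map_sites_to_genes <- function(site_pos, annotation) {
  out <- rep(NA_integer_, nrow(site_pos))
  for (l in unique(annotation$lg)) {
    ann_rows <- which(annotation$lg == l)
    ann_rows <- ann_rows[order(annotation$start[ann_rows])]
    st <- annotation$start[ann_rows]
    en <- annotation$end[ann_rows]
    s_rows <- which(site_pos$lg == l)
    if (length(s_rows) == 0) next
    k <- findInterval(site_pos$pos[s_rows], st)
    hit <- k >= 1 & site_pos$pos[s_rows] <= en[pmax(k, 1L)]
    out[s_rows[hit]] <- ann_rows[k[hit]]
  }
  out
}
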