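# Normalization, QC and sex-biased gene calling: TMM scaling factors, a
# variance-damping log transform for QC, outlier/sex-mismatch flagging, a
# negative-binomial Wald test per species x organ, bias categories from
# |LFC| bins, cross-species sharing and the variance sanity check.

#' Remove genes with (essentially) no counts
#'
#' Drops genes whose total count across all samples is below 1, i.e. rows
#' summing to zero for integer counts. Gene order is otherwise preserved.
#'
#' @param counts Gene x sample matrix of non-negative integers.
#' @return The filtered matrix (possibly zero rows, with a warning when
#'   empty).
#' @export
filter_low_count_genes <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  out <- counts[rowSums(counts) >= 1, , drop = FALSE]
  if (nrow(out) == 0) warning("no gene passed the count filter")
  out
}

#' TMM normalization factors and normalized counts
#'
#' Computes trimmed-mean-of-M-values scaling factors (trim 30% on M, 5% on
#' A, precision weights, reference sample = upper quartile closest to the
#' mean upper quartile), rescaled to geometric mean 1. Normalized counts
#' are counts divided by the effective library size (library size x
#' factor), rescaled by the geometric-mean effective library size so they
#' stay on the count scale.
#'
#' @param counts Gene x sample matrix.
#' @param ref_sample Optional reference column name or index.
#' @return List with `factors` (per-sample TMM factor), `lib_size`, and
#'   `normalized` (matrix on the count scale).
#' @export
tmm_normalize <- function(counts, ref_sample = NULL) {
  if (ncol(counts) == 0) stop("no samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  if (ncol(counts) == 1) {
    f <- stats::setNames(1, colnames(counts))
  } else {
    f <- edgeR::calcNormFactors(counts, method = "TMM",
                                refColumn = ref_sample)
    names(f) <- colnames(counts)
  }
  eff <- lib * f
  norm <- sweep(counts, 2, eff, "/") * exp(mean(log(eff)))
  list(factors = f, lib_size = lib, normalized = norm)
}

#' Variance-damping transform for QC
#'
#' `log2(normalized count + 1)`: a monotone transform that damps the
#' mean-variance relationship enough for Euclidean-distance QC.
#'
#' @param normalized Normalized count matrix.
#' @return Transformed matrix.
#' @export
vst_like <- function(normalized) log2(normalized + 1)

#' Flag suspicious samples
#'
#' Advisory QC flags (exclusion is a user decision): (i) "low_signal" for
#' samples whose median normalized count is near zero (sequencing failure
#' pattern); (ii) "sex_mismatch" for samples whose k nearest neighbours
#' (Euclidean distance on the log2 transform, within species x organ) are
#' majority-labelled with the opposite sex; (iii) "organ_mismatch" for
#' samples whose global nearest neighbours are majority another organ.
#'
#' @param counts Gene x sample matrix of raw counts.
#' @param metadata data.frame with `sample_id`, `species`, `sex`, `organ`.
#' @param k Neighbours for the majority votes (default 3).
#' @param low_median Threshold for the low-signal flag (default 1).
#' @return data.frame with `sample_id` and `flag` (zero rows when clean).
#' @export
qc_flag_samples <- function(counts, metadata, k = 3, low_median = 1) {
  stopifnot(all(colnames(counts) == metadata$sample_id))
  lib <- colSums(counts)
  flags <- list()
  low <- apply(counts, 2, stats::median) < low_median & lib > 0
  zero <- lib == 0
  lowsig <- colnames(counts)[low | zero]
  if (length(lowsig))
    flags[[length(flags) + 1L]] <- data.frame(sample_id = lowsig,
                                              flag = "low_signal")
  usable <- lib > 0
  if (sum(usable) >= 3) {
    norm <- tmm_normalize(counts[, usable, drop = FALSE])$normalized
    v <- vst_like(norm)
    md <- metadata[usable, , drop = FALSE]
    knn_majority <- function(d, labels, i, kk) {
      nb <- order(d[i, -i, drop = TRUE])[seq_len(kk)]
      lab_nb <- labels[-i][nb]
      names(sort(table(lab_nb), decreasing = TRUE))[1]
    }
    # sex-mismatch: within species x organ
    for (grp in split(seq_len(nrow(md)),
                      interaction(md$species, md$organ, drop = TRUE))) {
      if (length(grp) < 3 || length(unique(md$sex[grp])) < 2) next
      d <- as.matrix(stats::dist(t(v[, grp, drop = FALSE])))
      for (i in seq_along(grp)) {
        kk <- min(k, length(grp) - 1)
        maj <- knn_majority(d, md$sex[grp], i, kk)
        if (maj != md$sex[grp[i]])
          flags[[length(flags) + 1L]] <-
            data.frame(sample_id = md$sample_id[grp[i]],
                       flag = "sex_mismatch")
      }
    }
    # organ-mismatch: global ordination neighbourhood
    if (length(unique(md$organ)) >= 2 && nrow(md) >= 4) {
      d <- as.matrix(stats::dist(t(v)))
      for (i in seq_len(nrow(md))) {
        kk <- min(k, nrow(md) - 1)
        maj <- knn_majority(d, md$organ, i, kk)
        if (maj != md$organ[i])
          flags[[length(flags) + 1L]] <-
            data.frame(sample_id = md$sample_id[i], flag = "organ_mismatch")
      }
    }
  }
  if (length(flags) == 0)
    return(data.frame(sample_id = character(), flag = character()))
  unique(do.call(rbind, flags))
}

# method-of-moments NB dispersion with a trended shrink: per-gene pooled
# within-group variance vs mean, raw phi = (s2 - mu)/mu^2 floored, shrunk
# towards a 1/mu + const trend with weight df/(df + trend_df).
estimate_dispersion <- function(norm_m, norm_f, floor = 1e-8, trend_df = 4) {
  nM <- ncol(norm_m); nF <- ncol(norm_f)
  mu_m <- rowMeans(norm_m); mu_f <- rowMeans(norm_f)
  ss <- function(x, mu) rowSums((x - mu)^2)
  df <- nM + nF - 2
  s2 <- (ss(norm_m, mu_m) + ss(norm_f, mu_f)) / df
  mu <- (nM * mu_m + nF * mu_f) / (nM + nF)
  phi_raw <- ifelse(mu > 0, pmax((s2 - mu) / mu^2, floor), floor)
  use <- mu > 1 & phi_raw > floor
  if (sum(use) >= 10) {
    fit <- stats::lm(phi_raw[use] ~ I(1 / mu[use]))
    co <- stats::coef(fit)
    trend <- pmax(co[1] + co[2] / pmax(mu, 1e-8), floor)
  } else {
    trend <- rep(max(mean(phi_raw), floor), length(mu))
  }
  w <- df / (df + trend_df)
  pmax(w * phi_raw + (1 - w) * trend, floor)
}

#' Test for sex-biased expression in one species and organ
#'
#' A negative-binomial Wald test on TMM-normalized counts: the log2-fold
#' change is `log2((mean_M + c) / (mean_F + c))` (positive = male-biased),
#' its standard error follows from the NB variance `mu + phi mu^2` of the
#' group means (dispersion by a trended method-of-moments estimate), and
#' the Wald statistic is referred to a t distribution with
#' `n_M + n_F - 2` df. P-values are BH-adjusted within the species x organ
#' family. Genes with zero counts in every sample of both sexes are not
#' tested.
#'
#' @param counts Gene x sample raw counts for one species x organ.
#' @param sex Character vector ("M"/"F") per sample.
#' @param alpha Adjusted-p threshold for calling bias (default 0.05).
#' @param lfc_threshold |LFC| threshold for calling bias (default 2).
#' @param pseudo_count Pseudo-count c on the normalized scale (default 0.5).
#' @return data.frame per tested gene: `gene_id`, `base_mean`, `lfc`, `se`,
#'   `stat`, `p`, `padj`, `direction`, `category`.
#' @export
test_sex_bias <- function(counts, sex, alpha = 0.05, lfc_threshold = 2,
                          pseudo_count = 0.5) {
  sex <- as.character(sex)
  if (sum(sex == "M") < 2 || sum(sex == "F") < 2)
    stop("need at least two replicates per sex")
  counts <- filter_low_count_genes(counts)
  norm <- tmm_normalize(counts)$normalized
  m <- norm[, sex == "M", drop = FALSE]
  f <- norm[, sex == "F", drop = FALSE]
  expressed <- rowSums(counts) > 0
  mu_m <- rowMeans(m); mu_f <- rowMeans(f)
  phi <- estimate_dispersion(m, f)
  var_mean <- function(mu, n) (mu + phi * mu^2) / n
  lfc <- log2((mu_m + pseudo_count) / (mu_f + pseudo_count))
  se <- sqrt(var_mean(mu_m, ncol(m)) / (mu_m + pseudo_count)^2 +
               var_mean(mu_f, ncol(f)) / (mu_f + pseudo_count)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  df <- ncol(m) + ncol(f) - 2
  p <- 2 * stats::pt(-abs(stat), df = df)
  p[mu_m == 0 & mu_f == 0] <- NA    # nothing observed: untestable
  padj <- bh_adjust(p)
  direction <- rep("unbiased", length(lfc))
  direction[!is.na(padj) & padj < alpha & lfc > lfc_threshold] <- "MBG"
  direction[!is.na(padj) & padj < alpha & lfc < -lfc_threshold] <- "FBG"
  category <- ifelse(direction == "unbiased", "none",
                     assign_bias_category(lfc, lfc_threshold))
  data.frame(gene_id = rownames(counts), base_mean = (mu_m + mu_f) / 2,
             lfc = lfc, se = se, stat = stat, p = p, padj = padj,
             direction = direction, category = category,
             row.names = NULL)[expressed, , drop = FALSE]
}

#' Bias category from the log2-fold change
#'
#' Pure function of |LFC|: none (<= 2), low (2, 2.6), mid [2.6, 4.1),
#' high [4.1, 6.5), extreme (>= 6.5).
#'
#' @param lfc Log2-fold change(s); the absolute value is binned.
#' @param lfc_threshold Lower bound of the "low" bin (default 2).
#' @return Character vector of categories.
#' @export
assign_bias_category <- function(lfc, lfc_threshold = 2) {
  a <- abs(lfc)
  out <- rep("none", length(a))
  out[a > lfc_threshold & a < 2.6] <- "low"
  out[a >= 2.6 & a < 4.1] <- "mid"
  out[a >= 4.1 & a < 6.5] <- "high"
  out[a >= 6.5] <- "extreme"
  out
}

#' Cross-species sharing of sex-biased genes
#'
#' For each organ and bias direction, counts in how many species each gene
#' is biased; genes biased in >= 2 species are "shared", in exactly one
#' "species-specific".
#'
#' @param bias_tables data.frame stacking per-species results with columns
#'   `gene_id`, `species`, `organ`, `direction`.
#' @return data.frame per (organ, direction): `n_shared`, `n_specific`,
#'   `fraction_shared`, plus a `per_gene` attribute with species counts.
#' @export
shared_sbg_sets <- function(bias_tables) {
  bt <- bias_tables[bias_tables$direction %in% c("MBG", "FBG"), , drop = FALSE]
  if (nrow(bt) == 0)
    return(data.frame(organ = character(), direction = character(),
                      n_shared = integer(), n_specific = integer(),
                      fraction_shared = numeric()))
  per_gene <- stats::aggregate(species ~ organ + direction + gene_id,
                               data = bt,
                               FUN = function(s) length(unique(s)))
  names(per_gene)[names(per_gene) == "species"] <- "n_species"
  out <- do.call(rbind, lapply(
    split(per_gene, list(per_gene$organ, per_gene$direction), drop = TRUE),
    function(d) {
      ns <- sum(d$n_species >= 2)
      np <- sum(d$n_species == 1)
      data.frame(organ = d$organ[1], direction = d$direction[1],
                 n_shared = ns, n_specific = np,
                 fraction_shared = if (ns + np > 0) ns / (ns + np) else NA_real_)
    }))
  rownames(out) <- NULL
  attr(out, "per_gene") <- per_gene
  out
}

#' SBG count versus within-replicate variance
#'
#' Sanity check that the number of SBGs per species and organ does not just
#' track expression variance: Spearman correlation between per-(species,
#' organ) SBG counts and the median per-gene within-sex variance of
#' normalized counts.
#'
#' @param sbg_counts data.frame with `species`, `organ`, `n_sbg`.
#' @param med_variance data.frame with `species`, `organ`, `med_var`.
#' @return data.frame per scope (overall + per organ): `rho`, `p`, `n`
#'   (`rho` NA when ranks are degenerate; `p` NA with < 3 points).
#' @export
expression_variance_check <- function(sbg_counts, med_variance) {
  m <- merge(sbg_counts, med_variance, by = c("species", "organ"))
  one <- function(d, scope) {
    n <- nrow(d)
    rho <- p <- NA_real_
    if (n >= 2 && length(unique(d$med_var)) > 1 &&
        length(unique(d$n_sbg)) > 1) {
      ct <- suppressWarnings(
        stats::cor.test(d$n_sbg, d$med_var, method = "spearman"))
      rho <- unname(ct$estimate)
      p <- if (n >= 3) ct$p.value else NA_real_
    }
    data.frame(scope = scope, rho = rho, p = p, n = n)
  }
  out <- rbind(one(m, "overall"),
               do.call(rbind, lapply(split(m, m$organ),
                                     function(d) one(d, d$organ[1]))))
  rownames(out) <- NULL
  out
}
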