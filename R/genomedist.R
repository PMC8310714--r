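# Genomic-distribution statistics: per-linkage-group feminization /
# demasculinization tests, sex-chromosome vs autosome comparisons, and the
# shared nonparametric machinery (one-sided Fisher, Mann-Whitney,
# Kruskal-Wallis, Benjamini-Hochberg).

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability for enrichment in the stated
#' direction. With the table laid out as rows = (on this LG, elsewhere) and
#' columns = (FBG, MBG), `direction = "greater"` tests FBG excess on the LG
#' (feminization; identical to testing MBG deficit, i.e. demasculinization).
#' A zero margin returns p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param direction `"greater"` or `"less"` (odds-ratio tail for cell
#'   `[1,1]`).
#' @return The one-sided p-value.
#' @export
fisher_one_sided <- function(table, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table, alternative = direction)$p.value
}

#' Mann-Whitney U test (two-sample Wilcoxon)
#'
#' U statistic with average ranks for ties. The p-value is exact when
#' `min(n, m) <= 8` and there are no ties, otherwise a normal approximation
#' with tie and continuity corrections is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_max Largest `min(n, m)` for which the exact distribution is
#'   used (default 8).
#' @return List with `U` and `p`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided", exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1)     # fully tied: no rank information
    return(list(U = length(x) * length(y) / 2, p = 1))
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = use_exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' @param values Numeric vector of all observations.
#' @param groups Group labels (coerced to factor; >= 2 non-empty groups).
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 non-empty groups")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p P-values in `[0, 1]` (NAs carried through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-linkage-group sex-bias enrichment screen
#'
#' For each linkage group within a species, builds the 2x2 table of
#' (MBG, FBG) counts on the LG vs the rest of the genome and runs a
#' one-sided Fisher's exact test in the direction of the observed
#' MBG - FBG difference on that LG (an MBG deficit is tested as
#' feminization/demasculinization, an MBG excess as masculinization).
#' When MBG - FBG = 0 on the LG, p = 1 is reported.
#'
#' @param bias_table data.frame with `gene_id`, `direction` ("MBG", "FBG",
#'   "unbiased") for one species and organ.
#' @param gene_lg Named vector mapping gene_id -> linkage group.
#' @return data.frame per LG: counts, tested direction, p, padj (BH across
#'   LGs).
#' @export
lg_enrichment <- function(bias_table, gene_lg) {
  lg <- gene_lg[bias_table$gene_id]
  keep <- !is.na(lg)
  bt <- bias_table[keep, , drop = FALSE]
  lg <- lg[keep]
  mbg_tot <- sum(bt$direction == "MBG")
  fbg_tot <- sum(bt$direction == "FBG")
  out <- lapply(sort(unique(lg)), function(l) {
    on <- lg == l
    m_on <- sum(bt$direction == "MBG" & on)
    f_on <- sum(bt$direction == "FBG" & on)
    tab <- matrix(c(f_on, fbg_tot - f_on, m_on, mbg_tot - m_on), 2, 2)
    diffsign <- m_on - f_on
    if (diffsign == 0) {
      p <- 1; dir <- "none"
    } else if (diffsign < 0) {
      p <- fisher_one_sided(tab, "greater"); dir <- "feminized"
    } else {
      p <- fisher_one_sided(tab, "less"); dir <- "masculinized"
    }
    data.frame(lg = l, mbg_on = m_on, fbg_on = f_on,
               mbg_off = mbg_tot - m_on, fbg_off = fbg_tot - f_on,
               direction = dir, p = p)
  })
  res <- do.call(rbind, out)
  res$padj <- bh_adjust(res$p)
  res
}

#' Compare a statistic between sex-chromosome and autosomal genes
#'
#' For each gene class (FBG / MBG / unbiased), compares the per-gene values
#' of a statistic (intersex Fst, pi, Tajima's D, dN/dS, ...) on the
#' species' sex-chromosome linkage groups against all autosomal genes
#' pooled, with a Mann-Whitney test.
#'
#' @param gene_stats data.frame with `gene_id`, `lg`, and the statistic in
#'   column `stat_col`.
#' @param bias_table data.frame with `gene_id`, `direction` for the species
#'   and organ of interest.
#' @param sex_lgs Character vector of the species' sex-chromosome LG ids
#'   (may be empty: no comparisons).
#' @param stat_col Name of the statistic column.
#' @param alternative Test direction (default `"two.sided"`).
#' @return data.frame per gene class: group sizes, medians, U, p; zero rows
#'   if `sex_lgs` is empty or a class is absent from the sex chromosomes.
#' @export
sexchr_vs_autosome_compare <- function(gene_stats, bias_table, sex_lgs,
                                       stat_col,
                                       alternative = "two.sided") {
  if (length(sex_lgs) == 0)
    return(data.frame(class = character(), n_sex = integer(),
                      n_auto = integer(), median_sex = numeric(),
                      median_auto = numeric(), U = numeric(), p = numeric()))
  m <- merge(gene_stats, bias_table[, c("gene_id", "direction")],
             by = "gene_id")
  m <- m[!is.na(m[[stat_col]]), , drop = FALSE]
  out <- lapply(c("FBG", "MBG", "unbiased"), function(cl) {
    v <- m[m$direction == cl, , drop = FALSE]
    on_sex <- v$lg %in% sex_lgs
    if (sum(on_sex) == 0 || sum(!on_sex) == 0) return(NULL)
    mw <- mann_whitney_u(v[[stat_col]][on_sex], v[[stat_col]][!on_sex],
                         alternative = alternative)
    data.frame(class = cl, n_sex = sum(on_sex), n_auto = sum(!on_sex),
               median_sex = stats::median(v[[stat_col]][on_sex]),
               median_auto = stats::median(v[[stat_col]][!on_sex]),
               U = mw$U, p = mw$p)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(class = character(), n_sex = integer(),
                      n_auto = integer(), median_sex = numeric(),
                      median_auto = numeric(), U = numeric(), p = numeric())
  res
}
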