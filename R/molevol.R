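# Sequence- and expression-level selection statistics: pairwise dN/dS by
# Nei-Gojobori (1986) counting with Jukes-Cantor correction, and the
# standardized expression-shift statistic delta-x.

codon_split <- function(seq) {
  s <- toupper(seq)
  if (nchar(s) %% 3 != 0) stop("sequence length must be a multiple of 3")
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

.ng86_cache <- new.env(parent = emptyenv())

# standard-code codon -> amino acid lookup, built once from seqinr
codon_table <- function() {
  if (is.null(.ng86_cache$aa)) {
    nts <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE),
                    1, paste, collapse = "")
    .ng86_cache$aa <- stats::setNames(
      vapply(codons, function(cd) seqinr::translate(strsplit(cd, "")[[1]]),
             character(1)), codons)
  }
  .ng86_cache$aa
}

codon_aa <- function(codon) unname(codon_table()[codon])

# Per-codon synonymous / nonsynonymous site fractions. Mutations that create
# a stop codon are excluded from counting (each position still contributes a
# denominator of 3, so a codon's N + S is 3 minus its stop-mutant fraction).
ng86_codon_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  aa0 <- codon_aa(codon)
  if (aa0 == "*") stop("internal stop codon: ", codon)
  syn <- non <- 0
  chars <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (nt in setdiff(nts, chars[pos])) {
      mut <- chars
      mut[pos] <- nt
      aa1 <- codon_aa(paste(mut, collapse = ""))
      if (aa1 == "*") next
      if (aa1 == aa0) syn <- syn + 1 / 3 else non <- non + 1 / 3
    }
  }
  c(S = syn, N = non)
}

# Observed synonymous / nonsynonymous differences between two codons,
# averaged over all shortest substitution paths. Paths passing through a
# stop codon are excluded; if every path is blocked, all paths are used.
ng86_codon_diffs <- function(ca, cb) {
  if (ca == cb) return(c(Sd = 0, Nd = 0))
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  perms <- gtools_permute(pos)
  paths <- lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  count_path <- function(order) {
    cur <- a
    syn <- non <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_cur <- codon_aa(paste(cur, collapse = ""))
      aa_nxt <- codon_aa(paste(nxt, collapse = ""))
      if (aa_nxt == "*" || aa_cur == "*") return(NULL)
      if (aa_cur == aa_nxt) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  res <- Filter(Negate(is.null), lapply(paths, count_path))
  if (length(res) == 0) {   # all paths blocked by stops: use all, count stops
    res <- lapply(paths, function(order) {
      cur <- a; syn <- non <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- b[p]
        if (codon_aa(paste(cur, collapse = "")) ==
            codon_aa(paste(nxt, collapse = ""))) syn <- syn + 1
        else non <- non + 1
        cur <- nxt
      }
      c(syn, non)
    })
  }
  m <- colMeans(do.call(rbind, res))
  c(Sd = m[[1]], Nd = m[[2]])
}

# all permutations of a small vector (2 or 3 elements suffice here)
gtools_permute <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], gtools_permute(x[-i])))
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)  # saturated
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' Counts synonymous and nonsynonymous sites by per-codon mutation-fate
#' enumeration (averaged over the two sequences) and observed differences by
#' averaging over all shortest substitution paths per codon, then applies the
#' Jukes-Cantor correction to the proportions. Codons containing a gap or
#' ambiguous base in either sequence are removed pairwise.
#'
#' @param seq_a,seq_b In-frame aligned CDS strings of equal length
#'   (multiple of 3, no internal stop codons).
#' @return A one-row data.frame: `N`, `S_sites`, `Nd`, `Sd`, `pN`, `pS`,
#'   `dN`, `dS`, `omega`. `omega` is `NA` when `dS` is 0 or a correction
#'   saturates.
#' @examples
#' ng86_dnds("ATGGGT", "ATGGGC")  # one synonymous difference
#' @export
ng86_dnds <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  ca <- codon_split(seq_a)
  cb <- codon_split(seq_b)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0) stop("no ungapped codon remains")
  if (is.null(.ng86_cache$sites)) {
    tab <- vapply(names(codon_table()), function(cd) {
      if (codon_aa(cd) == "*") c(S = NA_real_, N = NA_real_)
      else ng86_codon_sites(cd)
    }, numeric(2))
    .ng86_cache$sites <- tab
  }
  sites_a <- .ng86_cache$sites[, ca, drop = FALSE]
  sites_b <- .ng86_cache$sites[, cb, drop = FALSE]
  if (anyNA(sites_a) || anyNA(sites_b)) stop("internal stop codon in input")
  S_sites <- (sum(sites_a["S", ]) + sum(sites_b["S", ])) / 2
  N <- (sum(sites_a["N", ]) + sum(sites_b["N", ])) / 2
  changed <- ca != cb
  Sd <- Nd <- 0
  if (any(changed)) {
    key <- paste(ca[changed], cb[changed])
    agg <- table(key)
    for (k in names(agg)) {
      pair <- strsplit(k, " ")[[1]]
      d <- ng86_codon_diffs(pair[1], pair[2])
      Sd <- Sd + d[["Sd"]] * agg[[k]]
      Nd <- Nd + d[["Nd"]] * agg[[k]]
    }
  }
  pS <- if (S_sites > 0) Sd / S_sites else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS
  else if (!is.na(dN) && dN == 0 && Sd > 0) 0   # no nonsyn change at all
  else NA_real_
  data.frame(N = N, S_sites = S_sites, Nd = Nd, Sd = Sd,
             pN = pN, pS = pS, dN = dN, dS = dS, omega = omega)
}

#' TPM from counts and gene lengths
#'
#' @param counts gene x sample matrix of raw counts.
#' @param lengths Per-gene lengths in bases (named or in row order).
#' @return Matrix of transcripts-per-million values.
#' @export
tpm_from_counts <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Standardized expression shift (delta-x)
#'
#' Expression divergence of a focal species relative to a reference species
#' (ancestral proxy), standardized by within-species variability:
#' `(mean(log2(TPM_focal + 1)) - mean(log2(TPM_ref + 1))) / pooled SD`,
#' where the pooled SD combines the replicate SDs of both species on the
#' log2(TPM + 1) scale. `|delta_x| > 1` flags putative directional selection
#' on expression level.
#'
#' @param tpm_focal,tpm_ref Replicate TPM values (>= 2 each).
#' @param threshold Direction threshold (default 1).
#' @param denominator `"pooled"` (default) or `"focal"` for the focal-only
#'   replicate SD.
#' @return One-row data.frame: `delta_x`, `direction` in
#'   `{"over","under","none"}`.
#' @export
delta_x <- function(tpm_focal, tpm_ref, threshold = 1,
                    denominator = c("pooled", "focal")) {
  denominator <- match.arg(denominator)
  if (length(tpm_focal) < 2 || length(tpm_ref) < 2)
    return(data.frame(delta_x = NA_real_, direction = NA_character_))
  xf <- log2(tpm_focal + 1)
  xr <- log2(tpm_ref + 1)
  n1 <- length(xf); n2 <- length(xr)
  sd_pool <- if (denominator == "pooled")
    sqrt(((n1 - 1) * stats::var(xf) + (n2 - 1) * stats::var(xr)) /
           (n1 + n2 - 2))
  else stats::sd(xf)
  dmean <- mean(xf) - mean(xr)
  if (sd_pool == 0) {
    dx <- if (dmean == 0) 0 else NA_real_   # flagged: shift with no variance
  } else dx <- dmean / sd_pool
  dir <- if (is.na(dx)) NA_character_
  else if (dx > threshold) "over"
  else if (dx < -threshold) "under"
  else "none"
  data.frame(delta_x = dx, direction = dir)
}

#' Genes under putative selection at both expression and sequence level
#'
#' Intersects the expression-shift candidates (`|delta_x|` beyond the
#' threshold) with the elevated-dN/dS candidates, per species.
#'
#' @param deltax data.frame with `gene_id`, `species`, `delta_x` (and
#'   optionally `organ`).
#' @param dnds data.frame with `gene_id`, `species`, `omega`.
#' @param dx_cut,dnds_cut Thresholds (defaults 1 and 1).
#' @param annotation Optional data.frame with `gene_id` and `lg` to report
#'   gene location.
#' @return data.frame of joint candidates with both statistics.
#' @export
joint_candidates <- function(deltax, dnds, dx_cut = 1, dnds_cut = 1,
                             annotation = NULL) {
  m <- merge(deltax, dnds, by = c("gene_id", "species"))
  hit <- !is.na(m$delta_x) & abs(m$delta_x) > dx_cut &
    !is.na(m$omega) & m$omega > dnds_cut
  out <- m[hit, , drop = FALSE]
  if (!is.null(annotation))
    out <- merge(out, annotation[, c("gene_id", "lg")], by = "gene_id",
                 all.x = TRUE)
  rownames(out) <- NULL
  out
}
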