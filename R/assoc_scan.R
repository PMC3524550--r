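# closed-form Cochran-Armitage trend chi-square with scores (0, 1, 2),
# vectorised over SNP columns; r* = case counts, n* = case + control counts
ca_trend_chi2 <- function(r0, r1, r2, n0, n1, n2) {
  R <- r0 + r1 + r2
  N <- n0 + n1 + n2
  T1 <- r1 + 2 * r2           # sum s_i r_i
  S1 <- n1 + 2 * n2           # sum s_i n_i
  S2 <- n1 + 4 * n2           # sum s_i^2 n_i
  num <- N * (N * T1 - R * S1)^2
  den <- R * (N - R) * (N * S2 - S1^2)
  chi2 <- ifelse(den > 0, num / den, NA_real_)
  list(chi2 = chi2, degenerate = !(den > 0) | !is.finite(den))
}

#' Cochran-Armitage trend test for one 2 x 3 genotype count table
#'
#' The additive-model single-marker association test: scores (0, 1, 2) on
#' minor-allele dosage, 1-df chi-square.  This is the per-SNP statistic
#' whose most significant value within a gene region becomes the gene-wise
#' statistic downstream.
#'
#' @param counts A 2 x 3 matrix of non-negative integer counts; rows are
#'   (case, control), columns dosages 0, 1, 2.  Alternatively pass the two
#'   rows via `cases` and `controls`.
#' @param cases,controls Length-3 count vectors; used when `counts` is
#'   missing.
#' @return List with `chi2` (>= 0), `p_value` (upper-tail chi-square 1 df),
#'   and `flagged` (`TRUE` for degenerate tables: monomorphic SNPs or a
#'   zero margin, which return `chi2 = 0`, `p_value = 1`).
#' @examples
#' trend_test(cases = c(10, 20, 10), controls = c(20, 20, 0))
#' @export
trend_test <- function(counts, cases = NULL, controls = NULL) {
  if (missing(counts)) {
    counts <- rbind(cases, controls)
  }
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 3L)))
    stop("counts must be a 2 x 3 (case/control x dosage) table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts[1, ]) == 0 || sum(counts[2, ]) == 0)
    stop("need at least one case and one control")
  z <- ca_trend_chi2(counts[1, 1], counts[1, 2], counts[1, 3],
                     sum(counts[, 1]), sum(counts[, 2]), sum(counts[, 3]))
  if (z$degenerate)
    return(list(chi2 = 0, p_value = 1, flagged = TRUE))
  chi2 <- unname(z$chi2)
  list(chi2 = chi2,
       p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
       flagged = FALSE)
}

#' Run the single-marker association scan
#'
#' Applies the Cochran-Armitage trend test to every SNP of a case/control
#' genotype dataset.  Missing dosages are handled per SNP by complete-case
#' analysis.  Degenerate SNPs (monomorphic in the analysed samples, or with
#' no usable case or control genotypes) are flagged rather than dropped and
#' carry `chi2 = 0`, `p_value = 1`.
#'
#' @param geno Genotype dataset list (`genotypes`, `phenotype`,
#'   `snp_table`) as produced by [sim_genotypes()], [read_plink()] or
#'   [read_geno_text()].
#' @return Data frame of per-SNP statistics in `snp_table` order:
#'   `snp_id`, `chr`, `pos`, `chi2`, `p_value`, `n_used`, `flagged`.
#' @export
run_scan <- function(geno) {
  g <- geno$genotypes
  ph <- geno$phenotype
  if (length(unique(ph[!is.na(ph)])) < 2)
    stop("phenotype must contain both cases and controls")
  case <- ph == 1
  gc <- g[case, , drop = FALSE]
  gt <- g[!case, , drop = FALSE]
  r0 <- colSums(gc == 0, na.rm = TRUE)
  r1 <- colSums(gc == 1, na.rm = TRUE)
  r2 <- colSums(gc == 2, na.rm = TRUE)
  c0 <- colSums(gt == 0, na.rm = TRUE)
  c1 <- colSums(gt == 1, na.rm = TRUE)
  c2 <- colSums(gt == 2, na.rm = TRUE)
  z <- ca_trend_chi2(r0, r1, r2, r0 + c0, r1 + c1, r2 + c2)
  flagged <- z$degenerate
  chi2 <- ifelse(flagged, 0, z$chi2)
  p <- ifelse(flagged, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
  st <- geno$snp_table
  data.frame(snp_id = st$snp_id, chr = st$chr, pos = st$pos,
             chi2 = unname(chi2), p_value = unname(p),
             n_used = unname(r0 + r1 + r2 + c0 + c1 + c2),
             flagged = unname(flagged),
             stringsAsFactors = FALSE)
}

#' Genome-wide proportion of significant SNPs
#'
#' The fraction of informative (non-flagged) SNPs with `p_value < alpha`
#' (strict).  This genome-wide proportion is the baseline against which a
#' gene's own significant-SNP fraction is compared to decide whether the
#' gene is informative for the weighting scheme.
#'
#' @param snp_stats Per-SNP statistics from [run_scan()].
#' @param alpha Significance threshold in `(0, 1)`; default 0.05.
#' @return A single proportion.
#' @export
significant_snp_proportion <- function(snp_stats, alpha = 0.05) {
  if (nrow(snp_stats) == 0)
    stop("empty SNP statistic table")
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  ok <- !snp_stats$flagged
  if (!any(ok)) stop("no informative SNPs")
  sum(snp_stats$p_value[ok] < alpha) / sum(ok)
}
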