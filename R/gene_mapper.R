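#' Map SNPs to genes with symmetric flanks
#'
#' Assigns a SNP to a gene when its position falls within
#' `[start - flank, end + flank]` (1-based, boundaries inclusive) on the
#' same chromosome.  The flank defaults to the conventional 5 kb window on
#' both sides; strand is ignored.  The assignment is many-to-many: a SNP
#' inside two overlapping (flanked) genes maps to both.
#'
#' @param snp_table Data frame with `snp_id`, `chr`, `pos`.
#' @param genes Gene annotation data frame with `gene_symbol`, `chr`,
#'   `start`, `end` (1-based inclusive).
#' @param flank Non-negative flank width in bp added to both gene ends.
#' @return Data frame of assignments (`snp_id`, `gene_symbol`), one row per
#'   (SNP, gene) pair.  SNPs on chromosomes absent from the annotation are
#'   left unmapped with a warning.
#' @export
map_snps_to_genes <- function(snp_table, genes, flank = 5000) {
  if (flank < 0) stop("flank must be non-negative")
  unknown <- setdiff(unique(snp_table$chr), unique(genes$chr))
  if (length(unknown))
    warning("SNPs on chromosome(s) ", paste(unknown, collapse = ", "),
            " have no annotated genes and are left unmapped")
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chr,
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - flank),
                              end = genes$end + flank))
  keep <- snp_table$chr %in% genes$chr
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snp_table$chr[keep],
    ranges = IRanges::IRanges(start = snp_table$pos[keep], width = 1))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  data.frame(snp_id = snp_table$snp_id[keep][S4Vectors::queryHits(hits)],
             gene_symbol = genes$gene_symbol[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Reduce SNP statistics to gene-level statistics
#'
#' For every gene with at least one mapped SNP: the minimum SNP p-value
#' (`p_min`), the gene-wise statistic `t` (the chi-square of the SNP
#' achieving `p_min`; ties broken by smallest p, then lowest genomic
#' position, then lexicographic SNP id), the mapped SNP count, and the
#' fraction of non-flagged mapped SNPs with `p_value < alpha` (strict).
#' Flagged (degenerate) SNPs never win the argmin unless a gene has no
#' informative SNP at all, and are excluded from the significant-fraction
#' denominator.
#'
#' @param snp_stats Per-SNP statistics from [run_scan()].
#' @param assignment SNP-to-gene assignment from [map_snps_to_genes()].
#' @param alpha Significance threshold for the per-gene significant-SNP
#'   fraction; default 0.05.
#' @return Data frame with one row per mapped gene: `gene_symbol`,
#'   `p_min`, `t`, `n_snps`, `sig_proportion`.
#' @export
gene_level_stats <- function(snp_stats, assignment, alpha = 0.05) {
  df <- merge(assignment, snp_stats, by = "snp_id")
  if (nrow(df) == 0)
    return(data.frame(gene_symbol = character(), p_min = numeric(),
                      t = numeric(), n_snps = integer(),
                      sig_proportion = numeric()))
  # deterministic argmin: flagged last, then p, position, id
  o <- order(df$gene_symbol, df$flagged, df$p_value, df$pos, df$snp_id)
  df <- df[o, ]
  first <- !duplicated(df$gene_symbol)
  top <- df[first, ]
  n_snps <- as.vector(table(df$gene_symbol)[top$gene_symbol])
  ok <- !df$flagged
  sig <- tapply(ok & df$p_value < alpha, df$gene_symbol, sum)
  denom <- tapply(ok, df$gene_symbol, sum)
  sp <- ifelse(denom[top$gene_symbol] > 0,
               sig[top$gene_symbol] / denom[top$gene_symbol], 0)
  res <- data.frame(gene_symbol = top$gene_symbol,
                    p_min = top$p_value, t = top$chi2,
                    n_snps = as.integer(n_snps),
                    sig_proportion = as.numeric(sp),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$gene_symbol), ]
}

#' Flag informative genes
#'
#' A gene is informative when its fraction of significant SNPs strictly
#' exceeds the genome-wide fraction of significant SNPs; informative counts
#' within the miTG / non-miTG partition of a pathway drive the weighting
#' scheme.
#'
#' @param gene_stats Gene statistics from [gene_level_stats()].
#' @param genomewide_proportion Genome-wide significant-SNP proportion from
#'   [significant_snp_proportion()]; must lie in `[0, 1]`.
#' @return `gene_stats` with an added logical `informative` column.
#' @export
flag_informative <- function(gene_stats, genomewide_proportion) {
  if (genomewide_proportion < 0 || genomewide_proportion > 1)
    stop("genomewide_proportion must lie in [0, 1]")
  gene_stats$informative <- gene_stats$sig_proportion > genomewide_proportion
  gene_stats
}
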