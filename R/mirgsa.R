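#' miRNA-informed weighted pathway analysis of a case/control GWAS
#'
#' The top-level fitting function.  Runs the full cascade on a genotype
#' dataset: single-marker Cochran-Armitage trend scan, SNP-to-gene mapping
#' with symmetric flanks, gene-level reduction (`p_min` and the chi-square
#' `t` of the most significant SNP), informative-gene flagging against the
#' genome-wide significant-SNP proportion, miTG selection through the
#' miRanda filtering cascade (when prediction tables are supplied), and the
#' four pathway-testing scenarios \{GSEA, SUM\} x \{unweighted, weighted\}
#' with permutation empirical p-values and per-scenario BH-FDR.
#'
#' @param geno Genotype dataset list (`genotypes`, `phenotype`,
#'   `snp_table`), e.g. from [sim_genotypes()], [read_plink()] or
#'   [read_geno_text()].
#' @param genes Gene annotation data frame (`gene_symbol`, `chr`, `start`,
#'   `end`).
#' @param pathways Named list of pathway member vectors, e.g. from
#'   [read_gmt()].
#' @param mitg Optional precomputed miTG gene set; when `NULL` it is
#'   derived from `predictions` and `mirna_classes` via
#'   [select_disease_mirnas()] and [filter_miranda()].
#' @param predictions miRanda-style site prediction table (required when
#'   `mitg` is `NULL`).
#' @param mirna_classes (`mirna`, `class`) annotation table used to select
#'   disease-associated miRNAs.
#' @param classes Disease classes defining the miRNA selection.
#' @param flank SNP-to-gene mapping flank in bp; default 5000.
#' @param alpha Per-SNP significance threshold used for the informative
#'   baseline; default 0.05.
#' @param size_min,size_max Pathway size filter; defaults 10 and 380.
#' @param permutations Number of permutations `B`; the study convention is
#'   5000.
#' @param mode Permutation unit, `"gene_label"` (fast, default) or
#'   `"phenotype"` (full-cascade relabelling).
#' @param gsea_exponent GSEA running-sum exponent; default 1.
#' @param fdr_threshold FDR cutoff used by [summary.mirgsa()]; default
#'   0.01.
#' @param seed Integer seed driving the permutation draws.
#' @return An object of class `"mirgsa"`: a list with `call`, `snp_stats`,
#'   `genome_proportion`, `gene_stats`, `mitg`, `results` (pathway x
#'   method x weighting with `statistic`, `empirical_p`, `q`),
#'   `pathway_info`, and the configuration fields.
#' @examples
#' study <- sim_study(sim_config(n_cases = 80, n_controls = 80,
#'   n_snps = 400, n_genes = 40, n_pathways = 8,
#'   pathway_size_range = c(8, 15), mirna_count = 12, seed = 3))
#' fit <- mirgsa(study$geno, study$genes, study$pathways,
#'               predictions = study$targets$miranda,
#'               mirna_classes = study$targets$mirna_classes,
#'               size_min = 5, permutations = 99, seed = 3)
#' summary(fit)
#' @export
mirgsa <- function(geno, genes, pathways, mitg = NULL,
                   predictions = NULL, mirna_classes = NULL,
                   classes = c("psychiatric", "neurological"),
                   flank = 5000, alpha = 0.05,
                   size_min = 10, size_max = 380,
                   permutations = 5000,
                   mode = c("gene_label", "phenotype"),
                   gsea_exponent = 1, fdr_threshold = 0.01,
                   seed = NULL) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (is.null(mitg) && (is.null(predictions) || is.null(mirna_classes)))
    stop("supply either mitg or both predictions and mirna_classes")
  snp_stats <- run_scan(geno)
  genome_prop <- significant_snp_proportion(snp_stats, alpha)
  assignment <- map_snps_to_genes(geno$snp_table, genes, flank)
  gene_stats <- gene_level_stats(snp_stats, assignment, alpha)
  gene_stats <- flag_informative(gene_stats, genome_prop)

  if (is.null(mitg)) {
    if (is.null(predictions) || is.null(mirna_classes))
      stop("supply either mitg or both predictions and mirna_classes")
    sel <- select_disease_mirnas(mirna_classes, classes)
    kept <- filter_miranda(predictions[predictions$mirna %in% sel, ,
                                       drop = FALSE])
    mitg <- mitg_set(kept)
  }

  results <- run_scenarios(gene_stats, pathways, mitg = mitg,
                           B = permutations, mode = mode, seed = seed,
                           exponent = gsea_exponent,
                           size_min = size_min, size_max = size_max,
                           geno = geno, assignment = assignment,
                           alpha = alpha)
  structure(list(call = cl,
                 snp_stats = snp_stats,
                 genome_proportion = genome_prop,
                 gene_stats = gene_stats,
                 mitg = mitg,
                 results = results,
                 pathway_info = attr(results, "pathway_info"),
                 permutations = permutations,
                 mode = mode,
                 flank = flank, alpha = alpha,
                 fdr_threshold = fdr_threshold,
                 seed = seed),
            class = "mirgsa")
}

#' @export
print.mirgsa <- function(x, ...) {
  cat("miRNA-informed pathway analysis of a case/control GWAS\n\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("SNPs scanned: %d (%.1f%% with p < %.2f)\n",
              nrow(x$snp_stats), 100 * x$genome_proportion, x$alpha))
  cat(sprintf("Genes with statistics: %d (%d informative)\n",
              nrow(x$gene_stats), sum(x$gene_stats$informative)))
  cat(sprintf("miTG set: %d genes\n", length(x$mitg)))
  cat(sprintf("Pathways tested: %d; permutations: %d (%s mode)\n",
              length(unique(x$results$pathway)), x$permutations, x$mode))
  invisible(x)
}

#' Summarise a fitted pathway analysis
#'
#' Tabulates, per scenario, the number of pathways significant at the
#' fitted FDR threshold, and reports the scenario set algebra (both
#' methods per weighting, all four scenarios, union).
#'
#' @param object A `"mirgsa"` fit.
#' @param fdr_threshold FDR cutoff; defaults to the fitted one.
#' @param ... Unused.
#' @return An object of class `"summary.mirgsa"`.
#' @export
summary.mirgsa <- function(object, fdr_threshold = object$fdr_threshold,
                           ...) {
  enr <- summarize_enriched(object$results, fdr_threshold)
  structure(list(fit = object, enriched = enr,
                 fdr_threshold = fdr_threshold),
            class = "summary.mirgsa")
}

#' @export
print.summary.mirgsa <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nPathways with q < %g per scenario:\n", x$fdr_threshold))
  print(x$enriched$counts)
  invisible(x)
}

#' Plot empirical p-values of a fitted pathway analysis
#'
#' One panel per scenario showing the sorted empirical p-values against
#' their uniform expectation, with the FDR-significant pathways marked.
#'
#' @param x A `"mirgsa"` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mirgsa <- function(x, ...) {
  res <- x$results
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (mth in c("GSEA", "SUM")) {
    for (w in c(FALSE, TRUE)) {
      r <- res[res$method == mth & res$weighted == w, ]
      p <- sort(r$empirical_p)
      n <- length(p)
      graphics::plot(ppoints(n), p, xlab = "uniform quantile",
                     ylab = "empirical p",
                     main = sprintf("%s, %sweighted", mth,
                                    if (w) "" else "un"), ...)
      graphics::abline(0, 1, lty = 2)
    }
  }
  invisible(x)
}
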