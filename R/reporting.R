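#' Percentage of miRNA target genes in a pathway
#'
#' `100 * n / (n + m)`, the miTG count divided by the total of miTGs plus
#' non-miTGs, reported to one decimal (rounded half-up, the display
#' convention of the report tables).
#'
#' @param n miTG count.
#' @param m Non-miTG count.
#' @return Percentage to one decimal; `NA` when `n + m = 0` (undefined).
#' @examples
#' percent_mitg(109, 85)  # 56.2
#' @export
percent_mitg <- function(n, m) {
  ifelse(n + m == 0, NA_real_, round_half_up(100 * n / (n + m), 1))
}

#' Scenario set algebra on significant pathways
#'
#' From a [run_scenarios()] result table, extracts the per-scenario sets of
#' pathways significant at `q < fdr_threshold` and their intersections and
#' union: GSEA-and-SUM within each weighting, the pathways significant in
#' all four scenarios, and the overall union.
#'
#' @param results Result table from [run_scenarios()].
#' @param fdr_threshold FDR cutoff (strict); default 0.01.
#' @return List with `sets` (named list of pathway id vectors per scenario,
#'   e.g. `GSEA.unweighted`), `both_methods_unweighted`,
#'   `both_methods_weighted`, `all_scenarios`, `union`, and `counts`
#'   (named integer vector of all of the above).
#' @export
summarize_enriched <- function(results, fdr_threshold = 0.01) {
  scen <- function(mth, w)
    sort(unique(results$pathway[results$method == mth &
                                  results$weighted == w &
                                  results$q < fdr_threshold]))
  sets <- list(GSEA.unweighted = scen("GSEA", FALSE),
               GSEA.weighted = scen("GSEA", TRUE),
               SUM.unweighted = scen("SUM", FALSE),
               SUM.weighted = scen("SUM", TRUE))
  both_unw <- intersect(sets$GSEA.unweighted, sets$SUM.unweighted)
  both_w <- intersect(sets$GSEA.weighted, sets$SUM.weighted)
  all4 <- Reduce(intersect, sets)
  un <- sort(unique(unlist(sets)))
  counts <- c(vapply(sets, length, integer(1)),
              both_methods_unweighted = length(both_unw),
              both_methods_weighted = length(both_w),
              all_scenarios = length(all4),
              union = length(un))
  list(sets = sets, both_methods_unweighted = both_unw,
       both_methods_weighted = both_w, all_scenarios = all4,
       union = un, counts = counts)
}

#' Per-pathway miRNA target-prediction summary
#'
#' For each enriched pathway, summarises the predictions for its miTG
#' members with `p_min < 0.01` (strict): the number of such genes, the
#' distinct miRNAs targeting them, the surviving (miRNA, gene) prediction
#' pairs, and the pairs that additionally pass the DIANA miTG-score filter.
#' Aggregates follow the report conventions: the unweighted mean over
#' pathways of `100 * n_genes / n_mitg` (pathways with no miTG are
#' excluded with a warning), the total of the score-filtered prediction
#' column, and the distinct gene and miRNA counts among score-filtered
#' predictions.
#'
#' @param enriched Named list of enriched pathway member vectors.
#' @param gene_stats Gene statistics (with `p_min`) from
#'   [gene_level_stats()].
#' @param predictions Filtered miRanda predictions (from
#'   [filter_miranda()]), restricted to the selected miRNAs.
#' @param diana DIANA-style prediction table with `mitg_score`, used for
#'   the score-filtered column; pairs absent from it are treated as not
#'   passing.
#' @param p_cut Gene-level significance cutoff (strict); default 0.01.
#' @param score_threshold miTG-score cutoff (strict); default 19.
#' @return List with `table` (one row per pathway: `pathway`, `size`,
#'   `n_mitg`, `n_genes`, `n_mirnas`, `n_predictions`,
#'   `n_predictions_score`), `mean_pct_sig_mitg`,
#'   `total_predictions_score`, `n_unique_genes`, `n_unique_mirnas`.
#' @export
prediction_summary <- function(enriched, gene_stats, predictions, diana,
                               p_cut = 0.01, score_threshold = 19) {
  pairs <- unique(predictions[, c("mirna", "gene_symbol")])
  diana_pass <- filter_diana(diana, score_threshold)
  pass_key <- paste(diana_pass$mirna, diana_pass$gene_symbol)
  pairs$score_pass <- paste(pairs$mirna, pairs$gene_symbol) %in% pass_key
  sig_genes <- gene_stats$gene_symbol[gene_stats$p_min < p_cut]
  mitg <- mitg_set(predictions)

  rows <- lapply(names(enriched), function(pw) {
    members <- enriched[[pw]]
    pw_mitg <- intersect(members, mitg)
    hits <- intersect(pw_mitg, sig_genes)
    pp <- pairs[pairs$gene_symbol %in% hits, , drop = FALSE]
    data.frame(pathway = pw, size = length(members),
               n_mitg = length(pw_mitg), n_genes = length(hits),
               n_mirnas = length(unique(pp$mirna)),
               n_predictions = nrow(pp),
               n_predictions_score = sum(pp$score_pass),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  agg <- prediction_aggregates(tab)
  keep_pairs <- pairs[pairs$score_pass &
                        pairs$gene_symbol %in% sig_genes &
                        pairs$gene_symbol %in%
                          unlist(lapply(enriched, intersect, y = mitg)), ]
  c(list(table = tab), agg,
    list(n_unique_genes = length(unique(keep_pairs$gene_symbol)),
         n_unique_mirnas = length(unique(keep_pairs$mirna))))
}

#' Aggregates of a prediction-summary table
#'
#' Computes the two headline aggregates from a per-pathway prediction
#' summary (either freshly computed by [prediction_summary()] or a
#' transcribed reference table): the unweighted mean over pathways of
#' `100 * n_genes / n_mitg` and the column total of score-filtered
#' predictions.
#'
#' @param tab Data frame with columns `n_mitg`, `n_genes`,
#'   `n_predictions_score`.
#' @return List with `mean_pct_sig_mitg` (one decimal, half-up) and
#'   `total_predictions_score`.
#' @export
prediction_aggregates <- function(tab) {
  ok <- tab$n_mitg > 0
  if (any(!ok))
    warning(sum(!ok), " pathway(s) with no miTG excluded from the mean")
  list(mean_pct_sig_mitg =
         round_half_up(mean(100 * tab$n_genes[ok] / tab$n_mitg[ok]), 1),
       total_predictions_score = sum(tab$n_predictions_score))
}

#' Pearson correlation between two summary-table columns
#'
#' @param tab Data frame with at least 3 rows.
#' @param column_a,column_b Column names; both must be numeric.
#' @return The product-moment correlation reported to two decimals
#'   (half-up); `NA` when either column has zero variance.
#' @export
column_correlation <- function(tab, column_a, column_b) {
  if (nrow(tab) < 3) stop("need at least 3 rows")
  a <- tab[[column_a]]; b <- tab[[column_b]]
  if (!is.numeric(a) || !is.numeric(b))
    stop("both columns must be numeric")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  round_half_up(cor(a, b), 2)
}

#' Genes recurring across enriched pathways
#'
#' Tallies, among score-filtered predicted target genes, how many enriched
#' pathways each gene belongs to, and reports the genes reaching
#' `min_pathways` (inclusive, default 3) together with their gene-level
#' `p_min` and associated miRNAs, sorted by pathway count (descending)
#' then symbol.
#'
#' @param predictions Score-filtered predictions (`mirna`, `gene_symbol`).
#' @param enriched Named list of enriched pathway member vectors.
#' @param gene_stats Gene statistics with `p_min`.
#' @param min_pathways Minimum pathway count (inclusive); default 3.
#' @return Data frame: `gene_symbol`, `n_pathways`, `p_min`, `mirnas`
#'   (comma-separated).
#' @export
multi_pathway_genes <- function(predictions, enriched, gene_stats,
                                min_pathways = 3) {
  genes <- unique(predictions$gene_symbol)
  count <- vapply(genes, function(g)
    sum(vapply(enriched, function(pw) g %in% pw, logical(1))), integer(1))
  keep <- genes[count >= min_pathways]
  if (length(keep) == 0)
    return(data.frame(gene_symbol = character(), n_pathways = integer(),
                      p_min = numeric(), mirnas = character()))
  res <- data.frame(
    gene_symbol = keep,
    n_pathways = count[match(keep, genes)],
    p_min = gene_stats$p_min[match(keep, gene_stats$gene_symbol)],
    mirnas = vapply(keep, function(g)
      paste(sort(unique(predictions$mirna[predictions$gene_symbol == g])),
            collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  res <- res[order(-res$n_pathways, res$gene_symbol), ]
  rownames(res) <- NULL
  res
}

#' Reference table: enriched pathways of the bipolar-disorder study
#'
#' The 38 enriched pathways (19 significant under all four scenarios, 19
#' additional under the weighted scheme) reported by the published
#' bipolar-disorder GWAS pathway analysis this package re-implements, with
#' their miTG / non-miTG counts and printed miTG percentages.  Shipped as
#' a plain-text transcription fixture so the reporting arithmetic can be
#' checked offline against printed values.
#'
#' @return Data frame: `pathway`, `type`, `size`, `n_mitg`, `n_non_mitg`,
#'   `pct_mitg`, `set` (`"core"` for the all-scenario set, `"weighted"`
#'   for the weighting-only additions).
#' @export
bpd_enriched_pathways <- function() {
  read_tsv(system.file("extdata", "bpd_enriched_pathways.tsv",
                       package = "mirgsa"))
}

#' Reference table: per-pathway target-prediction summary
#'
#' The published per-pathway prediction summary for the 38 enriched
#' pathways: pathway size, miTG count, miTG members with `p_min < 0.01`,
#' distinct miRNAs, miRNA:gene prediction pairs, and pairs passing the
#' DIANA miTG-score > 19 filter.  Transcription fixture used to verify
#' [prediction_aggregates()] and [column_correlation()] against printed
#' values.
#'
#' @return Data frame: `pathway`, `size`, `n_mitg`, `n_genes`,
#'   `n_mirnas`, `n_predictions`, `n_predictions_score`.
#' @export
bpd_prediction_summary <- function() {
  read_tsv(system.file("extdata", "bpd_prediction_summary.tsv",
                       package = "mirgsa"))
}
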