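#' Select disease-class-associated miRNAs
#'
#' Returns the deduplicated union of miRNAs annotated to any of the
#' requested disease classes (by default the psychiatric and neurological
#' classes, mirroring a PhenomiR-style annotation).
#'
#' @param mirna_classes Data frame of (`mirna`, `class`) association rows.
#' @param classes Character vector of disease classes to select.
#' @return Sorted character vector of unique miRNA identifiers; empty with
#'   a warning when no row matches.
#' @export
select_disease_mirnas <- function(mirna_classes,
                                  classes = c("psychiatric",
                                              "neurological")) {
  hit <- mirna_classes$class %in% classes
  if (nrow(mirna_classes) > 0 && !any(hit))
    warning("no miRNA annotated to class(es) ",
            paste(classes, collapse = ", "))
  sort(unique(mirna_classes$mirna[hit]))
}

#' Filter miRanda/mirSVR target-site predictions
#'
#' Keeps a predicted target site iff it meets all four criteria
#' (boundary-inclusive): alignment score >= 140, seed-site match length
#' >= 6 nucleotides, hybridisation free energy <= -17 kcal/mol, and
#' conservation score >= 0.57.  A gene enters the miRNA-target-gene (miTG)
#' set if any of its sites for a selected miRNA survives; use [mitg_set()]
#' on the returned table.  Records with a missing required field are
#' skipped, with the skipped count reported via a message.
#'
#' @param predictions Site-level prediction table with columns `mirna`,
#'   `gene_symbol`, `alignment_score`, `seed_length`, `free_energy`,
#'   `conservation` (plus optionally `mirsvr`).
#' @param min_alignment,min_seed,max_energy,min_conservation The four
#'   thresholds; defaults as above.
#' @return The surviving prediction rows.
#' @export
filter_miranda <- function(predictions, min_alignment = 140, min_seed = 6,
                           max_energy = -17, min_conservation = 0.57) {
  req <- c("alignment_score", "seed_length", "free_energy", "conservation")
  missing_cols <- setdiff(req, names(predictions))
  if (length(missing_cols))
    stop("prediction table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  complete <- complete.cases(predictions[, req])
  if (any(!complete))
    message(sum(!complete), " prediction record(s) skipped for missing fields")
  p <- predictions[complete, , drop = FALSE]
  keep <- p$alignment_score >= min_alignment &
    p$seed_length >= min_seed &
    p$free_energy <= max_energy &
    p$conservation >= min_conservation
  p[keep, , drop = FALSE]
}

#' miRNA target gene set of a prediction table
#'
#' @param predictions Prediction rows (typically output of
#'   [filter_miranda()] or [filter_diana()]).
#' @return Sorted unique gene symbols.
#' @export
mitg_set <- function(predictions) {
  sort(unique(predictions$gene_symbol))
}

#' Filter predictions by DIANA-microT miTG score
#'
#' Keeps (miRNA, gene) predictions with `mitg_score` strictly greater than
#' the threshold (default 19, a strict high-confidence cutoff); a score of
#' exactly 19 is dropped.  Used to post-filter miRanda-derived predictions
#' within enriched pathways.
#'
#' @param predictions Prediction table carrying a `mitg_score` column.
#' @param threshold Strict lower cutoff; default 19.
#' @return The surviving prediction rows.
#' @export
filter_diana <- function(predictions, threshold = 19) {
  if (!"mitg_score" %in% names(predictions))
    stop("prediction table lacks a mitg_score column")
  predictions[predictions$mitg_score > threshold, , drop = FALSE]
}

#' Partition a pathway into miTGs and non-miTGs
#'
#' Intersects the pathway's annotated members with the GWAS-covered gene
#' universe (genes that received a gene-level statistic), then partitions
#' the covered members into miRNA target genes (count `n`) and
#' non-target genes (count `m`); `n + m` equals the covered size, which is
#' at most the annotated pathway size.
#'
#' @param pathway_genes Character vector of annotated pathway members.
#' @param mitg Character vector, the miTG gene set.
#' @param gwas_genes Character vector of GWAS-covered gene symbols.
#' @return List with counts `n` and `m` and the member vectors
#'   `mitg_members` and `non_members`.
#' @export
annotate_pathway_mitg <- function(pathway_genes, mitg, gwas_genes) {
  covered <- intersect(pathway_genes, gwas_genes)
  is_t <- covered %in% mitg
  list(n = sum(is_t), m = sum(!is_t),
       mitg_members = covered[is_t], non_members = covered[!is_t])
}
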