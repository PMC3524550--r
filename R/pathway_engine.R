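#' Filter a pathway collection by annotated size
#'
#' Excludes pathways with fewer than `min_size` or more than `max_size`
#' annotated member genes, avoiding bias from extreme set sizes; the
#' boundary sizes themselves are kept.  Sizes are counted on the full
#' annotated membership, before intersection with the GWAS-covered
#' universe.
#'
#' @param pathways Named list of character vectors.
#' @param min_size,max_size Inclusive size bounds; defaults 10 and 380.
#' @return The filtered named list.
#' @export
restrict_pathways <- function(pathways, min_size = 10, max_size = 380) {
  sizes <- lengths(pathways)
  pathways[sizes >= min_size & sizes <= max_size]
}

#' Harmonic-average weights for miTGs and non-miTGs in a pathway
#'
#' Given the pathway's miTG count `n`, non-miTG count `m`, and the numbers
#' of informative genes in each class (`K_n`, `K_m`), assigns the
#' class weights:
#' \itemize{
#'   \item if the informative fraction among miTGs exceeds that among
#'     non-miTGs (`K_n/n > K_m/m`, with `K_m > 0`), the harmonic average
#'     `H = 1 / (1/(m K_n) + 1/(n K_m))` normalises the weights
#'     `w_mitg = m K_n / H` and `w_non = n K_m / H` (algebraically
#'     `w_mitg = 1 + (K_n/n)/(K_m/m)` and `w_non = 1 + (K_m/m)/(K_n/n)`);
#'   \item if no non-miTG is informative but some miTG is (`K_m = 0`,
#'     `K_n > 0`), non-miTGs get weight 1 and miTGs an integer weight 1-6
#'     binned on `K_n/n` with cutoffs 0.1, 0.3, 0.5, 0.7, 0.9 (bins
#'     right-open except the last);
#'   \item otherwise both classes get weight 1.
#' }
#'
#' @param n,m Non-negative member counts (`n + m >= 1`).
#' @param K_n,K_m Informative counts, `0 <= K_n <= n`, `0 <= K_m <= m`.
#' @return List of class `"weight_assignment"`: `n`, `m`, `K_n`, `K_m`,
#'   `H` (`NA` off the ratio branch), `w_mitg`, `w_non`, `branch`.
#' @examples
#' compute_weights(n = 5, K_n = 3, m = 10, K_m = 2)  # w_mitg 4, w_non 4/3
#' @export
compute_weights <- function(n, m, K_n, K_m) {
  if (any(c(n, m, K_n, K_m) < 0) || n + m < 1)
    stop("counts must be non-negative with n + m >= 1")
  if (K_n > n || K_m > m)
    stop("informative counts cannot exceed class sizes")
  rn <- if (n > 0) K_n / n else 0
  rm_ <- if (m > 0) K_m / m else 0
  if (K_m == 0 && K_n > 0) {
    w_mitg <- findInterval(rn, c(0.1, 0.3, 0.5, 0.7, 0.9)) + 1
    out <- list(H = NA_real_, w_mitg = w_mitg, w_non = 1,
                branch = "binned")
  } else if (K_m > 0 && rn > rm_) {
    H <- (m * K_n) * (n * K_m) / (m * K_n + n * K_m)
    out <- list(H = H, w_mitg = m * K_n / H, w_non = n * K_m / H,
                branch = "ratio")
  } else {
    out <- list(H = NA_real_, w_mitg = 1, w_non = 1, branch = "equal")
  }
  structure(c(list(n = n, m = m, K_n = K_n, K_m = K_m), out),
            class = "weight_assignment")
}

#' Apply class weights to gene-wise statistics
#'
#' Scales the gene-wise statistic of pathway members by their class weight
#' (`t' = w t`): miTG members by `w_mitg`, non-miTG members by `w_non`;
#' genes outside the pathway keep their statistic (weight 1).
#'
#' @param stats Named numeric vector of gene-wise statistics `t`.
#' @param pathway_genes Pathway member symbols.
#' @param mitg miTG gene set.
#' @param weights A `"weight_assignment"` from [compute_weights()].
#' @return The weighted named vector `t'`.
#' @export
apply_weights <- function(stats, pathway_genes, mitg, weights) {
  members <- intersect(pathway_genes, names(stats))
  is_t <- members %in% mitg
  stats[members[is_t]] <- stats[members[is_t]] * weights$w_mitg
  stats[members[!is_t]] <- stats[members[!is_t]] * weights$w_non
  stats
}

# core running-sum evaluation given a precomputed descending order and the
# member index set; hits add |t'|^p / N_R, misses subtract 1/(N - N_H)
es_core <- function(tv, ord, member_idx, exponent) {
  N <- length(tv)
  NH <- length(member_idx)
  if (NH >= N)
    stop("pathway spans the whole ranked universe; ES undefined")
  hit <- logical(N)
  hit[member_idx] <- TRUE
  hit <- hit[ord]
  w <- abs(tv[ord])^exponent
  NR <- sum(w[hit])
  incr <- rep.int(-1 / (N - NH), N)
  incr[hit] <- if (NR > 0) w[hit] / NR else 0
  max(0, max(cumsum(incr)))
}

#' GSEA enrichment score of a pathway
#'
#' Weighted Kolmogorov-Smirnov running sum over the genome-wide ranking of
#' gene-wise statistics (equivalently, of ascending gene p-values):
#' walking the list ranked by decreasing statistic, each pathway hit adds
#' `|t'|^exponent / N_R` (with `N_R` the sum of that quantity over all
#' hits) and each miss subtracts `1/(N - N_H)`.  The enrichment score is
#' the maximum of the running sum, or 0 if the sum never becomes positive.
#' Ties in the ranking are broken by gene symbol for determinism.
#'
#' @param stats Named numeric vector of (possibly weighted) gene-wise
#'   statistics over the whole ranked universe.
#' @param pathway_genes Pathway member symbols; must be non-empty within
#'   the universe and a strict subset of it.
#' @param exponent Running-sum weighting exponent; default 1.
#' @return The enrichment score, a number in `[0, 1]`.
#' @export
enrichment_score <- function(stats, pathway_genes, exponent = 1) {
  idx <- which(names(stats) %in% pathway_genes)
  if (length(idx) == 0)
    stop("no pathway gene present in the ranked universe")
  ord <- order(-stats, names(stats))
  es_core(stats, ord, idx, exponent)
}

#' Self-contained sum statistic of a pathway
#'
#' Sums the (possibly weighted) gene-wise statistics over the pathway
#' members.  Members absent from the statistic table contribute 0 and are
#' reported via a message; an empty intersection returns 0 with a warning.
#'
#' @inheritParams enrichment_score
#' @return The sum of member statistics.
#' @export
sum_statistic <- function(stats, pathway_genes) {
  present <- pathway_genes[pathway_genes %in% names(stats)]
  absent <- setdiff(pathway_genes, names(stats))
  if (length(present) == 0) {
    warning("no pathway gene present in the gene statistics; sum is 0")
    return(0)
  }
  if (length(absent))
    message(length(absent), " pathway gene(s) absent from the gene",
            " statistics contribute 0")
  sum(stats[present])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values) controlling the false discovery
#' rate; a thin validating front to the standard step-up algorithm.
#' Output order matches input order.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Vector of q-values in `(0, 1]`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

# observed and permuted GSEA/SUM statistics for every pathway under one
# weighting scenario; returns P x 2 matrices stacked in a list
scenario_statistics <- function(tv, cov_idx, wts, exponent) {
  P <- length(cov_idx)
  es <- numeric(P)
  sm <- numeric(P)
  unweighted <- is.null(wts)
  if (unweighted) {
    ord <- order(-tv, names(tv))
    for (i in seq_len(P)) {
      es[i] <- es_core(tv, ord, cov_idx[[i]], exponent)
      sm[i] <- sum(tv[cov_idx[[i]]])
    }
  } else {
    for (i in seq_len(P)) {
      w <- wts[[i]]
      tw <- tv
      tw[w$mitg_idx] <- tw[w$mitg_idx] * w$w_mitg
      tw[w$non_idx] <- tw[w$non_idx] * w$w_non
      ord <- order(-tw, names(tw))
      es[i] <- es_core(tw, ord, cov_idx[[i]], exponent)
      sm[i] <- sum(tw[cov_idx[[i]]])
    }
  }
  list(es = es, sum = sm)
}

# recompute gene-level state from a phenotype labelling (phenotype-mode
# permutation unit): scan -> gene stats -> informative flags
phenotype_state <- function(geno, assignment, labels, alpha) {
  g2 <- geno
  g2$phenotype <- labels
  ss <- run_scan(g2)
  gs <- gene_level_stats(ss, assignment, alpha)
  flag_informative(gs, significant_snp_proportion(ss, alpha))
}

#' Permutation null for pathway statistics
#'
#' Computes observed GSEA enrichment scores and SUM statistics for each
#' pathway and their empirical p-values from `B` permutations, under one
#' weighting scenario.
#'
#' Two permutation units are available.  `"gene_label"` permutes the
#' assignment of gene-wise statistics to gene symbols and recomputes both
#' statistics; informative flags and class weights are held fixed.
#' `"phenotype"` permutes case/control labels and replays the whole
#' cascade per permutation — scan, gene statistics, genome-wide baseline,
#' informative flags and (when weighting) the weights — preserving
#' exchangeability of everything label-dependent.
#'
#' The empirical p-value uses the add-one convention
#' `(1 + #\{permuted >= observed\}) / (B + 1)`, never returning 0.
#'
#' @param gene_stats Gene statistics with informative flags, from
#'   [flag_informative()].
#' @param pathways Named list of pathway member vectors (already
#'   size-filtered via [restrict_pathways()]).
#' @param B Number of permutations (>= 1); the study convention is 5000.
#' @param mode `"gene_label"` or `"phenotype"`.
#' @param seed Integer seed for the permutation draws (ignored when
#'   `perms` is supplied).
#' @param weighted Apply the harmonic-average weighting scheme?
#' @param mitg miTG gene set (required when `weighted`).
#' @param exponent GSEA running-sum exponent.
#' @param geno,assignment Genotype dataset and SNP-gene assignment;
#'   required in `"phenotype"` mode.
#' @param alpha Significance threshold for informative flags.
#' @param perms Optional pre-drawn permutation index matrix (one column
#'   per permutation): gene indices in `"gene_label"` mode, sample indices
#'   in `"phenotype"` mode.  Supplying the same matrix to several
#'   scenarios makes them share their null draws.
#' @return Data frame with one row per pathway and method: `pathway`,
#'   `method` (`"GSEA"`/`"SUM"`), `weighted`, `statistic`, `empirical_p`.
#'   The per-pathway weighting bookkeeping (`n`, `m`, `K_n`, `K_m`, `H`,
#'   `w_mitg`, `w_non`) is attached as attribute `"pathway_info"`.
#' @export
permutation_null <- function(gene_stats, pathways, B = 5000,
                             mode = c("gene_label", "phenotype"),
                             seed = NULL, weighted = FALSE,
                             mitg = character(), exponent = 1,
                             geno = NULL, assignment = NULL, alpha = 0.05,
                             perms = NULL) {
  mode <- match.arg(mode)
  if (B < 1) stop("B must be >= 1")
  if (length(pathways) == 0) stop("empty pathway collection")
  if (mode == "phenotype" && (is.null(geno) || is.null(assignment)))
    stop("phenotype mode requires geno and assignment")

  universe <- gene_stats$gene_symbol
  tv <- setNames(gene_stats$t, universe)
  N <- length(tv)
  cov <- lapply(pathways, function(g) intersect(g, universe))
  cov_idx <- lapply(cov, function(g) match(g, universe))
  if (any(lengths(cov_idx) >= N))
    stop("a pathway covers the entire gene universe; ES undefined")

  make_weights <- function(gs) {
    inf_genes <- gs$gene_symbol[gs$informative]
    lapply(cov, function(members) {
      is_t <- members %in% mitg
      wa <- compute_weights(n = sum(is_t), m = sum(!is_t),
                            K_n = sum(is_t & members %in% inf_genes),
                            K_m = sum(!is_t & members %in% inf_genes))
      list(w_mitg = wa$w_mitg, w_non = wa$w_non,
           mitg_idx = match(members[is_t], universe),
           non_idx = match(members[!is_t], universe),
           wa = wa)
    })
  }
  wts <- if (weighted) make_weights(gene_stats) else NULL

  obs <- scenario_statistics(tv, cov_idx, wts, exponent)
  exceed_es <- integer(length(cov))
  exceed_sum <- integer(length(cov))

  if (!is.null(seed) && is.null(perms))
    set.seed(substream_seed(seed, "permutations"))

  if (mode == "gene_label") {
    if (is.null(perms))
      perms <- replicate(B, sample.int(N))
    if (ncol(perms) != B) stop("perms must have B columns")
    for (b in seq_len(B)) {
      tb <- setNames(tv[perms[, b]], universe)
      st <- scenario_statistics(tb, cov_idx, wts, exponent)
      exceed_es <- exceed_es + (st$es >= obs$es)
      exceed_sum <- exceed_sum + (st$sum >= obs$sum)
    }
  } else {
    n_samp <- length(geno$phenotype)
    if (is.null(perms))
      perms <- replicate(B, sample.int(n_samp))
    if (ncol(perms) != B) stop("perms must have B columns")
    for (b in seq_len(B)) {
      gs_b <- phenotype_state(geno, assignment,
                              geno$phenotype[perms[, b]], alpha)
      tb <- setNames(gs_b$t, gs_b$gene_symbol)[universe]
      tb[is.na(tb)] <- 0
      names(tb) <- universe
      wts_b <- if (weighted) make_weights(gs_b) else NULL
      st <- scenario_statistics(tb, cov_idx, wts_b, exponent)
      exceed_es <- exceed_es + (st$es >= obs$es)
      exceed_sum <- exceed_sum + (st$sum >= obs$sum)
    }
  }

  res <- data.frame(
    pathway = rep(names(pathways), 2),
    method = rep(c("GSEA", "SUM"), each = length(pathways)),
    weighted = weighted,
    statistic = c(obs$es, obs$sum),
    empirical_p = c((1 + exceed_es) / (B + 1),
                    (1 + exceed_sum) / (B + 1)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL

  info_w <- if (weighted) wts else make_weights(gene_stats)
  attr(res, "pathway_info") <- data.frame(
    pathway = names(pathways),
    size = lengths(pathways),
    n = vapply(info_w, function(w) w$wa$n, numeric(1)),
    m = vapply(info_w, function(w) w$wa$m, numeric(1)),
    K_n = vapply(info_w, function(w) w$wa$K_n, numeric(1)),
    K_m = vapply(info_w, function(w) w$wa$K_m, numeric(1)),
    H = vapply(info_w, function(w) w$wa$H, numeric(1)),
    w_mitg = vapply(info_w, function(w) w$wa$w_mitg, numeric(1)),
    w_non = vapply(info_w, function(w) w$wa$w_non, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  res
}

#' Run all four pathway-testing scenarios
#'
#' Evaluates every pathway under \{GSEA, SUM\} x \{unweighted, weighted\}:
#' size-filters the collection, computes observed statistics and
#' permutation empirical p-values (the weighted and unweighted scenarios
#' share the same permutation draws), and applies Benjamini-Hochberg FDR
#' within each scenario.
#'
#' @inheritParams permutation_null
#' @param size_min,size_max Annotated-size filter bounds (default 10, 380).
#' @return Data frame with one row per pathway x method x weighting:
#'   `pathway`, `method`, `weighted`, `statistic`, `empirical_p`, `q`.
#'   Per-pathway weighting bookkeeping is attached as attribute
#'   `"pathway_info"`.
#' @export
run_scenarios <- function(gene_stats, pathways, mitg = character(),
                          B = 5000, mode = c("gene_label", "phenotype"),
                          seed = NULL, exponent = 1,
                          size_min = 10, size_max = 380,
                          geno = NULL, assignment = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  pathways <- restrict_pathways(pathways, size_min, size_max)
  if (length(pathways) == 0)
    stop("no pathway within the size bounds [", size_min, ", ",
         size_max, "]")
  if (!is.null(seed))
    set.seed(substream_seed(seed, "permutations"))
  n_units <- if (mode == "gene_label") nrow(gene_stats)
             else length(geno$phenotype)
  perms <- replicate(B, sample.int(n_units))

  run1 <- function(weighted) {
    permutation_null(gene_stats, pathways, B = B, mode = mode,
                     weighted = weighted, mitg = mitg, exponent = exponent,
                     geno = geno, assignment = assignment, alpha = alpha,
                     perms = perms)
  }
  unw <- run1(FALSE)
  wgt <- run1(TRUE)
  res <- rbind(unw, wgt)
  res$q <- NA_real_
  for (mth in c("GSEA", "SUM")) {
    for (w in c(FALSE, TRUE)) {
      i <- res$method == mth & res$weighted == w
      res$q[i] <- bh_fdr(res$empirical_p[i])
    }
  }
  rownames(res) <- NULL
  attr(res, "pathway_info") <- attr(wgt, "pathway_info")
  res
}
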