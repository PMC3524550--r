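#' Simulation configuration for a synthetic case/control GWAS study
#'
#' Bundles and validates the parameters of the synthetic-data generator:
#' case/control genotypes under Hardy-Weinberg sampling, gene annotation,
#' pathway collections, and miRNA target-prediction tables with planted
#' structure.  Defaults reflect the study design the package emulates
#' (roughly a thousand cases and controls, an additive per-allele disease
#' model) at a problem size suited to desk-scale simulation.
#'
#' @param n_cases,n_controls Sample sizes of the two phenotype groups.
#' @param n_snps Total number of autosomal SNPs to place.
#' @param n_genes Number of annotated genes.
#' @param n_pathways Number of gene sets in the simulated collection
#'   (extreme-size sets used to exercise the pathway size filter are added
#'   on top when `n_genes` permits).
#' @param maf_range Length-2 numeric, minor allele frequencies drawn
#'   uniformly from `[maf_range[1], maf_range[2]]`; must lie in `[0, 0.5]`.
#' @param causal_pathways Character vector of pathway ids carrying planted
#'   association signal (empty for a null study).
#' @param causal_gene_fraction Fraction of genes within each causal pathway
#'   whose SNPs receive the effect.
#' @param effect_odds_ratio Per-allele odds ratio (>= 1) applied to SNPs in
#'   causal genes: case allele odds are `effect_odds_ratio` times control
#'   allele odds.
#' @param snps_per_gene_range Length-2 integer range of SNP counts placed
#'   inside each gene body.
#' @param pathway_size_range Length-2 integer range of simulated set sizes;
#'   must lie within `[2, n_genes]`.
#' @param mirna_count Number of simulated miRNAs.
#' @param target_density Probability that a given (miRNA, gene) pair has a
#'   target-site prediction; must be in `(0, 1)`.
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @param seed Root integer seed; all generator randomness flows from it
#'   through named substreams, so identical configurations give
#'   bit-identical outputs.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_cases = 50, n_controls = 50, n_snps = 200,
#'                   n_genes = 20, n_pathways = 5, seed = 1)
#' @export
sim_config <- function(n_cases = 1001, n_controls = 1034, n_snps = 2000,
                       n_genes = 200, n_pathways = 100,
                       maf_range = c(0.05, 0.5),
                       causal_pathways = character(),
                       causal_gene_fraction = 0.3,
                       effect_odds_ratio = 1,
                       snps_per_gene_range = c(3, 12),
                       pathway_size_range = c(10, 60),
                       mirna_count = 157, target_density = 0.3,
                       missing_rate = 0, seed = 1L) {
  counts <- c(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
              n_genes = n_genes, n_pathways = n_pathways,
              mirna_count = mirna_count)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] < 0 || maf_range[2] > 0.5)
    stop("maf_range must be an increasing pair within [0, 0.5]")
  if (effect_odds_ratio < 1)
    stop("effect_odds_ratio must be >= 1")
  if (causal_gene_fraction < 0 || causal_gene_fraction > 1 ||
      missing_rate < 0 || missing_rate > 1)
    stop("proportions must lie in [0, 1]")
  if (length(snps_per_gene_range) != 2 ||
      snps_per_gene_range[1] > snps_per_gene_range[2] ||
      snps_per_gene_range[1] < 1)
    stop("snps_per_gene_range must be an increasing pair of counts >= 1")
  if (length(pathway_size_range) != 2 ||
      pathway_size_range[1] > pathway_size_range[2] ||
      pathway_size_range[1] < 2 || pathway_size_range[2] > n_genes)
    stop("pathway_size_range must lie within [2, n_genes]")
  if (target_density <= 0 || target_density >= 1)
    stop("target_density must lie in (0, 1)")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_snps = as.integer(n_snps),
                 n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 maf_range = as.numeric(maf_range),
                 causal_pathways = as.character(causal_pathways),
                 causal_gene_fraction = causal_gene_fraction,
                 effect_odds_ratio = effect_odds_ratio,
                 snps_per_gene_range = as.integer(snps_per_gene_range),
                 pathway_size_range = as.integer(pathway_size_range),
                 mirna_count = as.integer(mirna_count),
                 target_density = target_density,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a gene annotation table
#'
#' Places `n_genes` non-overlapping gene intervals on one synthetic
#' chromosome.  Coordinates are 1-based and inclusive.  Inter-gene gaps are
#' drawn wider than twice the conventional 5 kb mapping flank, so SNPs can
#' later be placed in all three strata: inside a gene body, within a flank,
#' and outside any flanked region.
#'
#' @param config A [sim_config()] object.
#' @param chrom_length Optional chromosome length; if supplied and too
#'   short to hold the placed genes, a configuration error is raised.
#' @return Data frame with columns `gene_symbol`, `chr`, `start`, `end`,
#'   `strand`.
#' @export
sim_gene_annotation <- function(config, chrom_length = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "annotation"))
  ng <- config$n_genes
  len <- round(runif(ng, 5000, 30000))
  gap <- round(runif(ng, 12000, 25000))
  start <- cumsum(gap) + cumsum(c(0, len[-ng]))
  end <- start + len - 1
  if (!is.null(chrom_length) && max(end) + 12000 > chrom_length)
    stop("chromosome too short to place ", ng, " genes")
  data.frame(gene_symbol = sprintf("G%04d", seq_len(ng)),
             chr = "1", start = as.integer(start), end = as.integer(end),
             strand = rep_len(c("+", "-"), ng),
             stringsAsFactors = FALSE)
}

# place SNP positions relative to the gene intervals so that the inside,
# flank (within 5 kb) and outside strata are all non-empty
sim_snp_positions <- function(config, genes, flank = 5000) {
  ng <- nrow(genes)
  k <- sample(config$snps_per_gene_range[1]:config$snps_per_gene_range[2],
              ng, replace = TRUE)
  if (sum(k) + 2 > config$n_snps)
    stop("n_snps too small: need at least ", sum(k) + 2,
         " for this gene layout")
  inside_pos <- unlist(lapply(seq_len(ng), function(i) {
    sort(sample(genes$start[i]:genes$end[i], k[i]))
  }))
  inside_gene <- rep(genes$gene_symbol, k)
  n_extra <- config$n_snps - length(inside_pos)
  n_flank <- max(1L, round(0.2 * n_extra))
  n_out <- n_extra - n_flank
  if (n_out < 1) { n_flank <- n_extra - 1L; n_out <- 1L }
  gi <- sample(seq_len(ng), n_flank, replace = TRUE)
  side <- sample(c(-1, 1), n_flank, replace = TRUE)
  off <- sample(seq_len(flank), n_flank, replace = TRUE)
  flank_pos <- ifelse(side < 0, genes$start[gi] - off, genes$end[gi] + off)
  # gaps are > 2 * flank wide, so their centres lie outside every flank
  gap_lo <- c(1, genes$end[-ng] + flank + 1)
  gap_hi <- genes$start - flank - 1
  ok <- which(gap_hi - gap_lo > 100)
  gj <- sample(ok, n_out, replace = TRUE)
  out_pos <- gap_lo[gj] +
    floor(runif(n_out) * (gap_hi[gj] - gap_lo[gj] + 1))
  pos <- c(inside_pos, flank_pos, out_pos)
  stratum <- c(rep("inside", length(inside_pos)),
               rep("flank", n_flank), rep("outside", n_out))
  gene <- c(inside_gene, rep(NA_character_, n_flank + n_out))
  o <- order(pos)
  data.frame(snp_id = sprintf("rs%06d", seq_along(pos)),
             chr = "1", pos = as.integer(pos[o]),
             stratum = stratum[o], in_gene = gene[o],
             stringsAsFactors = FALSE)
}

#' Simulate case/control genotypes
#'
#' Draws minor-allele dosages per SNP from a Hardy-Weinberg binomial model
#' at a MAF sampled uniformly from `maf_range`.  Under the null (no causal
#' genes) cases and controls share the same allele frequency.  SNPs inside
#' causal genes have their case allele frequency tilted by the per-allele
#' odds ratio: with control MAF `p`, cases are sampled at
#' `p' = OR * p / (1 - p + OR * p)` (allele odds multiplied by `OR`), the
#' standard retrospective model for a multiplicative per-allele effect.
#'
#' @param config A [sim_config()] object.
#' @param genes Gene annotation from [sim_gene_annotation()]; generated
#'   from `config` when `NULL`.
#' @param causal_genes Character vector of gene symbols whose body SNPs
#'   carry the effect.
#' @return A genotype dataset: list with `genotypes` (samples x SNPs
#'   integer dosage matrix, `NA` = missing), `phenotype` (1 = case,
#'   0 = control), and `snp_table` (`snp_id`, `chr`, `pos`, plus the
#'   placement `stratum` and `in_gene` bookkeeping columns and a logical
#'   `causal` column).
#' @export
sim_genotypes <- function(config, genes = NULL, causal_genes = character()) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(genes)) genes <- sim_gene_annotation(config)
  set.seed(substream_seed(config$seed, "genotypes"))
  st <- sim_snp_positions(config, genes)
  st$causal <- !is.na(st$in_gene) & st$in_gene %in% causal_genes &
    config$effect_odds_ratio > 1
  p <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  or <- config$effect_odds_ratio
  p_case <- ifelse(st$causal, or * p / (1 - p + or * p), p)
  nca <- config$n_cases; nco <- config$n_controls
  g_case <- matrix(rbinom(nca * config$n_snps, 2, rep(p_case, each = nca)),
                   nrow = nca)
  g_ctrl <- matrix(rbinom(nco * config$n_snps, 2, rep(p, each = nco)),
                   nrow = nco)
  g <- rbind(g_case, g_ctrl)
  if (config$missing_rate > 0)
    g[runif(length(g)) < config$missing_rate] <- NA_integer_
  storage.mode(g) <- "integer"
  rownames(g) <- sprintf("S%05d", seq_len(nca + nco))
  colnames(g) <- st$snp_id
  list(genotypes = g,
       phenotype = c(rep(1L, nca), rep(0L, nco)),
       snp_table = st,
       maf = p)
}

#' Simulate a pathway (gene-set) collection
#'
#' Samples `n_pathways` gene sets without replacement within each set, with
#' sizes uniform on `pathway_size_range`.  When `n_genes` permits, two
#' extreme sets (`SIZE5_SET` with 5 genes, `SIZE400_SET` with 400) are
#' appended so the 10..380 pathway size filter is exercised at both ends.
#'
#' @param gene_symbols Character vector of available gene symbols.
#' @param config A [sim_config()] object.
#' @param disjoint When `TRUE`, pathways are sampled without replacement
#'   across sets as well, so no gene belongs to two pathways.  Used in
#'   parameter-recovery experiments where planted signal must stay
#'   confined to the causal pathways; requires enough genes for the
#'   requested sizes.
#' @return Named list of character vectors (pathway id -> member symbols).
#' @export
sim_pathways <- function(gene_symbols, config, disjoint = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pathway_size_range[2] > length(gene_symbols))
    stop("pathway_size_range infeasible for ", length(gene_symbols),
         " genes")
  set.seed(substream_seed(config$seed, "pathways"))
  sizes <- sample(config$pathway_size_range[1]:config$pathway_size_range[2],
                  config$n_pathways, replace = TRUE)
  if (disjoint) {
    if (sum(sizes) > length(gene_symbols))
      stop("disjoint pathways need at least ", sum(sizes), " genes")
    pool <- sample(gene_symbols, sum(sizes))
    pws <- split(pool, rep(seq_along(sizes), sizes))
  } else {
    pws <- lapply(sizes, function(s) sample(gene_symbols, s))
  }
  names(pws) <- sprintf("PW%04d", seq_along(pws))
  if (length(gene_symbols) >= 5)
    pws$SIZE5_SET <- sample(gene_symbols, 5)
  if (length(gene_symbols) >= 400)
    pws$SIZE400_SET <- sample(gene_symbols, 400)
  pws
}

#' Simulate miRNA target-prediction tables
#'
#' Generates a miRanda/mirSVR-style site table (alignment score, seed-site
#' length, free energy, conservation, mirSVR score), a DIANA-style table
#' with per-(miRNA, gene) miTG scores straddling the 19 cutoff, and a
#' phenotype-class annotation table for the miRNAs.  Every predicted pair
#' is planted either to pass all four miRanda thresholds or to fail at
#' least one, so the filter cascade has known positive and negative sets.
#'
#' @param mirnas Character vector of miRNA identifiers.
#' @param gene_symbols Character vector of gene symbols.
#' @param config A [sim_config()] object.
#' @return List with elements `miranda` (site-level prediction table),
#'   `diana` (per-pair miTG scores), `mirna_classes` (`mirna`, `class`
#'   association rows), and the planted truth: `planted_pass` /
#'   `planted_fail` data frames of (mirna, gene_symbol) pairs.
#' @export
sim_target_predictions <- function(mirnas, gene_symbols, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(mirnas) == 0 || length(gene_symbols) == 0)
    stop("mirnas and gene_symbols must be non-empty")
  set.seed(substream_seed(config$seed, "targets"))
  pairs <- expand.grid(mirna = mirnas, gene_symbol = gene_symbols,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[runif(nrow(pairs)) < config$target_density, , drop = FALSE]
  if (nrow(pairs) == 0)
    stop("target_density too low: no pairs drawn")
  np <- nrow(pairs)
  pass <- runif(np) < 0.5
  draw_site <- function(ok) {
    n <- length(ok)
    # which criterion a failing site violates
    fail_on <- sample(4, n, replace = TRUE)
    align <- ifelse(ok | fail_on != 1, runif(n, 140, 185),
                    runif(n, 100, 139.5))
    seedl <- ifelse(ok | fail_on != 2, sample(6:8, n, replace = TRUE),
                    sample(2:5, n, replace = TRUE))
    energy <- ifelse(ok | fail_on != 3, runif(n, -35, -17),
                     runif(n, -16.5, -5))
    cons <- ifelse(ok | fail_on != 4, runif(n, 0.57, 1),
                   runif(n, 0, 0.56))
    data.frame(alignment_score = round(align, 1), seed_length = seedl,
               free_energy = round(energy, 2), conservation = round(cons, 3),
               mirsvr = round(runif(n, -1.5, -0.1), 4))
  }
  miranda <- cbind(pairs, draw_site(pass))
  # a fraction of passing pairs get a second predicted site
  dup <- which(pass & runif(np) < 0.1)
  if (length(dup))
    miranda <- rbind(miranda, cbind(pairs[dup, ], draw_site(rep(TRUE,
                                                       length(dup)))))
  rownames(miranda) <- NULL
  diana <- cbind(pairs,
                 mitg_score = round(runif(np, 5, 35), 2))
  rownames(diana) <- NULL

  disease <- c("psychiatric", "neurological", "cancer", "metabolic",
               "cardiovascular")
  m <- length(mirnas)
  cls1 <- sample(disease, m, replace = TRUE,
                 prob = c(0.25, 0.25, 0.2, 0.15, 0.15))
  # guarantee every required class is represented
  cls1[1] <- "psychiatric"; if (m > 1) cls1[2] <- "neurological"
  if (m > 2) cls1[3] <- "cancer"
  extra <- runif(m) < 0.3
  cls2 <- sample(disease, m, replace = TRUE)
  classes <- rbind(data.frame(mirna = mirnas, class = cls1),
                   data.frame(mirna = mirnas[extra], class = cls2[extra]))
  classes <- unique(classes[order(classes$mirna, classes$class), ])
  rownames(classes) <- NULL
  list(miranda = miranda, diana = diana, mirna_classes = classes,
       planted_pass = pairs[pass, , drop = FALSE],
       planted_fail = pairs[!pass, , drop = FALSE])
}

#' Simulate a complete synthetic study
#'
#' Orchestrates all generators from one configuration: gene annotation,
#' pathway collection, causal gene selection within the configured causal
#' pathways, case/control genotypes, miRNA identifiers and target
#' predictions.
#'
#' @param config A [sim_config()] object.
#' @param disjoint_pathways Passed to [sim_pathways()]; keeps planted
#'   signal confined to the causal pathways.
#' @return List with `config`, `genes`, `pathways`, `geno`, `mirnas`,
#'   `targets`, and `causal_genes`.
#' @examples
#' study <- sim_study(sim_config(n_cases = 60, n_controls = 60,
#'                    n_snps = 300, n_genes = 30, n_pathways = 6,
#'                    pathway_size_range = c(5, 10), mirna_count = 10,
#'                    seed = 7))
#' @export
sim_study <- function(config, disjoint_pathways = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_annotation(config)
  pathways <- sim_pathways(genes$gene_symbol, config, disjoint_pathways)
  missing_cp <- setdiff(config$causal_pathways, names(pathways))
  if (length(missing_cp))
    stop("unknown causal pathway ids: ", paste(missing_cp, collapse = ", "))
  set.seed(substream_seed(config$seed, "study"))
  causal_genes <- unique(unlist(lapply(config$causal_pathways, function(pw) {
    members <- pathways[[pw]]
    sample(members, max(1, ceiling(config$causal_gene_fraction *
                                     length(members))))
  })))
  if (is.null(causal_genes)) causal_genes <- character()
  geno <- sim_genotypes(config, genes, causal_genes)
  mirnas <- sprintf("hsa-miR-%03d", seq_len(config$mirna_count))
  targets <- sim_target_predictions(mirnas, genes$gene_symbol, config)
  list(config = config, genes = genes, pathways = pathways, geno = geno,
       mirnas = mirnas, targets = targets, causal_genes = causal_genes)
}
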