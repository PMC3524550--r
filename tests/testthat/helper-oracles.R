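# Independent oracles used across the suite.  Each re-derives the target
# quantity by a different route than the implementation (individual-level
# expansion, literal loops over definitions, all-pairs scans).

# Cochran-Armitage trend chi-square via individual-level expansion:
# the 1-df trend statistic equals N * cor(dosage, status)^2
trend_chi2_oracle <- function(cases, controls) {
  x <- c(rep(0:2, times = cases), rep(0:2, times = controls))
  y <- c(rep(1L, sum(cases)), rep(0L, sum(controls)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  length(x) * stats::cor(x, y)^2
}

# literal loop over the weighted Kolmogorov-Smirnov running-sum definition
es_oracle <- function(stats, pathway, exponent = 1) {
  o <- order(-stats, names(stats))
  nm <- names(stats)[o]
  hit <- nm %in% pathway
  N <- length(stats)
  NH <- sum(hit)
  NR <- sum(abs(stats[o][hit])^exponent)
  s <- 0; best <- 0
  for (i in seq_len(N)) {
    s <- s + if (hit[i]) abs(stats[o][i])^exponent / NR else -1 / (N - NH)
    if (s > best) best <- s
  }
  best
}

# literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  qo <- vapply(seq_len(m), function(i) min(m * po[i:m] / (i:m)), numeric(1))
  q <- numeric(m)
  q[o] <- pmin(qo, 1)
  q
}

# all-pairs interval containment scan for SNP-gene assignment
map_oracle <- function(snp_table, genes, flank = 5000) {
  rows <- list()
  for (i in seq_len(nrow(snp_table))) {
    for (j in seq_len(nrow(genes))) {
      if (snp_table$chr[i] == genes$chr[j] &&
          snp_table$pos[i] >= genes$start[j] - flank &&
          snp_table$pos[i] <= genes$end[j] + flank)
        rows[[length(rows) + 1]] <- data.frame(
          snp_id = snp_table$snp_id[i],
          gene_symbol = genes$gene_symbol[j])
    }
  }
  if (!length(rows))
    return(data.frame(snp_id = character(), gene_symbol = character()))
  do.call(rbind, rows)
}

# random non-degenerate 2x3 case/control tables
random_tables <- function(n, max_count = 200, seed = 1) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    ca <- rmultinom(1, sample(20:max_count, 1), c(0.3, 0.5, 0.2))[, 1]
    co <- rmultinom(1, sample(20:max_count, 1), c(0.3, 0.5, 0.2))[, 1]
    tot <- ca + co
    if (sum(tot > 0) >= 2) out[[length(out) + 1]] <- list(ca = ca, co = co)
  }
  out
}

# small study configuration shared by several end-to-end tests
tiny_config <- function(seed = 1, ...) {
  sim_config(n_cases = 60, n_controls = 60, n_snps = 300, n_genes = 30,
             n_pathways = 6, pathway_size_range = c(5, 12),
             mirna_count = 10, seed = seed, ...)
}
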