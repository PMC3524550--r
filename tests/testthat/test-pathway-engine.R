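test_that("pathway size filter keeps the boundary sizes", {
  pws <- list(a = letters[1:9], b = letters[1:10],
              c = sprintf("g%d", 1:380), d = sprintf("g%d", 1:381))
  kept <- restrict_pathways(pws)
  expect_setequal(names(kept), c("b", "c"))
  expect_length(restrict_pathways(list()), 0)
})

test_that("harmonic-average weights follow the three branches", {
  w <- compute_weights(n = 5, m = 10, K_n = 3, K_m = 2)
  expect_equal(w$H, 7.5)
  expect_equal(w$w_mitg, 4)
  expect_equal(w$w_non, 4 / 3)
  expect_equal(w$branch, "ratio")
  # equal informative fractions: both weights 1
  w <- compute_weights(n = 10, m = 20, K_n = 2, K_m = 4)
  expect_equal(c(w$w_mitg, w$w_non), c(1, 1))
  # miTG fraction below the non-miTG fraction: equal weights
  w <- compute_weights(n = 10, m = 10, K_n = 1, K_m = 5)
  expect_equal(c(w$w_mitg, w$w_non), c(1, 1))
  # K_m = 0 branch: binned integer weights on K_n / n
  expect_equal(compute_weights(20, 10, 11, 0)$w_mitg, 4)  # 0.55 -> bin 4
  expect_equal(compute_weights(20, 10, 1, 0)$w_mitg, 1)   # 0.05 -> bin 1
  expect_equal(compute_weights(20, 10, 2, 0)$w_mitg, 2)   # 0.10 -> bin 2
  expect_equal(compute_weights(10, 10, 9, 0)$w_mitg, 6)   # 0.90 -> bin 6
  expect_equal(compute_weights(10, 10, 10, 0)$w_mitg, 6)
  expect_equal(compute_weights(20, 10, 11, 0)$w_non, 1)
  # no informative genes at all
  expect_equal(compute_weights(5, 5, 0, 0)$branch, "equal")
  expect_error(compute_weights(5, 5, 6, 0), "exceed")
  expect_error(compute_weights(0, 0, 0, 0), "n \\+ m")
})

test_that("ratio-branch weights satisfy the algebraic identities", {
  set.seed(2)
  done <- 0
  while (done < 500) {
    n <- sample(1:50, 1); m <- sample(1:50, 1)
    K_n <- sample(0:n, 1); K_m <- sample(0:m, 1)
    if (K_m == 0 || K_n / n <= K_m / m) next
    w <- compute_weights(n, m, K_n, K_m)
    expect_lt(abs(w$w_mitg - (1 + (K_n / n) / (K_m / m))), 1e-12)
    expect_lt(abs(w$w_non - (1 + (K_m / m) / (K_n / n))), 1e-12)
    expect_gt(w$w_mitg, w$w_non)
    expect_gt(w$w_non, 1)
    done <- done + 1
  }
})

test_that("weights scale member statistics and reduce to identity", {
  stats <- c(A = 2, B = 3, C = 4)
  w1 <- compute_weights(2, 3, 0, 0)
  expect_equal(apply_weights(stats, c("A", "B"), "A", w1), stats)
  w <- compute_weights(n = 5, m = 10, K_n = 3, K_m = 2)  # 4 and 4/3
  out <- apply_weights(c(A = 2, B = 3, C = 4), c("A", "B"), "A", w)
  expect_equal(unname(out), c(8, 4, 4))
})

test_that("enrichment score follows the stated running-sum rule", {
  stats <- c(g1 = 9, g2 = 4, g3 = 1)
  expect_equal(enrichment_score(stats, "g1"), 1)
  expect_equal(enrichment_score(stats, "g3"), 0)  # never positive
  expect_error(enrichment_score(stats, c("g1", "g2", "g3")), "universe")
  expect_error(enrichment_score(stats, "absent"), "no pathway gene")
})

test_that("enrichment score equals the brute-force oracle and stays in [0,1]", {
  set.seed(12)
  for (i in 1:30) {
    stats <- setNames(rchisq(20, df = 1), sprintf("g%02d", 1:20))
    pw <- sample(names(stats), sample(2:10, 1))
    es <- enrichment_score(stats, pw)
    expect_lt(abs(es - es_oracle(stats, pw)), 1e-12)
    expect_gte(es, 0)
    expect_lte(es, 1)
  }
  # single hit occupying the top rank gives exactly 1
  stats <- setNames(c(10, 3, 2, 1), c("a", "b", "c", "d"))
  expect_equal(enrichment_score(stats, "a"), 1)
})

test_that("sum statistic adds member statistics, tolerating absences", {
  stats <- c(A = 2, B = 3, C = 4)
  expect_equal(sum_statistic(stats, c("A", "B", "C")), 9)
  expect_equal(sum_statistic(c(A = 8, B = 12, C = 6), c("A", "B", "C")), 26)
  expect_message(s <- sum_statistic(stats, c("A", "Z")), "absent")
  expect_equal(s, 2)
  expect_warning(s0 <- sum_statistic(stats, "Z"), "sum is 0")
  expect_equal(s0, 0)
})

test_that("BH adjustment matches hand-worked cases and the step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(5)
  for (i in 1:100) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("empirical p-values equal a brute-force recount of exceedances", {
  set.seed(61)
  genes <- sprintf("g%02d", 1:25)
  gs <- data.frame(gene_symbol = genes, t = rchisq(25, 1),
                   p_min = runif(25), sig_proportion = 0,
                   informative = FALSE)
  pws <- list(P1 = genes[1:6], P2 = genes[c(3, 9, 15, 21)],
              P3 = genes[20:25])
  B <- 100
  res <- permutation_null(gs, pws, B = B, mode = "gene_label", seed = 77)
  # independent recount with the same permutation stream
  tv <- setNames(gs$t, genes)
  set.seed(mirgsa:::substream_seed(77, "permutations"))
  perms <- replicate(B, sample.int(25))
  for (pw in names(pws)) {
    obs_es <- enrichment_score(tv, pws[[pw]])
    obs_sum <- sum(tv[pws[[pw]]])
    ce <- cs <- 0
    for (b in seq_len(B)) {
      tb <- setNames(tv[perms[, b]], genes)
      if (enrichment_score(tb, pws[[pw]]) >= obs_es) ce <- ce + 1
      if (sum(tb[pws[[pw]]]) >= obs_sum) cs <- cs + 1
    }
    r <- res[res$pathway == pw, ]
    expect_equal(r$empirical_p[r$method == "GSEA"], (1 + ce) / (B + 1))
    expect_equal(r$empirical_p[r$method == "SUM"], (1 + cs) / (B + 1))
  }
  expect_true(all(res$empirical_p >= 1 / (B + 1)))
})

test_that("identical statistics give empirical p of exactly 1", {
  genes <- sprintf("g%d", 1:12)
  gs <- data.frame(gene_symbol = genes, t = rep(2, 12), p_min = 0.5,
                   sig_proportion = 0, informative = FALSE)
  res <- permutation_null(gs, list(P = genes[1:4]), B = 19,
                          mode = "gene_label", seed = 1)
  expect_true(all(res$empirical_p == 1))
})

test_that("null empirical p-values are uniform on the achievable grid", {
  set.seed(202)
  genes <- sprintf("g%03d", 1:300)
  gs <- data.frame(gene_symbol = genes, t = rchisq(300, 1), p_min = 0.5,
                   sig_proportion = 0, informative = FALSE)
  pws <- lapply(1:200, function(i) sample(genes, 20))
  names(pws) <- sprintf("P%03d", 1:200)
  res <- permutation_null(gs, pws, B = 199, mode = "gene_label", seed = 3)
  p <- res$empirical_p[res$method == "SUM"]
  counts <- table(cut(p, breaks = seq(0, 1, by = 0.1)))
  gof <- sum((counts - 20)^2 / 20)
  expect_gt(pchisq(gof, df = 9, lower.tail = FALSE), 1e-4)
  expect_gt(min(p), 0)
  expect_lte(max(p), 1)
})

test_that("phenotype-mode permutation replays the cascade", {
  cfg <- tiny_config(seed = 44)
  study <- sim_study(cfg)
  ss <- run_scan(study$geno)
  asg <- map_snps_to_genes(study$geno$snp_table, study$genes)
  gs <- flag_informative(gene_level_stats(ss, asg),
                         significant_snp_proportion(ss))
  pws <- restrict_pathways(study$pathways, 5, 380)
  mitg <- mitg_set(filter_miranda(study$targets$miranda))
  res <- permutation_null(gs, pws, B = 20, mode = "phenotype", seed = 9,
                          weighted = TRUE, mitg = mitg,
                          geno = study$geno, assignment = asg)
  expect_true(all(res$empirical_p >= 1 / 21 & res$empirical_p <= 1))
  expect_error(permutation_null(gs, pws, B = 5, mode = "phenotype"),
               "requires geno")
})

test_that("scenario runs are deterministic and reduce under equal weights", {
  cfg <- tiny_config(seed = 14)
  study <- sim_study(cfg)
  ss <- run_scan(study$geno)
  asg <- map_snps_to_genes(study$geno$snp_table, study$genes)
  gs <- flag_informative(gene_level_stats(ss, asg),
                         significant_snp_proportion(ss))
  r1 <- run_scenarios(gs, study$pathways, mitg = character(), B = 50,
                      seed = 5, size_min = 5)
  r2 <- run_scenarios(gs, study$pathways, mitg = character(), B = 50,
                      seed = 5, size_min = 5)
  expect_identical(r1, r2)
  # empty miTG set forces the equal-weights branch everywhere
  unw <- r1[!r1$weighted, c("pathway", "method", "statistic",
                            "empirical_p", "q")]
  wgt <- r1[r1$weighted, c("pathway", "method", "statistic",
                           "empirical_p", "q")]
  rownames(unw) <- rownames(wgt) <- NULL
  expect_identical(unw, wgt)
  info <- attr(r1, "pathway_info")
  expect_true(all(info$w_mitg == 1 & info$w_non == 1))
})
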