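test_that("identical config and seed give bit-identical outputs", {
  s1 <- sim_study(tiny_config(seed = 11))
  s2 <- sim_study(tiny_config(seed = 11))
  expect_identical(s1$geno$genotypes, s2$geno$genotypes)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$pathways, s2$pathways)
  expect_identical(s1$targets$miranda, s2$targets$miranda)
  s3 <- sim_study(tiny_config(seed = 12))
  expect_false(identical(s1$geno$genotypes, s3$geno$genotypes))
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(maf_range = c(0.4, 0.1)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.7)), "maf_range")
  expect_error(sim_config(effect_odds_ratio = 0.5), "odds_ratio")
  expect_error(sim_config(n_genes = 0), "counts")
  expect_error(sim_config(target_density = 0), "target_density")
  expect_error(sim_config(n_genes = 10, pathway_size_range = c(2, 50)),
               "pathway_size_range")
  cfg <- tiny_config()
  expect_error(sim_gene_annotation(cfg, chrom_length = 1000),
               "chromosome too short")
})

test_that("forcing MAF to zero gives all-zero dosages", {
  g <- sim_genotypes(tiny_config(maf_range = c(0, 0)))
  expect_true(all(g$genotypes == 0))
})

test_that("null generator is calibrated: trend-test type-I error near 0.05", {
  hits <- 0; total <- 0
  for (seed in 1:3) {
    cfg <- sim_config(n_cases = 300, n_controls = 300, n_snps = 10000,
                      n_genes = 200, n_pathways = 10, seed = seed)
    ss <- run_scan(sim_genotypes(cfg))
    ok <- !ss$flagged
    hits <- hits + sum(ss$p_value[ok] < 0.05)
    total <- total + sum(ok)
  }
  ci <- qbinom(c(0.005, 0.995), total, 0.05) / total
  frac <- hits / total
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("SNP placement fills all three strata, verified by brute force", {
  cfg <- tiny_config(seed = 5)
  genes <- sim_gene_annotation(cfg)
  g <- sim_genotypes(cfg, genes)
  st <- g$snp_table
  inside <- flank <- outside <- 0
  for (i in seq_len(nrow(st))) {
    d_in <- any(st$pos[i] >= genes$start & st$pos[i] <= genes$end)
    d_fl <- any(st$pos[i] >= genes$start - 5000 &
                  st$pos[i] <= genes$end + 5000)
    if (d_in) inside <- inside + 1
    else if (d_fl) flank <- flank + 1
    else outside <- outside + 1
  }
  expect_gt(inside, 0); expect_gt(flank, 0); expect_gt(outside, 0)
  expect_equal(unname(table(st$stratum)[c("inside", "flank", "outside")]),
               c(inside, flank, outside), ignore_attr = TRUE)
})

test_that("pathway generator respects sizes, extremes, and GMT round-trip", {
  cfg <- sim_config(n_cases = 10, n_controls = 10, n_snps = 2000,
                    n_genes = 450, n_pathways = 20,
                    pathway_size_range = c(10, 60), seed = 2)
  pws <- sim_pathways(sprintf("G%04d", 1:450), cfg)
  sizes <- lengths(pws)
  expect_true(all(sizes[sprintf("PW%04d", 1:20)] >= 10 &
                    sizes[sprintf("PW%04d", 1:20)] <= 60))
  expect_equal(unname(sizes["SIZE5_SET"]), 5)
  expect_equal(unname(sizes["SIZE400_SET"]), 400)
  expect_true(all(!vapply(pws, anyDuplicated, integer(1))))
  path <- tempfile(fileext = ".gmt")
  write_gmt(pws, path)
  expect_identical(read_gmt(path), pws)
  expect_error(sim_pathways(sprintf("G%04d", 1:30), cfg), "infeasible")
})

test_that("disjoint pathway sampling keeps sets non-overlapping", {
  cfg <- sim_config(n_cases = 10, n_controls = 10, n_snps = 2000,
                    n_genes = 300, n_pathways = 12,
                    pathway_size_range = c(10, 20), seed = 4)
  pws <- sim_pathways(sprintf("G%04d", 1:300), cfg, disjoint = TRUE)
  members <- unlist(pws[sprintf("PW%04d", 1:12)])
  expect_equal(anyDuplicated(members), 0)
  cfg2 <- sim_config(n_cases = 10, n_controls = 10, n_snps = 2000,
                     n_genes = 60, n_pathways = 12,
                     pathway_size_range = c(10, 20), seed = 4)
  expect_error(sim_pathways(sprintf("G%04d", 1:60), cfg2, disjoint = TRUE),
               "disjoint")
})

test_that("target generator plants known pass and fail sets", {
  cfg <- tiny_config(seed = 9)
  tg <- sim_target_predictions(sprintf("m%02d", 1:10),
                               sprintf("G%04d", 1:30), cfg)
  kept <- filter_miranda(tg$miranda)
  kept_key <- unique(paste(kept$mirna, kept$gene_symbol))
  pass_key <- paste(tg$planted_pass$mirna, tg$planted_pass$gene_symbol)
  fail_key <- paste(tg$planted_fail$mirna, tg$planted_fail$gene_symbol)
  expect_true(all(pass_key %in% kept_key))
  expect_length(intersect(fail_key, kept_key), 0)
  cls <- tg$mirna_classes$class
  expect_true(all(c("psychiatric", "neurological") %in% cls))
  expect_true(any(!cls %in% c("psychiatric", "neurological")))
  expect_error(sim_target_predictions(character(), "G1", cfg), "non-empty")
})

test_that("stronger effects do not weaken the causal genes' statistics", {
  mean_causal_t <- vapply(c(1, 1.4, 1.8), function(or) {
    cfg <- sim_config(n_cases = 400, n_controls = 400, n_snps = 600,
                      n_genes = 60, n_pathways = 6,
                      pathway_size_range = c(10, 20),
                      causal_pathways = "PW0001",
                      effect_odds_ratio = or, seed = 21)
    st <- sim_study(cfg)
    ss <- run_scan(st$geno)
    asg <- map_snps_to_genes(st$geno$snp_table, st$genes)
    gs <- gene_level_stats(ss, asg)
    mean(gs$t[gs$gene_symbol %in% st$causal_genes])
  }, numeric(1))
  expect_true(all(diff(mean_causal_t) > -0.5))
  expect_gt(mean_causal_t[3], mean_causal_t[1])
})
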