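test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_planted_proteins = 30, n_proteins = 20),
               "n_planted_proteins")
  expect_error(synthetic_config(n_causal_snps = 10, n_snps = 5),
               "n_causal_snps")
  expect_error(synthetic_config(fst_like_divergence = 1), "fst_like")
  expect_error(synthetic_config(missing_rate = -0.1), "missing_rate")
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_cases = 15, n_controls = 15, n_proteins = 40,
                          n_metabolites = 60, n_contaminants = 8,
                          n_snps = 50, seed = 42)
  expect_identical(generate_proteome(cfg), generate_proteome(cfg))
  expect_identical(generate_metabolome(cfg), generate_metabolome(cfg))
  expect_identical(generate_genotypes(cfg), generate_genotypes(cfg))
})

test_that("null proteome config leaves groups exchangeable", {
  cfg <- synthetic_config(n_planted_proteins = 0, n_proteins = 150,
                          seed = 5)
  pr <- generate_proteome(cfg)
  expect_false(any(pr$truth$planted))
  lfc <- log2(rowMeans(pr$lfq[, pr$groups == "case"]) /
                rowMeans(pr$lfq[, pr$groups == "control"]))
  # only sampling noise: no systematic shift, no large effects
  expect_lt(abs(mean(lfc, na.rm = TRUE)), 0.1)
  expect_lt(mean(abs(lfc) > 1, na.rm = TRUE), 0.05)
})

test_that("planted protein effects are recovered at the configured size", {
  hit <- sapply(1:5, function(s) {
    cfg <- synthetic_config(planted_log2fc = 2.5, seed = s)
    pr <- generate_proteome(cfg)
    li <- triomix:::log_impute(pr$lfq)
    fc <- (rowMeans(li[, pr$groups == "case"]) -
             rowMeans(li[, pr$groups == "control"])) / log(2)
    pl <- pr$truth$planted
    mean(abs(fc[pl] - pr$truth$log2fc[pl]) < 0.3)
  })
  expect_gte(mean(hit), 0.9)
})

test_that("structural zeros track the configured missing rate", {
  cfg <- synthetic_config(n_proteins = 200, missing_rate = 0.1, seed = 2)
  pr <- generate_proteome(cfg)
  expect_lt(abs(mean(pr$lfq == 0) - 0.1), 0.01)
  mt <- generate_metabolome(synthetic_config(n_metabolites = 300,
                                             n_contaminants = 0,
                                             missing_rate = 0.08, seed = 2))
  expect_lt(abs(mean(mt$intensity == 0) - 0.08), 0.01)
})

test_that("spike-in generator is exact without noise and closes the loop", {
  std <- spikein_standard()
  expect_length(std$protein_ids, 48)
  expect_gte(max(std$known_concentration) / min(std$known_concentration),
             1e4)
  meas <- generate_spikein_measurements(std, slope = 1, intercept = 0,
                                        noise_sd = 0)
  expect_equal(meas[, 1], setNames(std$known_concentration,
                                   std$protein_ids))
  meas08 <- generate_spikein_measurements(std, slope = 0.8, intercept = 1,
                                          noise_sd = 0)
  fit <- fit_calibration(std, meas08)
  expect_equal(fit$slope, 0.8, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_error(generate_spikein_measurements(std, noise_sd = -1),
               "noise_sd")
})

test_that("metabolome truth covers every feature exactly once", {
  cfg <- synthetic_config(n_metabolites = 200, n_contaminants = 20,
                          seed = 9)
  mt <- generate_metabolome(cfg)
  expect_identical(sort(mt$features$feature_id),
                   sort(rownames(mt$intensity)))
  expect_false(any(duplicated(mt$features$kegg_id)))
  expect_false(any(duplicated(mt$features$hmdb_id)))
  expect_identical(mt$exclusion_list,
                   mt$features$feature_id[mt$features$is_contaminant])
  mt0 <- generate_metabolome(synthetic_config(n_metabolites = 100,
                                              n_contaminants = 0, seed = 9))
  expect_false(any(mt0$features$is_contaminant))
})

test_that("planted strongly suppressed metabolite keeps its sign", {
  signs <- sapply(1:20, function(s) {
    cfg <- synthetic_config(n_metabolites = 150, n_contaminants = 0,
                            seed = s)
    mt <- generate_metabolome(cfg, planted_log2fc = -3.26)
    li <- triomix:::log_impute(mt$intensity)
    fc <- rowMeans(li[, mt$groups == "case"]) -
      rowMeans(li[, mt$groups == "control"])
    sign(fc[mt$truth$planted])
  })
  expect_gte(mean(signs < 0), 0.95)
})

test_that("genotype structure follows the divergence parameter", {
  # no structure: leading eigenvalues comparable
  cfg0 <- synthetic_config(n_cases = 40, n_controls = 40, n_snps = 300,
                           n_causal_snps = 0, n_subpops = 1,
                           fst_like_divergence = 0, missing_rate = 0,
                           seed = 3)
  ev <- genotype_pca(generate_genotypes(cfg0)$genotypes)$explained_variance
  expect_lt(ev[1] / ev[2], 1.3)
  # two subpops at Fst 0.1: PC1 separates them
  cfg1 <- synthetic_config(n_cases = 40, n_controls = 40, n_snps = 300,
                           n_causal_snps = 0, n_subpops = 2,
                           fst_like_divergence = 0.1, missing_rate = 0,
                           seed = 3)
  gen <- generate_genotypes(cfg1)
  s1 <- genotype_pca(gen$genotypes)$scores[, 1]
  auc <- mean(outer(s1[gen$subpop == 1], s1[gen$subpop == 2], ">"))
  expect_gt(max(auc, 1 - auc), 0.9)
})

test_that("non-causal planted variants have uniform p-values", {
  p <- sapply(1:100, function(s) {
    cfg <- synthetic_config(n_cases = 25, n_controls = 25, n_snps = 20,
                            n_causal_snps = 1, causal_odds_ratio = 1,
                            n_subpops = 1, fst_like_divergence = 0,
                            missing_rate = 0, seed = s)
    gen <- generate_genotypes(cfg)
    hits <- logistic_scan(gen$genotypes, gen$phenotype, NULL, 0)
    hits$p[match(gen$variants$snp_id[gen$variants$causal], hits$variant)]
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})
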