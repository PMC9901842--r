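test_that("variant QC applies the missingness, MAF and count rules", {
  set.seed(19)
  n <- 100
  ph <- factor(rep(c("case", "control"), each = 50),
               levels = c("case", "control"))
  g <- matrix(rbinom(n * 5, 2, 0.3), n, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  g[1:3, 1] <- NA                      # 3% missing -> removed
  g[, 2] <- rbinom(n, 2, 0.02)         # rare -> MAF rule
  g[, 3] <- 0; g[1:4, 3] <- 1          # minor count < 10 somewhere
  qc <- qc_filter(g, ph)
  expect_false("v1" %in% colnames(qc$genotypes))
  expect_false("v2" %in% colnames(qc$genotypes))
  expect_false("v3" %in% colnames(qc$genotypes))
  # report accounts for every removal
  expect_identical(sum(qc$report), 5L - ncol(qc$genotypes))
  # boundary semantics: MAF exactly at the threshold is kept
  gb <- matrix(rep(c(rep(1, 10), rep(0, 90)), 2), n, 2)
  colnames(gb) <- c("b1", "b2")
  st <- qc_filter(gb, ph, min_maf = 0.05, min_cu = 0, min_ca = 0)$stats
  expect_identical(st$rule, c("pass", "pass"))
  expect_equal(st$maf, c(0.05, 0.05))
  st4 <- qc_filter(cbind(gb, ok = rbinom(n, 2, 0.4)), ph,
                   min_maf = 0.06, min_cu = 0, min_ca = 0)
  expect_identical(unname(st4$report["min_maf"]), 2L)
  # minor-allele count 9 in cases -> removed
  g9 <- matrix(0, n, 2, dimnames = list(NULL, c("fail", "keep")))
  g9[1:9, 1] <- 1; g9[51:80, 1] <- 1    # c_a = 9, c_u = 30
  g9[1:30, 2] <- 1; g9[51:80, 2] <- 1
  qc9 <- qc_filter(g9, ph)
  expect_identical(colnames(qc9$genotypes), "keep")
  expect_identical(unname(qc9$report["min_ca"]), 1L)
  expect_error(qc_filter(g9[, 1, drop = FALSE], ph), "no variants")
})

test_that("genotype PCA is invariant to allele-label flips and duplicates", {
  cfg <- synthetic_config(n_cases = 30, n_controls = 30, n_snps = 100,
                          n_causal_snps = 0, missing_rate = 0.01, seed = 8)
  g <- generate_genotypes(cfg)$genotypes
  s1 <- genotype_pca(g, 4)$scores
  flip <- g
  flip[, 1:40] <- 2L - flip[, 1:40]
  s2 <- genotype_pca(flip, 4)$scores
  for (j in 1:4) {
    d <- min(max(abs(s1[, j] - s2[, j])), max(abs(s1[, j] + s2[, j])))
    expect_lt(d, 1e-8)
  }
  gd <- rbind(g, g[1, ])
  sd_ <- genotype_pca(gd, 2)$scores
  expect_equal(unname(sd_[1, ]), unname(sd_[nrow(gd), ]), tolerance = 1e-8)
})

test_that("PC outlier rule excludes only distant cases", {
  set.seed(4)
  scores <- matrix(rnorm(200), 100, 2)
  ph <- factor(rep(c("case", "control"), each = 50),
               levels = c("case", "control"))
  scores[1, 1] <- 40                    # case far out on PC1
  scores[60, 1] <- 40                   # control far out: never excluded
  keep <- exclude_outlier_cases(scores, ph)
  expect_false(keep[1])
  expect_true(keep[60])
  expect_true(all(keep[-1]))
  # cases drawn from the control distribution are almost all retained
  retained <- sapply(1:30, function(s) {
    set.seed(s)
    sc <- matrix(rnorm(160), 80, 2)
    mean(exclude_outlier_cases(sc, factor(rep(c("case", "control"),
                                              each = 40),
                                          levels = c("case", "control"))))
  })
  expect_gt(mean(retained), 0.98)
})

test_that("unadjusted scan matches the contingency-table log odds ratio", {
  # binary dosage: the logistic model is saturated, so the fitted
  # per-allele effect equals the 2x2 carrier-table log odds ratio exactly
  set.seed(23)
  n <- 400
  ph <- factor(rep(c("case", "control"), each = n / 2),
               levels = c("case", "control"))
  g <- matrix(rbinom(n, 1, ifelse(ph == "case", 0.55, 0.35)), n, 1,
              dimnames = list(NULL, "v1"))
  hit <- logistic_scan(g, ph, NULL, 0)
  a <- sum(g[ph == "case", 1] == 1); b <- sum(g[ph == "case", 1] == 0)
  c_ <- sum(g[ph == "control", 1] == 1); d <- sum(g[ph == "control", 1] == 0)
  lor <- log((a * d) / (b * c_))
  expect_equal(hit$beta, lor, tolerance = 1e-6)
  expect_lt(hit$p, 0.05)
})

test_that("scan is calibrated under permuted phenotypes and flags separation", {
  fr <- sapply(1:40, function(s) {
    cfg <- synthetic_config(n_cases = 30, n_controls = 30, n_snps = 40,
                            n_causal_snps = 0, n_subpops = 1,
                            fst_like_divergence = 0, missing_rate = 0,
                            seed = s)
    gen <- generate_genotypes(cfg)
    set.seed(s)
    hits <- logistic_scan(gen$genotypes, sample(gen$phenotype), NULL, 0)
    mean(hits$p < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(fr), 0.05 + 0.01)
  # complete separation falls back to the penalized fit
  gsep <- matrix(c(rep(2, 10), rep(0, 10)), 20, 1,
                 dimnames = list(NULL, "sep"))
  psep <- factor(rep(c("case", "control"), each = 10),
                 levels = c("case", "control"))
  hsep <- logistic_scan(gsep, psep, NULL, 0)
  expect_identical(hsep$flag, "firth")
  expect_true(is.finite(hsep$beta) && is.finite(hsep$p))
})

test_that("planted causal variants surface among the nominated candidates", {
  found <- sapply(1:3, function(s) {
    cfg <- synthetic_config(n_cases = 250, n_controls = 250, n_snps = 500,
                            n_causal_snps = 5, causal_odds_ratio = 3,
                            n_subpops = 2, fst_like_divergence = 0.05,
                            missing_rate = 0.005, seed = s)
    gen <- generate_genotypes(cfg)
    qc <- qc_filter(gen$genotypes, gen$phenotype)
    pca <- genotype_pca(qc$genotypes)
    keep <- exclude_outlier_cases(pca$scores, gen$phenotype)
    hits <- logistic_scan(qc$genotypes[keep, ], gen$phenotype[keep],
                          genotype_pca(qc$genotypes[keep, ])$scores)
    cand <- nominate_candidates(hits, top_k = 100)
    sum(gen$variants$snp_id[gen$variants$causal] %in% cand$variant)
  })
  expect_gte(mean(found), 4)
})

test_that("candidate nomination orders by p with positional tie-break", {
  hits <- data.frame(variant = c("a", "b", "c", "d"),
                     beta = 1, se = 1,
                     p = c(0.5, 0.01, 0.01, 1e-7),
                     maf = 0.2, c_u = 20, c_a = 20, flag = "ok",
                     chrom = c(1, 2, 1, 3), pos = c(10, 5, 5, 1),
                     coding_region = c(TRUE, TRUE, FALSE, TRUE))
  cand <- nominate_candidates(hits, top_k = 3, soft_p = 1e-5)
  expect_identical(cand$variant, c("d", "c", "b"))
  expect_identical(cand$soft_significant, c(TRUE, FALSE, FALSE))
  expect_identical(nrow(nominate_candidates(hits, top_k = 100)), 4L)
  coding <- nominate_candidates(hits, top_k = 10, coding_only = TRUE)
  expect_false("c" %in% coding$variant)
})

test_that("VCF round-trip preserves dosages and metadata", {
  cfg <- synthetic_config(n_cases = 10, n_controls = 10, n_snps = 25,
                          missing_rate = 0.05, seed = 14)
  gen <- generate_genotypes(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(gen$genotypes, gen$variants, path)
  back <- read_genotype_vcf(path)
  expect_identical(unname(back$genotypes), unname(gen$genotypes))
  expect_identical(back$variants$snp_id, gen$variants$snp_id)
  expect_identical(back$variants$pos, as.integer(gen$variants$pos))
})
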