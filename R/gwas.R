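#' Variant quality control for a case-control panel
#'
#' Applies, in order: the missingness rule (call-rate), the minor-allele
#' frequency rule (inclusive at the boundary: MAF exactly at `min_maf` is
#' kept), and the minimum minor-allele count rules in controls (`C_U`) and
#' cases (`C_A`). Each removed variant is attributed to the first rule it
#' fails, so the report counts sum to the number removed.
#'
#' @param genotypes samples x variants matrix of 0/1/2 dosages with `NA`
#'   for missing calls.
#' @param phenotype factor with levels case/control (first level = case).
#' @param max_missing maximum missing fraction per variant (default 0.02).
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @param min_cu,min_ca minimum minor-allele count in controls/cases
#'   (default 10 each).
#' @return list with `genotypes` (surviving variants), `report` (counts
#'   removed per rule) and `stats` (per-variant missingness, maf, c_u,
#'   c_a, first failing rule or `"pass"`).
#' @export
qc_filter <- function(genotypes, phenotype, max_missing = 0.02,
                      min_maf = 0.05, min_cu = 10L, min_ca = 10L) {
  g <- as.matrix(genotypes)
  phenotype <- as.factor(phenotype)
  is_case <- phenotype == levels(phenotype)[1L]
  missingness <- colMeans(is.na(g))
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  # minor-allele counts per group, in terms of the minor allele of each variant
  minor_dose <- function(rows) {
    sub <- g[rows, , drop = FALSE]
    alt <- colSums(sub, na.rm = TRUE)
    ref <- colSums(2 - sub, na.rm = TRUE)
    ifelse(af <= 0.5, alt, ref)
  }
  c_a <- minor_dose(is_case)
  c_u <- minor_dose(!is_case)

  rule <- rep("pass", ncol(g))
  rule[c_a < min_ca] <- "min_ca"
  rule[c_u < min_cu] <- "min_cu"
  rule[maf < min_maf] <- "min_maf"
  rule[missingness > max_missing] <- "max_missing"
  keep <- rule == "pass"
  if (!any(keep)) stop("no variants survive quality control")
  report <- c(max_missing = sum(rule == "max_missing"),
              min_maf = sum(rule == "min_maf"),
              min_cu = sum(rule == "min_cu"),
              min_ca = sum(rule == "min_ca"))
  list(genotypes = g[, keep, drop = FALSE],
       report = report,
       stats = data.frame(
         variant = colnames(g) %||% as.character(seq_len(ncol(g))),
         missingness = missingness, maf = maf, c_u = c_u, c_a = c_a,
         rule = rule))
}

#' Genotype principal components for stratification control
#'
#' Missing calls are mean-imputed per variant, each variant column is
#' centred at twice its allele frequency and standardized by
#' `sqrt(2 p (1 - p))` (the smartpca convention), monomorphic variants
#' are dropped, and the scores come from the singular value
#' decomposition.
#'
#' @param genotypes samples x variants 0/1/2 matrix (`NA` allowed).
#' @param n_pcs number of components to return (default 10).
#' @return list with `scores` (samples x PCs) and `explained_variance`.
#' @export
genotype_pca <- function(genotypes, n_pcs = 10L) {
  g <- as.matrix(genotypes)
  af <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(af) & af > 0 & af < 1
  g <- g[, poly, drop = FALSE]
  af <- af[poly]
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (any(miss)) g[miss, j] <- 2 * af[j]
  }
  z <- sweep(g, 2L, 2 * af)
  z <- sweep(z, 2L, sqrt(2 * af * (1 - af)), "/")
  s <- svd(z)
  k <- min(n_pcs, length(s$d), nrow(g) - 1L)
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(genotypes), paste0("PC", seq_len(k)))
  list(scores = scores,
       explained_variance = (s$d^2 / sum(s$d^2))[seq_len(k)])
}

#' Exclude cases outside the control cloud on PC1/PC2
#'
#' A case is retained only if both of its first two principal-component
#' scores fall within `k_sd` standard deviations of the corresponding
#' control means; controls are never excluded.
#'
#' @param scores samples x (>= 2) PC score matrix.
#' @param phenotype factor with levels case/control (first level = case).
#' @param k_sd exclusion radius in control SDs (default 3).
#' @return logical keep vector over samples.
#' @export
exclude_outlier_cases <- function(scores, phenotype, k_sd = 3) {
  scores <- as.matrix(scores)
  phenotype <- as.factor(phenotype)
  is_case <- phenotype == levels(phenotype)[1L]
  if (sum(!is_case) < 3L) stop("need at least 3 controls")
  keep <- rep(TRUE, nrow(scores))
  for (j in 1:2) {
    mu <- mean(scores[!is_case, j])
    sdev <- stats::sd(scores[!is_case, j])
    keep <- keep & (!is_case | abs(scores[, j] - mu) <= k_sd * sdev)
  }
  keep
}

# Firth-penalized logistic regression (Jeffreys-prior score adjustment);
# fallback for separated variants where plain ML diverges.
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    h <- rowSums((XW %*% solve(info)) * XW)    # hat diagonal
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- solve(info, score)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  se <- sqrt(diag(solve(info)))
  list(beta = beta, se = se)
}

#' Per-variant logistic association scan with PC covariates
#'
#' For every variant, fits a maximum-likelihood logistic regression of
#' case status on allele dosage plus the first `n_covariate_pcs` genotype
#' principal components (complete cases per variant) and reports the Wald
#' test of the dosage term. Non-convergent or separated fits are refit
#' with a Firth-style Jeffreys penalty and flagged.
#'
#' @param genotypes samples x variants 0/1/2 matrix (`NA` allowed).
#' @param phenotype factor with levels case/control (first level = case).
#' @param pc_scores samples x PCs matrix from [genotype_pca()], or `NULL`
#'   for an unadjusted scan.
#' @param n_covariate_pcs PCs included as covariates (default 5).
#' @return data.frame of association results: `variant`, `beta` (log-odds
#'   per allele), `se`, `p`, `maf`, `c_u`, `c_a`, `flag` (`"ok"`,
#'   `"firth"` or `"degenerate"`).
#' @export
logistic_scan <- function(genotypes, phenotype, pc_scores = NULL,
                          n_covariate_pcs = 5L) {
  g <- as.matrix(genotypes)
  phenotype <- as.factor(phenotype)
  y_all <- as.numeric(phenotype == levels(phenotype)[1L])
  covs <- if (!is.null(pc_scores) && n_covariate_pcs > 0L)
    as.matrix(pc_scores)[, seq_len(min(n_covariate_pcs,
                                       ncol(pc_scores))), drop = FALSE]
  else NULL
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  is_case <- y_all == 1

  one <- function(j) {
    ok <- !is.na(g[, j])
    y <- y_all[ok]; dose <- g[ok, j]
    if (stats::var(dose) == 0 || length(unique(y)) < 2L)
      return(c(NA, NA, NA, 3))
    X <- cbind(1, dose, if (!is.null(covs)) covs[ok, , drop = FALSE])
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    sm <- tryCatch({
      info <- crossprod(X * sqrt(fit$weights))
      se <- sqrt(diag(solve(info)))
      list(beta = fit$coefficients[2L], se = se[2L],
           converged = fit$converged)
    }, error = function(e) NULL)
    separated <- is.null(sm) || !sm$converged ||
      !is.finite(sm$se) || abs(sm$beta) > 8 || sm$se > 50
    if (separated) {
      fb <- tryCatch(firth_logistic(X, y), error = function(e) NULL)
      if (is.null(fb)) return(c(NA, NA, NA, 3))
      z <- fb$beta[2L] / fb$se[2L]
      return(c(fb$beta[2L], fb$se[2L], 2 * stats::pnorm(-abs(z)), 1))
    }
    z <- sm$beta / sm$se
    c(sm$beta, sm$se, 2 * stats::pnorm(-abs(z)), 0)
  }
  res <- t(vapply(seq_len(ncol(g)), one, numeric(4)))
  minor_dose <- function(rows) {
    sub <- g[rows, , drop = FALSE]
    alt <- colSums(sub, na.rm = TRUE)
    ref <- colSums(2 - sub, na.rm = TRUE)
    ifelse(af <= 0.5, alt, ref)
  }
  data.frame(
    variant = colnames(g) %||% as.character(seq_len(ncol(g))),
    beta = res[, 1L], se = res[, 2L], p = res[, 3L],
    maf = maf, c_u = minor_dose(!is_case), c_a = minor_dose(is_case),
    flag = c("ok", "firth", "", "degenerate")[res[, 4L] + 1L],
    row.names = NULL)
}

#' Nominate candidate loci from an association scan
#'
#' Orders hits by ascending p-value (ties broken by chromosome, then
#' position) and takes the `top_k` best; optionally restricts to variants
#' in protein-coding regions. Hits below the soft significance threshold
#' are flagged.
#'
#' @param hits [logistic_scan()] output, optionally augmented with
#'   `chrom`, `pos`, `gene`, `coding_region` columns.
#' @param top_k candidates to nominate (default 100).
#' @param soft_p soft significance threshold (default 1e-5).
#' @param coding_only restrict to `coding_region` variants.
#' @return the nominated subset, ordered, with a `soft_significant`
#'   column.
#' @export
nominate_candidates <- function(hits, top_k = 100L, soft_p = 1e-5,
                                coding_only = FALSE) {
  h <- hits[!is.na(hits$p), , drop = FALSE]
  if (coding_only) {
    if (is.null(h$coding_region))
      stop("coding_only requires a coding_region column")
    h <- h[h$coding_region, , drop = FALSE]
  }
  ord <- order(h$p,
               h$chrom %||% rep(0L, nrow(h)),
               h$pos %||% seq_len(nrow(h)))
  h <- h[ord, , drop = FALSE]
  h <- utils::head(h, top_k)
  h$soft_significant <- h$p < soft_p
  rownames(h) <- NULL
  h
}
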