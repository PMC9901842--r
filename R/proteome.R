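#' Normalized spectral abundance factor (NSAF)
#'
#' For each sample, the spectral count of every protein is divided by the
#' protein length and normalized to the sample total, so that
#' `NSAF_i = (SpC_i / L_i) / sum_j(SpC_j / L_j)` and every sample column
#' sums to one.
#'
#' @param counts spectral-count matrix, proteins x samples.
#' @param lengths protein lengths in residues (positive), one per row.
#' @return NSAF matrix of the same dimensions; columns sum to 1.
#' @export
compute_nsaf <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("lengths must have one entry per protein")
  if (any(lengths <= 0)) stop("protein lengths must be positive")
  if (any(counts < 0)) stop("spectral counts must be >= 0")
  saf <- counts / lengths
  totals <- colSums(saf)
  bad <- which(totals == 0)
  if (length(bad))
    stop("sample(s) with all-zero spectral counts: ",
         paste(colnames(counts)[bad] %||% bad, collapse = ", "))
  sweep(saf, 2L, totals, "/")
}

#' Unicity filter on unique-peptide evidence
#'
#' Retains exactly the proteins identified by more than one unique peptide
#' (`ni(p) > 1`), the acceptance rule for confident protein-level
#' identifications.
#'
#' @param x matrix or data.frame with one row per protein.
#' @param unique_peptides unique-peptide count per row.
#' @return `x` restricted to rows with `unique_peptides > 1`.
#' @export
unicity_filter <- function(x, unique_peptides) {
  if (length(unique_peptides) != nrow(x))
    stop("unique_peptides must have one entry per row of x")
  x[unique_peptides > 1L, , drop = FALSE]
}

#' Impute zero group means by the half-minimum rule
#'
#' Group means equal to zero (the protein was never detected in that
#' group) are replaced by half of the smallest nonzero value observed for
#' that feature anywhere in the dataset, a standard left-censoring
#' surrogate that makes fold changes computable. Features that are zero
#' everywhere cannot be rescued and are dropped with a warning.
#'
#' @param means features x groups matrix of group summaries.
#' @param min_nonzero per-feature smallest nonzero observed value (e.g.
#'   from [row_min_nonzero] on the full matrix); `NA` marks all-zero
#'   features.
#' @return list with `means` (imputed, all-zero features removed) and
#'   `dropped` (row names or indices of removed features).
#' @export
impute_zero_means <- function(means, min_nonzero) {
  means <- as.matrix(means)
  if (length(min_nonzero) != nrow(means))
    stop("min_nonzero must have one entry per feature")
  all_zero <- is.na(min_nonzero) | (rowSums(means > 0) == 0L)
  if (any(all_zero)) {
    warning(sum(all_zero), " all-zero feature(s) dropped, not imputed")
  }
  keep <- !all_zero
  m <- means[keep, , drop = FALSE]
  fill <- (min_nonzero[keep] / 2)
  for (j in seq_len(ncol(m))) {
    z <- m[, j] == 0
    m[z, j] <- fill[z]
  }
  list(means = m, dropped = rownames(means)[all_zero] %||% which(all_zero))
}

#' Log2 fold change of case over control summaries
#'
#' @param case_summary,control_summary positive group summaries
#'   (imputation must precede: zeros are an error here).
#' @return `log2(case / control)`, vectorized.
#' @export
log2_fold_change <- function(case_summary, control_summary) {
  if (any(case_summary <= 0) || any(control_summary <= 0))
    stop("summaries must be positive; impute zero means first")
  log2(case_summary / control_summary)
}

#' Differential abundance test with frequency and fold-change gating
#'
#' Per feature: detection frequency per group, a group summary (mean by
#' default, median optionally) with half-minimum imputation of zero group
#' means, the log2 fold change, a two-sided Wilcoxon rank-sum p-value, and
#' Benjamini-Hochberg adjustment across all tested features as one family.
#' A feature is called significant iff its detection frequency reaches
#' `min_frequency` in at least one group, its linear fold change lies
#' strictly outside `fc_linear_bounds`, and `p_adj < alpha`.
#'
#' @param x abundance matrix (NSAF or intensities), features x samples.
#' @param groups factor with levels case/control (first level = case).
#' @param alpha adjusted-p cut-off (0.01 for a validated panel, 0.05 for a
#'   discovery pass).
#' @param fc_linear_bounds linear fold-change gate `(lower, upper)`;
#'   significance requires FC < lower or FC > upper (strict).
#' @param min_frequency minimum detection frequency in at least one group.
#' @param summary `"mean"` or `"median"` group summary for the fold change.
#' @return data.frame with per-feature summaries, `log2fc`, `p_raw`,
#'   `p_adj` and the `significant` call; all-zero features are dropped
#'   with a warning.
#' @export
differential_test <- function(x, groups, alpha = 0.01,
                              fc_linear_bounds = c(0.5, 2),
                              min_frequency = 0.85,
                              summary = c("mean", "median")) {
  x <- as.matrix(x)
  summary <- match.arg(summary)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  case <- levels(groups)[1L]
  ctrl <- levels(groups)[2L]

  min_nz <- row_min_nonzero(x)
  keep <- !is.na(min_nz)
  if (any(!keep)) warning(sum(!keep), " all-zero feature(s) dropped")
  x <- x[keep, , drop = FALSE]
  min_nz <- min_nz[keep]

  freq <- detection_frequency(x, groups)
  fun <- if (summary == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  means <- cbind(fun(x[, groups == case, drop = FALSE]),
                 fun(x[, groups == ctrl, drop = FALSE]))
  imp <- impute_zero_means(means, min_nz)$means
  log2fc <- log2_fold_change(imp[, 1L], imp[, 2L])
  linear_fc <- 2^log2fc

  p_raw <- vapply(seq_len(nrow(x)), function(i) {
    suppressWarnings(stats::wilcox.test(
      x[i, groups == case], x[i, groups == ctrl],
      alternative = "two.sided")$p.value)
  }, numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = "BH")

  freq_ok <- freq[, case] >= min_frequency | freq[, ctrl] >= min_frequency
  fc_ok <- linear_fc > fc_linear_bounds[2L] | linear_fc < fc_linear_bounds[1L]
  data.frame(
    feature_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    mean_case = means[, 1L], mean_control = means[, 2L],
    freq_case = freq[, case], freq_control = freq[, ctrl],
    log2fc = log2fc, p_raw = p_raw, p_adj = p_adj,
    significant = freq_ok & fc_ok & p_adj < alpha,
    row.names = NULL
  )
}

#' Validation flags for an absolutely quantified protein panel
#'
#' A protein passes validation iff its adjusted p-value is below `alpha`
#' and its measured concentration is significantly nonzero in at least one
#' group (configurable to a single group). "Significantly nonzero" is
#' read, by default, as the group mean exceeding twice its standard error
#' (`2 * SD / sqrt(n)`); setting `se_of_mean = FALSE` applies the literal
#' reading of the mean exceeding twice the per-sample standard deviation,
#' a far stricter gate.
#'
#' @param records data.frame with columns `conc_mean_case`, `conc_sd_case`,
#'   `conc_mean_control`, `conc_sd_control`, `p_adj`.
#' @param alpha adjusted-p cut-off (default 0.01).
#' @param n_case,n_control group sizes behind the concentration summaries
#'   (needed for the standard error; ignored when `se_of_mean = FALSE`).
#' @param se_of_mean compare the mean against twice its standard error
#'   (default) rather than twice the sample SD.
#' @param group which group(s) may satisfy the concentration rule.
#' @return logical `passes_validation` vector, one flag per record.
#' @export
validate_panel <- function(records, alpha = 0.01,
                           n_case = NULL, n_control = NULL,
                           se_of_mean = TRUE,
                           group = c("either", "case", "control")) {
  group <- match.arg(group)
  need <- c("conc_mean_case", "conc_sd_case",
            "conc_mean_control", "conc_sd_control", "p_adj")
  if (!all(need %in% names(records)))
    stop("records must contain: ", paste(need, collapse = ", "))
  div_case <- if (se_of_mean) {
    if (is.null(n_case)) stop("n_case required when se_of_mean = TRUE")
    sqrt(n_case)
  } else 1
  div_ctrl <- if (se_of_mean) {
    if (is.null(n_control)) stop("n_control required when se_of_mean = TRUE")
    sqrt(n_control)
  } else 1
  ok_case <- records$conc_mean_case > 2 * records$conc_sd_case / div_case
  ok_ctrl <- records$conc_mean_control > 2 * records$conc_sd_control / div_ctrl
  conc_ok <- switch(group,
                    either = ok_case | ok_ctrl,
                    case = ok_case,
                    control = ok_ctrl)
  conc_ok & records$p_adj < alpha
}
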