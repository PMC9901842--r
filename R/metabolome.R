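#' Remove drug-like and non-endogenous metabolite features
#'
#' Features whose identifier appears on the exclusion list (medication
#' metabolites, xenobiotics, non-human compounds) are removed before
#' differential analysis; removals are returned for the audit log.
#'
#' @param features data.frame with a `feature_id` column (additional id
#'   columns such as `kegg_id`/`hmdb_id` are matched too if present).
#' @param exclusion_list character vector of ids to exclude.
#' @param reason label recorded for the removals (default `"drug_like"`).
#' @return list with `retained` and `excluded` data.frames; `excluded`
#'   carries an `excluded_reason` column.
#' @export
exclude_contaminants <- function(features, exclusion_list,
                                 reason = "drug_like") {
  id_cols <- intersect(c("feature_id", "kegg_id", "hmdb_id"),
                       names(features))
  if (!length(id_cols)) stop("features must carry a feature_id column")
  hit <- Reduce(`|`, lapply(id_cols, function(col)
    features[[col]] %in% exclusion_list))
  matched <- unique(unlist(features[hit, id_cols, drop = FALSE]))
  missing <- setdiff(exclusion_list, matched)
  if (length(missing))
    warning(length(missing), " exclusion-list id(s) absent from the data")
  excluded <- features[hit, , drop = FALSE]
  if (nrow(excluded)) excluded$excluded_reason <- reason
  list(retained = features[!hit, , drop = FALSE], excluded = excluded)
}

#' Frequency filter for metabolite features
#'
#' Keeps features detected (intensity > 0) on more than one occasion in
#' each studied group, i.e. at least `min_per_group` nonzero observations
#' per group (default 2).
#'
#' @param x intensity matrix, features x samples.
#' @param groups two-level factor.
#' @param min_per_group minimum nonzero observations required in every
#'   group.
#' @return logical keep vector, one per feature.
#' @export
frequency_filter <- function(x, groups, min_per_group = 2L) {
  groups <- as.factor(groups)
  counts <- sapply(levels(groups), function(g)
    rowSums(x[, groups == g, drop = FALSE] > 0))
  apply(counts >= min_per_group, 1L, all)
}

# log intensities with half-minimum imputation of zeros (features all-zero
# stay at -Inf and should be filtered before use)
log_impute <- function(x) {
  x <- as.matrix(x)
  fill <- row_min_nonzero(x) / 2
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (any(z) && !is.na(fill[i])) x[i, z] <- fill[i]
  }
  log(x)
}

#' Permutation validation of group differences
#'
#' Label-permutation null of the per-feature group-difference statistic
#' (difference of group means of log intensity, zeros imputed at half the
#' feature minimum). The two-sided permutation p-value is
#' `(1 + #\{|null| >= |observed|\}) / (1 + n_perm)`, whose granularity
#' `1/(n_perm + 1)` must be able to resolve the requested `alpha`.
#'
#' @param x intensity matrix, features x samples.
#' @param groups two-level factor.
#' @param n_perm number of label permutations (>= 100).
#' @param alpha significance level the p-values must resolve.
#' @param seed integer seed for the permutations.
#' @return data.frame with observed statistic and permutation p per
#'   feature.
#' @export
permutation_validate <- function(x, groups, n_perm = 999L, alpha = 0.05,
                                 seed = 1L) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (1 / (n_perm + 1) > alpha)
    stop("n_perm too small to resolve alpha = ", alpha)
  set.seed(stream_seed(seed, "permutation"))
  lx <- log_impute(x)
  is_case <- groups == levels(groups)[1L]
  stat <- function(flag)
    rowMeans(lx[, flag, drop = FALSE]) - rowMeans(lx[, !flag, drop = FALSE])
  obs <- stat(is_case)
  exceed <- integer(nrow(x))
  for (b in seq_len(n_perm)) {
    flag <- sample(is_case)
    exceed <- exceed + (abs(stat(flag)) >= abs(obs))
  }
  data.frame(
    feature_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    statistic = obs,
    p_perm = (1 + exceed) / (1 + n_perm)
  )
}

#' Differential metabolite analysis
#'
#' The same machinery as [differential_test()] with metabolome defaults:
#' adjusted-p cut-off 0.05 and the `|log2FC| > 1` gate (linear fold change
#' strictly outside `(0.5, 2)`).
#'
#' @inheritParams differential_test
#' @export
differential_metabolites <- function(x, groups, alpha = 0.05,
                                     fc_linear_bounds = c(0.5, 2),
                                     min_frequency = 0.85,
                                     summary = c("mean", "median")) {
  differential_test(x, groups, alpha = alpha,
                    fc_linear_bounds = fc_linear_bounds,
                    min_frequency = min_frequency,
                    summary = summary)
}
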