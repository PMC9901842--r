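#' @keywords internal
"_PACKAGE"

# Derive a deterministic per-stream seed from the global seed so each
# generator can be re-run independently. Kept below 2^31 - 1.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 1009) %% 2147483629)
}

# Smallest nonzero value per row; NA for all-zero rows.
row_min_nonzero <- function(x) {
  apply(x, 1L, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v)) min(v) else NA_real_
  })
}

# Fraction of nonzero (detected) entries per row within each group level.
detection_frequency <- function(x, groups) {
  groups <- as.factor(groups)
  res <- vapply(levels(groups), function(g) {
    rowMeans(x[, groups == g, drop = FALSE] > 0, na.rm = TRUE)
  }, numeric(nrow(x)))
  matrix(res, nrow = nrow(x),
         dimnames = list(rownames(x), levels(groups)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
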