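# Independent oracles the implementation is checked against.

# Benjamini-Hochberg step-up by direct definition:
# adj p_(i) = min_{j >= i} ( m * p_(j) / j ), mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    adj[i] <- min(1, min(m * p[ord][j] / j))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Two-sided Wilcoxon rank-sum p by full enumeration of group assignments
# (tie-free data only).
wilcox_exact_oracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  W <- apply(utils::combn(length(r), n1), 2L, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(W <= obs), mean(W >= obs)))
}

# Newman assortativity as the Pearson correlation of endpoint degrees,
# expanding each undirected edge in both directions.
assortativity_oracle <- function(deg_from, deg_to) {
  if (!length(deg_from)) return(NA_real_)
  suppressWarnings(stats::cor(c(deg_from, deg_to), c(deg_to, deg_from)))
}

# Dense two-class PLS-DA by plain NIPALS on the cross-covariance, written
# independently of the package's sparse implementation.
dense_plsda_oracle <- function(x, groups, n_components = 2L) {
  xc <- scale(x)
  xc[is.na(xc)] <- 0
  y <- scale(stats::model.matrix(~ groups - 1))
  scores <- matrix(0, nrow(x), n_components)
  for (h in seq_len(n_components)) {
    M <- crossprod(xc, y)
    a <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    t_h <- drop(xc %*% a)
    c_h <- drop(crossprod(xc, t_h)) / sum(t_h^2)
    d_h <- drop(crossprod(y, t_h)) / sum(t_h^2)
    xc <- xc - tcrossprod(t_h, c_h)
    y <- y - tcrossprod(t_h, d_h)
    scores[, h] <- t_h
  }
  scores
}

# random mapped-element table over a small pathway universe
random_mapped_elements <- function(n_elements, n_pathways, seed) {
  set.seed(seed)
  paths <- sprintf("pw%02d", seq_len(n_pathways))
  pathways <- lapply(seq_len(n_elements), function(i)
    sample(paths, sample.int(min(4L, n_pathways), 1L)))
  out <- data.frame(
    element_id = sprintf("el%03d", seq_len(n_elements)),
    layer = sample(c("proteome", "metabolome", "gwas"), n_elements,
                   replace = TRUE),
    mapped_gene = rep(NA_character_, n_elements),
    n_pathways = lengths(pathways))
  out$pathways <- pathways
  out
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "triomix", mustWork = TRUE)
}
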