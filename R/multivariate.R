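#' Principal component analysis via singular value decomposition
#'
#' Columns (features) are centred and optionally unit-scaled; constant
#' features are dropped from scaling. Scores are the projections of the
#' samples, loadings have unit norm, and the explained-variance fractions
#' are the squared singular values over their total.
#'
#' @param x samples x features matrix.
#' @param n_components components to return (default all).
#' @param scale. unit-scale features (default FALSE).
#' @return object of class `projection`: `scores`, `loadings`,
#'   `explained_variance`, `method`.
#' @export
omx_pca <- function(x, n_components = NULL, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (scale.) {
    sds <- apply(xc, 2L, stats::sd)
    keepable <- sds > 0
    xc[, keepable] <- sweep(xc[, keepable, drop = FALSE], 2L,
                            sds[keepable], "/")
  }
  s <- svd(xc)
  ev <- s$d^2 / sum(s$d^2)
  k <- min(n_components %||% length(s$d), length(s$d))
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(k)],
                 explained_variance_all = ev, method = "pca"),
            class = "projection")
}

# keep exactly `keep` largest |v| entries, soft-thresholded by the next one
soft_threshold_keep <- function(v, keep) {
  keep <- min(keep, sum(v != 0), length(v))
  if (keep >= length(v)) return(v)
  a <- abs(v)
  lambda <- sort(a, decreasing = TRUE)[keep + 1L]
  out <- sign(v) * pmax(a - lambda, 0)
  # ties at lambda can keep fewer than `keep`; break by magnitude order
  if (sum(out != 0) < keep) {
    ord <- order(a, decreasing = TRUE)[seq_len(keep)]
    out <- numeric(length(v)); out[ord] <- v[ord] - sign(v[ord]) * lambda
  }
  out
}

#' Sparse partial least-squares discriminant analysis
#'
#' Supervised projection of a feature matrix against a one-hot class
#' matrix (columns centred and scaled, so classes are implicitly weighted
#' by their size). Per component, the feature weight vector of the
#' cross-covariance matrix is soft-thresholded so that exactly `keepX`
#' features retain a nonzero loading, scores are computed, and the data
#' matrix is deflated by regression on the scores. With `keepX` equal to
#' the number of features this is dense PLS-DA.
#'
#' @param x samples x features matrix.
#' @param groups class factor (two classes).
#' @param n_components number of latent components (default 2).
#' @param keepX retained features per component (scalar or vector);
#'   default `min(50, ncol(x))`.
#' @param scale. unit-scale the feature columns (default TRUE).
#' @param tol,max_iter convergence control of the inner iteration.
#' @return object of class `projection` with `scores`, `loadings`
#'   (unit-norm weight vectors), `explained_variance` (fraction of
#'   X-variance captured per component) and `keep_per_component`.
#' @export
splsda <- function(x, groups, n_components = 2L, keepX = NULL,
                   scale. = TRUE, tol = 1e-9, max_iter = 500L) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("groups must have at least two classes")
  keepX <- keepX %||% min(50L, ncol(x))
  keepX <- rep_len(as.integer(keepX), n_components)
  if (any(keepX < 1L)) stop("keepX must be >= 1")
  if (any(keepX > ncol(x))) stop("keepX must not exceed the feature count")

  xc <- scale(x, center = TRUE, scale = FALSE)
  if (scale.) {
    sds <- apply(xc, 2L, stats::sd)
    sds[sds == 0] <- 1
    xc <- sweep(xc, 2L, sds, "/")
  }
  y <- stats::model.matrix(~ groups - 1)
  y <- scale(y)
  total_var <- sum(xc^2)

  p <- ncol(xc)
  scores <- matrix(0, nrow(xc), n_components)
  loadings <- matrix(0, p, n_components)
  expvar <- numeric(n_components)
  Xh <- xc; Yh <- y
  for (h in seq_len(n_components)) {
    M <- crossprod(Xh, Yh)                      # p x q cross-covariance
    sv <- svd(M, nu = 1L, nv = 1L)
    a <- sv$u[, 1L]; b <- sv$v[, 1L]
    for (it in seq_len(max_iter)) {
      a_new <- soft_threshold_keep(drop(M %*% b), keepX[h])
      na <- sqrt(sum(a_new^2))
      if (na == 0) stop("degenerate component ", h)
      a_new <- a_new / na
      b_new <- drop(crossprod(M, a_new))
      b_new <- b_new / sqrt(sum(b_new^2))
      if (max(abs(a_new - a)) < tol && max(abs(b_new - b)) < tol) {
        a <- a_new; b <- b_new; break
      }
      a <- a_new; b <- b_new
    }
    t_h <- drop(Xh %*% a)
    c_h <- drop(crossprod(Xh, t_h)) / sum(t_h^2)  # x-loadings for deflation
    d_h <- drop(crossprod(Yh, t_h)) / sum(t_h^2)
    Xh <- Xh - tcrossprod(t_h, c_h)
    Yh <- Yh - tcrossprod(t_h, d_h)
    scores[, h] <- t_h
    loadings[, h] <- a
    expvar[h] <- sum(t_h^2) * sum(c_h^2) / total_var
  }
  dimnames(scores) <- list(rownames(x), paste0("comp", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(x), paste0("comp", seq_len(n_components)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = expvar,
                 keep_per_component = as.integer(colSums(loadings != 0)),
                 groups = groups, method = "splsda"),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("%s projection: %d samples, %d components (%s explained)\n",
              x$method, nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}

#' Per-group confidence ellipses in a 2-D score space
#'
#' For each group, the ellipse is centred at the sample mean with shape
#' from the sample covariance scaled by the chi-square quantile at `level`
#' with 2 degrees of freedom; axes are the square roots of the scaled
#' eigenvalues and the angle is that of the leading eigenvector.
#'
#' @param scores samples x 2 score matrix.
#' @param groups factor (>= 3 samples per group).
#' @param level confidence level (default 0.95).
#' @return data.frame per group: centre, semi-axes `a` >= `b`, `angle`
#'   (radians), and a `degenerate` flag for singular covariances.
#' @export
confidence_ellipse <- function(scores, groups, level = 0.95) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  groups <- as.factor(groups)
  if (any(table(groups) < 3L)) stop("need >= 3 samples per group")
  q <- stats::qchisq(level, df = 2)
  out <- lapply(levels(groups), function(g) {
    s <- scores[groups == g, , drop = FALSE]
    mu <- colMeans(s)
    cv <- stats::cov(s)
    e <- eigen(cv, symmetric = TRUE)
    degenerate <- any(e$values < .Machine$double.eps * max(1, e$values[1L]))
    data.frame(group = g, cx = mu[1L], cy = mu[2L],
               a = sqrt(max(e$values[1L], 0) * q),
               b = sqrt(max(e$values[2L], 0) * q),
               angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
               degenerate = degenerate)
  })
  do.call(rbind, out)
}

#' Test whether points fall inside a group's confidence ellipse
#'
#' @param ellipse one row of [confidence_ellipse()] output.
#' @param points n x 2 matrix.
#' @param level the level the ellipse was built at.
#' @return logical vector: point inside (or on) the ellipse.
#' @export
ellipse_contains <- function(ellipse, points, level = 0.95) {
  points <- as.matrix(points)
  q <- stats::qchisq(level, df = 2)
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2L, 2L)
  centred <- sweep(points, 2L, c(ellipse$cx, ellipse$cy)) %*% rot
  (centred[, 1L] / ellipse$a)^2 + (centred[, 2L] / ellipse$b)^2 <= 1
}
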