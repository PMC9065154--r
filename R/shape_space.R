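# Principal component analysis of Procrustes-aligned coordinates.
#
# Shapes are flattened column-major (all x, then all y); the covariance
# matrix (divisor n - 1) of the flattened coordinates is eigen-decomposed.
# PC scores are in dimensionless tangent-space (Procrustes) units.

#' Principal component analysis of a Procrustes superimposition
#'
#' Eigen-decomposes the covariance matrix of the flattened aligned
#' coordinates of a [gpa()] fit. At most `min(n - 1, 2K - 4)` components
#' carry variance (four dimensions are consumed by centering, scaling, and
#' rotation); all eigenvectors are retained so that every specimen is
#' exactly reconstructible as consensus + scores x loadings.
#'
#' @param fit A `gpa_fit` object (or a long landmark tibble of
#'   already-aligned coordinates).
#' @return An object of class `shape_space`: `scores` (tibble with one
#'   specimen per row, `PC1..PCm` columns and any metadata), `eigenvalues`,
#'   `percent_variance`, `loadings` (2K x m orthonormal matrix), `center`
#'   (flattened mean shape), `consensus`, `k`, `n`.
#' @export
shape_pca <- function(fit) {
  if (inherits(fit, "gpa_fit")) {
    aligned <- fit$aligned
  } else {
    aligned <- fit
    validate_landmarks(aligned)
  }
  meta <- lmk_meta(aligned)
  arr <- lmk_array(aligned)
  n <- dim(arr)[3]
  k <- dim(arr)[1]
  if (n < 3) abort("shape PCA needs at least 3 specimens")
  x <- t(apply(arr, 3, as.vector))          # n x 2K, column-major flattening
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  cv <- crossprod(xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  loadings <- eg$vectors
  m <- ncol(loadings)
  colnames(loadings) <- paste0("PC", seq_len(m))
  scores <- xc %*% loadings
  colnames(scores) <- colnames(loadings)
  ids <- dimnames(arr)[[3]]
  sc_tbl <- bind_cols(tibble(specimen = ids), as_tibble(scores))
  if (!is.null(meta)) sc_tbl <- left_join(sc_tbl, meta, by = "specimen")
  out <- list(
    scores = sc_tbl,
    eigenvalues = ev,
    percent_variance = if (sum(ev) > 0) 100 * ev / sum(ev) else ev,
    loadings = loadings,
    center = center,
    consensus = tibble(landmark = seq_len(k),
                       x = center[seq_len(k)], y = center[k + seq_len(k)]),
    k = k,
    n = n
  )
  class(out) <- "shape_space"
  out
}

#' Fix the arbitrary signs of principal components
#'
#' Eigenvector signs are arbitrary; this flips each component so that its
#' scores correlate non-negatively with an orienting statistic, making
#' score signs comparable across runs and datasets. The default statistic
#' is an elongation proxy: the per-specimen chord length between the two
#' landmarks that lie farthest apart in the consensus shape.
#'
#' @param space A `shape_space` object.
#' @param statistic Optional numeric vector, one value per specimen (in
#'   score order, or named by specimen).
#' @return The re-oriented `shape_space`; idempotent, and `|scores|`,
#'   eigenvalues and explained variance are unchanged.
#' @export
orient_axes <- function(space, statistic = NULL) {
  stopifnot(inherits(space, "shape_space"))
  ids <- space$scores$specimen
  if (is.null(statistic)) {
    statistic <- elongation_statistic(space)
  }
  if (!is.null(names(statistic))) {
    statistic <- statistic[ids]
    if (anyNA(statistic)) abort("statistic names do not cover all specimens")
  }
  if (length(statistic) != length(ids)) {
    abort("statistic must have one value per specimen")
  }
  if (sd(statistic) == 0) {
    warn("orientation statistic has zero variance; axes left unchanged")
    return(space)
  }
  pc_cols <- grep("^PC[0-9]+$", names(space$scores), value = TRUE)
  for (pc in pc_cols) {
    s <- space$scores[[pc]]
    if (sd(s) > 0 && cor(s, statistic) < 0) {
      space$scores[[pc]] <- -s
      space$loadings[, pc] <- -space$loadings[, pc]
    }
  }
  space
}

#' @describeIn orient_axes Default orienting statistic: each specimen's
#'   aspect ratio (square root of the ratio of its two principal-axis
#'   variances), a scale-free elongation proxy computed from the
#'   reconstructed aligned shapes.
#' @export
elongation_statistic <- function(space) {
  k <- space$k
  pc_cols <- grep("^PC[0-9]+$", names(space$scores), value = TRUE)
  sc <- as.matrix(space$scores[pc_cols])
  recon <- sweep(sc %*% t(space$loadings), 2, space$center, "+")
  out <- vapply(seq_len(nrow(recon)), function(i) {
    m <- cbind(recon[i, seq_len(k)], recon[i, k + seq_len(k)])
    m <- sweep(m, 2, colMeans(m))
    ev <- eigen(crossprod(m), symmetric = TRUE, only.values = TRUE)$values
    sqrt(ev[1] / max(ev[2], .Machine$double.eps))
  }, numeric(1))
  stats::setNames(out, space$scores$specimen)
}

#' Explained-variance table of a shape space
#'
#' @param space A `shape_space` object.
#' @return Tibble with `component`, `eigenvalue`, `percent`, `cumulative`.
#' @export
variance_table <- function(space) {
  stopifnot(inherits(space, "shape_space"))
  tibble(
    component = paste0("PC", seq_along(space$eigenvalues)),
    eigenvalue = space$eigenvalues,
    percent = space$percent_variance,
    cumulative = cumsum(space$percent_variance)
  )
}

#' @export
print.shape_space <- function(x, ...) {
  cat("Shape space (PCA of Procrustes coordinates)\n")
  cat("  specimens:", x$n, "  landmarks:", x$k, "\n")
  nz <- sum(x$eigenvalues > max(x$eigenvalues) * 1e-10)
  cat("  non-zero components:", nz, "\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% (cumulative %.1f%%)\n",
              x$percent_variance[1], x$percent_variance[2],
              sum(x$percent_variance[1:2])))
  invisible(x)
}

#' @describeIn shape_pca Specimen scores as a tibble.
#' @param x A `shape_space` object.
#' @param ... Unused.
#' @export
tidy.shape_space <- function(x, ...) {
  x$scores
}

#' @describeIn shape_pca One-row summary (specimens, landmarks, leading
#'   explained variance).
#' @export
glance.shape_space <- function(x, ...) {
  tibble(n = x$n, k = x$k,
         pc1_percent = x$percent_variance[1],
         pc2_percent = x$percent_variance[2],
         cumulative_pc2 = sum(x$percent_variance[1:2]))
}
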