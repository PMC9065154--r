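# Thin-plate spline interpolation for 2-D landmark configurations.
#
# Kernel U(r) = r^2 log r, the biharmonic fundamental solution in 2-D.
# The bending-energy matrix (upper-left block of the inverted TPS system)
# is also used to slide semi-landmarks under the minimum-bending-energy
# criterion.

tps_kernel <- function(r) {
  out <- r
  out[] <- 0
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos])
  out
}

# K x K bending-energy matrix of a reference configuration (K x 2 matrix).
# Positive semidefinite; its null space is the affine maps.
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  d <- as.matrix(stats::dist(ref))
  if (any(d[upper.tri(d)] == 0)) {
    abort("coincident landmarks: thin-plate spline system is singular")
  }
  kk <- tps_kernel(d)
  p <- cbind(1, ref)
  l <- rbind(cbind(kk, p), cbind(t(p), matrix(0, 3, 3)))
  linv <- tryCatch(solve(l), error = function(e) {
    abort("singular thin-plate spline system")
  })
  be <- linv[seq_len(k), seq_len(k), drop = FALSE]
  (be + t(be)) / 2
}

# Fit a TPS map taking `src` landmarks onto `dst` landmarks.
# Returns a list with the warp function and the bending energy.
tps_fit <- function(src, dst) {
  src <- as.matrix(src)
  dst <- as.matrix(dst)
  if (!all(dim(src) == dim(dst))) abort("src and dst must have the same dimensions")
  k <- nrow(src)
  d <- as.matrix(stats::dist(src))
  if (any(d[upper.tri(d)] == 0)) {
    abort("coincident landmarks: thin-plate spline system is singular")
  }
  kk <- tps_kernel(d)
  p <- cbind(1, src)
  l <- rbind(cbind(kk, p), cbind(t(p), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coefs <- tryCatch(solve(l, rhs), error = function(e) {
    abort("singular thin-plate spline system")
  })
  w <- coefs[seq_len(k), , drop = FALSE]
  a <- coefs[k + 1:3, , drop = FALSE]
  energy <- sum(diag(t(w) %*% kk %*% w))
  warp <- function(pts) {
    pts <- as.matrix(pts)
    u <- tps_kernel(sqrt(outer(pts[, 1], src[, 1], "-")^2 +
                         outer(pts[, 2], src[, 2], "-")^2))
    cbind(1, pts) %*% a + u %*% w
  }
  list(warp = warp, energy = energy, weights = w, affine = a)
}

#' Thin-plate-spline deformation grid for a shape-space position
#'
#' Back-projects a position in principal-component space to a landmark
#' configuration (consensus + scores x loadings), fits the thin-plate
#' spline taking the consensus onto it, and warps a rectangular reference
#' grid — the classic deformation-grid visualization of a morphospace
#' direction.
#'
#' @param space A [shape_pca()] result.
#' @param target_scores Named or positional numeric vector of PC scores
#'   (unspecified components are 0).
#' @param n_grid Grid lines per axis.
#' @param pad Fractional padding of the grid beyond the consensus range.
#' @return A list of class `tps_warp`: `grid` (tibble of source and warped
#'   grid points), `consensus` and `target` landmark tibbles, and the
#'   `bending_energy` of the warp.
#' @export
tps_warp <- function(space, target_scores, n_grid = 20, pad = 0.15) {
  stopifnot(inherits(space, "shape_space"))
  cons <- matrix(space$center, ncol = 2)
  m <- ncol(space$loadings)
  sc <- numeric(m)
  if (!is.null(names(target_scores))) {
    idx <- match(names(target_scores), colnames(space$loadings))
    if (anyNA(idx)) abort("unknown component name in target_scores")
    sc[idx] <- target_scores
  } else {
    sc[seq_along(target_scores)] <- target_scores
  }
  target <- matrix(space$center + as.vector(space$loadings %*% sc),
                   ncol = 2)
  fit <- tps_fit(cons, target)
  rx <- range(cons[, 1]); ry <- range(cons[, 2])
  ex <- diff(rx) * pad; ey <- diff(ry) * pad
  gx <- seq(rx[1] - ex, rx[2] + ex, length.out = n_grid)
  gy <- seq(ry[1] - ey, ry[2] + ey, length.out = n_grid)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  warped <- fit$warp(grid)
  out <- list(
    grid = tibble(x = grid[, 1], y = grid[, 2],
                  x_warped = warped[, 1], y_warped = warped[, 2],
                  row = rep(seq_len(n_grid), each = n_grid),
                  col = rep(seq_len(n_grid), times = n_grid)),
    consensus = tibble(landmark = seq_len(nrow(cons)),
                       x = cons[, 1], y = cons[, 2]),
    target = tibble(landmark = seq_len(nrow(target)),
                    x = target[, 1], y = target[, 2]),
    bending_energy = fit$energy
  )
  class(out) <- "tps_warp"
  out
}

#' @export
print.tps_warp <- function(x, ...) {
  cat("Thin-plate spline deformation grid\n")
  cat("  landmarks:", nrow(x$consensus), "\n")
  cat("  bending energy:", format(x$bending_energy, digits = 4), "\n")
  invisible(x)
}
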