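make_space <- function(n_per_group = 4, seed = 5) {
  ds <- generate_claw_dataset(
    claw_preset("basal", n_per_group = n_per_group, seed = 1),
    claw_preset("derived", n_per_group = n_per_group, seed = 2), seed = seed)
  list(ds = ds, fit = gpa(ds$landmarks, ds$sliders))
}

test_that("a single deformation direction gives a rank-1 shape space", {
  base <- center_scale(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                             c(0.5, 0.5)))
  dir <- matrix(0, 5, 2); dir[2, ] <- c(0.05, 0.02); dir[4, ] <- c(-0.03, 0.01)
  arr <- array(NA_real_, c(5, 2, 6))
  for (i in 1:6) arr[, , i] <- base + (i - 3.5) * dir
  # bypass GPA so the single direction is not re-mixed by alignment
  sp <- shape_pca(arr_to_tbl(arr))
  expect_equal(sp$percent_variance[1], 100, tolerance = 1e-6)
})

test_that("explained variance sums to 100 and reconstruction is exact", {
  ms <- make_space()
  sp <- shape_pca(ms$fit)
  expect_equal(sum(sp$percent_variance), 100, tolerance = 1e-6)
  expect_true(all(diff(sp$eigenvalues) <= 1e-12))
  # loadings orthonormal
  g <- crossprod(sp$loadings)
  expect_lt(max(abs(g - diag(nrow(g)))), 1e-8)
  # scores have zero column means
  pc <- as.matrix(sp$scores[grep("^PC", names(sp$scores))])
  expect_lt(max(abs(colMeans(pc))), 1e-10)
  # full-rank reconstruction of every specimen
  arr <- clawmorph:::lmk_array(ms$fit$aligned)
  recon <- sweep(pc %*% t(sp$loadings), 2, sp$center, "+")
  flat <- t(apply(arr, 3, as.vector))
  expect_lt(max(abs(recon - flat)), 1e-8)
  # rank bound: at most min(n - 1, 2K - 4) informative components
  nz <- sum(sp$eigenvalues > max(sp$eigenvalues) * 1e-8)
  expect_lte(nz, min(sp$n - 1, 2 * sp$k - 4))
})

test_that("eigenvalues agree with an independent SVD route", {
  ms <- make_space(seed = 9)
  sp <- shape_pca(ms$fit)
  arr <- clawmorph:::lmk_array(ms$fit$aligned)
  flat <- t(apply(arr, 3, as.vector))
  xc <- sweep(flat, 2, colMeans(flat))
  sv <- svd(xc)$d^2 / (nrow(flat) - 1)
  expect_equal(sp$eigenvalues[seq_along(sv)], sv, tolerance = 1e-10)
})

test_that("PCA scores are invariant to specimen order up to sign", {
  ms <- make_space(seed = 3)
  sp1 <- shape_pca(ms$fit)
  shuffled <- ms$fit$aligned |>
    dplyr::arrange(factor(specimen, levels = rev(unique(specimen))))
  sp2 <- shape_pca(shuffled)
  m1 <- sp1$scores[order(sp1$scores$specimen), ]
  m2 <- sp2$scores[order(sp2$scores$specimen), ]
  for (pc in c("PC1", "PC2", "PC3")) {
    expect_equal(abs(m1[[pc]]), abs(m2[[pc]]), tolerance = 1e-8)
  }
})

test_that("orient_axes fixes signs, is idempotent, preserves magnitudes", {
  ms <- make_space(seed = 6)
  sp <- shape_pca(ms$fit)
  stat <- elongation_statistic(sp)
  flipped <- sp
  flipped$scores$PC1 <- -flipped$scores$PC1
  flipped$loadings[, "PC1"] <- -flipped$loadings[, "PC1"]
  out <- orient_axes(flipped)
  expect_gte(cor(out$scores$PC1, stat[out$scores$specimen]), 0)
  out2 <- orient_axes(out)
  expect_equal(out2$scores, out$scores)
  expect_equal(abs(out$scores$PC1), abs(sp$scores$PC1), tolerance = 1e-12)
  expect_equal(out$eigenvalues, sp$eigenvalues)
  expect_warning(orient_axes(sp, statistic = rep(1, sp$n)), "zero variance")
})

test_that("oriented PC1 tracks the elongation contrast between presets", {
  ms <- make_space(n_per_group = 5, seed = 12)
  sp <- orient_axes(shape_pca(ms$fit))
  sc <- dplyr::inner_join(sp$scores, ms$ds$true_params, by = "specimen")
  expect_gt(cor(sc$PC1, sc$elongation), 0.8)
})

test_that("TPS warp is the identity at zero scores and interpolates", {
  ms <- make_space(seed = 4)
  sp <- shape_pca(ms$fit)
  w0 <- tps_warp(sp, c(PC1 = 0))
  expect_lt(max(abs(w0$grid$x_warped - w0$grid$x),
                abs(w0$grid$y_warped - w0$grid$y)), 1e-10)
  s1 <- 2 * sqrt(sp$eigenvalues[1])
  w1 <- tps_warp(sp, c(PC1 = s1))
  fit <- clawmorph:::tps_fit(cbind(w1$consensus$x, w1$consensus$y),
                             cbind(w1$target$x, w1$target$y))
  back <- fit$warp(cbind(w1$consensus$x, w1$consensus$y))
  expect_lt(max(abs(back - cbind(w1$target$x, w1$target$y))), 1e-10)
})

test_that("affine-only displacement has zero bending energy", {
  src <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.3, 0.6))
  aff <- function(p) sweep(p %*% matrix(c(1.4, 0.3, -0.2, 0.8), 2, 2),
                           2, c(2, -1), "+")
  fit <- clawmorph:::tps_fit(src, aff(src))
  expect_lt(abs(fit$energy), 1e-10)
  # and a genuinely non-affine map has positive energy
  dst <- src; dst[5, ] <- dst[5, ] + c(0.2, -0.1)
  expect_gt(clawmorph:::tps_fit(src, dst)$energy, 1e-6)
})

test_that("coincident landmarks make the TPS system singular", {
  src <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_error(clawmorph:::tps_fit(src, src), "singular|coincident")
})
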