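test_that("center_scale normalizes, is idempotent, rejects degenerates", {
  m <- rbind(c(0, 0), c(2, 0))
  z <- center_scale(m)
  expect_equal(z[, 1], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  z2 <- center_scale(z)
  expect_lt(max(abs(z2 - z)), 1e-12)
  expect_equal(attr(z, "centroid_size"), sqrt(2))
  expect_error(center_scale(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("optimal rotation recovers a known rotation exactly", {
  set.seed(1)
  ref <- center_scale(matrix(rnorm(16), 8, 2))
  shp <- rotate_pts(ref, 30)
  out <- optimal_rotation(shp, ref)
  expect_equal(attr(out, "angle") * 180 / pi, -30, tolerance = 1e-10)
  expect_lt(sqrt(sum((out - ref)^2)), 1e-10)
  same <- optimal_rotation(ref, ref)
  expect_equal(attr(same, "angle"), 0, tolerance = 1e-12)
  expect_error(optimal_rotation(ref[1:5, ], ref), "same number")
})

test_that("procrustes distance matches the complex closed-form oracle", {
  expect_equal(procrustes_distance(diag(2), diag(2)), 0, tolerance = 1e-12)
  tri_a <- rbind(c(0, 0), c(1, 0), c(0, 1))
  tri_b <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(procrustes_distance(tri_a, tri_b),
               oracle_procrustes_distance(tri_a, tri_b), tolerance = 1e-10)
  set.seed(42)
  for (i in 1:20) {
    a <- matrix(rnorm(16), 8, 2)
    b <- matrix(rnorm(16), 8, 2)
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
                 tolerance = 1e-12)
    expect_equal(procrustes_distance(a, b), oracle_procrustes_distance(a, b),
                 tolerance = 1e-10)
  }
})

test_that("GPA removes similarity transforms exactly", {
  set.seed(2)
  base <- matrix(rnorm(20), 10, 2)
  arr <- array(NA_real_, c(10, 2, 4))
  arr[, , 1] <- base
  arr[, , 2] <- rotate_pts(base, 73) * 2.5
  arr[, , 3] <- sweep(rotate_pts(base, -120) * 0.3, 2, c(5, -7), "+")
  arr[, , 4] <- sweep(base * 10, 2, c(-1, 1), "+")
  fit <- gpa(arr_to_tbl(arr))
  arr_al <- clawmorph:::lmk_array(fit$aligned)
  for (i in 2:4) {
    expect_lt(procrustes_distance(arr_al[, , 1], arr_al[, , i]), 1e-10)
  }
  cons <- cbind(fit$consensus$x, fit$consensus$y)
  expect_lt(procrustes_distance(cons, base), 1e-10)
})

test_that("two-shape GPA is symmetric about the consensus", {
  a <- center_scale(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  b <- center_scale(rbind(c(0, 0), c(1, 0), c(1.5, 1.2), c(-0.2, 0.9)))
  arr <- array(c(a, b), c(4, 2, 2))
  fit <- gpa(arr_to_tbl(arr))
  arr_al <- clawmorph:::lmk_array(fit$aligned)
  cons <- cbind(fit$consensus$x, fit$consensus$y)
  d1 <- sqrt(sum((arr_al[, , 1] - cons)^2))
  d2 <- sqrt(sum((arr_al[, , 2] - cons)^2))
  expect_equal(d1, d2, tolerance = 1e-8)
  expect_equal(cons, (arr_al[, , 1] + arr_al[, , 2]) / 2, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("GPA is invariant to similarity transforms of the inputs", {
  ds <- generate_claw_dataset(claw_preset("basal", n_per_group = 3, seed = 1),
                              claw_preset("derived", n_per_group = 3, seed = 2),
                              seed = 5)
  f1 <- gpa(ds$landmarks, ds$sliders)
  set.seed(99)
  arr <- clawmorph:::lmk_array(ds$landmarks)
  for (i in seq_len(dim(arr)[3])) {
    arr[, , i] <- sweep(rotate_pts(arr[, , i], runif(1, 0, 360)) *
                          runif(1, 0.3, 4), 2, runif(2, -9, 9), "+")
  }
  lm2 <- arr_to_tbl(arr, ids = unique(ds$landmarks$specimen))
  f2 <- gpa(lm2, ds$sliders)
  expect_lt(max(abs(f1$aligned$x - f2$aligned$x),
                abs(f1$aligned$y - f2$aligned$y)), 1e-8)
})

test_that("the GPA objective is non-increasing across iterations", {
  set.seed(3)
  arr <- array(rnorm(10 * 2 * 6, sd = 1), c(10, 2, 6))
  fit <- gpa(arr_to_tbl(arr))
  expect_true(all(diff(fit$objective) <= 1e-12))
  expect_lt(fit$final_delta, 1e-8)
})

test_that("sliding improves the fit of a re-parameterized common curve", {
  # same quarter-circle arc, semi-landmarks unevenly re-parameterized:
  # sliding should recover the common shape
  make_arc <- function(warp) {
    s <- seq(0, 1, length.out = 8)
    s_mid <- s[2:7]^warp                 # uneven spacing of the semis
    th <- c(0, s_mid, 1) * (pi / 2)
    cbind(cos(th), sin(th))
  }
  arr <- array(NA_real_, c(8, 2, 4))
  warps <- c(0.6, 0.8, 1.2, 1.6)
  for (i in 1:4) arr[, , i] <- make_arc(warps[i])
  tbl <- arr_to_tbl(arr)
  sliders <- make_sliders(before = 1:6, slide = 2:7, after = 3:8, k = 8)
  plain <- gpa(tbl)
  for (mode in c("bending", "procrustes")) {
    slid <- gpa(tbl, sliders, mode = mode)
    expect_lt(tail(slid$objective, 1), tail(plain$objective, 1))
  }
})

test_that("sliding never moves fixed landmarks", {
  ds <- generate_claw_dataset(claw_preset("basal", n_per_group = 3, seed = 2),
                              claw_preset("derived", n_per_group = 3, seed = 3),
                              seed = 8)
  fit <- gpa(ds$landmarks, ds$sliders)
  expect_setequal(unique(fit$sliding$landmark), ds$sliders$slide)
  fixed <- setdiff(1:16, ds$sliders$slide)
  expect_false(any(fit$sliding$landmark %in% fixed))
})

test_that("with no sliders GPA matches an independent plain-GPA oracle", {
  set.seed(4)
  arr <- array(rnorm(8 * 2 * 5, sd = 1), c(8, 2, 5))
  fit <- gpa(arr_to_tbl(arr), project = FALSE)
  ora <- oracle_plain_gpa(arr)
  arr_al <- clawmorph:::lmk_array(fit$aligned)
  # the two solutions agree up to one global rotation
  rot <- optimal_rotation(ora$consensus,
                          cbind(fit$consensus$x, fit$consensus$y))
  ang <- attr(rot, "angle")
  rmat <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
  for (i in 1:5) {
    expect_lt(max(abs(ora$aligned[, , i] %*% rmat - arr_al[, , i])), 1e-6)
  }
})

test_that("tangent projection keeps configurations centered", {
  set.seed(5)
  arr <- array(rnorm(12 * 2 * 4), c(12, 2, 4))
  # near-random shapes superimpose slowly; allow extra iterations
  fit <- gpa(arr_to_tbl(arr), project = TRUE, max_iter = 1000)
  cents <- fit$aligned |>
    dplyr::summarise(cx = mean(x), cy = mean(y), .by = specimen)
  expect_lt(max(abs(c(cents$cx, cents$cy))), 1e-8)
  # consensus equals the arithmetic mean of the aligned configurations
  mn <- fit$aligned |>
    dplyr::summarise(x = mean(x), y = mean(y), .by = landmark)
  expect_equal(mn$x, fit$consensus$x, tolerance = 1e-8)
  expect_equal(mn$y, fit$consensus$y, tolerance = 1e-8)
})
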