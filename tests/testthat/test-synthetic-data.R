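test_that("claw generation is seed-deterministic", {
  p <- claw_params(landmark_noise_sd = 0.02)
  a <- generate_claw(p, specimen_seed = 7, specimen_id = "x")
  b <- generate_claw(p, specimen_seed = 7, specimen_id = "x")
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$levers, b$levers)
  c_ <- generate_claw(p, specimen_seed = 8, specimen_id = "x")
  expect_false(identical(a$landmarks$x, c_$landmarks$x))

  d1 <- generate_claw_dataset(claw_preset("basal", n_per_group = 3, seed = 1),
                              claw_preset("derived", n_per_group = 3, seed = 2),
                              seed = 5)
  d2 <- generate_claw_dataset(claw_preset("basal", n_per_group = 3, seed = 1),
                              claw_preset("derived", n_per_group = 3, seed = 2),
                              seed = 5)
  expect_identical(d1, d2)
})

test_that("zero tubercle prominence gives DFT exactly zero", {
  p <- claw_params(tubercle_prominence = 0, landmark_noise_sd = 0)
  cl <- generate_claw(p)
  sc <- claw_scores(cl$levers)
  expect_identical(sc$DFT, 0)
  expect_identical(sc$output, 0)
})

test_that("generated DFT equals the prominence parameter exactly", {
  for (pr in c(0.1, 0.2, 0.35)) {
    p <- claw_params(tubercle_prominence = pr, landmark_noise_sd = 0)
    sc <- claw_scores(generate_claw(p)$levers)
    expect_equal(sc$DFT, pr, tolerance = 1e-12)
  }
})

test_that("doubling elongation strictly increases the a/d ratio", {
  for (el in c(1.3, 1.8, 2.4)) {
    p1 <- claw_params(elongation = el, landmark_noise_sd = 0)
    p2 <- claw_params(elongation = 2 * el, landmark_noise_sd = 0)
    r1 <- with(generate_claw(p1)$levers, a / d)
    r2 <- with(generate_claw(p2)$levers, a / d)
    expect_gt(r2, r1)
  }
})

test_that("impossible outlines are rejected", {
  expect_error(clawmorph:::claw_geometry(120, 50, 0.2, 0.15),
               "self-intersecting")
  expect_error(generate_claw(claw_params(elongation = 60)),
               "self-intersecting")
})

test_that("generated landmark files round-trip through the readers", {
  ds <- generate_claw_dataset(claw_preset("basal", n_per_group = 2, seed = 1),
                              claw_preset("derived", n_per_group = 2, seed = 2),
                              seed = 3)
  dir <- withr::local_tempdir()
  write_claw_dataset(ds, dir)
  back_tps <- read_tps(file.path(dir, "landmarks.tps"))
  expect_equal(back_tps$x, ds$landmarks$x, tolerance = 1e-9)
  back_csv <- read_landmark_csv(file.path(dir, "landmarks.csv"))
  expect_equal(back_csv$y, ds$landmarks$y, tolerance = 1e-9)
  expect_equal(back_csv$clade_group, ds$landmarks$clade_group)
  lv <- read_levers(file.path(dir, "levers.csv"))
  expect_equal(lv$a, ds$levers$a, tolerance = 1e-9)
  sl <- read_sliders(file.path(dir, "sliders.csv"), 16)
  expect_equal(sl, ds$sliders)
})

test_that("generated measurements satisfy the lever invariants over many draws", {
  set.seed(30)
  n_draw <- 250
  curv <- runif(n_draw, 60, 165)
  elong <- runif(n_draw, 1.2, 4)
  prom <- runif(n_draw, 0, 0.5)
  ok <- 0L
  for (i in seq_len(n_draw)) {
    geo <- tryCatch(clawmorph:::claw_geometry(curv[i], elong[i], prom[i], 0.15),
                    error = function(e) NULL)
    if (is.null(geo)) next       # rejected as self-intersecting, by contract
    lv <- clawmorph:::lm_levers(geo)
    expect_gt(lv$a, 0); expect_gt(lv$d, 0)
    expect_gt(geo$b, 0); expect_gte(geo$h, 0)
    expect_gt(lv$theta + lv$delta, 0)
    expect_lt(lv$theta + lv$delta, 180)
    ok <- ok + 1L
  }
  expect_gt(ok, n_draw * 0.6)
})

test_that("character evolution respects its degenerate settings", {
  tr <- random_topology(6, seed = 3)
  sim0 <- generate_character_matrix(tr, nchar = 12, change_prob = 0, seed = 4)
  expect_equal(sum(sim0$true_changes), 0L)
  expect_equal(tree_length(random_topology(6, seed = 9), sim0$matrix)$S, 0)

  sim1 <- generate_character_matrix(tr, nchar = 12, change_prob = 0.3,
                                    missing_prob = 1, seed = 5)
  expect_true(all(is.na(sim1$matrix$cells)))
  f <- withr::local_tempfile(fileext = ".tnt")
  write_tnt(sim1$matrix, f)
  cm2 <- read_character_matrix(f)       # parse-compatible, zero information
  expect_equal(cm2$ntax, 6)
  expect_equal(tree_length(tr, cm2)$S, 0)
})

test_that("groups separate in DFT as designed", {
  ds <- generate_claw_dataset(claw_preset("basal", n_per_group = 8, seed = 1),
                              claw_preset("derived", n_per_group = 8, seed = 2),
                              seed = 77)
  sc <- claw_scores(ds$levers)
  m <- tapply(sc$DFT, sc$clade_group, mean)
  expect_gt(m[["non_therizinosaurid"]], m[["therizinosaurid"]])
})

test_that("equal parameters without noise give identical groups (Welch t = 0)", {
  p <- claw_preset("basal", n_per_group = 4, landmark_noise_sd = 0,
                   param_cv = 0)
  ds <- generate_claw_dataset(p, p, seed = 1)
  sc <- claw_scores(ds$levers)
  w <- welch_test(sc, MA, clade_group)
  expect_equal(w$t, 0, tolerance = 1e-12)
})
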