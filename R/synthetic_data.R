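# Synthetic claw generator: landmark configurations, lever measurements,
# and character matrices with known ground truth.
#
# Claw outlines are built from two concentric circular arcs (dorsal and
# ventral margins) spanning `curvature` degrees; the ventral radius tapers
# linearly to meet the dorsal arc at the tip, giving a closed, sharp-tipped
# outline whose lever geometry is analytic. A triangular tubercle bump of
# height h = prominence * b sits on the ventral margin, and the proximal
# ventral process extends by `articular_depth` of the proximal thickness.
# Circular arcs are used instead of logarithmic spirals because the tests
# need exact ground truth, not anatomical realism.

#' Parameters for the synthetic claw generator
#'
#' @param n_per_group Specimens per group (>= 2).
#' @param curvature Arc angle subtended by the dorsal outline, degrees.
#' @param elongation Tip-chord length over proximal thickness.
#' @param tubercle_prominence Tubercle height over base length (h/b, >= 0).
#' @param articular_depth Proximal extension of the ventral process as a
#'   fraction of proximal thickness.
#' @param landmark_noise_sd Isotropic Gaussian landmark noise, in
#'   Procrustes units (scaled by centroid size).
#' @param param_cv Between-specimen coefficient of variation applied
#'   (log-normally) to elongation and tubercle prominence.
#' @param seed Integer seed.
#' @return A list of class `claw_params`.
#' @export
claw_params <- function(n_per_group = 10, curvature = 120, elongation = 2,
                        tubercle_prominence = 0.2, articular_depth = 0.15,
                        landmark_noise_sd = 0.01, param_cv = 0.15, seed = 1) {
  stopifnot(n_per_group >= 2, curvature > 0, curvature < 180,
            elongation > 0, tubercle_prominence >= 0,
            articular_depth >= 0, landmark_noise_sd >= 0, param_cv >= 0)
  structure(list(n_per_group = n_per_group, curvature = curvature,
                 elongation = elongation,
                 tubercle_prominence = tubercle_prominence,
                 articular_depth = articular_depth,
                 landmark_noise_sd = landmark_noise_sd,
                 param_cv = param_cv, seed = seed),
            class = "claw_params")
}

#' @describeIn claw_params Group presets: `"basal"` (short, strongly
#'   tubercled: curvature 140, elongation 1.6, prominence 0.30) and
#'   `"derived"` (elongate, weakly tubercled: curvature 100, elongation
#'   2.6, prominence 0.12).
#' @param preset `"basal"` or `"derived"`.
#' @param ... Overrides passed to [claw_params()].
#' @export
claw_preset <- function(preset = c("basal", "derived"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    basal = list(curvature = 140, elongation = 1.6, tubercle_prominence = 0.30),
    derived = list(curvature = 100, elongation = 2.6, tubercle_prominence = 0.12))
  do.call(claw_params, utils::modifyList(defaults, list(...)))
}

#' The slider table of the synthetic claw scheme
#'
#' Sixteen landmarks: 1 tip, 2 proximodorsal lip, 3 proximoventral
#' process, 4 tubercle apex (fixed), 5-11 dorsal and 12-16 ventral
#' semi-landmarks in proximal-to-distal curve order.
#'
#' @return A 12-row slider tibble.
#' @export
claw_sliders <- function() {
  make_sliders(
    before = c(2L, 5L, 6L, 7L, 8L, 9L, 10L, 3L, 4L, 13L, 14L, 15L),
    slide  = c(5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L, 16L),
    after  = c(6L, 7L, 8L, 9L, 10L, 11L, 1L, 4L, 14L, 15L, 16L, 1L),
    k = 16L
  )
}

# circular arc from p to q subtending `phi` radians, bulging toward the
# left normal of p->q; returns point(s)/tangent(s) at parameter s in [0,1]
circular_arc <- function(p, q, phi) {
  v <- q - p
  len <- sqrt(sum(v^2))
  u <- v / len
  n <- c(-u[2], u[1])
  r <- (len / 2) / sin(phi / 2)
  ctr <- (p + q) / 2 - n * (len / 2) / tan(phi / 2)
  a_p <- atan2(p[2] - ctr[2], p[1] - ctr[1])
  a_q <- atan2(q[2] - ctr[2], q[1] - ctr[1])
  # sweep from p to q passing the n side of the chord
  sweep_ <- (a_q - a_p) %% (2 * pi)
  if (abs(sweep_ - phi) > abs((sweep_ - 2 * pi) - (-phi))) sweep_ <- sweep_ - 2 * pi
  list(
    point = function(s) {
      ang <- a_p + s * sweep_
      cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
    },
    outward = function(s) {         # unit normal pointing away from the center
      ang <- a_p + s * sweep_
      cbind(cos(ang), sin(ang))
    },
    tangent = function(s) {         # unit tangent in direction of increasing s
      ang <- a_p + s * sweep_
      sign(sweep_) * cbind(-sin(ang), cos(ang))
    },
    length = r * abs(sweep_), radius = r, center = ctr
  )
}

# noiseless outline geometry for one claw, in chord coordinates: the
# proximodorsal lip sits at (0, 0), the tip at (1, 0), dorsal is up
claw_geometry <- function(curvature, elongation, tubercle_prominence,
                          articular_depth) {
  phi <- curvature * pi / 180
  thick <- 1 / elongation                      # proximal height (chord = 1)
  tip <- c(1, 0)
  pd <- c(0, 0)                                # proximodorsal lip
  pv <- c(0, -thick)                           # proximoventral corner
  dorsal <- circular_arc(pd, tip, phi)
  ventral <- circular_arc(pv, tip, phi)
  arc_v <- ventral$length
  # the flexor tubercle sits just distal to the articular end, at an arc
  # distance scaling with claw depth (not with claw length): elongate thin
  # claws have proportionally short in-levers, as in the real unguals
  s_t <- 0.8 * thick / arc_v                   # tubercle position on ventral arc
  b_len <- 0.3 * thick
  h <- tubercle_prominence * b_len
  ds <- b_len / arc_v                          # bump base width in parameter
  bump <- function(s) {
    out <- h * (1 - abs(s - s_t) / (ds / 2))
    out[out < 0] <- 0
    out
  }
  ventral_out <- function(s) {
    # outward (ventral) side is away from the arc center, i.e. -outward
    # if the center lies below; the arc bulges dorsally, center below,
    # so outward normal of the arc points up -> ventral bump points down
    ventral$point(s) - ventral$outward(s) * bump(s)
  }
  lm <- matrix(NA_real_, 16, 2)
  lm[1, ] <- tip
  lm[2, ] <- pd
  lm[3, ] <- pv + c(-articular_depth * thick, 0)     # proximoventral process
  lm[4, ] <- as.vector(ventral$point(s_t) - ventral$outward(s_t) * h)
  lm[5:11, ] <- dorsal$point((1:7) / 8)
  lm[12:16, ] <- ventral_out((1:5) / 6)
  # validity check: the ventral outline must keep clear daylight below the
  # dorsal arc; zero clearance means the margins touch or cross (a
  # degenerate, self-intersecting sliver)
  sg <- seq(0.02, 0.9, length.out = 40)
  dpts <- dorsal$point(sg)
  vpts <- ventral_out(sg)
  dy <- stats::approx(dpts[, 1], dpts[, 2], xout = vpts[, 1], rule = 2)$y
  if (min(dy - vpts[, 2]) < 5e-3) {
    abort("self-intersecting outline: ventral margin meets the dorsal margin")
  }
  base1 <- as.vector(ventral$point(s_t - ds / 2))
  base2 <- as.vector(ventral$point(s_t + ds / 2))
  fulcrum <- (pd + pv) / 2                     # mid articular surface
  # flexor-tendon direction: ventral tangent just proximal to the tubercle,
  # pointing proximally (decreasing s)
  tang <- -as.vector(ventral$tangent(max(s_t - 2 * ds, 0.01)))
  list(landmarks = lm,
       base = rbind(base1, base2),
       fulcrum = fulcrum,
       force = tang,
       b = sqrt(sum((base2 - base1)^2)),
       h = h * sqrt(sum((base2 - base1)^2)) / b_len)
}

#' Generate one synthetic claw
#'
#' Builds the noiseless outline geometry, samples the 16-landmark scheme
#' (see [claw_sliders()]), adds isotropic Gaussian landmark noise, and
#' derives the lever measurements from the noiseless geometry: `a` and `d`
#' from the fulcrum (mid articular surface) to tip and tubercle apex,
#' `theta` from the flexor-tendon direction (ventral-margin tangent
#' proximal to the tubercle), and `h`, `b` from the analytic bump, so
#' `DFT = tubercle_prominence` exactly.
#'
#' @param params A [claw_params()] object (its `elongation`,
#'   `tubercle_prominence`, `curvature`, `articular_depth`,
#'   `landmark_noise_sd` fields are used).
#' @param specimen_seed Integer seed for the landmark noise.
#' @param specimen_id,taxon,digit,clade_group Metadata attached to the
#'   output.
#' @return List with `landmarks` (16-row tibble) and `levers` (one-row
#'   tibble).
#' @export
generate_claw <- function(params, specimen_seed = 1, specimen_id = "claw_1",
                          taxon = specimen_id, digit = "unknown",
                          clade_group = "unknown") {
  geo <- claw_geometry(params$curvature, params$elongation,
                       params$tubercle_prominence, params$articular_depth)
  lm <- geo$landmarks
  if (params$landmark_noise_sd > 0) {
    set.seed(specimen_seed %% .Machine$integer.max)
    cs <- centroid_size(lm)
    lm <- lm + matrix(rnorm(32, sd = params$landmark_noise_sd * cs), 16, 2)
  }
  out_lever <- lm_levers(geo)
  levers <- tibble(specimen = specimen_id, digit = digit, taxon = taxon,
                   clade_group = clade_group,
                   a = out_lever$a, d = out_lever$d,
                   theta = out_lever$theta, delta = out_lever$delta,
                   h = geo$h, b = geo$b)
  validate_levers(levers)
  landmarks <- tibble(specimen = specimen_id, landmark = 1:16,
                      x = lm[, 1], y = lm[, 2],
                      taxon = taxon, digit = digit, clade_group = clade_group)
  list(landmarks = landmarks, levers = levers)
}

lm_levers <- function(geo) {
  tip <- geo$landmarks[1, ]
  apex <- geo$landmarks[4, ]
  f <- geo$fulcrum
  out_v <- tip - f
  in_v <- apex - f
  list(a = sqrt(sum(out_v^2)),
       d = sqrt(sum(in_v^2)),
       delta = angle_between(in_v, out_v),
       theta = angle_to_line(geo$force, out_v))
}

#' Generate a two-group synthetic claw dataset
#'
#' Emulates the basal-versus-derived contrast: each group draws
#' per-specimen elongation and tubercle prominence log-normally around its
#' preset means (coefficient of variation `param_cv`) and generates
#' landmark configurations plus matching lever measurements.
#'
#' @param params_basal,params_derived [claw_params()] objects; group sizes
#'   and noise come from each group's own parameters.
#' @param seed Integer seed governing all draws.
#' @return List with `landmarks` (pooled tibble, `clade_group` labels
#'   `"non_therizinosaurid"`/`"therizinosaurid"`), `levers`, `sliders`
#'   (the claw scheme), and `true_params` (per-specimen drawn parameters).
#' @export
generate_claw_dataset <- function(params_basal, params_derived, seed = 1) {
  set.seed(seed)
  groups <- list(non_therizinosaurid = params_basal,
                 therizinosaurid = params_derived)
  lms <- list(); lvs <- list(); tps <- list()
  idx <- 0L
  for (gname in names(groups)) {
    p <- groups[[gname]]
    for (i in seq_len(p$n_per_group)) {
      idx <- idx + 1L
      el <- p$elongation * exp(rnorm(1, 0, p$param_cv))
      pr <- p$tubercle_prominence * exp(rnorm(1, 0, p$param_cv))
      cv <- p$curvature
      pi_ <- claw_params(n_per_group = 2, curvature = cv, elongation = el,
                         tubercle_prominence = pr,
                         articular_depth = p$articular_depth,
                         landmark_noise_sd = p$landmark_noise_sd,
                         param_cv = 0, seed = p$seed)
      id <- sprintf("%s_%02d", substr(gname, 1, 5), i)
      spec_seed <- (seed * 10007L + idx * 101L) %% .Machine$integer.max
      cl <- generate_claw(pi_, specimen_seed = spec_seed, specimen_id = id,
                          taxon = id, digit = "III", clade_group = gname)
      lms[[idx]] <- cl$landmarks
      lvs[[idx]] <- cl$levers
      tps[[idx]] <- tibble(specimen = id, clade_group = gname,
                           elongation = el, tubercle_prominence = pr,
                           curvature = cv)
    }
  }
  list(landmarks = bind_rows(lms), levers = bind_rows(lvs),
       sliders = claw_sliders(), true_params = bind_rows(tps))
}

#' Random unrooted binary topology
#'
#' Uniform random sequential addition (each taxon attaches to a uniformly
#' chosen branch), giving a tree usable as simulation ground truth.
#'
#' @param ntip Number of leaves (>= 3).
#' @param labels Tip labels (default `t1..tn`).
#' @param seed Optional integer seed.
#' @return An ape `phylo`.
#' @export
random_topology <- function(ntip, labels = paste0("t", seq_len(ntip)),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ntip >= 3, length(labels) == ntip)
  e <- tree3(1:3, ntip)
  next_id <- ntip + 2L
  for (t in seq_len(ntip)[-(1:3)]) {
    i <- sample.int(nrow(e), 1)
    w <- next_id
    e <- rbind(e[-i, , drop = FALSE], c(e[i, 1], w), c(w, e[i, 2]), c(w, t))
    next_id <- next_id + 1L
  }
  edges_to_phylo(e, labels)
}

#' Evolve a character matrix on a known tree
#'
#' Each character evolves along the tree from state 0 at the root: on each
#' branch a change happens with probability `change_prob` (unordered
#' characters jump to a uniformly chosen different state among
#' `0..max_state`; ordered characters step by +/-1, reflected at the
#' bounds). Cells are then masked to missing with probability
#' `missing_prob`. The true number of changes per character is recorded.
#'
#' @param tree An ape `phylo` (binary) whose tips name the taxa.
#' @param nchar Number of characters.
#' @param change_prob Per-branch change probability.
#' @param ordered_fraction Fraction of characters flagged additive.
#' @param missing_prob Per-cell missing probability.
#' @param max_state Largest state index (default 3, i.e. up to 4 states).
#' @param max_changes Optional cap on true changes per character: characters
#'   exceeding it are re-drawn (rejection), giving guaranteed low-homoplasy
#'   matrices (`max_changes = 1` yields perfectly clean characters whose
#'   parsimony length equals the true change count on the true tree).
#' @param seed Optional integer seed.
#' @return List: `matrix` (a `character_matrix`), `tree`, `true_changes`
#'   (integer per character).
#' @export
generate_character_matrix <- function(tree, nchar, change_prob,
                                      ordered_fraction = 0, missing_prob = 0,
                                      max_state = 3, max_changes = NULL,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(change_prob >= 0, change_prob <= 1,
            missing_prob >= 0, missing_prob <= 1,
            ordered_fraction >= 0, ordered_fraction <= 1)
  taxa <- tree$tip.label
  ntax <- length(taxa)
  e <- phylo_to_edges(tree, taxa)
  tr <- tree_traversal(e)
  n_ord <- round(ordered_fraction * nchar)
  ordered <- rep(c(TRUE, FALSE), c(n_ord, nchar - n_ord))
  cells <- matrix(NA_character_, ntax, nchar)
  true_changes <- integer(nchar)
  pre <- rev(tr$post)
  for (j in seq_len(nchar)) {
    state <- integer(length(tr$adj))
    state[tr$root] <- 0L
    changes <- 0L
    evolve_edge <- function(s) {
      if (runif(1) >= change_prob) return(s)
      if (ordered[j]) {
        cand <- c(s - 1L, s + 1L)
        cand <- cand[cand >= 0L & cand <= max_state]
        new <- if (length(cand) == 1) cand else sample(cand, 1)
      } else {
        new <- sample(setdiff(0:max_state, s), 1)
      }
      new
    }
    repeat {
      state[] <- 0L
      changes <- 0L
      for (v in pre) {
        for (w in c(if (v == tr$root) 1L, tr$kids[[match(v, tr$post)]])) {
          state[w] <- evolve_edge(state[v])
          if (state[w] != state[v]) changes <- changes + 1L
        }
      }
      if (is.null(max_changes) || changes <= max_changes) break
    }
    true_changes[j] <- changes
    cells[, j] <- as.character(state_symbols[state[seq_len(ntax)] + 1L])
  }
  if (missing_prob > 0) {
    miss <- matrix(runif(ntax * nchar) < missing_prob, ntax, nchar)
    cells[miss] <- NA_character_
  }
  list(matrix = character_matrix(cells, taxa, ordered = ordered),
       tree = tree, true_changes = true_changes)
}

#' Write a synthetic claw dataset to disk
#'
#' Emits the TPS and long-CSV landmark files, the slider table, the lever
#' table, and a ground-truth JSON (drawn parameters).
#'
#' @param dataset A [generate_claw_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_claw_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tps(dataset$landmarks, file.path(dir, "landmarks.tps"))
  write_landmark_csv(dataset$landmarks, file.path(dir, "landmarks.csv"))
  readr::write_csv(dataset$sliders, file.path(dir, "sliders.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$levers, file.path(dir, "levers.csv"),
                   progress = FALSE)
  jsonlite::write_json(dataset$true_params,
                       file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}
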