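# Class-3 lever model of ungual (claw) mechanics.
#
# The flexor tendon inserts on the flexor tubercle a distance d from the
# joint fulcrum; the claw tip lies a distance a from the fulcrum. With
# theta the angle of the input-force vector to the output-lever line and
# delta the angle between the fulcrum-tubercle line and the output lever,
# the mechanical advantage is MA = sin(theta + delta) * d / a. Tubercle
# development (DFT) is the perpendicular height of the tubercle apex over
# its base segment divided by that segment's length, a proxy for input
# force; MA * DFT is the hypothesized output force at the tip. All three
# are dimensionless.

#' Mechanical advantage of a claw lever
#'
#' `MA = sin(theta + delta) * d / a`, the ratio of output force at the
#' claw tip to input force at the flexor tubercle for a class-3 lever.
#' Vectorized over all arguments.
#'
#' @param theta Angle of the input force vector to the output-lever line,
#'   degrees.
#' @param delta Angle between the fulcrum-tubercle line and the
#'   output-lever line, degrees.
#' @param d In-lever length, fulcrum to flexor tubercle.
#' @param a Out-lever length, fulcrum to claw tip (same unit as `d`).
#' @return Dimensionless mechanical advantage in `(0, d/a]`.
#' @export
mechanical_advantage <- function(theta, delta, d, a) {
  if (any(a <= 0) || any(d <= 0)) abort("lever lengths a and d must be positive")
  s <- theta + delta
  if (any(s <= 0) || any(s >= 180)) {
    abort("theta + delta must lie strictly between 0 and 180 degrees")
  }
  sin(s * pi / 180) * d / a
}

#' Development of the flexor tubercle
#'
#' The perpendicular height of the tubercle apex above the segment joining
#' the tubercle base, divided by that base-segment length. Proxies the
#' cross-sectional area of the attached flexor muscle, hence the maximum
#' input force.
#'
#' @param h Perpendicular apex height (>= 0).
#' @param b Base-segment length (> 0, same unit as `h`).
#' @return Dimensionless ratio `h / b`.
#' @export
development_of_flexor_tubercle <- function(h, b) {
  if (any(b <= 0)) abort("tubercle base length b must be positive")
  if (any(h < 0)) abort("tubercle height h must be non-negative")
  h / b
}

#' Hypothesized output force
#'
#' The product of mechanical advantage and flexor-tubercle development, a
#' dimensionless proxy for the force the claw tip can exert.
#'
#' @param ma Mechanical advantage (>= 0).
#' @param dft Development of the flexor tubercle (>= 0).
#' @return `ma * dft`.
#' @export
hypothesized_output <- function(ma, dft) {
  if (any(ma < 0) || any(dft < 0)) abort("ma and dft must be non-negative")
  ma * dft
}

#' Biomechanical score table from lever measurements
#'
#' Computes MA, DFT, and hypothesized output for every row of a lever
#' measurement table, carrying identifier and grouping columns through.
#'
#' @param levers A validated lever tibble (see [read_levers()]).
#' @return Tibble with `specimen`, `digit`, grouping metadata, `MA`,
#'   `DFT`, and `output`; `output = MA * DFT` holds row-wise exactly.
#' @export
claw_scores <- function(levers) {
  levers <- validate_levers(levers)
  keep <- intersect(c("specimen", "digit", "taxon", "clade_group"), names(levers))
  levers |>
    mutate(
      MA = mechanical_advantage(.data$theta, .data$delta, .data$d, .data$a),
      DFT = development_of_flexor_tubercle(.data$h, .data$b),
      output = hypothesized_output(.data$MA, .data$DFT)
    ) |>
    select(all_of(keep), "MA", "DFT", "output")
}

angle_between <- function(u, v) {
  cp <- u[1] * v[2] - u[2] * v[1]
  dp <- sum(u * v)
  abs(atan2(cp, dp)) * 180 / pi
}

# angle between a direction vector and a *line* (<= 90 degrees): the
# input-force angle theta is measured against the output-lever line, so
# the sense of the force vector does not matter
angle_to_line <- function(u, v) {
  ang <- angle_between(u, v)
  min(ang, 180 - ang)
}

#' Derive lever measurements from designated landmarks
#'
#' Measures `a`, `d`, `theta`, `delta`, `h`, `b` from a single landmark
#' configuration, given which landmarks play the anatomical roles. Makes a
#' fully landmark-based pipeline possible; the dimensionless outputs
#' (theta, delta, and DFT inputs) are invariant under rigid motion and
#' uniform scaling, the lengths scale linearly.
#'
#' @param config A landmark tibble for one specimen (or a K x 2 matrix).
#' @param role_map Named list with 1-based landmark indices: `fulcrum`,
#'   `tip`, `apex` (tubercle apex), `base` (length-2 vector, tubercle base
#'   endpoints), and either `force` (a 2-vector giving the input-force
#'   direction in coordinate space) or `theta` (an explicit angle in
#'   degrees).
#' @return One-row lever tibble.
#' @export
measure_levers_from_landmarks <- function(config, role_map) {
  if (is.data.frame(config)) {
    id <- if ("specimen" %in% names(config)) config$specimen[1] else "specimen"
    dg <- if ("digit" %in% names(config)) config$digit[1] else "unknown"
    m <- cbind(config$x, config$y)[order(config$landmark %||% seq_len(nrow(config))), ]
  } else {
    id <- "specimen"; dg <- "unknown"
    m <- as.matrix(config)
  }
  need <- c("fulcrum", "tip", "apex", "base")
  miss <- setdiff(need, names(role_map))
  if (length(miss) > 0) {
    abort(paste0("role_map lacks: ", paste(miss, collapse = ", ")))
  }
  f <- m[role_map$fulcrum, ]
  tp <- m[role_map$tip, ]
  ap <- m[role_map$apex, ]
  b1 <- m[role_map$base[1], ]
  b2 <- m[role_map$base[2], ]
  out_lever <- tp - f
  in_lever <- ap - f
  base_seg <- b2 - b1
  a <- sqrt(sum(out_lever^2))
  d <- sqrt(sum(in_lever^2))
  b <- sqrt(sum(base_seg^2))
  if (a == 0) abort("tip coincides with fulcrum")
  if (d == 0) abort("tubercle apex coincides with fulcrum")
  if (b == 0) abort("tubercle base endpoints coincide")
  delta <- angle_between(in_lever, out_lever)
  if (!is.null(role_map$theta)) {
    theta <- role_map$theta
  } else if (!is.null(role_map$force)) {
    theta <- angle_to_line(role_map$force, out_lever)
  } else {
    abort("role_map needs either a force vector or an explicit theta")
  }
  # perpendicular distance from the apex to the (infinite) base-segment line
  h <- abs((ap[1] - b1[1]) * base_seg[2] - (ap[2] - b1[2]) * base_seg[1]) / b
  tibble(specimen = id, digit = dg, a = a, d = d,
         theta = theta, delta = delta, h = h, b = b)
}
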