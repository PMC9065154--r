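# Generalized Procrustes analysis with semi-landmark sliding.
#
# Internals operate on K x 2 coordinate matrices (complex arithmetic for the
# 2-D rotation); the user-facing surface consumes and emits long landmark
# tibbles. Rotations only — reflections are never fitted, so left and right
# unguals must be mirrored at I/O time, not silently during superimposition.

#' Center a configuration and scale it to unit centroid size
#'
#' Translates the centroid to the origin and divides by centroid size
#' (the root summed squared distance of the landmarks to their centroid).
#'
#' @param coords A K x 2 numeric matrix, or a data frame with `x` and `y`.
#' @return An object of the same shape, centered with centroid size 1 and a
#'   `centroid_size` attribute holding the original size.
#' @export
center_scale <- function(coords) {
  df_in <- is.data.frame(coords)
  m <- if (df_in) cbind(coords$x, coords$y) else as.matrix(coords)
  ctr <- colMeans(m)
  m <- sweep(m, 2, ctr)
  cs <- sqrt(sum(m^2))
  if (cs <= 0) abort("degenerate configuration: all landmarks coincide")
  m <- m / cs
  if (df_in) {
    coords$x <- m[, 1]
    coords$y <- m[, 2]
    attr(coords, "centroid_size") <- cs
    coords
  } else {
    attr(m, "centroid_size") <- cs
    m
  }
}

centroid_size <- function(m) {
  m <- as.matrix(m)
  sqrt(sum(sweep(m, 2, colMeans(m))^2))
}

# proper rotation aligning a centered configuration's major principal axis
# with x, with a deterministic 180-degree disambiguation
canonical_rotation <- function(m) {
  v <- eigen(crossprod(m), symmetric = TRUE)$vectors
  if (det(v) < 0) v[, 2] <- -v[, 2]
  r <- v                      # columns: major, minor axis directions
  p <- m %*% r
  i <- which.max(abs(p[, 1]))
  if (p[i, 1] < 0) r <- -r    # 180-degree flip (still a proper rotation)
  r
}

#' Optimal rotation of one shape onto another
#'
#' Finds the proper 2-D rotation (no reflection) minimizing the summed
#' squared distances between corresponding landmarks of two centered
#' configurations.
#'
#' @param shape,reference K x 2 centered coordinate matrices.
#' @return The rotated `shape`, with attribute `angle` (radians,
#'   counter-clockwise).
#' @export
optimal_rotation <- function(shape, reference) {
  shape <- as.matrix(shape); reference <- as.matrix(reference)
  if (!all(dim(shape) == dim(reference))) {
    abort("shape and reference must have the same number of landmarks")
  }
  zs <- complex(real = shape[, 1], imaginary = shape[, 2])
  zr <- complex(real = reference[, 1], imaginary = reference[, 2])
  ang <- Arg(sum(zr * Conj(zs)))
  zrot <- zs * exp(1i * ang)
  out <- cbind(Re(zrot), Im(zrot))
  dimnames(out) <- dimnames(shape)
  attr(out, "angle") <- ang
  out
}

#' Procrustes distance between two shapes
#'
#' Root summed squared difference between two configurations after
#' centering, unit-size scaling, and optimal rotation (partial Procrustes
#' distance). Symmetric; zero exactly when the shapes differ only by a
#' similarity transform.
#'
#' @param shape_a,shape_b K x 2 coordinate matrices (or data frames with
#'   `x`, `y` columns).
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  a <- center_scale(if (is.data.frame(shape_a)) cbind(shape_a$x, shape_a$y) else shape_a)
  b <- center_scale(if (is.data.frame(shape_b)) cbind(shape_b$x, shape_b$y) else shape_b)
  if (nrow(a) != nrow(b)) abort("shapes must have the same number of landmarks")
  rb <- optimal_rotation(b, a)
  sqrt(sum((a - rb)^2))
}

# slide the semi-landmarks of one configuration toward the consensus
# y, cons: K x 2 matrices; sliders: tibble(before, slide, after)
# be: bending-energy matrix of the consensus (bending mode only)
slide_semilandmarks <- function(y, cons, sliders, mode, be = NULL) {
  k <- nrow(y)
  sl <- sliders$slide
  tang <- cbind(y[sliders$after, 1] - y[sliders$before, 1],
                y[sliders$after, 2] - y[sliders$before, 2])
  len <- sqrt(rowSums(tang^2))
  len[len == 0] <- 1
  tang <- tang / len
  if (mode == "procrustes") {
    amt <- (cons[sl, 1] - y[sl, 1]) * tang[, 1] +
           (cons[sl, 2] - y[sl, 2]) * tang[, 2]
    disp <- tang * amt
    y[sl, ] <- y[sl, ] + disp
  } else {
    m <- length(sl)
    tt <- matrix(0, 2 * k, m)
    tt[cbind(sl, seq_len(m))] <- tang[, 1]
    tt[cbind(k + sl, seq_len(m))] <- tang[, 2]
    e2 <- rbind(cbind(be, matrix(0, k, k)), cbind(matrix(0, k, k), be))
    yv <- c(y[, 1], y[, 2])
    cv <- c(cons[, 1], cons[, 2])
    a <- crossprod(tt, e2 %*% tt)
    diag(a) <- diag(a) + 1e-12
    gam <- solve(a, crossprod(tt, e2 %*% (cv - yv)))
    disp <- tang * as.vector(gam)
    y[sl, ] <- y[sl, ] + disp
  }
  attr(y, "displacement") <- disp
  y
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes a set of landmark configurations: each is
#' centered and scaled to unit centroid size, rotated to the current
#' consensus, optionally slid (semi-landmarks move along their tangent
#' chords under the bending-energy or Procrustes-distance criterion), and
#' the consensus is re-estimated until it stops moving. After convergence
#' the aligned shapes are orthogonally projected to the tangent space at
#' the consensus.
#'
#' @param data A long landmark tibble (see [read_tps()]).
#' @param sliders A slider tibble from [make_sliders()]/[read_sliders()],
#'   or `NULL`/empty for plain GPA.
#' @param mode Sliding criterion: `"bending"` (minimum bending energy,
#'   default) or `"procrustes"` (minimum Procrustes distance).
#' @param tol Convergence tolerance on consensus displacement.
#' @param max_iter Maximum outer iterations; non-convergence is an error.
#' @param project Project to tangent space after convergence (default TRUE).
#' @return An object of class `gpa_fit` with elements `aligned` (long
#'   tibble), `consensus` (tibble, the arithmetic mean of the aligned
#'   shapes), `centroid_sizes`, `sliding` (per-semi-landmark displacement),
#'   `iterations`, `final_delta`, and `objective` (per-iteration sum of
#'   squared distances to the mean shape).
#' @export
gpa <- function(data, sliders = NULL, mode = c("bending", "procrustes"),
                tol = 1e-8, max_iter = 100, project = TRUE) {
  mode <- match.arg(mode)
  meta <- lmk_meta(data)
  arr <- lmk_array(data)
  n <- dim(arr)[3]
  k <- dim(arr)[1]
  if (n < 2) abort("GPA needs at least 2 configurations")
  if (!is.null(sliders) && nrow(sliders) > 0) {
    sliders <- validate_sliders(sliders, k)
  } else {
    sliders <- NULL
  }
  cs <- numeric(n)
  for (i in seq_len(n)) {
    sc <- center_scale(arr[, , i])
    cs[i] <- attr(sc, "centroid_size")
    arr[, , i] <- sc
  }
  cons <- center_scale(arr[, , 1])
  objective <- numeric(0)
  delta <- Inf
  iter <- 0L
  # phase 1: plain GPA (rotate to consensus, re-estimate) on all landmarks
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      arr[, , i] <- optimal_rotation(arr[, , i], cons)
    }
    mn <- apply(arr, c(1, 2), mean)
    objective <- c(objective, sum(sweep(arr, c(1, 2), mn)^2))
    new_cons <- center_scale(mn)
    delta <- sqrt(sum((new_cons - cons)^2))
    cons <- new_cons
    if (delta < tol) break
  }
  if (delta >= tol) {
    abort(paste0("GPA did not converge after ", max_iter,
                 " iterations (last consensus delta ", format(delta), ")"))
  }
  # phase 2: semi-landmark sliding. The unslid aligned configurations stay
  # the base; each iteration re-derives the slid positions from that base
  # against the current consensus (sliding already-slid coordinates lets
  # semi-landmarks drift along the outline, a near-null direction of the
  # objective, and the consensus never settles). Iterations stop when the
  # Procrustes objective is stationary; a step that worsens it is reverted.
  disp <- NULL
  if (!is.null(sliders)) {
    base <- arr
    s_iter <- 0L
    disp <- array(0, dim = c(nrow(sliders), 2, n))
    q_prev <- Inf
    while (s_iter < max_iter) {
      s_iter <- s_iter + 1L
      prev_state <- list(arr = arr, cons = cons, disp = disp)
      be <- if (mode == "bending") bending_energy_matrix(cons) else NULL
      for (i in seq_len(n)) {
        b <- optimal_rotation(base[, , i], cons)
        base[, , i] <- b
        y <- slide_semilandmarks(b, cons, sliders, mode, be)
        disp[, , i] <- attr(y, "displacement")
        y <- center_scale(y)
        arr[, , i] <- optimal_rotation(y, cons)
      }
      mn <- apply(arr, c(1, 2), mean)
      q <- sum(sweep(arr, c(1, 2), mn)^2)
      new_cons <- center_scale(mn)
      delta <- sqrt(sum((new_cons - cons)^2))
      cons <- new_cons
      if (s_iter > 1 && q > q_prev - tol) {
        if (q > q_prev) {          # revert the worsening step
          arr <- prev_state$arr
          cons <- prev_state$cons
          disp <- prev_state$disp
        } else {
          objective <- c(objective, q)
        }
        break
      }
      objective <- c(objective, q)
      q_prev <- q
    }
    iter <- iter + s_iter
  }
  if (project) {
    cv <- as.vector(cons)
    cv <- cv / sqrt(sum(cv^2))
    for (i in seq_len(n)) {
      yv <- as.vector(arr[, , i])
      yv <- yv - (sum(yv * cv) - 1) * cv
      arr[, , i] <- matrix(yv, ncol = 2)
    }
  }
  # canonical output frame: consensus principal axes along x with a
  # deterministic sign, so results do not depend on the inputs' original
  # orientations (only proper rotations are used)
  mean_shape <- apply(arr, c(1, 2), mean)
  rot <- canonical_rotation(mean_shape)
  for (i in seq_len(n)) arr[, , i] <- arr[, , i] %*% rot
  if (!is.null(disp)) {
    for (i in seq_len(n)) disp[, , i] <- disp[, , i] %*% rot
  }
  mean_shape <- mean_shape %*% rot
  ids <- dimnames(arr)[[3]]
  sliding <- NULL
  if (!is.null(sliders)) {
    sliding <- tibble(
      specimen = rep(ids, each = nrow(sliders)),
      landmark = rep(sliders$slide, times = n),
      dx = as.vector(apply(disp, 3, function(m) m[, 1])),
      dy = as.vector(apply(disp, 3, function(m) m[, 2]))
    ) |>
      mutate(displacement = sqrt(.data$dx^2 + .data$dy^2))
  }
  out <- list(
    aligned = array_lmk(arr, meta),
    consensus = tibble(landmark = seq_len(k),
                       x = mean_shape[, 1], y = mean_shape[, 2]),
    centroid_sizes = tibble(specimen = ids, centroid_size = cs),
    sliding = sliding,
    sliders = sliders,
    mode = if (is.null(sliders)) "none" else mode,
    iterations = iter,
    final_delta = delta,
    objective = objective,
    k = k,
    n = n,
    projected = project
  )
  class(out) <- "gpa_fit"
  out
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes analysis\n")
  cat("  specimens:", x$n, "  landmarks:", x$k, "\n")
  cat("  sliding:", x$mode,
      if (!is.null(x$sliders)) paste0("(", nrow(x$sliders), " semi-landmarks)") else "",
      "\n")
  cat("  iterations:", x$iterations,
      "  final delta:", format(x$final_delta, digits = 3), "\n")
  cat("  Procrustes sum of squares:",
      format(tail(x$objective, 1), digits = 6), "\n")
  invisible(x)
}

#' @describeIn gpa Aligned coordinates as a tibble.
#' @param x A `gpa_fit` object.
#' @param ... Unused.
#' @export
tidy.gpa_fit <- function(x, ...) {
  x$aligned
}

#' @describeIn gpa One-row model summary.
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble(n = x$n, k = x$k, mode = x$mode, iterations = x$iterations,
         final_delta = x$final_delta,
         procrustes_ss = tail(x$objective, 1))
}
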