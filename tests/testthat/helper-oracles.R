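# Independent oracles and fixture builders. These deliberately use
# different algorithms from the package internals (complex closed forms,
# brute-force enumeration) so that agreement is evidence, not tautology.

# closed-form two-shape partial Procrustes distance via complex inner
# product: d = sqrt(2 - 2|<a, b>|) for centered unit-size shapes
oracle_procrustes_distance <- function(a, b) {
  norm_shape <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm_shape(as.matrix(a)); b <- norm_shape(as.matrix(b))
  za <- complex(real = a[, 1], imaginary = a[, 2])
  zb <- complex(real = b[, 1], imaginary = b[, 2])
  sqrt(max(0, 2 - 2 * Mod(sum(za * Conj(zb)))))
}

# independent plain GPA: SVD (Kabsch) rotations, align-to-mean iteration
oracle_plain_gpa <- function(arr, tol = 1e-10, max_iter = 200) {
  n <- dim(arr)[3]
  for (i in seq_len(n)) {
    m <- arr[, , i]
    m <- sweep(m, 2, colMeans(m))
    arr[, , i] <- m / sqrt(sum(m^2))
  }
  kabsch <- function(s, r) {
    sv <- svd(t(s) %*% r)
    d <- sign(det(sv$v %*% t(sv$u)))
    q <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
    s %*% q
  }
  ref <- arr[, , 1]
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) arr[, , i] <- kabsch(arr[, , i], ref)
    mn <- apply(arr, c(1, 2), mean)
    mn <- mn / sqrt(sum(mn^2))
    if (sqrt(sum((mn - ref)^2)) < tol) break
    ref <- mn
  }
  list(aligned = arr, consensus = apply(arr, c(1, 2), mean))
}

# rigid-motion helper: counter-clockwise rotation of row-vector points
rotate_pts <- function(m, degrees) {
  a <- degrees * pi / 180
  as.matrix(m) %*% matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
}

# simple landmark tibble from a K x 2 x n array
arr_to_tbl <- function(arr, ids = paste0("s", seq_len(dim(arr)[3]))) {
  k <- dim(arr)[1]
  tibble::tibble(
    specimen = rep(ids, each = k),
    landmark = rep(seq_len(k), times = length(ids)),
    x = as.vector(apply(arr, 3, function(m) m[, 1])),
    y = as.vector(apply(arr, 3, function(m) m[, 2]))
  )
}

# ---- parsimony oracles -------------------------------------------------

# all unrooted binary topologies over n leaves, as internal edge matrices
# (leaves 1..n, internal ids > n); n = 6 gives 105
enumerate_topologies <- function(n) {
  trees <- list(cbind(c(1L, 2L, 3L), rep(n + 1L, 3L)))
  for (leaf in seq_len(n)[-(1:3)]) {
    nxt <- list()
    for (e in trees) {
      w <- max(e) + 1L
      for (i in seq_len(nrow(e))) {
        nxt[[length(nxt) + 1L]] <-
          rbind(e[-i, , drop = FALSE], c(e[i, 1], w), c(w, e[i, 2]), c(w, leaf))
      }
    }
    trees <- nxt
  }
  trees
}

# brute-force character length: enumerate all internal-node state
# assignments; leaf edges cost the minimum over the leaf's allowed states.
# `leaf_sets` is a list of integer state vectors (missing = all states).
brute_force_char_length <- function(edges, ntip, leaf_sets, ordered,
                                    max_state) {
  internals <- sort(unique(as.vector(edges[edges > ntip])))
  states <- 0:max_state
  grid <- do.call(expand.grid, rep(list(states), length(internals)))
  cost_pair <- function(s1, s2) if (ordered) abs(s1 - s2) else as.integer(s1 != s2)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    asg <- as.integer(grid[g, ])
    names(asg) <- internals
    total <- 0
    for (r in seq_len(nrow(edges))) {
      u <- edges[r, 1]; v <- edges[r, 2]
      su <- if (u <= ntip) NA else asg[as.character(u)]
      sv <- if (v <= ntip) NA else asg[as.character(v)]
      if (!is.na(su) && !is.na(sv)) {
        total <- total + cost_pair(su, sv)
      } else {
        leaf <- if (u <= ntip) u else v
        internal_state <- if (u <= ntip) sv else su
        total <- total + min(vapply(leaf_sets[[leaf]], cost_pair,
                                    numeric(1), s2 = internal_state))
      }
      if (total >= best) break
    }
    best <- min(best, total)
  }
  best
}

# random character matrix (with optional missing/polymorphic cells) plus
# its list-of-state-sets form for the brute-force oracle
random_char_column <- function(ntip, max_state, p_missing = 0.15,
                               p_poly = 0.15) {
  sets <- vector("list", ntip)
  cells <- character(ntip)
  for (i in seq_len(ntip)) {
    u <- stats::runif(1)
    if (u < p_missing) {
      sets[[i]] <- 0:max_state
      cells[i] <- NA_character_
    } else if (u < p_missing + p_poly) {
      ss <- sort(sample(0:max_state, 2))
      sets[[i]] <- ss
      cells[i] <- paste(ss, collapse = "")
    } else {
      s <- sample(0:max_state, 1)
      sets[[i]] <- s
      cells[i] <- as.character(s)
    }
  }
  list(sets = sets, cells = cells)
}

edges_phylo <- function(e, ntip) {
  clawmorph:::edges_to_phylo(e, paste0("t", seq_len(ntip)))
}

toy_matrix <- function(cells, taxa = paste0("t", seq_len(nrow(cells))), ...) {
  character_matrix(cells, taxa, ...)
}
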