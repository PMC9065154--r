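# Maximum-parsimony engine for discrete morphological characters.
#
# Unordered characters are optimized with Fitch set operations on state
# bitmasks; additive (ordered) characters with Farris minimal-cost
# intervals. Polymorphic cells have any-of semantics; missing cells accept
# every observed state. Trees with polytomies (e.g. consensus trees, or
# zero-length-branch collapse tests) are scored exactly with a Sankoff
# dynamic program. All scoring is vectorized across characters.

BIG_COST <- 1e9

# precompute leaf-level structures for scoring
prep_matrix <- function(cm) {
  act <- cm$active
  obs <- integer(cm$nchar)
  for (j in seq_len(cm$nchar)) {
    obs[j] <- Reduce(bitwOr, cm$mask[, j], accumulate = FALSE)
  }
  mask_range <- function(lo, hi) {
    bitwShiftL(1L, hi + 1L) - bitwShiftL(1L, lo)
  }
  leafmask <- cm$mask
  lo <- cm$lo
  hi <- cm$hi
  for (j in seq_len(cm$nchar)) {
    miss <- leafmask[, j] == 0L
    if (obs[j] == 0L) {           # all-missing character: single dummy state
      leafmask[miss, j] <- 1L
      lo[miss, j] <- 0L; hi[miss, j] <- 0L
    } else if (cm$ordered[j]) {
      # ordered: a missing cell accepts the whole observed state interval
      rlo <- min(cm$lo[, j], na.rm = TRUE)
      rhi <- max(cm$hi[, j], na.rm = TRUE)
      leafmask[miss, j] <- mask_range(rlo, rhi)
      lo[miss, j] <- rlo
      hi[miss, j] <- rhi
    } else {
      leafmask[miss, j] <- obs[j]
      lo[miss, j] <- min(cm$lo[, j], na.rm = TRUE)
      hi[miss, j] <- max(cm$hi[, j], na.rm = TRUE)
    }
  }
  uno <- which(act & !cm$ordered)
  ord <- which(act & cm$ordered)
  # the Farris interval pass is exact only when every cell's state set is
  # contiguous; ordered characters with gapped polymorphic sets (any-of
  # semantics) are scored with the exact Sankoff program instead
  gapped <- vapply(seq_len(cm$nchar), function(j) {
    if (!cm$ordered[j]) return(FALSE)
    cells <- which(cm$mask[, j] != 0L)
    !all(leafmask[cells, j] == mask_range(lo[cells, j], hi[cells, j]))
  }, logical(1))
  list(cm = cm, uno = uno,
       ord = ord[!gapped[ord]], ord_gap = ord[gapped[ord]], gapped = gapped,
       leafmask = leafmask, lo = lo, hi = hi, obs = obs,
       weights = cm$weights, ntax = cm$ntax)
}

# per-character lengths on a binary tree (internal edge matrix)
fitch_farris_lengths <- function(e, prep, chars_uno, chars_ord) {
  tr <- tree_traversal(e)
  maxid <- length(tr$adj)
  out_u <- integer(length(chars_uno))
  out_o <- integer(length(chars_ord))
  if (length(chars_uno) > 0) {
    msk <- matrix(0L, maxid, length(chars_uno))
    msk[seq_len(prep$ntax), ] <- prep$leafmask[, chars_uno, drop = FALSE]
    for (i in seq_along(tr$post)) {
      v <- tr$post[i]
      kd <- tr$kids[[i]]
      m1 <- msk[kd[1], ]; m2 <- msk[kd[2], ]
      iv <- bitwAnd(m1, m2)
      z <- iv == 0L
      msk[v, ] <- ifelse(z, bitwOr(m1, m2), iv)
      out_u <- out_u + z
    }
    out_u <- out_u + (bitwAnd(msk[tr$root, ], msk[tr$root_leaf, ]) == 0L)
  }
  if (length(chars_ord) > 0) {
    lo <- matrix(0L, maxid, length(chars_ord))
    hi <- lo
    lo[seq_len(prep$ntax), ] <- prep$lo[, chars_ord, drop = FALSE]
    hi[seq_len(prep$ntax), ] <- prep$hi[, chars_ord, drop = FALSE]
    for (i in seq_along(tr$post)) {
      v <- tr$post[i]
      kd <- tr$kids[[i]]
      nl <- pmax(lo[kd[1], ], lo[kd[2], ])
      nh <- pmin(hi[kd[1], ], hi[kd[2], ])
      out_o <- out_o + pmax(0L, nl - nh)
      lo[v, ] <- pmin(nl, nh)
      hi[v, ] <- pmax(nl, nh)
    }
    nl <- pmax(lo[tr$root, ], lo[tr$root_leaf, ])
    nh <- pmin(hi[tr$root, ], hi[tr$root_leaf, ])
    out_o <- out_o + pmax(0L, nl - nh)
  }
  list(uno = out_u, ord = out_o)
}

# exact Sankoff lengths; handles polytomies. Characters split by type.
sankoff_lengths <- function(e, prep, chars_uno, chars_ord) {
  tr <- tree_traversal(e)
  smax <- max(1L, prep$hi[is.finite(prep$hi)], na.rm = TRUE)
  ns <- smax + 1L
  score_group <- function(chars, ordered) {
    if (length(chars) == 0) return(integer(0))
    ncc <- length(chars)
    leafcost <- function(leaf) {
      cst <- matrix(BIG_COST, ns, ncc)
      mk <- prep$leafmask[leaf, chars]
      for (s in 0:smax) {
        allowed <- bitwAnd(mk, bitwShiftL(1L, s)) != 0L
        cst[s + 1L, allowed] <- 0
      }
      cst
    }
    contribution <- function(cst) {
      if (ordered) {
        if (ns > 1) {
          for (s in 2:ns) cst[s, ] <- pmin(cst[s, ], cst[s - 1L, ] + 1)
          for (s in (ns - 1L):1L) cst[s, ] <- pmin(cst[s, ], cst[s + 1L, ] + 1)
        }
        cst
      } else {
        mins <- Reduce(pmin, asplit(cst, 1))
        pmin(cst, matrix(mins + 1, ns, ncc, byrow = TRUE))
      }
    }
    costs <- vector("list", length(tr$adj))
    for (lf in seq_len(prep$ntax)) costs[[lf]] <- leafcost(lf)
    for (i in seq_along(tr$post)) {
      v <- tr$post[i]
      tot <- 0
      for (w in tr$kids[[i]]) tot <- tot + contribution(costs[[w]])
      costs[[v]] <- tot
    }
    final <- costs[[tr$root]] + contribution(costs[[tr$root_leaf]])
    as.integer(round(Reduce(pmin, asplit(final, 1))))
  }
  list(uno = score_group(chars_uno, FALSE),
       ord = score_group(chars_ord, TRUE))
}

is_binary_edges <- function(e, ntip) {
  ids <- as.vector(e)
  deg <- table(ids)
  internal <- as.integer(names(deg)) > ntip
  all(deg[internal] == 3) && all(deg[!internal] == 1)
}

char_lengths_any <- function(e, prep) {
  binary <- is_binary_edges(e, prep$ntax)
  len <- numeric(prep$cm$nchar)
  if (binary) {
    res <- fitch_farris_lengths(e, prep, prep$uno, prep$ord)
    len[prep$uno] <- res$uno
    len[prep$ord] <- res$ord
    if (length(prep$ord_gap) > 0) {
      len[prep$ord_gap] <- sankoff_lengths(e, prep, integer(0),
                                           prep$ord_gap)$ord
    }
  } else {
    res <- sankoff_lengths(e, prep, prep$uno, c(prep$ord, prep$ord_gap))
    len[prep$uno] <- res$uno
    len[c(prep$ord, prep$ord_gap)] <- res$ord
  }
  len
}

# minimum possible steps per character (best case over all trees)
char_min_steps <- function(prep) {
  cm <- prep$cm
  out <- numeric(cm$nchar)
  for (j in seq_len(cm$nchar)) {
    cells <- cm$mask[cm$mask[, j] != 0L, j]
    if (length(cells) == 0) { out[j] <- 0; next }
    if (cm$ordered[j]) {
      out[j] <- max(0L, max(cm$lo[, j], na.rm = TRUE) -
                      min(cm$hi[, j], na.rm = TRUE))
    } else {
      states <- which(bitwAnd(Reduce(bitwOr, cells),
                              bitwShiftL(1L, 0:30)) != 0L) - 1L
      if (length(states) <= 1) { out[j] <- 0; next }
      found <- NA_integer_
      for (size in seq_along(states)) {
        for (sub in utils::combn(states, size, simplify = FALSE)) {
          mk <- sum(bitwShiftL(1L, sub))
          if (all(bitwAnd(cells, mk) != 0L)) { found <- size; break }
        }
        if (!is.na(found)) break
      }
      out[j] <- found - 1L
    }
  }
  out
}

# maximum steps per character (star tree / complete homoplasy bound)
char_max_steps <- function(prep) {
  cm <- prep$cm
  out <- numeric(cm$nchar)
  for (j in seq_len(cm$nchar)) {
    nonmiss <- which(cm$mask[, j] != 0L)
    if (length(nonmiss) == 0) { out[j] <- 0; next }
    if (cm$ordered[j]) {
      smax <- max(cm$hi[, j], na.rm = TRUE)
      # exact any-of distance: min over a cell's member states
      cell_states <- lapply(nonmiss, function(i) {
        which(bitwAnd(cm$mask[i, j], bitwShiftL(1L, 0:30)) != 0L) - 1L
      })
      best <- Inf
      for (s in 0:smax) {
        d <- vapply(cell_states, function(st) min(abs(st - s)), numeric(1))
        best <- min(best, sum(d))
      }
      out[j] <- best
    } else {
      counts <- vapply(0:30, function(s) {
        sum(bitwAnd(cm$mask[nonmiss, j], bitwShiftL(1L, s)) != 0L)
      }, 1L)
      out[j] <- length(nonmiss) - max(counts)
    }
  }
  out
}

#' Minimum state changes of single characters on a tree
#'
#' Fitch set optimization for unordered characters, Farris minimal-cost
#' intervals for additive ones; missing cells accept any observed state
#' and polymorphic cells any of their members. Exact on binary trees and,
#' via a Sankoff dynamic program, on trees with polytomies.
#'
#' @param tree An ape `phylo` (unrooted) whose tips are the matrix taxa.
#' @param cm A `character_matrix`.
#' @param chars 1-based character indices (default: all active characters).
#' @return Integer vector of per-character minimum change counts.
#' @export
character_length <- function(tree, cm, chars = NULL) {
  prep <- prep_matrix(cm)
  if (!is.null(chars)) {
    if (any(chars < 1 | chars > cm$nchar)) abort("character index out of range")
    prep$uno <- intersect(chars, which(!cm$ordered))
    ord_all <- intersect(chars, which(cm$ordered))
    prep$ord <- ord_all[!prep$gapped[ord_all]]
    prep$ord_gap <- ord_all[prep$gapped[ord_all]]
  }
  e <- as_internal_tree(tree, cm$taxa)
  len <- char_lengths_any(e, prep)
  idx <- if (is.null(chars)) which(cm$active) else chars
  as.integer(len[idx])
}

#' Parsimony score of a tree
#'
#' Tree length (weighted sum of character changes over active characters)
#' with the ensemble consistency and retention indices. `M` is the summed
#' per-character minimum (achievable on some tree), `G` the summed star-tree
#' maximum, `CI = M/S` and `RI = (G - S)/(G - M)`. Uninformative characters
#' are included in the sums; an all-invariant matrix (S = 0) reports
#' `CI = 1` by convention, flagged with `ci_defined = FALSE`.
#'
#' @param tree An ape `phylo` over the matrix taxa.
#' @param cm A `character_matrix`.
#' @return Object of class `parsimony_score`: `S`, `M`, `G`, `CI`, `RI`,
#'   `ci_defined`, and a `per_character` tibble.
#' @export
tree_length <- function(tree, cm) {
  prep <- prep_matrix(cm)
  e <- as_internal_tree(tree, cm$taxa)
  len <- char_lengths_any(e, prep)
  act <- which(cm$active)
  w <- cm$weights
  s <- sum(len[act] * w[act])
  m <- char_min_steps(prep)
  g <- char_max_steps(prep)
  ms <- sum(m[act] * w[act])
  gs <- sum(g[act] * w[act])
  out <- list(
    S = s,
    M = ms,
    G = gs,
    CI = if (s > 0) ms / s else 1,
    RI = if (gs > ms) (gs - s) / (gs - ms) else 1,
    ci_defined = s > 0,
    per_character = tibble(character = act, length = len[act],
                           min_steps = m[act], max_steps = g[act],
                           ordered = cm$ordered[act], weight = w[act])
  )
  class(out) <- "parsimony_score"
  out
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat("Parsimony score\n")
  cat(sprintf("  length S = %g (min M = %g, max G = %g)\n", x$S, x$M, x$G))
  cat(sprintf("  CI = %.3f%s  RI = %.3f\n", x$CI,
              if (!x$ci_defined) " (S = 0; by convention)" else "", x$RI))
  invisible(x)
}

#' @describeIn tree_length One-row tibble of the ensemble statistics.
#' @param x A `parsimony_score`.
#' @param ... Unused.
#' @export
glance.parsimony_score <- function(x, ...) {
  tibble(S = x$S, M = x$M, G = x$G, CI = x$CI, RI = x$RI,
         ci_defined = x$ci_defined)
}

# total weighted length of an internal edge tree (search hot path)
score_edges <- function(e, prep) {
  len <- char_lengths_any(e, prep)
  act <- c(prep$uno, prep$ord, prep$ord_gap)
  sum(len[act] * prep$weights[act])
}

wagner_build_edges <- function(prep, addition_order) {
  ntax <- prep$ntax
  ord <- addition_order
  e <- tree3(ord[1:3], ntax)
  next_id <- ntax + 2L
  if (ntax == 3) return(e)
  for (t in ord[4:ntax]) {
    best <- Inf
    best_edges <- list()
    for (i in seq_len(nrow(e))) {
      w <- next_id
      cand <- rbind(e[-i, , drop = FALSE],
                    c(e[i, 1], w), c(w, e[i, 2]), c(w, t))
      s <- score_edges(cand, prep)
      if (s < best - 1e-9) {
        best <- s
        best_edges <- list(cand)
      } else if (s < best + 1e-9) {
        best_edges <- c(best_edges, list(cand))
      }
    }
    pick <- if (length(best_edges) > 1) {
      sample.int(length(best_edges), 1)
    } else 1L
    e <- best_edges[[pick]]
    next_id <- next_id + 1L
  }
  e
}

#' Wagner stepwise-addition starting tree
#'
#' Builds a binary unrooted tree by adding taxa one at a time on the branch
#' that minimizes total tree length; ties are broken uniformly at random
#' (seed the session RNG for reproducibility).
#'
#' @param cm A `character_matrix`.
#' @param addition_order Taxon indices or names; default a random
#'   permutation.
#' @param seed Optional integer seed for the tie-breaking RNG.
#' @return An ape `phylo`.
#' @export
wagner_build <- function(cm, addition_order = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cm$ntax < 3) abort("Wagner build needs at least 3 taxa")
  prep <- prep_matrix(cm)
  if (is.null(addition_order)) {
    addition_order <- sample.int(cm$ntax)
  } else if (is.character(addition_order)) {
    addition_order <- match(addition_order, cm$taxa)
    if (anyNA(addition_order)) abort("unknown taxon in addition_order")
  }
  if (!setequal(addition_order, seq_len(cm$ntax))) {
    abort("addition_order must be a permutation of all taxa")
  }
  edges_to_phylo(wagner_build_edges(prep, addition_order), cm$taxa)
}

#' Heuristic parsimony search with branch swapping
#'
#' Random-addition Wagner starting trees refined by hill-climbing branch
#' swapping (TBR, SPR, or NNI neighborhoods), holding up to `hold` distinct
#' equally parsimonious trees per replicate; results are pooled and
#' deduplicated across replicates.
#'
#' @param cm A `character_matrix`.
#' @param replicates Number of random-addition replicates.
#' @param strategy `"tbr"` (default), `"spr"`, or `"nni"`.
#' @param hold Maximum trees retained per replicate.
#' @param max_rounds Safety cap on swapping rounds per replicate.
#' @param seed Optional integer seed (all randomness funnels through the
#'   session RNG).
#' @param start_trees Optional list of `phylo` starting trees (recycled
#'   across replicates) instead of Wagner builds.
#' @return Object of class `parsimony_search`: `trees` (list of `phylo`
#'   at the best length found), `best_length`, `score` (a
#'   [tree_length()] result), `replicates`, `strategy`.
#' @export
branch_swap_search <- function(cm, replicates = 10,
                               strategy = c("tbr", "spr", "nni"),
                               hold = 10, max_rounds = 100, seed = NULL,
                               start_trees = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  if (cm$ntax < 4) {
    tr <- edges_to_phylo(tree3(1:3, cm$ntax), cm$taxa)
    sc <- tree_length(tr, cm)
    out <- list(trees = list(tr), best_length = sc$S, score = sc,
                replicates = replicates, strategy = strategy)
    class(out) <- "parsimony_search"
    return(out)
  }
  prep <- prep_matrix(cm)
  pool <- list()
  pool_sigs <- character(0)
  pool_len <- Inf
  for (rep_i in seq_len(replicates)) {
    e <- if (is.null(start_trees)) {
      wagner_build_edges(prep, sample.int(cm$ntax))
    } else {
      as_internal_tree(start_trees[[(rep_i - 1L) %% length(start_trees) + 1L]],
                       cm$taxa)
    }
    best_len <- score_edges(e, prep)
    current <- list(e)
    sigs <- tree_signature(e, cm$ntax)
    for (round_i in seq_len(max_rounds)) {
      improved <- FALSE
      added <- FALSE
      nb_all <- list()
      for (tr in current) {
        nb_all <- c(nb_all, neighborhood_moves(tr, cm$ntax, strategy))
      }
      if (length(nb_all) == 0) break
      lens <- vapply(nb_all, score_edges, numeric(1), prep = prep)
      mn <- min(lens)
      if (mn < best_len - 1e-9) {
        best_len <- mn
        cand <- nb_all[lens < mn + 1e-9]
        csig <- vapply(cand, tree_signature, character(1), ntip = cm$ntax)
        keep <- !duplicated(csig)
        cand <- cand[keep]; csig <- csig[keep]
        if (length(cand) > hold) {
          pick <- sample.int(length(cand), hold)
          cand <- cand[pick]; csig <- csig[pick]
        }
        current <- cand
        sigs <- csig
        improved <- TRUE
      } else if (length(current) < hold) {
        eq <- which(lens < best_len + 1e-9)
        for (ix in eq) {
          if (length(current) >= hold) break
          sg <- tree_signature(nb_all[[ix]], cm$ntax)
          if (!sg %in% sigs) {
            current <- c(current, nb_all[ix])
            sigs <- c(sigs, sg)
            added <- TRUE
          }
        }
      }
      if (!improved && !added) break
    }
    if (best_len < pool_len - 1e-9) {
      pool <- current
      pool_sigs <- sigs
      pool_len <- best_len
    } else if (best_len < pool_len + 1e-9) {
      new <- !sigs %in% pool_sigs
      pool <- c(pool, current[new])
      pool_sigs <- c(pool_sigs, sigs[new])
    }
  }
  trees <- lapply(pool, edges_to_phylo, labels = cm$taxa)
  sc <- tree_length(trees[[1]], cm)
  out <- list(trees = trees, best_length = pool_len, score = sc,
              replicates = replicates, strategy = strategy)
  class(out) <- "parsimony_search"
  out
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("Heuristic parsimony search (", toupper(x$strategy), ", ",
      x$replicates, " replicates)\n", sep = "")
  cat("  best length:", x$best_length, " trees retained:", length(x$trees), "\n")
  cat(sprintf("  CI = %.3f  RI = %.3f\n", x$score$CI, x$score$RI))
  invisible(x)
}

#' @describeIn branch_swap_search One-row summary of the search.
#' @param x A `parsimony_search`.
#' @param ... Unused.
#' @export
glance.parsimony_search <- function(x, ...) {
  tibble(best_length = x$best_length, n_trees = length(x$trees),
         CI = x$score$CI, RI = x$score$RI,
         replicates = x$replicates, strategy = x$strategy)
}

check_same_leaves <- function(trees) {
  if (length(trees) == 0) abort("need at least one tree")
  taxa <- trees[[1]]$tip.label
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa)) abort("trees have different leaf sets")
  }
  taxa
}

consensus_splits <- function(trees, taxa) {
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    e <- phylo_to_edges(tr, taxa)
    for (sp in unique(tree_splits(e, length(taxa)))) {
      assign(sp, (get0(sp, envir = counts) %||% 0L) + 1L, envir = counts)
    }
  }
  keys <- ls(counts)
  tibble(split = keys,
         count = vapply(keys, get, 1L, envir = counts))
}

#' Strict consensus tree
#'
#' Retains exactly the bipartitions present in every input tree.
#'
#' @param trees A list of ape `phylo` trees (or a `parsimony_search`) on
#'   one leaf set.
#' @return An ape `phylo` (possibly with polytomies).
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "parsimony_search")) trees <- trees$trees
  taxa <- check_same_leaves(trees)
  sp <- consensus_splits(trees, taxa)
  keep <- sp$split[sp$count == length(trees)]
  clades <- lapply(strsplit(keep, ","), as.integer)
  clades_to_phylo(clades, length(taxa), taxa)
}

#' Majority-rule consensus tree
#'
#' Retains bipartitions occurring in strictly more than `threshold` of the
#' input trees (so a clade in exactly half of an even set is excluded) and
#' annotates each retained clade with its frequency as a node label.
#'
#' @inheritParams strict_consensus
#' @param threshold Frequency threshold (default 0.5 for the 50%
#'   majority-rule tree; must be >= 0.5 so retained clades are mutually
#'   compatible).
#' @return An ape `phylo` with `node.label` frequencies.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "parsimony_search")) trees <- trees$trees
  if (threshold < 0.5) abort("threshold below 0.5 can retain incompatible clades")
  taxa <- check_same_leaves(trees)
  sp <- consensus_splits(trees, taxa)
  freq <- sp$count / length(trees)
  keep <- freq > threshold
  clades <- lapply(strsplit(sp$split[keep], ","), as.integer)
  clades_to_phylo(clades, length(taxa), taxa, freqs = freq[keep])
}

#' Collapse branches of zero minimum length
#'
#' Contracts every internal branch whose contraction leaves the tree
#' length unchanged — branches that can have zero changes under at least
#' one most-parsimonious reconstruction. This is the usual convention
#' before counting distinct most-parsimonious trees; the resulting count
#' is convention-dependent.
#'
#' @param tree An ape `phylo`.
#' @param cm The `character_matrix` the tree is scored against.
#' @return An ape `phylo`, possibly with polytomies.
#' @export
collapse_zero_branches <- function(tree, cm) {
  prep <- prep_matrix(cm)
  e <- as_internal_tree(tree, cm$taxa)
  s0 <- score_edges(e, prep)
  ntip <- cm$ntax
  drop <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    if (e[i, 1] <= ntip || e[i, 2] <= ntip) next
    e2 <- e[-i, , drop = FALSE]
    e2[e2 == e[i, 2]] <- e[i, 1]
    if (score_edges(e2, prep) <= s0 + 1e-9) drop[i] <- TRUE
  }
  if (any(drop)) {
    for (i in which(drop)) {
      a <- e[i, 1]; b <- e[i, 2]
      if (a == b) next
      e[e == b] <- a
    }
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
  }
  edges_to_phylo(e, cm$taxa)
}
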