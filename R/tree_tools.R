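# Internal unrooted-tree toolkit for the parsimony engine.
#
# A tree over ntip taxa is an integer edge matrix E (two columns); leaves
# are 1..ntip, internal nodes carry arbitrary labels > ntip. Scoring and
# clade extraction root the tree at leaf 1. ape `phylo` objects are the
# user-facing currency; conversion happens at the module boundary.

# star tree / unique 3-taxon tree helpers
tree3 <- function(tips, ntip) {
  cbind(c(tips[1], tips[2], tips[3]), rep(ntip + 1L, 3))
}

# adjacency list keyed by node id (named list is too slow; use max-id vector
# indexing). Returns list(adj = list of integer vectors indexed by node id,
# nodes = sorted node ids)
edge_adjacency <- function(e) {
  maxid <- max(e)
  adj <- vector("list", maxid)
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1]; b <- e[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Rooted traversal at leaf 1. Returns postorder internal node list with
# children, suitable for vectorized Fitch/Farris passes.
# list(post = integer vector of internal node ids in postorder,
#      kids = 2-column matrix of their children ids,
#      root = internal node adjacent to leaf 1)
tree_traversal <- function(e, root_leaf = NULL) {
  adj <- edge_adjacency(e)
  if (is.null(root_leaf) || root_leaf > length(adj) ||
      is.null(adj[[root_leaf]])) {
    # smallest present leaf (degree-1 node)
    root_leaf <- which(lengths(adj) == 1L)[1]
  }
  root <- adj[[root_leaf]][1]
  maxid <- length(adj)
  parent <- integer(maxid)
  order_stack <- integer(0)
  stack <- root
  parent[root] <- root_leaf
  preorder <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    preorder <- c(preorder, v)
    for (w in adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        if (length(adj[[w]]) > 1) stack <- c(stack, w) else preorder <- c(preorder, w)
      }
    }
  }
  internal <- preorder[vapply(preorder, function(v) length(adj[[v]]) > 1, TRUE)]
  post <- rev(internal)
  kids <- lapply(post, function(v) setdiff(adj[[v]], parent[v]))
  list(post = post, kids = kids, root = root, root_leaf = root_leaf,
       parent = parent, adj = adj)
}

# splits (bipartitions) of an unrooted tree as canonical strings: each split
# is the leaf set on the side not containing leaf 1, sorted, comma-joined.
# Only informative splits (size 2..ntip-2) are returned.
tree_splits <- function(e, ntip) {
  tr <- tree_traversal(e)
  maxid <- length(tr$adj)
  leafsets <- vector("list", maxid)
  for (v in seq_len(min(ntip, maxid))) leafsets[[v]] <- v
  for (i in seq_along(tr$post)) {
    v <- tr$post[i]
    leafsets[[v]] <- sort(unlist(leafsets[tr$kids[[i]]]))
  }
  keep <- tr$post[tr$post != tr$root]
  sets <- leafsets[keep]
  sets <- sets[vapply(sets, function(s) length(s) >= 2 && length(s) <= ntip - 2, TRUE)]
  vapply(sets, paste, character(1), collapse = ",")
}

tree_signature <- function(e, ntip) {
  paste(sort(tree_splits(e, ntip)), collapse = ";")
}

# convert internal edge matrix -> ape phylo (unrooted, binary or not)
edges_to_phylo <- function(e, labels) {
  ntip <- length(labels)
  tr <- tree_traversal(e)
  internal_ids <- unique(c(tr$root, tr$post))
  # ape numbering: tips 1..ntip, internals ntip+1.. in preorder from root
  pre_internal <- rev(tr$post)            # post was reverse preorder of internals
  ape_id <- integer(length(tr$adj))
  ape_id[seq_len(ntip)] <- seq_len(ntip)
  nxt <- ntip + 1L
  for (v in pre_internal) {
    ape_id[v] <- nxt
    nxt <- nxt + 1L
  }
  edges <- matrix(0L, nrow = nrow(e), ncol = 2)
  r <- 1L
  # root edge to the root leaf plus parent->child edges from traversal
  edges[r, ] <- c(ape_id[tr$root], tr$root_leaf); r <- r + 1L
  for (i in rev(seq_along(tr$post))) {   # preorder for tidy edge ordering
    v <- tr$post[i]
    for (w in tr$kids[[i]]) {
      edges[r, ] <- c(ape_id[v], ape_id[w])
      r <- r + 1L
    }
  }
  phy <- list(edge = edges, tip.label = labels,
              Nnode = length(pre_internal))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

# ape phylo -> internal edge matrix, with leaves renumbered to match `taxa`
phylo_to_edges <- function(phy, taxa) {
  ntip <- length(phy$tip.label)
  if (length(taxa) != ntip || !setequal(phy$tip.label, taxa)) {
    abort("tree leaves do not match the taxon set")
  }
  leaf_map <- match(phy$tip.label, taxa)
  e <- phy$edge
  out <- matrix(0L, nrow(e), 2)
  for (col in 1:2) {
    v <- e[, col]
    is_tip <- v <= ntip
    out[is_tip, col] <- leaf_map[v[is_tip]]
    out[!is_tip, col] <- as.integer(v[!is_tip])  # internals already > ntip
  }
  # splice degree-2 internal nodes (e.g. ape's rooted-binary root) so the
  # tree is genuinely unrooted
  repeat {
    deg <- table(out)
    two <- as.integer(names(deg)[deg == 2 & as.integer(names(deg)) > ntip])
    if (length(two) == 0) break
    out <- splice_degree2(out, two[1])
  }
  out
}

as_internal_tree <- function(tree, taxa) {
  if (inherits(tree, "phylo")) phylo_to_edges(tree, taxa) else tree
}

# delete edge `ei`, splice resulting degree-2 vertices, return the two
# component edge matrices plus their node sets
bisect_tree <- function(e, ei) {
  u <- e[ei, 1]; v <- e[ei, 2]
  e2 <- e[-ei, , drop = FALSE]
  # component membership by BFS over remaining edges
  comp_of <- function(start) {
    seen <- start
    frontier <- start
    while (length(frontier) > 0) {
      hit <- e2[, 1] %in% frontier | e2[, 2] %in% frontier
      nodes <- unique(as.vector(e2[hit, , drop = FALSE]))
      frontier <- setdiff(nodes, seen)
      seen <- union(seen, frontier)
    }
    seen
  }
  nodes_u <- comp_of(u)
  in_u <- (e2[, 1] %in% nodes_u)
  eu <- e2[in_u, , drop = FALSE]
  ev <- e2[!in_u, , drop = FALSE]
  list(eu = splice_degree2(eu, u), ev = splice_degree2(ev, v),
       nodes_u = nodes_u)
}

# if `node` has degree 2 in component `e`, remove it and join its neighbors
splice_degree2 <- function(e, node) {
  if (nrow(e) == 0) return(e)
  hits <- which(e[, 1] == node | e[, 2] == node)
  if (length(hits) != 2) return(e)
  nb <- c(e[hits[1], ], e[hits[2], ])
  nb <- nb[nb != node]
  e <- e[-hits, , drop = FALSE]
  rbind(e, nb)
}

# attach the component `e_other` (attachment point `ap`: a node id if the
# component is a single node, otherwise an edge row index) to edge `ei` of
# `e_main`, using fresh internal ids
reconnect_trees <- function(e_main, ei, e_other, ap_edge, next_id) {
  a <- e_main[ei, 1]; b <- e_main[ei, 2]
  w <- next_id
  e_main <- e_main[-ei, , drop = FALSE]
  if (is.null(ap_edge$edge)) {
    # other side is a single node (leaf) or we attach at a node directly
    rbind(e_main, c(a, w), c(w, b), c(w, ap_edge$node),
          if (nrow(e_other) > 0) e_other)
  } else {
    x <- next_id + 1L
    c1 <- e_other[ap_edge$edge, 1]; c2 <- e_other[ap_edge$edge, 2]
    e_other <- e_other[-ap_edge$edge, , drop = FALSE]
    rbind(e_main, c(a, w), c(w, b), c(w, x), c(c1, x), c(x, c2), e_other)
  }
}

# all NNI rearrangements of a binary unrooted tree
nni_moves <- function(e, ntip) {
  adj <- edge_adjacency(e)
  out <- list()
  for (i in seq_len(nrow(e))) {
    u <- e[i, 1]; v <- e[i, 2]
    if (u <= ntip || v <= ntip) next
    nu <- setdiff(adj[[u]], v)
    nv <- setdiff(adj[[v]], u)
    for (swap in 1:2) {
      a <- nu[2]; c <- nv[swap]
      e2 <- e
      # replace edges (u,a) and (v,c) with (u,c) and (v,a)
      for (r in seq_len(nrow(e2))) {
        if ((e2[r, 1] == u && e2[r, 2] == a) || (e2[r, 1] == a && e2[r, 2] == u)) {
          e2[r, ] <- c(u, c)
        } else if ((e2[r, 1] == v && e2[r, 2] == c) || (e2[r, 1] == c && e2[r, 2] == v)) {
          e2[r, ] <- c(v, a)
        }
      }
      out[[length(out) + 1L]] <- e2
    }
  }
  out
}

# all SPR rearrangements: prune each directed subtree, regraft on every
# edge of the remaining tree
spr_moves <- function(e, ntip) {
  out <- list()
  next_id <- max(e) + 1L
  for (i in seq_len(nrow(e))) {
    for (dir in 1:2) {
      v <- e[i, dir]          # root of pruned subtree (kept as attachment)
      u <- e[i, 3 - dir]
      e2 <- e[-i, , drop = FALSE]
      hit <- e2[, 1] == v | e2[, 2] == v
      # component containing v keeps v as its attachment node
      nodes_v <- v
      frontier <- v
      while (length(frontier) > 0) {
        sel <- e2[, 1] %in% frontier | e2[, 2] %in% frontier
        nodes <- unique(as.vector(e2[sel, , drop = FALSE]))
        frontier <- setdiff(nodes, nodes_v)
        nodes_v <- union(nodes_v, frontier)
      }
      in_v <- e2[, 1] %in% nodes_v
      ev <- e2[in_v, , drop = FALSE]
      eu <- splice_degree2(e2[!in_v, , drop = FALSE], u)
      if (nrow(eu) == 0) next
      for (j in seq_len(nrow(eu))) {
        out[[length(out) + 1L]] <-
          reconnect_trees(eu, j, ev, list(node = v, edge = NULL), next_id)
      }
    }
  }
  out
}

# all TBR rearrangements: bisect every edge, reroot/reattach both sides at
# every edge pair
tbr_moves <- function(e, ntip) {
  out <- list()
  next_id <- max(e) + 2L
  for (i in seq_len(nrow(e))) {
    bs <- bisect_tree(e, i)
    eu <- bs$eu; ev <- bs$ev
    u_single <- nrow(eu) == 0
    v_single <- nrow(ev) == 0
    if (u_single && v_single) next
    if (u_single || v_single) {
      # one side is a single leaf: TBR degenerates to SPR of that leaf
      leaf <- if (u_single) e[i, 1] else e[i, 2]
      main <- if (u_single) ev else eu
      for (j in seq_len(nrow(main))) {
        out[[length(out) + 1L]] <-
          reconnect_trees(main, j, matrix(0L, 0, 2),
                          list(node = leaf, edge = NULL), next_id)
      }
    } else {
      for (j in seq_len(nrow(eu))) {
        for (l in seq_len(nrow(ev))) {
          out[[length(out) + 1L]] <-
            reconnect_trees(eu, j, ev, list(edge = l), next_id)
        }
      }
    }
  }
  out
}

neighborhood_moves <- function(e, ntip, strategy) {
  switch(strategy,
         nni = nni_moves(e, ntip),
         spr = spr_moves(e, ntip),
         tbr = tbr_moves(e, ntip),
         abort(paste0("unknown strategy: ", strategy)))
}

# build a phylo tree from a set of mutually compatible clades (leaf-index
# sets not containing leaf 1), attaching leaf 1 at the root; `freqs` are
# optional per-clade support frequencies used as node labels
clades_to_phylo <- function(clades, ntip, labels, freqs = NULL) {
  full <- list(seq(2L, ntip))
  sizes <- c(ntip - 1L, vapply(clades, length, 1L))
  all_clades <- c(full, clades)
  ord <- order(-sizes)
  all_clades <- all_clades[ord]
  all_freqs <- if (!is.null(freqs)) c(NA_real_, freqs)[ord] else NULL
  n_cl <- length(all_clades)
  parent_cl <- integer(n_cl)         # parent clade index (0 = none)
  for (i in seq_len(n_cl)[-1]) {
    for (j in rev(seq_len(i - 1L))) {
      if (all(all_clades[[i]] %in% all_clades[[j]])) {
        # deepest (smallest) enclosing clade seen so far
        if (parent_cl[i] == 0 ||
            length(all_clades[[j]]) < length(all_clades[[parent_cl[i]]])) {
          parent_cl[i] <- j
        }
      }
    }
  }
  node_id <- ntip + seq_len(n_cl)
  edges <- matrix(0L, 0, 2)
  # clade-to-clade edges
  for (i in seq_len(n_cl)[-1]) {
    edges <- rbind(edges, c(node_id[parent_cl[i]], node_id[i]))
  }
  # leaves: each leaf attaches to its smallest containing clade
  leaf_parent <- integer(ntip)
  leaf_parent[1] <- node_id[1]
  for (lf in seq(2L, ntip)) {
    best <- 0L
    for (j in seq_len(n_cl)) {
      if (lf %in% all_clades[[j]] &&
          (best == 0L || length(all_clades[[j]]) < length(all_clades[[best]]))) {
        best <- j
      }
    }
    leaf_parent[lf] <- node_id[best]
  }
  edges <- rbind(edges, cbind(leaf_parent, seq_len(ntip)))
  phy <- list(edge = edges, tip.label = labels, Nnode = n_cl)
  if (!is.null(all_freqs)) phy$node.label <- as.character(all_freqs)
  class(phy) <- "phylo"
  phy <- ape::collapse.singles(phy)
  phy
}
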