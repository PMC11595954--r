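# Independent oracles, deliberately implemented apart from the package's
# own code paths (plain R, different algorithms).

# Exhaustive affine-gap alignment score by recursive search over all
# monotone alignment paths, tracking the gap state so run penalties
# follow the open + length * extend convention.
brute_force_align_score <- function(a, b, scoring) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(va) && j > length(vb)) return(0)
    best <- -Inf
    if (i <= length(va) && j <= length(vb)) {
      s <- if (va[i] == vb[j]) scoring$match else scoring$mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(va)) {
      pen <- scoring$gap_extend + if (state == "ga") 0 else scoring$gap_open
      best <- max(best, pen + rec(i + 1, j, "ga"))
    }
    if (j <= length(vb)) {
      pen <- scoring$gap_extend + if (state == "gb") 0 else scoring$gap_open
      best <- max(best, pen + rec(i, j + 1, "gb"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# All nontrivial bipartitions of a phylo tree by deleting each edge in
# turn and flood-filling the two components over the remaining edges.
brute_force_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  edges <- tree$edge
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- min(tips)
  out <- character(0)
  for (e in seq_len(nrow(edges))) {
    rest <- edges[-e, , drop = FALSE]
    # component containing the child end of the removed edge
    comp <- edges[e, 2]
    repeat {
      grow <- unique(c(rest[rest[, 1] %in% comp, 2],
                       rest[rest[, 2] %in% comp, 1]))
      grow <- setdiff(grow, comp)
      if (length(grow) == 0) break
      comp <- c(comp, grow)
    }
    side <- tips[comp[comp <= n]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (!anchor %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

brute_force_rf <- function(t1, t2) {
  b1 <- brute_force_bipartitions(t1)
  b2 <- brute_force_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# position-by-position mismatch count over resolved bases
hamming_resolved <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  sum(va[ok] != vb[ok])
}

# All unrooted binary leaf-labelled topologies on the given labels.
# Unrooted trees on n leaves correspond to rooted binary trees on the
# last n-1 leaves (the first leaf attaches at the root trifurcation);
# rooted trees are enumerated by inserting each new leaf on every edge,
# including above the root.
all_unrooted_topologies <- function(labels) {
  stopifnot(length(labels) >= 4)
  insert_all <- function(tree, leaf) {
    res <- list(list(tree, leaf))          # above the current root
    if (is.list(tree)) {
      for (sub in insert_all(tree[[1]], leaf))
        res[[length(res) + 1]] <- list(sub, tree[[2]])
      for (sub in insert_all(tree[[2]], leaf))
        res[[length(res) + 1]] <- list(tree[[1]], sub)
    }
    res
  }
  to_newick <- function(tree) {
    if (!is.list(tree)) return(tree)
    sprintf("(%s,%s)", to_newick(tree[[1]]), to_newick(tree[[2]]))
  }
  rest <- labels[-1]
  rooted <- list(rest[1])
  for (lab in rest[-1]) {
    nxt <- list()
    for (tr in rooted) nxt <- c(nxt, insert_all(tr, lab))
    rooted <- nxt
  }
  lapply(rooted, function(tr) {
    stopifnot(is.list(tr))
    ape::read.tree(text = sprintf("(%s,%s,%s);", labels[1],
                                  to_newick(tr[[1]]), to_newick(tr[[2]])))
  })
}

# least-squares branch-length fit of a distance matrix on a fixed
# topology (nonnegativity not enforced; residual comparison only)
ls_tree_residual <- function(topology, D) {
  tips <- topology$tip.label
  # path matrix: rows = leaf pairs, cols = edges
  n <- length(tips)
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), nrow(topology$edge))
  g <- igraph_free_paths(topology)
  for (p in seq_len(ncol(pairs))) {
    A[p, g[[p]]] <- 1
  }
  d <- apply(pairs, 2, function(ij) D[tips[ij[1]], tips[ij[2]]])
  fit <- stats::lm.fit(A, d)
  sum(fit$residuals^2)
}

# edge indices on the path between each leaf pair, by walking parent
# pointers on the (arbitrarily rooted) phylo edge table
igraph_free_paths <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  pedge <- integer(max(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    pedge[tree$edge[e, 2]] <- e
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  anc <- function(v) {
    path <- integer(0)
    while (v != root) { path <- c(path, pedge[v]); v <- parent[v] }
    path
  }
  pairs <- utils::combn(n, 2)
  lapply(seq_len(ncol(pairs)), function(p) {
    e1 <- anc(pairs[1, p]); e2 <- anc(pairs[2, p])
    c(setdiff(e1, e2), setdiff(e2, e1))
  })
}
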