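# Distance matrices, native Saitou-Nei neighbor joining, Robinson-Foulds
# bipartition distance, and supermatrix concatenation. Trees are ape
# "phylo" objects throughout; newick I/O delegates to ape.

#' Validate a square symmetric matrix as a distance matrix
#'
#' @param m Numeric matrix with taxon dimnames, symmetric, zero diagonal.
#' @export
as_distance_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m)))
    stop("distance matrix needs taxon labels as dimnames", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon labels", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(diag(m) != 0))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  structure(m, class = c("distance_matrix", "matrix"))
}

#' Pairwise distance matrix from an alignment
#'
#' The p-distance (proportion of differing comparable sites) is the
#' default model; within-genus mitochondrial divergence here is tiny, so
#' a substitution-model correction would change nothing. Jukes-Cantor is
#' available for longer branches.
#'
#' @param msa A `dna_msa`.
#' @param gap_mode `"pairwise_deletion"` (sites where both members of a
#'   pair are resolved) or `"complete_deletion"` (sites resolved in all
#'   taxa).
#' @param model `"p"` or `"jc"`.
#' @return A `distance_matrix`.
#' @export
p_distance_matrix <- function(msa,
                              gap_mode = c("pairwise_deletion",
                                           "complete_deletion"),
                              model = c("p", "jc")) {
  gap_mode <- match.arg(gap_mode)
  model <- match.arg(model)
  stopifnot(inherits(msa, "dna_msa"))
  taxa <- names(msa)
  n <- length(taxa)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  rows <- unclass(msa)
  if (gap_mode == "complete_deletion") {
    m <- as.matrix(msa)
    keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(keep))
      stop("no columns are resolved in all taxa", call. = FALSE)
    rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
    names(rows) <- taxa
  }
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cnt <- pair_site_counts_cpp(rows[[i]], rows[[j]])
      if (cnt[2] == 0L)
        stop("no comparable columns between ", taxa[i], " and ", taxa[j],
             call. = FALSE)
      p <- cnt[1] / cnt[2]
      if (model == "jc") {
        if (p >= 0.75)
          stop("p-distance ", signif(p, 3), " between ", taxa[i], " and ",
               taxa[j], " exceeds the Jukes-Cantor domain", call. = FALSE)
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  as_distance_matrix(D)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration implemented natively. Negative branch-length
#' estimates are clamped to zero. Tie-breaking on equal Q values joins
#' the pair whose (sorted) representative labels are lexicographically
#' smallest, so output is reproducible. The returned tree is unrooted.
#'
#' @param D A `distance_matrix` (>= 3 taxa).
#' @return An ape `phylo` tree.
#' @export
nj_tree <- function(D) {
  stopifnot(inherits(D, "distance_matrix") || is.matrix(D))
  labels <- rownames(D)
  n <- length(labels)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  d <- unclass(D)
  # working state: subtree newick fragments and representative labels
  # (smallest leaf label in the subtree, used only for tie-breaking)
  nwk <- labels
  rep_lab <- labels
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(nwk) > 3L) {
    m <- length(nwk)
    r <- rowSums(d)
    # Q matrix; pick minimal pair with lexicographic tie-break
    best <- NULL; best_q <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        key <- sort(c(rep_lab[i], rep_lab[j]))
        take <- if (is.null(best) || q < best_q - 1e-12) {
          TRUE
        } else if (q <= best_q + 1e-12) {
          key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])
        } else FALSE
        if (take) {
          best_q <- min(q, best_q)
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    dk <- pmax(dk[-c(i, j)], 0)
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, dk), c(dk, 0))
    nwk <- c(nwk[-c(i, j)], new_nwk)
    rep_lab <- c(rep_lab[-c(i, j)], new_rep)
  }
  # resolve the final trifurcation with exact three-point lengths
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  nwk[1], fmt(l1), nwk[2], fmt(l2), nwk[3], fmt(l3))
  ape::read.tree(text = text)
}

# nontrivial bipartitions of an unrooted tree as canonical strings: each
# split is represented by the side containing the alphabetically first
# leaf, as a sorted comma-joined label string
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  anchor <- min(tips)
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- tips[p]
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    if (!anchor %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the nontrivial bipartition sets,
#' compared unrooted. Zero iff the topologies are identical.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @param normalized If TRUE divide by `2 * (n - 3)`, the maximum for
#'   binary trees.
#' @return Numeric distance.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  s1 <- sort(t1$tip.label); s2 <- sort(t2$tip.label)
  if (!identical(s1, s2))
    stop("leaf sets differ: ",
         paste(c(setdiff(s1, s2), setdiff(s2, s1)), collapse = ", "),
         call. = FALSE)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (normalized) {
    n <- length(s1)
    if (n <= 3L) return(0)
    return(rf / (2 * (n - 3)))
  }
  rf
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param blocks List of `dna_msa` objects over identical taxa.
#' @return A `dna_msa` whose width is the sum of block widths, with a
#'   `blocks` attribute recording per-block provenance (name, width).
#' @export
concat_alignment <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  taxa <- names(blocks[[1]])
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    stopifnot(inherits(b, "dna_msa"))
    missing <- setdiff(taxa, names(b))
    extra <- setdiff(names(b), taxa)
    if (length(missing) > 0 || length(extra) > 0)
      stop("block ", if (!is.null(names(blocks))) names(blocks)[k] else k,
           " does not cover the same taxa (missing: ",
           paste(missing, collapse = ","), ")", call. = FALSE)
  }
  rows <- vapply(taxa, function(tx) {
    paste(vapply(blocks, function(b) unclass(b)[[tx]], ""), collapse = "")
  }, "")
  out <- msa_from_rows(stats::setNames(rows, taxa))
  attr(out, "blocks") <- data.frame(
    name = if (!is.null(names(blocks))) names(blocks)
           else as.character(seq_along(blocks)),
    width = vapply(blocks, msa_width, 0),
    stringsAsFactors = FALSE)
  out
}

#' Write / read newick
#'
#' Round trip preserves topology exactly and branch lengths to the
#' printed precision.
#'
#' @param tree A `phylo`.
#' @param path Optional file path; if NULL the newick text is returned.
#' @export
newick_write <- function(tree, path = NULL) {
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_label <- function(l) {
    if (grepl("[^A-Za-z0-9_.|-]", l)) paste0("'", l, "'") else l
  }
  fmt_len <- function(e) {
    if (is.null(tree$edge.length)) ""
    else sprintf(":%.10g", tree$edge.length[e])
  }
  descend <- function(node) {
    if (node <= n) return(quote_label(tree$tip.label[node]))
    parts <- vapply(kids[[as.character(node)]], function(e) {
      paste0(descend(tree$edge[e, 2]), fmt_len(e))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- n + 1L
  text <- paste0(descend(root), ";")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(path)
}

#' @param text Newick text (or NULL to read from `path`).
#' @rdname newick_write
#' @export
newick_read <- function(text = NULL, path = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("newick parse error", call. = FALSE)
  tr$tip.label <- gsub("^'|'$", "", tr$tip.label)
  tr
}
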