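# Native pairwise (Needleman-Wunsch, affine gaps) and progressive multiple
# alignment, plus the SNP/InDel counting used by the marker screen.

#' Default alignment scoring
#'
#' Match +2, mismatch -1, gap open -1, gap extend -1; a gap run of length
#' L costs `gap_open + L * gap_extend`. Under this scheme a window of two
#' adjacent mismatches and its paired-single-base-gap presentation (e.g.
#' ATAT-TA vs AT-TCTA for the sequences ATATTA/ATTCTA) score exactly
#' equally, so the InDel reading is admitted as co-optimal while the
#' deterministic traceback — which prefers substitutions — never
#' introduces gaps into substitution-only data. Making the gapped
#' presentation strictly optimal is impossible without also gapping
#' every transposed-mismatch pair in long alignments, which would plant
#' spurious InDels.
#' @export
default_scoring <- function() {
  list(match = 2, mismatch = -1, gap_open = -1, gap_extend = -1)
}

#' Score a given (already gapped) pairwise alignment
#'
#' Evaluates the affine-gap objective on an explicit alignment, e.g. to
#' check that a published gap placement achieves the optimal score.
#'
#' @param a_aligned,b_aligned Equal-length gapped strings.
#' @param scoring See [default_scoring()].
#' @return Numeric score.
#' @export
alignment_score <- function(a_aligned, b_aligned,
                            scoring = default_scoring()) {
  va <- strsplit(toupper(a_aligned), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b_aligned), "", fixed = TRUE)[[1]]
  if (length(va) != length(vb))
    stop("aligned rows must have equal width", call. = FALSE)
  if (any(va == "-" & vb == "-"))
    stop("gap/gap columns are not allowed", call. = FALSE)
  run_penalty <- function(gapped) {
    r <- rle(gapped)
    sum(scoring$gap_open * r$values) +
      scoring$gap_extend * sum(r$lengths[r$values])
  }
  resolved <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  sum(ifelse(va[resolved] == vb[resolved], scoring$match,
             scoring$mismatch)) +
    run_penalty(va == "-") + run_penalty(vb == "-")
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch with affine gap penalties, implemented natively.
#' Deterministic traceback: on ties prefer the diagonal move, then a gap
#' in the second sequence, then a gap in the first.
#'
#' @param a,b Nucleotide strings.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (see [default_scoring()]).
#' @return A `pairwise_alignment`: list with gapped strings `a`, `b`,
#'   the optimal `score`, and the input `labels`.
#' @export
global_align <- function(a, b, scoring = default_scoring()) {
  sa <- check_dna(a, "sequence a")
  sb <- check_dna(b, "sequence b")
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("cannot align empty sequences", call. = FALSE)
  res <- nw_affine_cpp(sa, sb, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  structure(list(a = res$a, b = res$b, score = res$score,
                 labels = c(if (!is.null(names(a))) names(a) else "a",
                            if (!is.null(names(b))) names(b) else "b")),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> width %d, score %.1f\n%s\n%s\n",
              nchar(x$a), x$score, x$a, x$b))
  invisible(x)
}

# 6-row count profile (A,C,G,T,N,-) from a character matrix of rows
profile_counts <- function(rows) {
  w <- nchar(rows[1])
  mat <- matrix(0, nrow = 6, ncol = w)
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L, "-" = 6L)
  for (r in rows) {
    v <- codes[strsplit(r, "", fixed = TRUE)[[1]]]
    for (j in seq_len(w)) mat[v[j], j] <- mat[v[j], j] + 1
  }
  mat
}

# fractional common k-mer distance used only for the MSA guide tree
kmer_distance <- function(seqs, k = 4L) {
  tabs <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- sum(pmin(
        as.numeric(tabs[[i]][names(tabs[[j]])]),
        as.numeric(tabs[[j]])), na.rm = TRUE)
      denom <- min(nchar(seqs[i]), nchar(seqs[j])) - k + 1L
      d <- 1 - shared / max(denom, 1L)
      D[i, j] <- D[j, i] <- max(d, 0)
    }
  }
  D
}

msa_from_rows <- function(rows) {
  structure(rows, class = "dna_msa")
}

#' Wrap pre-aligned rows as a multiple alignment
#'
#' For sequences already aligned elsewhere (or equal-length gap-free
#' orthologs that need no aligning): validates equal widths and unique
#' labels and returns a `dna_msa` without touching the rows.
#'
#' @param rows Named character vector of equal-width (gapped) rows.
#' @export
as_msa <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("rows must be named", call. = FALSE)
  if (anyDuplicated(names(rows)))
    stop("duplicate row labels", call. = FALSE)
  if (length(unique(nchar(rows))) != 1L)
    stop("rows must have equal width", call. = FALSE)
  msa_from_rows(toupper(rows))
}

#' @export
print.dna_msa <- function(x, ...) {
  cat(sprintf("<dna_msa> %d taxa x %d columns\n", length(x), nchar(x[1])))
  invisible(x)
}

#' Alignment width (number of columns)
#' @param x A `dna_msa`.
#' @export
msa_width <- function(x) nchar(x[[1]])

#' @export
as.matrix.dna_msa <- function(x, ...) {
  do.call(rbind, lapply(strsplit(unclass(x), "", fixed = TRUE), identity))
}

#' Multiple sequence alignment
#'
#' If all inputs have equal length and, for every pair, the ungapped
#' column stack already achieves the optimal pairwise score, the MSA is
#' that trivial stack (the common case for equal-length conserved
#' mitochondrial genes). Otherwise sequences are aligned progressively:
#' a neighbor-joining guide tree is built from k-mer distances and
#' profiles are merged by affine-gap profile alignment in post-order.
#'
#' @param sequences Named character vector, length >= 2.
#' @param scoring See [default_scoring()].
#' @return A `dna_msa`: named character vector of equal-width gapped rows.
#' @export
msa <- function(sequences, scoring = default_scoring()) {
  if (length(sequences) < 2L)
    stop("need at least 2 sequences to align", call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named", call. = FALSE)
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence labels", call. = FALSE)
  seqs <- vapply(sequences, check_dna, "", USE.NAMES = TRUE)

  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L && stack_is_optimal(seqs, scoring))
    return(msa_from_rows(seqs))

  if (length(seqs) == 2L) {
    pa <- global_align(seqs[1], seqs[2], scoring)
    return(msa_from_rows(stats::setNames(c(pa$a, pa$b), names(seqs))))
  }

  D <- kmer_distance(seqs)
  guide <- nj_tree(as_distance_matrix(D))
  merge_order <- ape::reorder.phylo(guide, "postorder")
  # progressive merge: profiles held per node
  profiles <- as.list(stats::setNames(seqs[guide$tip.label], guide$tip.label))
  profiles <- lapply(profiles, function(s) stats::setNames(s, NULL))
  node_prof <- vector("list", max(merge_order$edge))
  for (i in seq_along(guide$tip.label))
    node_prof[[i]] <- stats::setNames(seqs[guide$tip.label[i]],
                                      guide$tip.label[i])
  edges <- merge_order$edge
  for (node in unique(edges[, 1])) {
    children <- edges[edges[, 1] == node, 2]
    acc <- node_prof[[children[1]]]
    for (ch in children[-1])
      acc <- merge_profiles(acc, node_prof[[ch]], scoring)
    node_prof[[node]] <- acc
  }
  root <- length(guide$tip.label) + 1L
  out <- node_prof[[root]][names(seqs)[names(seqs) %in% names(node_prof[[root]])]]
  msa_from_rows(out[names(seqs)])
}

# Is the ungapped column stack optimal for every pair? An alignment with
# G gap bases per row scores at most (L-G)*match + 2*(gap_open +
# G*gap_extend), so only alignments with G below a bound derived from the
# pair's mismatch count can beat the stack; a banded NW over exactly that
# band decides the question without the full quadratic search.
stack_is_optimal <- function(seqs, scoring) {
  n <- length(seqs)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (seqs[i] == seqs[j]) next
      cnt <- pair_site_counts_cpp(seqs[i], seqs[j])
      # N-containing columns score 0 either way
      stacked <- (cnt[2] - cnt[1]) * scoring$match + cnt[1] * scoring$mismatch
      band <- floor((cnt[1] * (scoring$match - scoring$mismatch) +
                       2 * scoring$gap_open) /
                      (scoring$match - 2 * scoring$gap_extend))
      if (band < 1) next  # no gapped alignment can beat the stack
      opt <- nw_affine_score_banded_cpp(seqs[i], seqs[j], scoring$match,
                                        scoring$mismatch, scoring$gap_open,
                                        scoring$gap_extend, band)
      if (opt > stacked + 1e-9) return(FALSE)
    }
  }
  TRUE
}

merge_profiles <- function(rows_a, rows_b, scoring) {
  pa <- profile_counts(rows_a)
  pb <- profile_counts(rows_b)
  res <- profile_nw_cpp(pa, pb, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
  expand <- function(rows, cols) {
    chs <- strsplit(rows, "", fixed = TRUE)
    out <- vapply(chs, function(v) {
      paste(ifelse(cols == 0L, "-", v[pmax(cols, 1L)]), collapse = "")
    }, "")
    stats::setNames(out, names(rows))
  }
  c(expand(rows_a, res$cols_a), expand(rows_b, res$cols_b))
}

#' SNP and InDel summary for a pairwise alignment
#'
#' SNPs are aligned columns where both rows carry resolved bases that
#' differ; columns with `N` in either row are excluded and tallied as
#' ambiguous. InDel "sites" are maximal gap runs (in either row,
#' terminal runs included); "gap bases" is their total length. SNP
#' positions are numbered 1-based on the ungapped reference row.
#'
#' @param alignment A `pairwise_alignment`.
#' @param reference Which row provides position numbering: 1 or 2 (or a
#'   label present in `alignment$labels`).
#' @return A `variant_summary`: list with `snp_count`,
#'   `indel_site_count`, `gap_base_count`, `ambiguous_count` and
#'   `snp_positions` (data.frame: pos, ref, alt, label like "A→G at 69").
#' @export
count_variants <- function(alignment, reference = 1L) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  if (is.character(reference))
    reference <- match(reference, alignment$labels)
  if (is.na(reference) || !reference %in% c(1L, 2L))
    stop("reference must identify one of the two aligned rows",
         call. = FALSE)
  ref <- strsplit(if (reference == 1L) alignment$a else alignment$b,
                  "", fixed = TRUE)[[1]]
  alt <- strsplit(if (reference == 1L) alignment$b else alignment$a,
                  "", fixed = TRUE)[[1]]
  base <- c("A", "C", "G", "T")
  both <- ref %in% base & alt %in% base
  snp <- both & ref != alt
  ambiguous <- (ref == "N" | alt == "N") & ref != "-" & alt != "-"

  gap_runs <- function(v) {
    r <- rle(v == "-")
    sum(r$values)
  }
  gaps_a <- strsplit(alignment$a, "", fixed = TRUE)[[1]] == "-"
  gaps_b <- strsplit(alignment$b, "", fixed = TRUE)[[1]] == "-"
  indel_sites <- sum(rle(gaps_a)$values) + sum(rle(gaps_b)$values)
  gap_bases <- sum(gaps_a) + sum(gaps_b)

  ref_pos <- cumsum(ref != "-")
  pos <- ref_pos[snp]
  snp_df <- data.frame(
    pos = pos, ref = ref[snp], alt = alt[snp],
    label = sprintf("%s→%s at %d", ref[snp], alt[snp], pos),
    stringsAsFactors = FALSE)
  structure(list(snp_count = sum(snp),
                 indel_site_count = indel_sites,
                 gap_base_count = gap_bases,
                 ambiguous_count = sum(ambiguous),
                 snp_positions = snp_df),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("<variant_summary> %d SNPs, %d InDel sites (%d gap bases)\n",
              x$snp_count, x$indel_site_count, x$gap_base_count))
  if (nrow(x$snp_positions) > 0)
    cat(" ", paste(x$snp_positions$label, collapse = "; "), "\n")
  invisible(x)
}

#' Classify alignment sites against a taxon grouping
#'
#' Each column is `invariant` (all rows identical),
#' `within_group_variable` (some group is internally polymorphic at the
#' site), or `between_group_diagnostic` (fixed within every group and
#' different between at least two groups) — the property that makes a
#' site usable to tell groups apart.
#'
#' @param msa A `dna_msa`.
#' @param groups Named character/factor vector mapping every taxon label
#'   to a group.
#' @return Character vector of per-site classes, length `msa_width(msa)`.
#' @export
variable_sites <- function(msa, groups) {
  stopifnot(inherits(msa, "dna_msa"))
  taxa <- names(msa)
  missing <- setdiff(taxa, names(groups))
  if (length(missing) > 0)
    stop("taxa without a group assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(msa)
  grp <- as.character(groups[taxa])
  apply(m, 2L, function(col) {
    if (length(unique(col)) == 1L) return("invariant")
    per_group <- tapply(col, grp, function(v) length(unique(v)))
    if (any(per_group > 1L)) return("within_group_variable")
    "between_group_diagnostic"
  })
}
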