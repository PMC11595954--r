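# Candidate barcode-marker screening: score the core protein-coding genes
# (and the two rRNAs) for length stability, SNP/InDel load, topological
# concordance with the concatenated-gene reference tree and presence of
# clade-diagnostic variation; then report per-clade SNPs against a chosen
# barcode standard.

#' Screening configuration
#'
#' @param core_genes Genes forming the concatenated reference tree
#'   (default: the 15 core protein-coding genes).
#' @param candidates Genes to score (default: core genes plus rrnl/rrns).
#' @param max_barcode_length Longest acceptable barcode (bp). A marker
#'   must be amplifiable and renderable as a compact barcode; 300 bp
#'   keeps the three short candidates in and every medium/long gene out.
#' @param reference_accession Record supplying the barcode standard
#'   sequences (defaults to the first retained record).
#' @param max_indel_sites Gap-containing MSA columns tolerated before a
#'   gene is excluded as InDel-laden (default 0).
#' @param max_variable_fraction Variable-column fraction above which a
#'   gene is excluded as hypervariable (default 0.10).
#' @param scoring Alignment scoring, see [default_scoring()].
#' @export
screening_config <- function(core_genes = CORE_GENES,
                             candidates = c(CORE_GENES, "rrnl", "rrns"),
                             max_barcode_length = 300,
                             reference_accession = NULL,
                             max_indel_sites = 0,
                             max_variable_fraction = 0.10,
                             scoring = default_scoring()) {
  stopifnot(length(core_genes) > 0, max_barcode_length > 0,
            max_variable_fraction > 0)
  structure(list(core_genes = core_genes, candidates = candidates,
                 max_barcode_length = max_barcode_length,
                 reference_accession = reference_accession,
                 max_indel_sites = max_indel_sites,
                 max_variable_fraction = max_variable_fraction,
                 scoring = scoring),
            class = "screening_config")
}

# named accession -> sequence vector for one gene; NA where absent or
# ambiguous (multi-copy)
gene_sequences <- function(records, gene) {
  out <- vapply(records, function(r) {
    f <- tryCatch(extract_gene(r, gene), error = function(e) NULL)
    if (is.null(f)) NA_character_ else f$sequence
  }, "")
  stats::setNames(out, vapply(records, `[[`, "", "accession"))
}

retained_records <- function(records, config) {
  keep <- vapply(records, function(r) {
    all(vapply(config$core_genes, function(g) {
      !is.null(tryCatch(extract_gene(r, g), error = function(e) NULL))
    }, TRUE))
  }, TRUE)
  if (any(!keep)) {
    dropped <- vapply(records[!keep], `[[`, "", "accession")
    message("dropped record(s) missing core genes: ",
            paste(dropped, collapse = ", "))
  }
  records[keep]
}

core_gene_msas <- function(records, config) {
  lapply(stats::setNames(config$core_genes, config$core_genes),
         function(g) msa(gene_sequences(records, g), config$scoring))
}

#' Reference tree from the concatenated core genes
#'
#' Records missing any core gene are dropped (with a message); the
#' survivors' per-gene alignments are concatenated into a supermatrix
#' and a neighbor-joining tree is built on p-distances.
#'
#' @param records List of `mitogenome` objects.
#' @param config A [screening_config()].
#' @return An ape `phylo` tree.
#' @export
build_reference_tree <- function(records, config = screening_config()) {
  records <- retained_records(records, config)
  if (length(records) < 3L)
    stop("fewer than 3 records retain all core genes", call. = FALSE)
  blocks <- core_gene_msas(records, config)
  super <- concat_alignment(blocks)
  nj_tree(p_distance_matrix(super))
}

# zero-distance groups on the concatenated core alignment; used as the
# grouping against which between-group-diagnostic sites are counted
concat_groups <- function(super) {
  key <- unclass(super)
  stats::setNames(as.integer(factor(key, levels = unique(key))), names(super))
}

#' Screen candidate genes as barcode markers
#'
#' Produces one score row per candidate. rRNA genes are excluded
#' whenever their annotated lengths differ between records (intron-count
#' variance) or any record lacks the annotation. Protein-coding genes
#' are excluded as InDel-laden/hypervariable when their alignment
#' carries more gap columns or variable columns than configured;
#' survivors must have a single-gene tree topologically identical
#' (Robinson-Foulds 0) to the concatenated reference tree and at least
#' one clade-diagnostic site to be `selected`; concordant genes longer
#' than `max_barcode_length` are graded `candidate`.
#'
#' @param records List of `mitogenome` objects.
#' @param config A [screening_config()].
#' @return A `marker_screen` data.frame, ranked selected-first by
#'   ascending length, with the reference tree, per-gene trees and MSAs
#'   attached as attributes.
#' @export
screen_markers <- function(records, config = screening_config()) {
  records <- retained_records(records, config)
  if (length(records) < 3L)
    stop("fewer than 3 records retain all core genes", call. = FALSE)
  accs <- vapply(records, `[[`, "", "accession")
  blocks <- core_gene_msas(records, config)
  super <- concat_alignment(blocks)
  reference <- nj_tree(p_distance_matrix(super))
  groups <- concat_groups(super)

  gene_trees <- list()
  msas <- list()
  rows <- lapply(config$candidates, function(g) {
    seqs <- gene_sequences(records, g)
    present <- !is.na(seqs)
    lens <- ifelse(present, nchar(seqs), NA_integer_)
    length_stable <- all(present) && length(unique(lens)) == 1L
    med_len <- as.integer(stats::median(lens, na.rm = TRUE))
    is_rrna <- g %in% c("rrnl", "rrns")
    score <- list(gene = g, median_length_bp = med_len,
                  length_stable = length_stable,
                  rf_vs_reference = NA_integer_,
                  interspecies_diagnostic_sites = NA_integer_,
                  variable_sites = NA_integer_, indel_columns = NA_integer_,
                  protein_conserved = NA, verdict = NA_character_,
                  reason = "")

    if (is_rrna && (!all(present) || !length_stable)) {
      score$verdict <- "excluded_length_unstable"
      score$reason <- if (!all(present)) "annotation incomplete in some records"
                      else "annotated length varies between records (introns)"
      return(score)
    }
    if (!all(present)) {
      score$verdict <- "excluded_length_unstable"
      score$reason <- "gene absent from some records"
      return(score)
    }
    aln <- if (g %in% names(blocks)) blocks[[g]] else msa(seqs, config$scoring)
    msas[[g]] <<- aln
    m <- as.matrix(aln)
    gap_cols <- sum(apply(m, 2L, function(col) any(col == "-")))
    var_cols <- sum(apply(m, 2L, function(col) {
      b <- unique(col[col != "-"]); length(b) > 1L
    }))
    score$indel_columns <- gap_cols
    score$variable_sites <- var_cols
    if (!is_rrna) {
      tr <- tryCatch(paste0(translate_cds(seqs[[1]], mode = "complete")),
                     error = function(e) NULL)
      if (!is.null(tr)) {
        prots <- vapply(seqs, function(s)
          tryCatch(translate_cds(s, mode = "complete"),
                   error = function(e) NA_character_), "")
        score$protein_conserved <- !anyNA(prots) &&
          length(unique(prots)) == 1L
      }
    }
    if (gap_cols > config$max_indel_sites ||
        var_cols > config$max_variable_fraction * msa_width(aln)) {
      score$verdict <- "excluded_too_long_variable"
      score$reason <- sprintf("%d gap columns, %d/%d variable columns",
                              gap_cols, var_cols, msa_width(aln))
      return(score)
    }
    if (!length_stable) {
      score$verdict <- "excluded_length_unstable"
      score$reason <- "length varies between records"
      return(score)
    }
    gt <- nj_tree(p_distance_matrix(aln))
    gene_trees[[g]] <<- gt
    score$rf_vs_reference <- rf_distance(gt, reference)
    sites <- variable_sites(aln, groups)
    score$interspecies_diagnostic_sites <-
      sum(sites == "between_group_diagnostic")
    if (score$rf_vs_reference > 0 ||
        score$interspecies_diagnostic_sites == 0L) {
      score$verdict <- "excluded_insufficient_resolution"
      score$reason <- if (score$rf_vs_reference > 0)
        "single-gene tree disagrees with the reference topology"
      else "no clade-diagnostic variation"
      return(score)
    }
    if (med_len <= config$max_barcode_length) {
      score$verdict <- "selected"
      score$reason <- "concordant, diagnostic, short and length-stable"
    } else {
      score$verdict <- "candidate"
      score$reason <- "concordant but too long for a compact barcode"
    }
    score
  })

  df <- do.call(rbind, lapply(rows, function(s)
    as.data.frame(s, stringsAsFactors = FALSE)))
  verdict_rank <- match(df$verdict,
                        c("selected", "candidate",
                          "excluded_insufficient_resolution",
                          "excluded_too_long_variable",
                          "excluded_length_unstable"))
  df <- df[order(verdict_rank, df$median_length_bp, df$gene), ]
  rownames(df) <- NULL
  structure(df, class = c("marker_screen", "data.frame"),
            reference_tree = reference, gene_trees = gene_trees,
            msas = msas, taxa = accs)
}

#' Selected marker names from a screen
#' @param screen A `marker_screen`.
#' @export
selected_markers <- function(screen) {
  screen$gene[screen$verdict == "selected"]
}

#' Group taxa into zero-SNP clades over the selected markers
#'
#' A clade is a maximal set of leaves with zero pairwise SNPs in every
#' supplied marker alignment (connected components of the zero-SNP
#' relation, so ambiguous bases cannot split a clade). Clades are
#' numbered by tree traversal order; if `reference` names a leaf, its
#' clade is number 1.
#'
#' @param tree `phylo` over the same accessions as the MSAs.
#' @param marker_msas Named list of `dna_msa` objects.
#' @param reference Optional accession anchoring clade numbering.
#' @return A `clade_table` data.frame: clade_id, accession.
#' @export
assign_clades <- function(tree, marker_msas, reference = NULL) {
  taxa <- tree$tip.label
  for (g in names(marker_msas)) {
    missing <- setdiff(taxa, names(marker_msas[[g]]))
    if (length(missing) > 0)
      stop("marker '", g, "' alignment lacks leaves: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- length(taxa)
  # zero-SNP adjacency across all markers
  same <- matrix(TRUE, n, n)
  for (g in names(marker_msas)) {
    rows <- unclass(marker_msas[[g]])[taxa]
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- pair_site_counts_cpp(rows[[i]], rows[[j]])[1]
        if (d > 0L) same[i, j] <- same[j, i] <- FALSE
      }
    }
  }
  comp <- seq_len(n)  # connected components via label propagation
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (same[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
        if (same[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  # number clades in tree traversal (plotted leaf) order
  ord <- ape::reorder.phylo(tree, "cladewise")$tip.label
  ord <- ord[ord %in% taxa]
  comp_by_acc <- stats::setNames(comp, taxa)
  first_seen <- unique(comp_by_acc[ord])
  if (!is.null(reference)) {
    if (!reference %in% taxa)
      stop("reference accession ", reference, " not in tree", call. = FALSE)
    rc <- comp_by_acc[[reference]]
    first_seen <- c(rc, setdiff(first_seen, rc))
  }
  clade_id <- stats::setNames(match(comp_by_acc, first_seen), taxa)
  out <- data.frame(clade_id = unname(clade_id[ord]), accession = ord,
                    stringsAsFactors = FALSE)
  out <- out[order(out$clade_id), ]
  rownames(out) <- NULL
  structure(out, class = c("clade_table", "data.frame"))
}

#' Per-clade SNP/InDel counts against the barcode standard
#'
#' Aligns one representative per clade to the standard record's marker
#' sequences and reports SNP counts, InDel sites and SNP position labels
#' for each marker. The standard's own clade reports zeros.
#'
#' @param clades A `clade_table`.
#' @param standard Accession of the barcode-standard record.
#' @param marker_msas Named list of `dna_msa` (gaps are stripped before
#'   re-alignment to the standard).
#' @param scoring See [default_scoring()].
#' @return data.frame with one row per clade and, per marker, columns
#'   `snps_<m>`, `indel_sites_<m>`, `snp_detail_<m>`.
#' @export
snps_vs_standard <- function(clades, standard, marker_msas,
                             scoring = default_scoring()) {
  stopifnot(inherits(clades, "clade_table"))
  if (!standard %in% clades$accession)
    stop("standard accession ", standard, " absent from clade table",
         call. = FALSE)
  ids <- sort(unique(clades$clade_id))
  out <- data.frame(clade_id = ids,
                    n_members = as.integer(table(clades$clade_id)[as.character(ids)]),
                    representative = vapply(ids, function(cid)
                      clades$accession[clades$clade_id == cid][1], ""),
                    stringsAsFactors = FALSE)
  for (m in names(marker_msas)) {
    rows <- unclass(marker_msas[[m]])
    degap <- function(s) gsub("-", "", s, fixed = TRUE)
    std_seq <- degap(rows[[standard]])
    snps <- integer(length(ids)); indels <- integer(length(ids))
    detail <- character(length(ids))
    for (k in seq_along(ids)) {
      rep_seq <- degap(rows[[out$representative[k]]])
      if (rep_seq == std_seq) {
        snps[k] <- 0L; indels[k] <- 0L; detail[k] <- ""
        next
      }
      pa <- global_align(std_seq, rep_seq, scoring)
      vs <- count_variants(pa, reference = 1L)
      snps[k] <- vs$snp_count
      indels[k] <- vs$indel_site_count
      detail[k] <- paste(vs$snp_positions$label, collapse = "; ")
    }
    out[[paste0("snps_", m)]] <- snps
    out[[paste0("indel_sites_", m)]] <- indels
    out[[paste0("snp_detail_", m)]] <- detail
  }
  out
}
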