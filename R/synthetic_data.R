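# Simulator for annotated mitogenome collections with known ground truth:
# a true tree, per-gene per-branch mutation logs, and clade assignments.
# Substitutions follow a continuous-time Jukes-Cantor process; an optional
# synonymous-only mode keeps every leaf's protein identical to the root's
# while nucleotides diverge; rRNA genes can carry taxon-specific introns
# so their annotated lengths vary between taxa.

#' Default per-gene coding-sequence lengths (bp)
#'
#' The 15 core protein-coding genes at lengths typical of conserved
#' fungal mitogenomes, plus exon lengths for the two rRNA genes (introns
#' are added per taxon by the simulator when enabled).
#' @export
default_gene_lengths <- function() {
  c(atp6 = 774, atp8 = 159, atp9 = 222, cob = 1158, cox1 = 1587,
    cox2 = 756, cox3 = 810, nad1 = 1017, nad2 = 1509, nad3 = 360,
    nad4 = 1452, nad4l = 267, nad5 = 1983, nad6 = 612, rps3 = 1020,
    rrnl = 2300, rrns = 1700)
}

#' Simulation configuration
#'
#' @param n_taxa Number of leaves (used when `tree` is NULL).
#' @param tree Fixed topology: newick text or `phylo`; NULL draws a
#'   random bifurcating (Yule-process) topology with uniform branch
#'   lengths on \[0.1, 0.5\].
#' @param gene_lengths Named bp vector; see [default_gene_lengths()].
#' @param subst_rate Substitutions per site per unit branch length;
#'   scalar or named per-gene vector.
#' @param indel_rate InDel events per site per unit branch length
#'   (length 1-3, insertion or deletion with equal probability); scalar
#'   or named per-gene vector.
#' @param synonymous_only Gene names whose substitutions are restricted
#'   to amino-acid-preserving changes under `code`.
#' @param code A [genetic_code()].
#' @param rrna_introns Insert introns into rrnl/rrns per taxon?
#' @param intron_count_range,intron_length_range Integer ranges.
#' @param gc_target Genome GC fraction target.
#' @param spacer_length_range Intergenic spacer lengths (bp).
#' @param seed Integer; fixes all randomness.
#' @export
sim_config <- function(n_taxa = 9, tree = NULL,
                       gene_lengths = default_gene_lengths(),
                       subst_rate = 0.01, indel_rate = 0,
                       synonymous_only = character(0),
                       code = genetic_code(4),
                       rrna_introns = TRUE,
                       intron_count_range = c(1L, 4L),
                       intron_length_range = c(125L, 225L),
                       gc_target = 0.27,
                       spacer_length_range = c(100L, 400L),
                       seed = 1L) {
  stopifnot(n_taxa >= 2, all(gene_lengths > 0), all(subst_rate >= 0),
            all(indel_rate >= 0), gc_target > 0, gc_target < 1)
  cds <- intersect(names(gene_lengths), CORE_GENES)
  if (any(gene_lengths[cds] %% 3 != 0))
    stop("CDS gene lengths must be divisible by 3", call. = FALSE)
  structure(list(n_taxa = n_taxa, tree = tree, gene_lengths = gene_lengths,
                 subst_rate = subst_rate, indel_rate = indel_rate,
                 synonymous_only = synonymous_only, code = code,
                 rrna_introns = rrna_introns,
                 intron_count_range = as.integer(intron_count_range),
                 intron_length_range = as.integer(intron_length_range),
                 gc_target = gc_target,
                 spacer_length_range = as.integer(spacer_length_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# uniform integer in [a, b]; safe when a == b (sample() would misread it)
rint <- function(a, b) if (a >= b) a else a + sample.int(b - a + 1L, 1L) - 1L

random_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

# random complete CDS: sense codons weighted toward the GC target, then a
# TAA stop
random_cds <- function(len, gc, code) {
  n_codons <- len %/% 3L
  sense <- names(code$codon_map)[code$codon_map != "*"]
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(strsplit(sense, ""), function(b) prod(p[b]), 0)
  codons <- sample(sense, n_codons - 1L, replace = TRUE, prob = w)
  paste(c(codons, "TAA"), collapse = "")
}

# an unnamed scalar applies to every gene; a named vector sets listed
# genes only (unlisted genes get rate 0)
rate_for <- function(rates, gene) {
  if (is.null(names(rates))) return(unname(rates[1]))
  if (gene %in% names(rates)) unname(rates[gene]) else 0
}

# apply n Jukes-Cantor substitutions to a character vector of bases,
# logging each; synonymous mode rejects amino-acid-changing proposals
mutate_bases <- function(v, n_sub, synonymous, code) {
  log <- vector("list", n_sub)
  k <- 0L; tries <- 0L
  while (k < n_sub && tries < 1000L * (n_sub + 1L)) {
    tries <- tries + 1L
    pos <- sample.int(length(v), 1L)
    from <- v[pos]
    to <- sample(setdiff(BASES, from), 1L)
    if (synonymous) {
      ci <- (pos - 1L) %/% 3L
      codon <- paste(v[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      mutated <- v; mutated[pos] <- to
      codon2 <- paste(mutated[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      if (code$codon_map[codon] != code$codon_map[codon2]) next
    }
    v[pos] <- to
    k <- k + 1L
    log[[k]] <- list(type = "sub", position = pos, from = from, to = to)
  }
  list(seq = v, log = log[seq_len(k)])
}

apply_indels <- function(v, n_ind, gc) {
  log <- vector("list", n_ind)
  for (k in seq_len(n_ind)) {
    len <- rint(1L, 3L)
    if (stats::runif(1) < 0.5 && length(v) > len + 2L) {
      pos <- sample.int(length(v) - len, 1L)
      removed <- paste(v[pos:(pos + len - 1L)], collapse = "")
      v <- v[-(pos:(pos + len - 1L))]
      log[[k]] <- list(type = "del", position = pos, from = removed, to = "")
    } else {
      pos <- sample.int(length(v) + 1L, 1L)
      ins <- random_bases(len, gc)
      v <- append(v, ins, after = pos - 1L)
      log[[k]] <- list(type = "ins", position = pos, from = "",
                       to = paste(ins, collapse = ""))
    }
  }
  list(seq = v, log = log)
}

#' Simulate an annotated mitogenome collection with ground truth
#'
#' Evolves every configured gene independently along a shared true tree,
#' assembles each leaf's genes (some on the minus strand) with random
#' intergenic spacers into a circular annotated genome, and returns both
#' the records and a `truth_set` carrying the tree, the full mutation
#' log, per-gene leaf sequences and a clade assignment (groups of leaves
#' with identical atp9 + nad4l sequences, the pipeline's own clade
#' notion applied to the generator's exact sequences).
#'
#' @param config A [sim_config()].
#' @return List with `records` (list of `mitogenome`) and `truth`.
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    topo <- ape::rtree(config$n_taxa, rooted = TRUE, br = NULL)
    topo$edge.length <- stats::runif(nrow(topo$edge), 0.1, 0.5)
    tree <- topo
  } else if (is.character(tree)) {
    tree <- ape::read.tree(text = tree)
  }
  n <- length(tree$tip.label)
  tree$tip.label <- sprintf("SIM%04d.1", seq_len(n))
  accs <- tree$tip.label

  genes <- names(config$gene_lengths)
  rrna <- intersect(genes, c("rrnl", "rrns"))
  cds <- setdiff(genes, rrna)

  # root sequences
  root_seqs <- lapply(stats::setNames(genes, genes), function(g) {
    if (g %in% cds) random_cds(config$gene_lengths[g], config$gc_target,
                               config$code)
    else paste(random_bases(config$gene_lengths[g], config$gc_target),
               collapse = "")
  })

  # preorder traversal: sequence state per node, events per (gene, edge)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  root <- n + 1L
  log_rows <- list()
  leaf_seqs <- lapply(stats::setNames(genes, genes), function(g) {
    stats::setNames(character(n), accs)
  })
  for (g in genes) {
    rate <- rate_for(config$subst_rate, g)
    ind_rate <- rate_for(config$indel_rate, g)
    syn <- g %in% config$synonymous_only
    state <- vector("list", max(tree$edge))
    state[[root]] <- strsplit(root_seqs[[g]], "")[[1]]
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      t_len <- tree$edge.length[e]
      v <- state[[parent]]
      n_sub <- stats::rpois(1L, rate * length(v) * t_len)
      ms <- mutate_bases(v, n_sub, syn, config$code)
      v <- ms$seq
      ev <- ms$log
      if (ind_rate > 0 && !g %in% rrna) {
        n_ind <- stats::rpois(1L, ind_rate * length(v) * t_len)
        ai <- apply_indels(v, n_ind, config$gc_target)
        v <- ai$seq
        ev <- c(ev, ai$log)
      }
      if (length(ev) > 0) {
        node_lab <- if (child <= n) accs[child] else as.character(child)
        for (o in seq_along(ev)) {
          evo <- ev[[o]]
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            gene = g, node = node_lab, order = o, type = evo$type,
            position = evo$position, from = evo$from, to = evo$to,
            stringsAsFactors = FALSE)
        }
      }
      state[[child]] <- v
    }
    for (i in seq_len(n))
      leaf_seqs[[g]][accs[i]] <- paste(state[[i]], collapse = "")
  }

  # taxon-specific rRNA introns (annotated length varies between taxa)
  if (config$rrna_introns && length(rrna) > 0) {
    for (g in rrna) {
      for (acc in accs) {
        k <- rint(config$intron_count_range[1],
                  config$intron_count_range[2])
        v <- strsplit(leaf_seqs[[g]][acc], "")[[1]]
        for (ii in seq_len(k)) {
          len <- rint(config$intron_length_range[1],
                      config$intron_length_range[2])
          pos <- rint(2L, length(v))
          ins <- random_bases(len, config$gc_target)
          v <- append(v, ins, after = pos - 1L)
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            gene = g, node = acc, order = 1000L + ii, type = "intron",
            position = pos, from = "", to = paste(ins, collapse = ""),
            stringsAsFactors = FALSE)
        }
        leaf_seqs[[g]][acc] <- paste(v, collapse = "")
      }
    }
  }

  # strand assignment fixed across taxa (no rearrangement)
  strands <- stats::setNames(sample(c("+", "-"), length(genes),
                                    replace = TRUE, prob = c(0.7, 0.3)),
                             genes)

  records <- lapply(accs, function(acc) {
    assemble_genome(acc, sprintf("Fungus syntheticus %s", sub("\\.1$", "", acc)),
                    genes, lapply(leaf_seqs, `[[`, acc), strands,
                    rrna, config)
  })
  names(records) <- accs

  mutation_log <- if (length(log_rows) > 0) do.call(rbind, log_rows)
    else data.frame(gene = character(0), node = character(0),
                    order = integer(0), type = character(0),
                    position = integer(0), from = character(0),
                    to = character(0), stringsAsFactors = FALSE)

  clade_of <- clade_assignment(leaf_seqs)

  truth <- structure(list(true_tree = tree, mutation_log = mutation_log,
                          root_seqs = root_seqs, leaf_seqs = leaf_seqs,
                          clade_of = clade_of, config = config),
                     class = "truth_set")
  list(records = records, truth = truth)
}

clade_assignment <- function(leaf_seqs) {
  accs <- names(leaf_seqs[[1]])
  markers <- intersect(c("atp9", "nad4l"), names(leaf_seqs))
  key <- if (length(markers) == 0) rep("", length(accs))
         else do.call(paste, lapply(leaf_seqs[markers], `[`, accs))
  stats::setNames(as.integer(factor(key, levels = unique(key))), accs)
}

assemble_genome <- function(acc, organism, genes, gene_seqs, strands,
                            rrna, config) {
  sp <- config$spacer_length_range
  pieces <- character(0)
  features <- list()
  pos <- 1L
  for (g in genes) {
    spacer <- paste(random_bases(rint(sp[1], sp[2]), config$gc_target),
                    collapse = "")
    pieces <- c(pieces, spacer)
    pos <- pos + nchar(spacer)
    gs <- gene_seqs[[g]]
    genome_piece <- if (strands[g] == "-") reverse_complement(gs) else gs
    features[[length(features) + 1L]] <- new_gene_feature(
      gene_name = g, start = pos, end = pos + nchar(gs) - 1L,
      strand = strands[[g]], sequence = gs,
      kind = if (g %in% rrna) "rRNA" else "CDS")
    pieces <- c(pieces, genome_piece)
    pos <- pos + nchar(gs)
  }
  pieces <- c(pieces, paste(random_bases(rint(sp[1], sp[2]),
                                         config$gc_target), collapse = ""))
  new_mitogenome(acc, organism, paste(pieces, collapse = ""), features,
                 is_circular = TRUE)
}

#' Replay a truth set's mutation log
#'
#' Recomputes every leaf's gene sequence by walking the true tree from
#' the root and applying the logged events in order. Used to verify the
#' log's replay-identity invariant.
#'
#' @param truth A `truth_set`.
#' @return Per-gene named vectors of reconstructed leaf sequences.
#' @export
replay_mutations <- function(truth) {
  tree <- truth$true_tree
  n <- length(tree$tip.label)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  out <- list()
  for (g in names(truth$root_seqs)) {
    lg <- truth$mutation_log[truth$mutation_log$gene == g, , drop = FALSE]
    state <- vector("list", max(tree$edge))
    state[[n + 1L]] <- strsplit(truth$root_seqs[[g]], "")[[1]]
    for (e in seq_len(nrow(edges))) {
      child <- edges[e, 2]
      lab <- if (child <= n) tree$tip.label[child] else as.character(child)
      v <- state[[edges[e, 1]]]
      ev <- lg[lg$node == lab, , drop = FALSE]
      ev <- ev[order(ev$order), , drop = FALSE]
      for (r in seq_len(nrow(ev))) {
        v <- apply_event(v, ev[r, ])
      }
      state[[child]] <- v
    }
    out[[g]] <- stats::setNames(
      vapply(seq_len(n), function(i) paste(state[[i]], collapse = ""), ""),
      tree$tip.label)
  }
  out
}

apply_event <- function(v, ev) {
  if (ev$type == "sub") {
    stopifnot(v[ev$position] == ev$from)
    v[ev$position] <- ev$to
  } else if (ev$type == "del") {
    len <- nchar(ev$from)
    v <- v[-(ev$position:(ev$position + len - 1L))]
  } else {  # ins / intron
    ins <- strsplit(ev$to, "")[[1]]
    v <- append(v, ins, after = ev$position - 1L)
  }
  v
}

#' Plant clade-diagnostic substitutions
#'
#' Overwrites a given base in a given gene for every member of a clade,
#' so the site becomes between-group-diagnostic by construction. Both
#' the records (feature and genome sequence) and the truth set are
#' updated.
#'
#' @param collection List as returned by [simulate_collection()].
#' @param plan List of `list(taxa=, gene=, position=, base=)` entries.
#' @return The modified collection.
#' @export
plant_diagnostics <- function(collection, plan) {
  records <- collection$records
  truth <- collection$truth
  for (p in plan) {
    g <- p$gene
    for (acc in p$taxa) {
      if (!acc %in% names(records))
        stop("unknown accession ", acc, call. = FALSE)
      seq_now <- truth$leaf_seqs[[g]][acc]
      if (p$position < 1 || p$position > nchar(seq_now))
        stop("position ", p$position, " outside gene ", g, call. = FALSE)
      cur <- substr(seq_now, p$position, p$position)
      if (cur == p$base)
        stop("planted base at ", g, ":", p$position, " in ", acc,
             " equals the current base", call. = FALSE)
      lg <- truth$mutation_log
      clash <- lg$gene == g & lg$node == acc & lg$position == p$position &
        lg$type == "sub"
      if (any(clash))
        stop("position collision with an existing mutation at ", g, ":",
             p$position, " in ", acc, call. = FALSE)
      substr(seq_now, p$position, p$position) <- p$base
      truth$leaf_seqs[[g]][acc] <- seq_now
      truth$mutation_log <- rbind(truth$mutation_log, data.frame(
        gene = g, node = acc, order = 2000L + p$position, type = "sub",
        position = p$position, from = cur, to = p$base,
        stringsAsFactors = FALSE))
      records[[acc]] <- update_record_gene(records[[acc]], g, seq_now)
    }
  }
  truth$clade_of <- clade_assignment(truth$leaf_seqs)
  list(records = records, truth = truth)
}

update_record_gene <- function(record, gene, new_seq) {
  idx <- which(vapply(record$features, `[[`, "", "gene_name") == gene)
  stopifnot(length(idx) == 1L)
  f <- record$features[[idx]]
  stopifnot(nchar(new_seq) == nchar(f$sequence))
  f$sequence <- new_seq
  genome_piece <- if (f$strand == "-") reverse_complement(new_seq) else new_seq
  substr(record$sequence, f$start, f$end) <- genome_piece
  record$features[[idx]] <- f
  record
}

#' Clade-structured true tree
#'
#' A genus-scale topology: `n_clades` clades hang off a ladder backbone
#' at `between`-length internal branches, each clade splitting into its
#' taxa over short `within` branches — emulating a genus where samples
#' of one species are nearly identical while species are separated by a
#' few substitutions per short gene.
#'
#' @param n_clades Number of clades.
#' @param taxa_per_clade Taxa in each clade (recycled).
#' @param within Branch length inside clades.
#' @param between Backbone/stem branch length between clades.
#' @return A `phylo` tree (leaf labels are placeholders; the simulator
#'   renames them).
#' @export
clade_tree <- function(n_clades = 4, taxa_per_clade = 3,
                       within = 0.01, between = 1) {
  taxa_per_clade <- rep_len(taxa_per_clade, n_clades)
  idx <- 0L
  clade_nwk <- vapply(seq_len(n_clades), function(k) {
    labs <- sprintf("t%d", idx + seq_len(taxa_per_clade[k]))
    idx <<- idx + taxa_per_clade[k]
    sub <- sprintf("%s:%.6f", labs[1], within)
    for (l in labs[-1])
      sub <- sprintf("(%s,%s:%.6f):%.6f", sub, l, within, within)
    sub
  }, "")
  # ladder backbone
  nwk <- clade_nwk[1]
  for (k in seq_len(n_clades)[-1])
    nwk <- sprintf("(%s,%s:%.6f):%.6f", nwk, clade_nwk[k], between, between)
  ape::read.tree(text = paste0(nwk, ";"))
}
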