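# GenBank flat-file text builder for parser tests, plus small scenario
# builders used across test files.

genbank_text <- function(accession, sequence, features = list(),
                         organism = "Fungus testus", circular = TRUE) {
  topo <- if (circular) "circular" else "linear"
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s   UNA", accession,
            nchar(sequence), topo),
    sprintf("DEFINITION  %s mitochondrion.", organism),
    sprintf("VERSION     %s", accession),
    "SOURCE      mitochondrion",
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers")
  for (f in features) {
    key <- if (is.null(f$key)) "CDS" else f$key
    lines <- c(lines, sprintf("     %-16s%s", key, f$loc),
               sprintf('                     /gene="%s"', f$gene))
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(sequence)
  for (st in seq(1, nchar(s), by = 60)) {
    chunk <- substr(s, st, min(st + 59, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
  }
  c(lines, "//")
}

write_genbank_text <- function(lines) {
  path <- tempfile(fileext = ".gbk")
  writeLines(lines, path)
  path
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# a genus-style collection: 4 clades x 2 taxa, no background divergence,
# clade-diagnostic substitutions planted into the short genes so that
# the screening outcome is fully determined by construction
planted_genus_collection <- function(seed = 7) {
  genes <- c(atp8 = 159, atp9 = 222, nad4l = 267, cob = 1158, rps3 = 1020)
  cfg <- sim_config(tree = clade_tree(4, 2, within = 0, between = 1),
                    gene_lengths = genes, subst_rate = 0,
                    rrna_introns = FALSE, seed = seed)
  sim <- simulate_collection(cfg)
  accs <- sim$truth$true_tree$tip.label
  clades <- split(accs, rep(1:4, each = 2))
  base_at <- function(gene, pos)
    substr(sim$truth$leaf_seqs[[gene]][1], pos, pos)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  plan <- list()
  # distinct diagnostic patterns in atp9/nad4l and the two long genes so
  # that every gene tree separates the same four clades
  for (g in c("atp9", "nad4l", "cob", "rps3")) {
    L <- nchar(sim$truth$leaf_seqs[[g]][1])
    pos <- c(round(L * 0.2), round(L * 0.5), round(L * 0.8))
    for (k in 2:4) {
      for (p in pos[seq_len(k - 1)]) {
        plan[[length(plan) + 1]] <- list(
          taxa = clades[[k]], gene = g, position = p,
          base = other(base_at(g, p)))
      }
    }
  }
  planted <- plant_diagnostics(sim, plan)
  list(records = planted$records, truth = planted$truth,
       clades = clades,
       config = screening_config(core_genes = names(genes),
                                 candidates = names(genes)))
}
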