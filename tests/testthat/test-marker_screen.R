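test_that("the concatenated reference tree recovers the true topology", {
  sim <- simulate_collection(sim_config(n_taxa = 9, subst_rate = 0.01,
                                        seed = 51))
  ref <- build_reference_tree(sim$records)
  expect_equal(rf_distance(ref, sim$truth$true_tree), 0)
})

test_that("three records give a valid three-leaf tree", {
  sim <- simulate_collection(sim_config(
    n_taxa = 3, gene_lengths = c(atp9 = 222, nad4l = 267),
    subst_rate = 0.02, rrna_introns = FALSE, seed = 52))
  cfg <- screening_config(core_genes = c("atp9", "nad4l"),
                          candidates = c("atp9", "nad4l"))
  tr <- build_reference_tree(sim$records, cfg)
  expect_length(tr$tip.label, 3)
  expect_setequal(tr$tip.label, names(sim$records))
})

test_that("records missing a core gene are dropped with a message", {
  sim <- simulate_collection(sim_config(
    n_taxa = 5, gene_lengths = c(atp9 = 222, nad4l = 267, rps3 = 1020),
    subst_rate = 0.02, rrna_introns = FALSE, seed = 53))
  records <- sim$records
  # delete rps3 from one record
  drop_acc <- names(records)[2]
  keep <- vapply(records[[drop_acc]]$features, function(f)
    f$gene_name != "rps3", TRUE)
  records[[drop_acc]]$features <- records[[drop_acc]]$features[keep]
  cfg <- screening_config(core_genes = c("atp9", "nad4l", "rps3"),
                          candidates = c("atp9", "nad4l", "rps3"))
  expect_message(tr <- build_reference_tree(records, cfg), drop_acc)
  expect_false(drop_acc %in% tr$tip.label)
  expect_error(build_reference_tree(records[1:3][c(1, 2)], cfg),
               "fewer than 3")
})

test_that("planted genus scenario selects the short diagnostic genes only", {
  fx <- planted_genus_collection()
  scr <- screen_markers(fx$records, fx$config)
  expect_setequal(selected_markers(scr), c("atp9", "nad4l"))
  # ranking: selected first, by ascending length
  expect_equal(scr$gene[1:2], c("atp9", "nad4l"))
  # the zero-variation 159 bp gene can never be selected
  atp8 <- scr[scr$gene == "atp8", ]
  expect_equal(atp8$verdict, "excluded_insufficient_resolution")
  expect_equal(atp8$interspecies_diagnostic_sites, 0)
  # concordant long genes are candidates, not barcodes
  expect_true(all(scr$verdict[scr$gene %in% c("cob", "rps3")] ==
                    "candidate"))
  # every selected gene satisfies the verdict invariant
  sel <- scr[scr$verdict == "selected", ]
  expect_true(all(sel$rf_vs_reference == 0))
  expect_true(all(sel$interspecies_diagnostic_sites >= 1))
  expect_true(all(sel$median_length_bp <= fx$config$max_barcode_length))
  expect_true(all(sel$length_stable))
})

test_that("an InDel-laden gene is excluded as too variable", {
  sim <- simulate_collection(sim_config(
    n_taxa = 6,
    gene_lengths = c(atp9 = 222, nad4l = 267, nad5 = 1983),
    subst_rate = 0.01, indel_rate = c(nad5 = 0.003),
    rrna_introns = FALSE, seed = 54))
  cfg <- screening_config(core_genes = c("atp9", "nad4l"),
                          candidates = c("atp9", "nad4l", "nad5"))
  scr <- screen_markers(sim$records, cfg)
  expect_equal(scr$verdict[scr$gene == "nad5"],
               "excluded_too_long_variable")
  expect_gt(scr$indel_columns[scr$gene == "nad5"], 0)
})

test_that("intron-bearing rRNA genes are excluded as length-unstable", {
  sim <- simulate_collection(sim_config(
    n_taxa = 6,
    gene_lengths = c(atp9 = 222, nad4l = 267, rrnl = 2300, rrns = 1700),
    subst_rate = 0.01, rrna_introns = TRUE, seed = 55))
  cfg <- screening_config(core_genes = c("atp9", "nad4l"))
  scr <- screen_markers(sim$records, cfg)
  expect_equal(scr$verdict[scr$gene == "rrnl"], "excluded_length_unstable")
  expect_equal(scr$verdict[scr$gene == "rrns"], "excluded_length_unstable")
})

test_that("screening output is deterministic", {
  fx <- planted_genus_collection()
  s1 <- screen_markers(fx$records, fx$config)
  s2 <- screen_markers(fx$records, fx$config)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("a gene with zero substitutions is never selected across replicates", {
  for (seed in 1:5) {
    sim <- simulate_collection(sim_config(
      n_taxa = 6,
      gene_lengths = c(atp8 = 159, atp9 = 222, nad4l = 267),
      subst_rate = c(atp8 = 0, atp9 = 0.02, nad4l = 0.02),
      rrna_introns = FALSE, seed = 600 + seed))
    cfg <- screening_config(core_genes = c("atp8", "atp9", "nad4l"),
                            candidates = c("atp8", "atp9", "nad4l"))
    scr <- screen_markers(sim$records, cfg)
    expect_false("atp8" %in% selected_markers(scr))
  }
})

test_that("zero-SNP clades partition the taxa as the generator says", {
  fx <- planted_genus_collection()
  scr <- screen_markers(fx$records, fx$config)
  msas <- attr(scr, "msas")[selected_markers(scr)]
  ref <- attr(scr, "reference_tree")
  clades <- assign_clades(ref, msas)
  got <- stats::setNames(clades$clade_id, clades$accession)
  truth <- fx$truth$clade_of
  # same partition (ids may be permuted)
  expect_equal(length(unique(got)), length(unique(truth)))
  for (cid in unique(truth)) {
    members <- names(truth)[truth == cid]
    expect_length(unique(got[members]), 1)
  }
})

test_that("all-identical markers give one clade; a private SNP a singleton", {
  sim <- simulate_collection(sim_config(
    n_taxa = 4, gene_lengths = c(atp9 = 222, nad4l = 267),
    subst_rate = 0, rrna_introns = FALSE, seed = 56))
  m <- list(atp9 = msa(sim$truth$leaf_seqs$atp9),
            nad4l = msa(sim$truth$leaf_seqs$nad4l))
  tr <- nj_tree(p_distance_matrix(concat_alignment(m)))
  cl <- assign_clades(tr, m)
  expect_equal(length(unique(cl$clade_id)), 1)

  accs <- names(sim$records)
  cur <- substr(sim$truth$leaf_seqs$atp9[1], 10, 10)
  planted <- plant_diagnostics(sim, list(
    list(taxa = accs[4], gene = "atp9", position = 10,
         base = setdiff(c("A", "C", "G", "T"), cur)[1])))
  m2 <- list(atp9 = msa(planted$truth$leaf_seqs$atp9),
             nad4l = msa(planted$truth$leaf_seqs$nad4l))
  tr2 <- nj_tree(p_distance_matrix(concat_alignment(m2)))
  cl2 <- assign_clades(tr2, m2)
  expect_equal(length(unique(cl2$clade_id)), 2)
  expect_equal(sum(cl2$clade_id == cl2$clade_id[cl2$accession == accs[4]]),
               1)
  expect_error(assign_clades(tr2, list(atp9 = m2$atp9[1:3])), "lacks")
})

test_that("per-clade SNP reports against the standard carry counts and labels", {
  fx <- planted_genus_collection()
  scr <- screen_markers(fx$records, fx$config)
  msas <- attr(scr, "msas")[c("atp9", "nad4l")]
  ref <- attr(scr, "reference_tree")
  standard <- fx$clades[[1]][1]
  clades <- assign_clades(ref, msas, reference = standard)
  rep_tab <- snps_vs_standard(clades, standard, msas)
  std_row <- rep_tab[rep_tab$clade_id ==
                       clades$clade_id[clades$accession == standard], ]
  expect_equal(std_row$snps_atp9, 0)
  expect_equal(std_row$snps_nad4l, 0)
  # the genus fixture plants 1, 2, 3 diffs in successive clades: counts
  # must be non-decreasing with divergence from the standard clade
  expect_equal(sort(rep_tab$snps_atp9), c(0, 1, 2, 3))
  expect_equal(sort(rep_tab$snps_nad4l), c(0, 1, 2, 3))
  expect_error(snps_vs_standard(clades, "NOPE", msas), "absent")
})
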