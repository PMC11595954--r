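test_that("identity alignment has no gaps and full match score", {
  sc <- default_scoring()
  pa <- global_align("ACGT", "ACGT", sc)
  expect_equal(pa$a, "ACGT")
  expect_equal(pa$b, "ACGT")
  expect_equal(pa$score, 4 * sc$match)
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("the paired single-base InDel reading of ATATTA/ATTCTA is co-optimal", {
  sc <- default_scoring()
  opt <- global_align("ATATTA", "ATTCTA", sc)$score
  # the two-InDel presentation: 5 matches, two 1-base gap runs, 0 mismatches
  expect_equal(alignment_score("ATAT-TA", "AT-TCTA", sc), opt)
  placement <- structure(list(a = "ATAT-TA", b = "AT-TCTA", score = opt,
                              labels = c("a", "b")),
                         class = "pairwise_alignment")
  vs <- count_variants(placement)
  expect_equal(vs$snp_count, 0)
  expect_equal(vs$indel_site_count, 2)
  expect_equal(vs$gap_base_count, 2)
})

test_that("global alignment score equals exhaustive enumeration", {
  sc <- default_scoring()
  # every pair over {A,C} up to length 4, exhaustively
  strs <- unlist(lapply(1:4, function(L) {
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")
  }))
  for (a in strs) {
    for (b in strs) {
      expect_equal(global_align(a, b, sc)$score,
                   brute_force_align_score(a, b, sc),
                   info = paste(a, b))
    }
  }
  # sampled longer pairs over the full alphabet
  set.seed(21)
  for (rep in 1:200) {
    a <- random_dna(sample(3:6, 1))
    b <- random_dna(sample(3:6, 1))
    expect_equal(global_align(a, b, sc)$score,
                 brute_force_align_score(a, b, sc), info = paste(a, b))
  }
})

test_that("alignments never produce gap/gap columns and ungap to the inputs", {
  set.seed(22)
  for (rep in 1:50) {
    a <- random_dna(sample(5:40, 1))
    b <- random_dna(sample(5:40, 1))
    pa <- global_align(a, b)
    expect_equal(nchar(pa$a), nchar(pa$b))
    va <- strsplit(pa$a, "")[[1]]; vb <- strsplit(pa$b, "")[[1]]
    expect_false(any(va == "-" & vb == "-"))
    expect_equal(gsub("-", "", pa$a), a)
    expect_equal(gsub("-", "", pa$b), b)
  }
})

test_that("msa of identical or substitution-only sequences is the column stack", {
  s3 <- c(x = "ACGTACGT", y = "ACGTACGT", z = "ACGTACGT")
  m <- msa(s3)
  expect_equal(msa_width(m), 8)
  expect_false(any(grepl("-", unclass(m), fixed = TRUE)))
  expect_error(msa(s3[1]), "at least 2")

  # 52 simulated orthologs, substitutions only -> gap-free width 222
  sim <- simulate_collection(sim_config(
    n_taxa = 52, gene_lengths = c(atp9 = 222), subst_rate = 0.01,
    rrna_introns = FALSE, seed = 13))
  m52 <- msa(sim$truth$leaf_seqs$atp9)
  expect_equal(msa_width(m52), 222)
  expect_false(any(grepl("-", unclass(m52), fixed = TRUE)))
})

test_that("two-sequence msa equals the pairwise alignment columns", {
  a <- "ACGTACGTAA"; b <- "ACGTCGTAA"   # one deletion
  pa <- global_align(a, b)
  m <- msa(c(s1 = a, s2 = b))
  expect_equal(unname(unclass(m)["s1"]), pa$a)
  expect_equal(unname(unclass(m)["s2"]), pa$b)
})

test_that("progressive msa handles length-variable sequences", {
  set.seed(30)
  core <- random_dna(120)
  seqs <- c(
    a = core,
    b = paste0(substr(core, 1, 50), "ACGTACGT", substr(core, 51, 120)),
    c = paste0(substr(core, 1, 80), substr(core, 87, 120)),
    d = core)
  m <- msa(seqs)
  expect_equal(length(unique(nchar(unclass(m)))), 1)
  for (nm in names(seqs))
    expect_equal(gsub("-", "", unclass(m)[[nm]]), unname(seqs[nm]))
})

test_that("count_variants reports SNPs, gaps and reference positions", {
  pa <- global_align(paste(rep("ACGT", 8), collapse = ""),
                     paste(rep("ACGT", 8), collapse = ""))
  vs <- count_variants(pa)
  expect_equal(vs$snp_count, 0)
  expect_equal(vs$gap_base_count, 0)

  # planted mismatch with the clade-style position label
  a <- random_dna(100)
  b <- a
  substr(b, 69, 69) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 69, 69))[1]
  vs2 <- count_variants(global_align(a, b))
  expect_equal(vs2$snp_count, 1)
  expect_equal(vs2$snp_positions$pos, 69)
  expect_match(vs2$snp_positions$label, "at 69$")
})

test_that("variant counts are symmetric in the reference choice", {
  set.seed(23)
  for (rep in 1:20) {
    a <- random_dna(60)
    # derive b from a so the pair is alignable, with real indels
    b <- paste0(substr(a, 1, 20), substr(a, 25, 60), random_dna(3))
    pa <- global_align(a, b)
    v1 <- count_variants(pa, reference = 1)
    v2 <- count_variants(pa, reference = 2)
    expect_equal(v1$snp_count, v2$snp_count)
    expect_equal(v1$gap_base_count, v2$gap_base_count)
    expect_equal(v1$indel_site_count, v2$indel_site_count)
  }
})

test_that("N columns are excluded from SNP counts and tallied as ambiguous", {
  pa <- structure(list(a = "ANGT", b = "AAGA", score = 0,
                       labels = c("a", "b")), class = "pairwise_alignment")
  vs <- count_variants(pa)
  expect_equal(vs$snp_count, 1)      # T/A at position 4 only
  expect_equal(vs$ambiguous_count, 1)
})

test_that("snp counts on substitution-only simulations match a direct count", {
  sim <- simulate_collection(sim_config(
    n_taxa = 6, gene_lengths = c(atp9 = 222, nad4l = 267),
    subst_rate = 0.03, indel_rate = 0, rrna_introns = FALSE, seed = 17))
  for (g in c("atp9", "nad4l")) {
    seqs <- sim$truth$leaf_seqs[[g]]
    for (i in 1:5) {
      for (j in (i + 1):6) {
        vs <- count_variants(global_align(seqs[i], seqs[j]))
        expect_equal(vs$snp_count, hamming_resolved(seqs[[i]], seqs[[j]]))
        expect_equal(vs$gap_base_count, 0)
      }
    }
  }
})

test_that("variable_sites classifies invariant, polymorphic and diagnostic columns", {
  m0 <- msa(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_true(all(variable_sites(m0, c(a = 1, b = 1, c = 2)) == "invariant"))

  # one fixed between-group difference
  m1 <- msa(c(a = "ACGT", b = "ACGT", c = "AGGT", d = "AGGT"))
  cls <- variable_sites(m1, c(a = "g1", b = "g1", c = "g2", d = "g2"))
  expect_equal(sum(cls == "between_group_diagnostic"), 1)
  expect_equal(which(cls == "between_group_diagnostic"), 2)

  # within-group polymorphism is not diagnostic
  m2 <- msa(c(a = "ACGT", b = "ATGT", c = "AGGT", d = "AGGT"))
  cls2 <- variable_sites(m2, c(a = "g1", b = "g1", c = "g2", d = "g2"))
  expect_equal(unname(cls2[2]), "within_group_variable")

  expect_error(variable_sites(m1, c(a = 1, b = 1, c = 2)), "without a group")
})

test_that("a three-species fixture with two planted differences shows two diagnostic sites", {
  cfg <- sim_config(tree = clade_tree(3, 2, within = 0, between = 1),
                    gene_lengths = c(atp8 = 159), subst_rate = 0,
                    rrna_introns = FALSE, seed = 5)
  sim <- simulate_collection(cfg)
  accs <- sim$truth$true_tree$tip.label
  cur <- function(p) substr(sim$truth$leaf_seqs$atp8[1], p, p)
  alt <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  planted <- plant_diagnostics(sim, list(
    list(taxa = accs[3:4], gene = "atp8", position = 40, base = alt(cur(40))),
    list(taxa = accs[5:6], gene = "atp8", position = 90, base = alt(cur(90)))))
  m <- msa(planted$truth$leaf_seqs$atp8)
  groups <- stats::setNames(rep(1:3, each = 2), accs)
  cls <- variable_sites(m, groups)
  expect_equal(sum(cls == "between_group_diagnostic"), 2)
  expect_setequal(which(cls == "between_group_diagnostic"), c(40, 90))
})
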