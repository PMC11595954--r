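test_that("p-distances match a direct per-pair count", {
  m <- msa(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  D <- p_distance_matrix(m)
  expect_true(all(D[upper.tri(D)] == 0))

  rows <- c(x = paste(rep("A", 222), collapse = ""),
            y = paste(c(rep("A", 221), "G"), collapse = ""))
  D2 <- p_distance_matrix(msa(rows))
  expect_equal(D2["x", "y"], 1 / 222)

  set.seed(31)
  seqs <- stats::setNames(replicate(5, random_dna(80)), letters[1:5])
  D3 <- p_distance_matrix(as_msa(seqs))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(D3[i, j],
                   hamming_resolved(seqs[[i]], seqs[[j]]) / 80)
    }
  }
})

test_that("gap modes differ in which columns a pair compares", {
  m <- as_msa(c(a = "ACGTA", b = "AC-TA", c = "ACGTT"))
  Dp <- p_distance_matrix(m, "pairwise_deletion")
  Dc <- p_distance_matrix(m, "complete_deletion")
  expect_equal(Dp["a", "c"], 1 / 5)   # all five columns comparable
  expect_equal(Dc["a", "c"], 1 / 4)   # gap column dropped for everyone
  # Jukes-Cantor correction exceeds p for nonzero distances
  Dj <- p_distance_matrix(m, "pairwise_deletion", model = "jc")
  expect_gt(Dj["a", "c"], Dp["a", "c"])
})

test_that("three-taxon NJ solves the exact closed form", {
  D <- as_distance_matrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
                                 dimnames = list(c("a", "b", "c"),
                                                 c("a", "b", "c"))))
  tr <- nj_tree(D)
  # closed form: la = (dab + dac - dbc)/2 etc.
  lens <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(unname(lens["a"]), 1)
  expect_equal(unname(lens["b"]), 2)
  expect_equal(unname(lens["c"]), 3)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers a 5-taxon additive matrix against a least-squares oracle", {
  set.seed(32)
  for (rep in 1:5) {
    true <- ape::rtree(5, br = function(n) stats::runif(n, 0.3, 1))
    D <- as_distance_matrix(ape::cophenetic.phylo(true))
    inferred <- nj_tree(D)
    # oracle: the true topology minimizes least-squares residual over
    # all 15 unrooted 5-leaf topologies
    topos <- all_unrooted_topologies(sort(true$tip.label))
    expect_length(topos, 15)
    res <- vapply(topos, ls_tree_residual, 0, D = D)
    best <- topos[[which.min(res)]]
    expect_lt(min(res), 1e-12)
    expect_equal(rf_distance(inferred, best), 0)
    expect_equal(rf_distance(inferred, true), 0)
  }
})

test_that("NJ is consistent on additive matrices from random binary trees", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    D <- as_distance_matrix(ape::cophenetic.phylo(true))
    expect_equal(rf_distance(nj_tree(D), true), 0)
  }
})

test_that("native NJ agrees with an independent NJ implementation", {
  # continuous perturbed-additive matrices: no exact Q ties, so both
  # implementations must settle on the same topology
  set.seed(34)
  for (rep in 1:10) {
    true <- ape::rtree(7, br = function(k) stats::runif(k, 0.2, 1))
    D <- ape::cophenetic.phylo(true)
    noise <- matrix(stats::runif(49, 0, 0.01), 7, 7)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    D <- as_distance_matrix(D + noise)
    ours <- nj_tree(D)
    theirs <- ape::nj(stats::as.dist(unclass(D)))
    expect_equal(rf_distance(ours, theirs), 0)
  }
})

test_that("rf_distance equals brute-force bipartition comparison", {
  t1 <- ape::rtree(6)
  expect_equal(rf_distance(t1, t1), 0)

  q1 <- ape::read.tree(text = "((a,b),(c,d));")
  q2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(q1, q2), 2)

  set.seed(35)
  for (rep in 1:40) {
    n <- sample(4:7, 1)
    a <- ape::rtree(n, tip.label = letters[1:n])
    b <- ape::rtree(n, tip.label = letters[1:n])
    expect_equal(rf_distance(a, b), brute_force_rf(a, b))
  }
})

test_that("rf_distance on all 4- and 5-leaf binary topology pairs matches the oracle", {
  for (n in 4:5) {
    topos <- all_unrooted_topologies(letters[1:n])
    for (i in seq_along(topos)) {
      for (j in seq_along(topos)) {
        expect_equal(rf_distance(topos[[i]], topos[[j]]),
                     brute_force_rf(topos[[i]], topos[[j]]))
      }
    }
  }
})

test_that("rf_distance is a metric and errors on mismatched leaf sets", {
  set.seed(36)
  trees <- replicate(3, ape::rtree(6, tip.label = letters[1:6]),
                     simplify = FALSE)
  for (i in 1:3) {
    for (j in 1:3) {
      dij <- rf_distance(trees[[i]], trees[[j]])
      expect_gte(dij, 0)
      expect_equal(dij, rf_distance(trees[[j]], trees[[i]])) # symmetry
    }
  }
  # triangle inequality, spot-checked
  d12 <- rf_distance(trees[[1]], trees[[2]])
  d23 <- rf_distance(trees[[2]], trees[[3]])
  d13 <- rf_distance(trees[[1]], trees[[3]])
  expect_lte(d13, d12 + d23)
  # normalized form bounded by 1
  expect_lte(rf_distance(trees[[1]], trees[[2]], normalized = TRUE), 1)

  other <- ape::rtree(6, tip.label = LETTERS[1:6])
  expect_error(rf_distance(trees[[1]], other), "leaf sets differ")
})

test_that("concatenation sums block widths and tracks provenance", {
  a <- as_msa(stats::setNames(replicate(3, random_dna(222)), c("x", "y", "z")))
  b <- as_msa(stats::setNames(replicate(3, random_dna(267)), c("x", "y", "z")))
  super <- concat_alignment(list(atp9 = a, nad4l = b))
  expect_equal(msa_width(super), 489)
  expect_equal(attr(super, "blocks")$width, c(222, 267))

  one <- concat_alignment(list(atp9 = a))
  expect_equal(unclass(one)[names(a)], unclass(a)[names(a)])

  lens <- default_gene_lengths()[CORE_GENES]
  blocks <- lapply(lens, function(L)
    as_msa(stats::setNames(replicate(3, random_dna(L)), c("x", "y", "z"))))
  expect_equal(msa_width(concat_alignment(blocks)), sum(lens))

  bad <- as_msa(stats::setNames(replicate(3, random_dna(50)), c("x", "y", "w")))
  expect_error(concat_alignment(list(a, bad)), "same taxa")
})

test_that("newick text round-trips topology and branch lengths", {
  t1 <- newick_read("(a:1,b:1,(c:1,d:1):1);")
  txt <- newick_write(t1)
  t2 <- newick_read(txt)
  expect_equal(rf_distance(t1, t2), 0)
  expect_equal(sort(t2$edge.length), sort(t1$edge.length))

  tq <- newick_read("('taxon one':1,'taxon two':2,(c:1,d:1):1);")
  expect_true("taxon one" %in% tq$tip.label)

  set.seed(37)
  big <- ape::rtree(50)
  p <- tempfile(fileext = ".nwk")
  newick_write(big, p)
  back <- newick_read(path = p)
  expect_equal(rf_distance(big, back), 0)
  expect_equal(sort(back$edge.length), sort(big$edge.length),
               tolerance = 1e-6)
  expect_error(newick_read("((a,b);"), "parse")
})

test_that("the concatenated tree recovers truth at least as often as any single gene", {
  genes <- c(atp9 = 222, nad4l = 267, nad3 = 360, rps3 = 1020, cob = 1158)
  hits <- vapply(1:50, function(r) {
    sim <- simulate_collection(sim_config(
      n_taxa = 6, gene_lengths = genes, subst_rate = 0.01,
      rrna_introns = FALSE, seed = 7000 + r))
    blocks <- lapply(sim$truth$leaf_seqs, msa)
    recover <- function(m)
      rf_distance(nj_tree(p_distance_matrix(m)), sim$truth$true_tree) == 0
    c(concat = recover(concat_alignment(blocks)),
      vapply(blocks, recover, TRUE))
  }, c(concat = TRUE, stats::setNames(rep(TRUE, length(genes)),
                                      names(genes))))
  rates <- rowMeans(hits)
  expect_true(all(rates["concat"] >= rates[names(genes)]))
})
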