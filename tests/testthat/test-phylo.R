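test_that("p-distance counts differing comparable sites", {
  expect_equal(p_distance("ACGT", "ACGA")$distance, 0.25)
  expect_equal(p_distance("ACGT", "ACGT")$distance, 0)
  r <- p_distance("AC-T", "ACGT")
  expect_equal(r$distance, 0)
  expect_equal(r$comparable_sites, 3)
  expect_true(is.na(p_distance("----", "AC-T")$distance))
})

test_that("K2P distance matches its closed form and flags saturation", {
  # P = 0.25, Q = 0 on four sites: one transition
  r <- k2p_distance("ACGT", "GCGT")
  expect_equal(r$P, 0.25)
  expect_equal(r$Q, 0)
  expect_equal(r$distance, -0.5 * log(0.5), tolerance = 1e-9)
  expect_equal(round(r$distance, 6), 0.346574)

  # P = 0.1, Q = 0.05 over 100 sites
  ref <- strrep("A", 100)
  qry <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  r2 <- k2p_distance(qry, ref)
  expect_equal(r2$P, 0.1)
  expect_equal(r2$Q, 0.05)
  expect_equal(r2$distance, -0.5 * log(0.75) - 0.25 * log(0.9),
               tolerance = 1e-12)
  expect_lt(abs(r2$distance - 0.170182), 1e-6)

  expect_equal(k2p_distance("ACGT", "ACGT")$distance, 0)

  # saturated pair: transitions at over half the sites
  sat <- k2p_distance(strrep("A", 10), strrep("G", 10))
  expect_true(sat$saturated)
  expect_true(is.na(sat$distance))
})

test_that("K2P is never below p-distance where both are defined", {
  set.seed(71)
  for (i in 1:50) {
    a <- random_dna(200)
    b <- mutate_frac(a, runif(1, 0.01, 0.3), seed = i)
    k <- k2p_distance(a, b)
    if (k$saturated) next
    expect_gte(k$distance + 1e-12, p_distance(a, b)$distance)
  }
})

test_that("distance matrices agree with ape::dist.dna", {
  set.seed(72)
  base <- random_dna(300)
  aln <- c(s1 = base,
           s2 = mutate_frac(base, 0.05, 1),
           s3 = mutate_frac(base, 0.10, 2),
           s4 = mutate_frac(base, 0.20, 3))
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(aln), ""), identity)))

  d_p <- dist_rdna(aln, model = "p", deletion = "pairwise")
  ref_p <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
  expect_equal(matrix(d_p, 4, 4), matrix(ref_p, 4, 4), tolerance = 1e-12)

  d_k <- dist_rdna(aln, model = "k2p", deletion = "pairwise")
  ref_k <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(matrix(d_k, 4, 4), matrix(ref_k, 4, 4), tolerance = 1e-9)
})

test_that("complete deletion drops columns gapped in any sequence", {
  aln <- c(a = "ACGTA", b = "AC-TA", c = "ACGTT")
  d_complete <- dist_rdna(aln, model = "p", deletion = "complete")
  # column 3 removed for everyone: 4 comparable sites
  expect_equal(attr(d_complete, "sites")["a", "b"], 4L)
  expect_equal(d_complete["a", "c"], 0.25)  # 1 diff / 4 sites
  d_pair <- dist_rdna(aln, model = "p", deletion = "pairwise")
  expect_equal(d_pair["a", "c"], 0.2)       # 1 diff / 5 sites
})

test_that("average p-distance is the mean over unordered pairs", {
  expect_equal(average_p_distance(c(a = "ACGT", b = "ACGT")), 0)
  aln <- c(a = "AAAA", b = "AAAT", c = "AATT")
  # pairwise distances 0.25, 0.5, 0.25
  expect_equal(average_p_distance(aln), mean(c(0.25, 0.5, 0.25)))
  expect_true(is.na(average_p_distance(c(a = "ACGT"))))
})

test_that("NJ recovers a 4-taxon additive tree with exact branch lengths", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(ids, ids))
  tree <- nj_tree(d)
  expect_s3_class(tree, "phylo")
  # split AB|CD present
  purity <- clade_purity(tree, c(A = "functional", B = "functional",
                                 C = "pseudogene", D = "pseudogene"))
  expect_true(purity$is_bipartition_separating)
  # path lengths reproduce the input distances exactly (additivity)
  coph <- ape::cophenetic.phylo(tree)[ids, ids]
  expect_equal(unname(coph), unname(d), tolerance = 1e-9)
})

test_that("three taxa resolve to the unique star with exact lengths", {
  d <- matrix(c(0, 2, 3,
                2, 0, 3,
                3, 3, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- nj_tree(d)
  coph <- ape::cophenetic.phylo(tree)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(unname(coph), unname(d), tolerance = 1e-9)
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
})

test_that("NJ reproduces random additive topologies and matches ape", {
  set.seed(73)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(gen)
    ids <- sort(rownames(d))
    d <- d[ids, ids]
    tree <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(gen), tree), 0,
                 ignore_attr = TRUE, info = paste("case", i))
    # independent oracle: ape's own NJ on the same matrix
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ref, tree), 0, ignore_attr = TRUE)
  }
})

test_that("undefined distances abort NJ with the offending pair named", {
  d <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_error(nj_tree(d), "a-b")
})

test_that("bootstrap supports are deterministic and permutation-invariant", {
  u <- small_unit()
  sub <- unit_subunit_seq(u, "18S")
  aln <- c(f1 = sub, f2 = sub)
  for (i in 1:3)
    aln[paste0("p", i)] <- apply_rip(sub, uniform_rip(0.2,
                                                      seed = 80 + i))$sequence
  b1 <- bootstrap_support(aln, model = "k2p", n_replicates = 50, seed = 5)
  b2 <- bootstrap_support(aln, model = "k2p", n_replicates = 50, seed = 5)
  expect_identical(b1$splits, b2$splits)

  perm <- aln[c(3, 1, 5, 2, 4)]
  b3 <- bootstrap_support(perm, model = "k2p", n_replicates = 50, seed = 5)
  m1 <- setNames(b1$splits$support, b1$splits$key)
  m3 <- setNames(b3$splits$support, b3$splits$key)
  shared <- intersect(names(m1), names(m3))
  expect_setequal(names(m1), names(m3))
  expect_equal(m1[shared], m3[shared])
})

test_that("clade purity detects exact and near separations", {
  t1 <- ape::read.tree(text = "((p1:1,p2:1):1,(f1:1,f2:1):1);")
  r1 <- clade_purity(t1, c(p1 = "pseudogene", p2 = "pseudogene",
                           f1 = "functional", f2 = "functional"))
  expect_true(r1$is_bipartition_separating)
  expect_equal(r1$best_split_impurity, 0)

  t2 <- ape::read.tree(text = "((p1:1,f1:1):1,(p2:1,f2:1):1);")
  r2 <- clade_purity(t2, c(p1 = "pseudogene", p2 = "pseudogene",
                           f1 = "functional", f2 = "functional"))
  expect_false(r2$is_bipartition_separating)
  expect_equal(r2$best_split_impurity, 1)

  expect_error(clade_purity(t1, c(p1 = "pseudogene")), "unlabeled")
})

test_that("functional and RIPped clades separate with strong support", {
  u <- small_unit()
  sub <- unit_subunit_seq(u, "18S")
  aln <- setNames(rep(sub, 3), paste0("f", 1:3))
  for (i in 1:4)
    aln[paste0("p", i)] <- apply_rip(sub, uniform_rip(0.2,
                                                      seed = 90 + i))$sequence
  bs <- bootstrap_support(aln, model = "k2p", n_replicates = 100, seed = 3)
  labels <- setNames(c(rep("functional", 3), rep("pseudogene", 4)),
                     names(aln))
  purity <- clade_purity(bs$tree, labels)
  expect_true(purity$is_bipartition_separating)
  key <- paste(sort(paste0("p", 1:4)), collapse = "|")
  expect_gte(bs$splits$support[bs$splits$key == key], 95)
})
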