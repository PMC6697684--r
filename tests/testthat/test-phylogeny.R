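test_that("p-distance is the mismatch proportion; deletion modes differ only with gaps", {
  aln <- aln_from_strings(a = "ACGT", b = "ACGA")
  expect_equal(p_distance(aln)[1, 2], 0.25)
  expect_equal(p_distance(aln_from_strings(a = "ACGT", b = "ACGT"))[1, 2], 0)
  # gap-free: pairwise and complete deletion identical
  expect_equal(p_distance(aln, "pairwise"), p_distance(aln, "complete"))
  # with a gap in c, complete deletion drops the column for all pairs
  g <- aln_from_strings(a = "ACGT", b = "ACGA", c = "ACG-")
  expect_equal(p_distance(g, "pairwise")[1, 2], 0.25)
  expect_equal(p_distance(g, "complete")[1, 2], 0)
})

test_that("K2P distance matches its closed form and dominates the p-distance", {
  # 100 sites, 10 transitions, 5 transversions: P = 0.1, Q = 0.05
  x <- rep("A", 100); y <- x
  y[1:10] <- "G"; y[11:15] <- "C"
  aln <- rbind(a = x, b = y)
  closed <- -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05)
  expect_equal(k2p_distance(aln)[1, 2], closed, tolerance = 1e-12)
  expect_equal(k2p_distance(aln_from_strings(a = "ACGT", b = "ACGT"))[1, 2], 0)
  # Jensen-type property on random alignments
  for (seed in 1:5) {
    spec <- alignment_spec(n_taxa = 6, length = 200, n_variable = 30,
                           n_informative = 10, ts = 12, tv = 18, seed = seed,
                           informative_clades = list(sprintf("t%02d", 1:2)))
    m <- simulate_alignment(spec)$alignment
    expect_true(all(k2p_distance(m) >= p_distance(m) - 1e-12))
  }
})

test_that("NJ solves the 3-taxon closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  got <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(got, d, tolerance = 1e-12)
  # pendant lengths: a = (dAB + dAC - dBC)/2 = 1, b = 2, c = 3
  tips <- tr$edge[, 2] <= 3
  lens <- tr$edge.length[tips][order(tr$tip.label[tr$edge[tips, 2]])]
  expect_equal(lens, c(1, 2, 3))
})

test_that("NJ recovers a 4-taxon additive tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 3
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 4
  d["C", "D"] <- d["D", "C"] <- 4
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  expect_true(is_monophyletic(root_with_outgroup(tr, "D"), c("A", "B")))
  expect_equal(attr(tr, "clamped_branches"), 0L)
})

test_that("NJ agrees with an independent implementation on random matrices", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    tr0 <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr0)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    mine <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(mine, ref)), 0)
  }
})

test_that("NJ topology on an ultrametric matrix equals single linkage", {
  set.seed(5)
  for (i in 1:3) {
    tr0 <- ape::rcoal(6)
    d <- ape::cophenetic.phylo(tr0)
    sl <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "single"))
    expect_equal(as.numeric(ape::dist.topo(nj_tree(d), ape::unroot(sl))), 0)
  }
})

test_that("NJ validates its input and clamps negative branch lengths", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(d), "three taxa")
  bad <- matrix(runif(16), 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_error(nj_tree(bad), "symmetric|diagonal")
  set.seed(2)
  for (i in 1:20) {   # noisy non-additive matrices: lengths never negative
    d0 <- as.matrix(stats::dist(matrix(runif(10), 5)))
    dimnames(d0) <- list(letters[1:5], letters[1:5])
    tr <- nj_tree(d0)
    expect_true(all(tr$edge.length >= 0))
    expect_true(is.numeric(attr(tr, "clamped_branches")))
  }
})

test_that("Newick output round-trips topology, lengths and supports", {
  fix <- miscanthus_fixture()
  bt <- bootstrap_support(fix$alignment, n_reps = 25, seed = 2)
  s <- write_newick(bt, digits = 6)
  back <- ape::read.tree(text = s)
  expect_equal(as.numeric(ape::dist.topo(back, bt)), 0)
  expect_equal(sort(back$tip.label), sort(bt$tip.label))
  # written lengths are the 6-decimal rounding, recovered exactly
  expect_equal(sort(back$edge.length), sort(round(bt$edge.length, 6)))
  # at high precision the round-trip is length-exact to 1e-9
  hi <- ape::read.tree(text = write_newick(bt, digits = 12))
  expect_lt(max(abs(sort(hi$edge.length) - sort(bt$edge.length))), 1e-9)
  expect_equal(as.numeric(back$node.label), as.numeric(bt$node.label))
  f <- tempfile(fileext = ".nwk")
  write_newick(bt, f)
  expect_equal(readLines(f), s)
})

test_that("bootstrap supports are reproducible, bounded and 100 at the root", {
  fix <- miscanthus_fixture()
  b1 <- bootstrap_support(fix$alignment, n_reps = 40, seed = 9)
  b2 <- bootstrap_support(fix$alignment, n_reps = 40, seed = 9)
  expect_identical(write_newick(b1), write_newick(b2))
  sup <- as.numeric(b1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  expect_equal(sup[1], 100)   # trivial bipartition at the root node
})

test_that("outgroup rooting bisects the pendant edge and preserves ingroup splits", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  ro <- root_with_outgroup(tr, "C")
  expect_true(ape::is.rooted(ro))
  expect_true(is_monophyletic(ro, c("A", "B")))
  # the outgroup pendant length is split evenly around the root
  root <- length(ro$tip.label) + 1L
  re <- ro$edge.length[ro$edge[, 1] == root]
  expect_equal(re[1], re[2])
  # path lengths are preserved; unrooting restores the bipartition set
  expect_equal(ape::cophenetic.phylo(ro)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  fix <- miscanthus_fixture()
  big <- nj_tree(k2p_distance(fix$alignment))
  rooted <- root_with_outgroup(big, fix$outgroup)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rooted), big)), 0)
  expect_error(root_with_outgroup(big, "nope"), "not a tip")
})

test_that("monophyly is clade-exactness on a rooted tree", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, "A"))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
  expect_error(is_monophyletic(ape::unroot(tr), c("A", "B")), "rooted")
})

test_that("PHYLIP square distance output parses back", {
  fix <- miscanthus_fixture()
  d <- p_distance(fix$alignment[1:4, ])
  f <- tempfile()
  write_phylip_dist(d, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 4)
  row1 <- strsplit(trimws(lines[2]), "[ ]+")[[1]]
  # values are printed with 6 decimals: absolute error at most 5e-7
  expect_true(all(abs(as.numeric(row1[-1]) - unname(d[1, ])) <= 5e-7))
})
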