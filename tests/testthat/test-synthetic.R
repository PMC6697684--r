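test_that("zero-noise, unit-scale generation reproduces true values exactly", {
  spec <- karyotype_spec(noise_cv = 0, condensation_scales = rep(1, 5))
  sim <- simulate_measurements(spec)
  m <- sim$measurements
  expect_equal(nrow(m), 5 * 19 * 2)
  for (p in c(1, 7, 19)) {
    expect_true(all(m$short_arm_um[m$pair_id == p] == spec$true_short[p]))
    expect_true(all(m$long_arm_um[m$pair_id == p] == spec$true_long[p]))
  }
  # satellite annotation survives on the right arm
  expect_true(all(m$satellite_arm[m$pair_id == 1] == "long"))
  expect_true(all(m$satellite_um[m$pair_id == 1] == 0.4))
})

test_that("measurement generation is reproducible and respects the spec", {
  s1 <- simulate_measurements(karyotype_spec(seed = 4L))
  s2 <- simulate_measurements(karyotype_spec(seed = 4L))
  expect_identical(s1$measurements, s2$measurements)
  s3 <- simulate_measurements(karyotype_spec(seed = 5L))
  expect_false(identical(s1$measurements, s3$measurements))
  # the truth ledger carries consistent RL/AR/CI
  tr <- s1$truth
  expect_equal(sum(tr$RL), 100)
  expect_equal(tr$AR, tr$true_long / tr$true_short)
  expect_equal(tr$CI, 100 * tr$true_short / tr$total_len)
})

test_that("karyotype specs reject invalid parameters", {
  expect_error(karyotype_spec(n_pairs = 0), "n_pairs")
  expect_error(karyotype_spec(true_short = c(-1, rep(1, 18)),
                              true_long = rep(2, 19)), "positive")
  expect_error(karyotype_spec(noise_cv = -0.1), "noise_cv")
  expect_error(karyotype_spec(condensation_scales = c(1, 1, 1, 1, 0)),
               "positive")
  expect_error(karyotype_spec(sat_pairs = data.frame(pair_id = 99L,
                                                     arm = "long",
                                                     sat_len = 0.4)),
               "sat_pairs")
})

test_that("alignment generation realizes its targets exactly and matches the classifier", {
  # feasible spec with Table-4-like magnitudes
  spec <- alignment_spec(
    n_taxa = 24, length = 660, n_variable = 16, n_informative = 8,
    n_indel_events = 3, ts = 6, tv = 10, seed = 7,
    group_labels = stats::setNames(rep(c("g1", "g2", "g3", "g4"), each = 6),
                                   sprintf("t%02d", 1:24)))
  sim <- simulate_alignment(spec)
  cs <- classify_sites(sim$alignment)
  expect_equal(cs$counts$n_variable, 16)
  expect_equal(cs$counts$n_informative, 8)
  expect_equal(cs$counts$transitions, 6)
  expect_equal(cs$counts$transversions, 10)
  expect_equal(cs$counts$ratio, "6:10")
  expect_equal(count_indels(sim$alignment), 3)
  # classifier labels agree column-by-column with the ledger
  led <- sim$ledger$columns
  expect_equal(cs$labels[led$col], led$class)
  # reproducibility
  sim2 <- simulate_alignment(spec)
  expect_identical(sim$alignment, sim2$alignment)
})

test_that("a variable-free spec yields identical sequences up to gaps", {
  spec <- alignment_spec(n_taxa = 5, length = 80, n_variable = 0,
                         n_indel_events = 2, seed = 3)
  aln <- simulate_alignment(spec)$alignment
  degapped <- apply(aln, 1, function(r) paste(r[r != "-"], collapse = ""))
  # every sequence is a subsequence of the ancestral: no substitutions at all
  expect_equal(classify_sites(aln)$counts$n_variable, 0)
  expect_equal(length(unique(nchar(degapped))) <= 3, TRUE)
})

test_that("infeasible alignment targets fail loudly naming the violation", {
  expect_error(alignment_spec(n_taxa = 8, length = 100, n_variable = 5,
                              n_informative = 9, ts = 5, tv = 0),
               "n_informative")
  expect_error(alignment_spec(n_taxa = 8, length = 10, n_variable = 20,
                              ts = 20, tv = 0),
               "n_variable \\(20\\) > length")
  # one event per biallelic variable column: ts + tv must equal n_variable
  expect_error(alignment_spec(n_taxa = 24, length = 660, n_variable = 16,
                              n_informative = 8, n_indel_events = 3,
                              ts = 3, tv = 10, seed = 7),
               "ts \\+ tv")
  expect_error(alignment_spec(n_taxa = 4, length = 30, n_variable = 10,
                              ts = 10, tv = 0, n_indel_events = 10),
               "indel space")
  expect_error(alignment_spec(n_taxa = 3, length = 100, n_variable = 4,
                              n_informative = 2, ts = 4, tv = 0),
               ">= 4 taxa")
})

test_that("groups separated by informative sites come out monophyletic under NJ", {
  taxa <- c(sprintf("a%02d", 1:4), sprintf("b%02d", 1:4), "out")
  groups <- stats::setNames(c(rep("A", 4), rep("B", 4), "out"), taxa)
  spec <- alignment_spec(
    n_taxa = 9, length = 300, group_labels = groups,
    n_variable = 10, n_informative = 6, ts = 5, tv = 5,
    informative_clades = list(taxa[1:4], taxa[5:8]),
    singleton_taxa = "out", seed = 13)
  aln <- simulate_alignment(spec)$alignment
  tr <- root_with_outgroup(nj_tree(k2p_distance(aln)), "out")
  expect_true(is_monophyletic(tr, taxa[1:4]))
  expect_true(is_monophyletic(tr, taxa[5:8]))
})

test_that("the packaged fixture has the study's headline structure", {
  fix <- miscanthus_fixture()
  k <- karyotype(fix$measurements)
  expect_equal(k$two_n, 38)
  # exactly one rDNA marker pair, on arm 1L
  rdna <- as.data.frame(fix$markers)
  rdna <- rdna[rdna$marker_class == "rDNA_45S", ]
  expect_equal(nrow(rdna), 1)
  expect_equal(rdna$pair_id, 1L)
  expect_equal(rdna$arm, "L")
  expect_equal(rdna$homologs_present, "both")
  # 24 ingroup taxa plus one outgroup
  expect_equal(sum(fix$group_labels != "outgroup"), 24)
  expect_equal(nrow(fix$alignment), 25)
  # deterministic fixture
  expect_identical(miscanthus_fixture()$alignment, fix$alignment)
  expect_identical(miscanthus_fixture()$measurements, fix$measurements)
})
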