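test_that("GC content excludes gaps and ambiguity codes", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("AT-GC-NN"), 50)
  expect_equal(gc_content("acgt"), 50)       # case-insensitive
  expect_error(gc_content("NN--"), "no unambiguous")
  expect_equal(gc_content("AAGGCCTT", region = c(2, 6)), 100)
})

test_that("site classification distinguishes singleton and informative columns", {
  aln <- aln_from_strings(a = "AAAA", b = "AAAA", c = "GAAG", d = "GAAA")
  # col1 {A,A,G,G}: informative; col4 {A,A,G,A}: singleton; cols 2-3 conserved
  cs <- classify_sites(aln)
  expect_equal(cs$labels,
               c("variable_informative", "conserved", "conserved",
                 "variable_singleton"))
  expect_equal(cs$counts$n_variable, 2)
  expect_equal(cs$counts$n_informative, 1)
  # identical sequences: nothing variable
  cs0 <- classify_sites(aln_from_strings(a = "ACGT", b = "ACGT"))
  expect_equal(cs0$counts$n_variable, 0)
  # ambiguity codes never create states; gaps preempt variability
  csn <- classify_sites(aln_from_strings(a = "AN-", b = "AN-", c = "ANA"))
  expect_equal(csn$labels, c("conserved", "conserved", "gap_containing"))
  expect_error(classify_sites(c(a = "ACG", b = "AC")), "ragged")
})

test_that("substitution events are typed per unordered base pair per column", {
  expect_equal(count_substitution_types(
    aln_from_strings(a = "A", b = "G"))[c("transitions", "transversions")],
    list(transitions = 1, transversions = 0))
  expect_equal(count_substitution_types(
    aln_from_strings(a = "A", b = "C"))[c("transitions", "transversions")],
    list(transitions = 0, transversions = 1))
  # three states in one column: one event per distinct pair (A/G ts, A/C+C/G tv)
  st <- count_substitution_types(aln_from_strings(a = "A", b = "G", c = "C"))
  expect_equal(st$transitions, 1)
  expect_equal(st$transversions, 2)
  expect_equal(st$ratio, "1:2")
})

test_that("indel events are maximal shared-pattern gap runs", {
  expect_equal(count_indels(aln_from_strings(a = "ACGT", b = "ACGT")), 0)
  # one 2-column gap in one sequence
  expect_equal(count_indels(aln_from_strings(a = "AC--GT", b = "ACAAGT")), 1)
  # the same 1-column gap shared by two sequences counts once
  expect_equal(count_indels(aln_from_strings(a = "A-G", b = "A-G", c = "AAG")), 1)
  # adjacent columns with different gap patterns are separate events
  expect_equal(count_indels(aln_from_strings(a = "A--G", b = "AA-G", c = "AAAG")), 2)
  # separated gaps with the same pattern are separate events
  expect_equal(count_indels(aln_from_strings(a = "A-A-A", b = "AAAAA")), 2)
})

test_that("region table tiles the alignment and matches per-region recomputation", {
  fix <- miscanthus_fixture()
  rt <- region_table(fix$alignment, fix$regions)
  complete <- rt[rt$region == "complete", ]
  parts <- rt[rt$region != "complete", ]
  expect_equal(sum(parts$variable_sites), complete$variable_sites)
  expect_equal(sum(parts$informative_sites), complete$informative_sites)
  expect_equal(sum(parts$transitions), complete$transitions)
  expect_equal(sum(parts$transversions), complete$transversions)
  expect_equal(sum(parts$indels), complete$indels)
  # the 5.8S-like region is indel-free hence constant length
  expect_equal(rt$length_range[rt$region == "5.8S"], "157")
  expect_equal(rt$indels[rt$region == "5.8S"], 0)
  # ledger agreement per region
  led <- fix$aln_ledger$per_region
  expect_equal(parts$variable_sites, led$variable_sites)
  expect_equal(parts$informative_sites, led$informative_sites)
  expect_equal(parts$indels, led$indels)
  expect_error(region_table(fix$alignment,
                            data.frame(region = "x", start = 0, end = 10000)),
               "outside")
})

test_that("ungapped intervals map onto alignment columns", {
  # seq: A-CG-T ; ungapped ACGT
  expect_equal(ungapped_to_alignment("A-CG-T", 0, 2), c(0, 3))
  expect_equal(ungapped_to_alignment("A-CG-T", 3, 4), c(5, 6))
  expect_error(ungapped_to_alignment("A-CG-T", 0, 9), "outside")
})

test_that("alignment FASTA IO round-trips", {
  fix <- miscanthus_fixture()
  f <- tempfile(fileext = ".fasta")
  write_alignment(fix$alignment, f)
  back <- read_alignment(f)
  expect_equal(dim(back), dim(fix$alignment))
  expect_equal(rownames(back), rownames(fix$alignment))
  expect_equal(unname(back), unname(fix$alignment))
})

test_that("informative <= variable <= length holds on random alignments", {
  for (seed in 1:5) {
    spec <- alignment_spec(n_taxa = 8, length = 120, n_variable = 20,
                           n_informative = 9, ts = 11, tv = 9,
                           n_indel_events = 2, seed = seed,
                           informative_clades = list(sprintf("t%02d", 1:3)))
    cs <- classify_sites(simulate_alignment(spec)$alignment)
    expect_lte(cs$counts$n_informative, cs$counts$n_variable)
    expect_lte(cs$counts$n_variable, 120)
  }
})
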