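---
title: "Karyotype characterization and ITS phylogenetics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype characterization and ITS phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotypeR)
```

# What the package computes

karyotypeR implements the quantitative half of a molecular-cytogenetic
species comparison: from per-cell chromosome arm-length measurements it
derives the standard karyotype descriptors; from band/FISH annotations it
derives marker statistics; and from an ITS1-5.8S-ITS2 alignment it derives
site statistics, distances and a neighbour-joining (NJ) tree with bootstrap
supports. A synthetic-data module generates all three inputs with known
ground truth, so the whole pipeline is testable without external data.

# The karyotype model

A measurement table holds one row per chromosome per metaphase cell:
`cell_id`, homolog pair, homolog (1 or 2), short- and long-arm lengths in
micrometres, and an optional satellite segment. `karyotype()` aggregates
over cells and homologs into homolog-pair means and computes:

* **RL** — relative length, `100 * pair total / haploid complement total`
  (sums to 100 by construction);
* **AR** — arm ratio `long / short` (orientation is normalized first, so
  AR >= 1 always; the longer measured arm *is* the long arm);
* **CI** — centromeric index `100 * short / (short + long)`;
* **Levan class** — m for AR in [1, 1.7], sm in (1.7, 3], st in (3, 7],
  t above 7. Boundary values go to the more symmetric class and Levan's
  strict metacentric point (AR = 1) is folded into m; the formula strings
  this produces use only the four coarse classes;
* **TCL** — the haploid karyotype length. Because absolute lengths depend
  on how condensed each metaphase plate is, TCL is computed over the
  `n_cells_for_tcl` *most condensed* cells, operationalized as the cells
  with the smallest summed chromosome length (higher condensation means
  shorter chromosomes). The reported SD is across those cells.
* the **karyotype formula**, e.g. `2n=2x=38=34m(2SAT)+4sm`: chromosome
  counts per Levan class in the order m, sm, st, t, with `(kSAT)` attached
  to a class containing k satellite chromosomes.

Pairs are renumbered by decreasing mean total length; ties break by lower
AR, then by the original pair id, so renumbering is deterministic and a
permutation.

Two modelling decisions deserve a note. First, satellite segments are
*excluded* from arm lengths for RL/AR/CI and carried as annotations: the
secondary constriction is treated as a marker, and whether published tables
fold it into the arm is typically unstated. Second, "most condensed =
shortest complement" is an inference; it is the only reading that makes a
condensation-based cell selection computable from lengths alone.

# Asymmetry indices

All complement-level statistics use homolog-pair means, and all standard
deviations are **sample** (n-1) SDs — small-n karyotype tables conventionally
report sample SDs, and fixing the convention makes exact-recovery tests
well-defined.

* `a1_intra`: A1 = 1 - mean(short/long) over pairs (intrachromosomal).
* `a2_inter`: A2 = sd(pair totals)/mean(pair totals) (interchromosomal CV).
* `as_k_percent`: As K% = 100 * sum(long arms) / total complement length.
  Identity: As K% = 100 - 100 * sum(short)/sum(total).
* `paszko_ai`: AI = (CV of pair lengths x CV of pair CIs)/100.
* `stebbins_category`: letter from longest/shortest ratio (A < 2,
  B 2-4, C > 4) and digit from the proportion p of chromosomes with
  AR strictly above 2 (1: p = 0; 2: p <= 0.5; 3: p < 1; 4: p = 1).
  Boundary ratios 2 and 4 are read as B, p = 0.5 as digit 2, and a 1e-9
  numerical guard keeps boundary inputs from flipping on arithmetic noise.

`CI_mean` is the mean of pair CIs; `CI_sd` is taken over the 2n individual
chromosomes of the *mean cell* (per-homolog arm means), matching the
"CI +/- SD" presentation style of comparative tables. Note that
`CI_mean + As K%` is near but not exactly 100: one is a mean of ratios, the
other a ratio of sums.

# Cytogenetic markers

Markers (CPD bands, DAPI bands, 45S rDNA FISH sites) are rows of a
validated table. The position statistic for rDNA sites is
`di = d * 100 / a`, the distance of the site centre from the centromere as
a percentage of its arm; `rdna_di_summary()` gives the conventional
"mean +/- SD" over cells. Codes follow table conventions
(`1L-PROX (25.53%)`, `19S-PCEN`, `15 PCEN (one homologue)`) and round-trip
through `parse_marker_code()`.

Band amounts are percentages of the karyotype length. Because TCL is
haploid while bands sit on both homologs (possibly with different sizes),
the package sums each homolog's own band length and divides by `2 * TCL` —
diploid accounting that stays well-defined for heteromorphic bands; whether
published percentages count one or both homologs is usually unstated.

The `position_class_of()` helper bins a *fractional arm position*
(centromere 0 to telomere 1) at cutoffs 0.05/0.15/0.40/0.85 into
CEN/PCEN/PROX/INT/TER. Arm-fraction coordinates are used (rather than
whole-chromosome fractions) because terminal positions are unreachable on
a whole-chromosome scale; the cutoffs are configurable.

# ITS site statistics

`classify_sites()` labels every alignment column exactly one of:
`gap_containing` (any gap; excluded from variability statistics,
complete-deletion style), `conserved`, `variable_singleton`, or
`variable_informative` (>= 2 distinct unambiguous bases each in >= 2
sequences). Ambiguity codes and N never count as states, for GC content or
variability. Substitution events are typed per column over the *distinct
observed bases* — one event per unordered pair, A/G and C/T transitions,
the rest transversions — a tree-free convention that is fully reproducible;
columns with three states contribute one event per base pair.

Indels are counted as **events**, not gap columns: a maximal run of
consecutive gap columns sharing an identical presence/absence pattern is
one event. This matches the small indel counts such tables print (a
three-column deletion in one accession is one indel, and the same deletion
shared by a clade is still one).

`region_table()` reports the per-region (ITS1 / 5.8S / ITS2 / complete)
length ranges, GC ranges and counts; regions are alignment-column intervals
(0-based half-open), with `ungapped_to_alignment()` mapping per-sequence
annotations onto columns. When the regions tile the alignment the region
counts sum to the complete-alignment counts.

# Distances, NJ and bootstrap

Distances are standard: uncorrected p-distance and Kimura two-parameter
(K2P), each with complete or pairwise gap deletion (computed via
`ape::dist.dna` behind the package surface). The default for tree building
is **K2P with pairwise deletion** — the long-standing default of
distance-based ITS analyses — and it is configurable because published
methods sections frequently omit the model.

`nj_tree()` is the package's own Saitou-Nei implementation: Q-criterion
agglomeration, ties broken by the lexicographically smallest pair of
cluster representatives (each cluster's alphabetically first taxon), and
negative branch lengths clamped to zero with a count kept in an attribute.
On an additive matrix NJ provably recovers the generating tree; the test
suite checks topology *and* branch lengths exactly against random trees of
4-6 taxa and against an independent NJ implementation.

`bootstrap_support()` resamples columns with replacement; replicate r draws
under seed `seed + r`, so runs are reproducible and replicate streams are
order-independent. Supports are mapped onto the *full-data* tree (not a
consensus), as support-on-best-tree figures are conventionally drawn; the
root's trivial bipartition is 100% by definition. Rooting
(`root_with_outgroup()`) bisects the outgroup's pendant edge, preserving
path lengths and all ingroup bipartitions.

Maximum-likelihood and maximum-parsimony inference are deliberately out of
scope: methods sections of the kind this package mirrors delegate them to
external software and are often inconsistent about which was run. Trees
produced elsewhere can be read with `ape::read.tree` and compared through
`is_monophyletic()` and the Newick utilities.

# The synthetic-data generator

`karyotype_spec()` defaults describe the emulated study complement:
19 homolog pairs, TCL about 74 um (mean chromosome about 3.9 um),
longest/shortest ratio 2.33, seventeen metacentric pairs (AR 1.07-1.22) and
two submetacentric pairs (AR 2.2, 2.35), a 0.4 um satellite on the long arm
of pair 1, five metaphase cells with condensation scales 0.94-1.06, and a
3% per-arm measurement CV. This profile puts the complement where the
emulated tables sit: mean CI near 44-45, A1 about 0.17, As K% about 55,
Stebbins 2B, formula `2n=2x=38=34m(2SAT)+4sm`. Measurement noise is
multiplicative Gaussian, independent per arm and cell — the simplest model
that reproduces table-style SDs; condensation is a single per-cell scalar,
which is exactly the degree of freedom the TCL cell-selection rule targets.

`alignment_spec()` pins the realized statistics exactly: every variable
column is biallelic and carries one substitution event (hence the
feasibility identity `ts + tv = n_variable`; combinations violating it
fail loudly naming the inequality). Informative columns place the derived
base on whole clades (round-robin over the supplied clade list), singletons
on single taxa; indel events are placed on conserved columns, mutually
separated, so the event counter is unambiguous. The packaged
`miscanthus_fixture()` uses 24 ingroup accessions (4 species x 6) plus one
outgroup over 660 columns with 16 variable / 8 informative sites, a 4:12
ts:tv split, 3 indels kept out of the 157-column 5.8S region, and the
informative sites allocated so that the two species groups are each
separated by three exclusive sites — enough signal that their bipartitions
bootstrap in the 90s, mirroring the two-clade structure such analyses
recover.

What the generator does *not* emulate: rate heterogeneity along the
sequence, homoplasy, back-substitution, within-species polymorphism beyond
planted singletons, or correlated measurement error within a cell. Passing
tests therefore demonstrate correctness of the computations under clean,
controlled conditions — not robustness to every pathology of real
micrographs or real alignments.

# Numerical conventions and degenerate inputs

* Sample (n-1) SDs everywhere; means are plain arithmetic means.
* Orientation normalization swaps measured arms when noise inverts them,
  and the satellite annotation follows its physical arm.
* Single-pair karyotypes: A2, AI and the length ratio are undefined and
  error; A1/AsK still compute.
* Classification boundaries are closed toward the more symmetric class,
  with a 1e-9 guard (Levan and Stebbins).
* Non-positive simulated lengths are resampled with bounded retries, then
  error.
* Saturated K2P distances error by default (`saturated = "flag"` keeps
  non-finite entries flagged instead).
* NJ Q-ties and the bootstrap replicate streams are deterministic as
  described above, so identical inputs and seeds give byte-identical
  Newick output.

# Problem sizes

The shipped tests and the acceptance script run at the emulated study's own
scale: 5 cells x 38 chromosomes for the karyotype half; a 25 x 660
alignment; 1000 bootstrap replicates; 100 random additive matrices of 4-6
taxa for the NJ exactness check; 50 random generator specs for the
ledger-agreement check.

# Worked example

```{r, eval = FALSE}
fix <- miscanthus_fixture()
k <- karyotype(fix$measurements, species = "synthetic")
summary(k)
species_report(k, markers = fix$markers)
svg <- render_idiogram(k, fix$markers)

bt <- bootstrap_support(fix$alignment, n_reps = 1000, seed = 1)
tree <- root_with_outgroup(bt, fix$outgroup)
is_monophyletic(tree, fix$group_i)
```

# Known limitations

Homolog pairing is taken from the input (no automatic pairing of unlabeled
chromosomes); alignments are inputs (no alignment algorithm); ML/MP
inference is external; GISH signal comparison is qualitative in the
emulated study design and has no quantitative procedure here.
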