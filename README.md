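# karyotypeR

Karyotype characterization, cytogenetic-marker bookkeeping and ITS
phylogenetics for plant chromosome studies.

Comparative plant cytogenetics papers summarize each species by a small,
highly conventional set of numbers: a karyotype formula, relative chromosome
lengths, arm ratios and centromeric indices, asymmetry indices, the positions
and amounts of fluorochrome bands and 45S rDNA FISH sites, and — on the
molecular side — ITS1-5.8S-ITS2 sequence statistics feeding a
neighbour-joining tree with bootstrap supports. Those numbers are usually
produced ad hoc in spreadsheets and point-and-click software. karyotypeR
implements the whole chain as tested, reproducible R functions, for
cytogeneticists and systematists who have arm-length measurement tables and
aligned ITS sequences and want the standard tables, idiograms and trees out
the other end.

## What it computes

For a complement measured over metaphase cells (arm lengths in µm, homolog
pairs labelled):

- **RL** = 100·(pair total)/(haploid complement total); **AR** = long/short;
  **CI** = 100·short/(short + long)
- Levan centromere classes (m / sm / st / t at AR 1.7, 3, 7) and the
  karyotype formula, e.g. `2n=2x=38=34m(2SAT)+4sm`
- **TCL** (haploid karyotype length) over the most condensed cells, ± SD
- Asymmetry: Romero-Zarco **A1** = 1 − mean(short/long) and
  **A2** = CV of pair lengths; **As K%** = 100·Σlong/Σtotal; Paszko
  **AI** = (CV of lengths × CV of CIs)/100; the **Stebbins** two-way
  category (longest/shortest ratio × proportion of chromosomes with AR > 2)
- Marker codes (`1L-PROX (25.53%)`, `19S-PCEN`, …), band amounts as
  percentages of the karyotype length, heteromorphism flags, and the rDNA
  position statistic **di** = d·100/a
- To-scale SVG idiograms (and a base-graphics `plot()` method)
- ITS statistics per region and overall: GC content, variable and
  parsimony-informative sites, indel *events*, transition/transversion
  counts
- p-distance / Kimura two-parameter distances, an exact Saitou–Nei
  neighbour-joining implementation, column bootstrap with per-replicate
  seeds, outgroup rooting and monophyly tests

A synthetic-data module (`karyotype_spec()` / `alignment_spec()` /
`miscanthus_fixture()`) generates measurement tables, marker sets and
alignments with exactly known ground truth, which is how the test suite
validates every stage end to end.

## Worked example

```r
library(karyotypeR)

fix <- miscanthus_fixture()                       # packaged synthetic study
k <- karyotype(fix$measurements, species = "synthetic")
k
#> Karyotype of synthetic
#>   2n = 38  ( 19 homolog pairs, 5 cells )
#>   formula: 2n=2x=38=34m(2SAT)+4sm
#>   TCL: 73.87 um +/- 3.48
#>   RL range: 3.15-7.39 %   length ratio: 2.35

summary(k)
#> Karyotype indices for synthetic
#>    2n=2x=38=34m(2SAT)+4sm
#>   TCL 73.87 +/- 3.48 um   RRL 3.15~7.39 %   CI 45.09 +/- 5.04
#>   A1 0.17   A2 0.25   As K% 54.81   AI 2.82   Stebbins 2B
```

Reading the output: the complement is 19 homolog pairs (2n = 38), 34
metacentric and 4 submetacentric chromosomes with one satellite pair; the
haploid karyotype is 73.9 µm long averaged over the most condensed cells;
relative lengths run from 3.15% to 7.39% of the complement (ratio 2.35,
hence Stebbins letter B); the mean centromeric index of 45.1% and A1 of
0.17 describe a fairly symmetric, mostly metacentric karyotype (digit 2:
some but at most half of the chromosomes exceed arm ratio 2).

Markers and the idiogram:

```r
species_report(k, markers = fix$markers)$marker_table
#>   marker_class                     code amount_percent
#> 1     rDNA_45S         1L-PROX (25.27%)      0.9341334
#> 2     CPD_band                  1L-PROX      0.9341334
#> 3    DAPI_band                   10 CEN      1.9359576
#> 4    DAPI_band                 12L-PCEN      1.9359576
#> 5    DAPI_band                   19 CEN      1.9359576
#> 6    DAPI_band 19L-PROX (one homologue)      1.9359576

render_idiogram(k, fix$markers, file = "idiogram.svg")
```

The single 45S rDNA pair sits proximally on the long arm of pair 1, 25.3%
of the arm from the centromere; CPD bands cover 0.93% of the karyotype
length and DAPI bands 1.94% (`amount_percent` is per marker class).

Tree building with bootstrap:

```r
bt <- bootstrap_support(fix$alignment, n_reps = 1000, seed = 1)
tree <- root_with_outgroup(bt, fix$outgroup)
is_monophyletic(tree, fix$group_i)   # TRUE; both species groups come out
is_monophyletic(tree, fix$group_ii)  # monophyletic with ~96% support
write_newick(tree, "its_nj.nwk")
```

## File formats

- Measurements: CSV with header
  `cell_id,pair_id,homolog,short_arm_um,long_arm_um,satellite_um,satellite_arm`
  (`read_measurements()` / `write_measurements()`)
- Markers: CSV with header
  `marker_class,pair_id,arm,position_class,band_len_um,homologs_present,d_um`
- Alignments: aligned FASTA (`read_alignment()` / `write_alignment()`);
  region annotations as 0-based half-open column intervals
- Trees: Newick with supports as internal node labels (`write_newick()`);
  distance matrices in square PHYLIP format (`write_phylip_dist()`)
- Reports: CSV or JSON (`write_species_report()` /
  `read_species_report()`), idiograms as SVG 1.1

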