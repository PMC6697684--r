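# shared in-code fixtures; everything is generated, nothing is stored

# a 2-pair, 1-cell measurement table with exact arm lengths
tiny_measurements <- function(short = c(1.5, 1), long = c(1.5, 3),
                              sat_arm = c("none", "none")) {
  do.call(rbind, lapply(seq_along(short), function(p) {
    do.call(rbind, lapply(1:2, function(h) data.frame(
      cell_id = "c1", pair_id = p, homolog = h,
      short_arm_um = short[p], long_arm_um = long[p],
      satellite_um = 0, satellite_arm = sat_arm[p],
      stringsAsFactors = FALSE)))
  }))
}

# noise-free simulated study complement passed through the generator
zero_noise_karyotype <- function() {
  spec <- karyotype_spec(noise_cv = 0, condensation_scales = rep(1, 5))
  sim <- simulate_measurements(spec)
  list(k = karyotype(sim$measurements, species = "zero-noise"),
       truth = sim$truth, spec = spec)
}

# small alignment from explicit strings
aln_from_strings <- function(...) {
  s <- c(...)
  do.call(rbind, lapply(stats::setNames(s, names(s)), function(x)
    strsplit(x, "")[[1]]))
}

# a synthetic karyotype with prescribed pair totals and arm ratios
karyotype_from_profile <- function(totals, ARs) {
  short <- totals / (1 + ARs)
  spec <- karyotype_spec(n_pairs = length(totals), true_short = short,
                         true_long = totals - short,
                         sat_pairs = data.frame(pair_id = integer(0),
                                                arm = character(0),
                                                sat_len = numeric(0)),
                         n_cells = 1L, condensation_scales = 1,
                         noise_cv = 0, seed = 1L)
  karyotype(simulate_measurements(spec)$measurements)
}
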