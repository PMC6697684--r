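#' Specification of a synthetic karyotype measurement experiment
#'
#' Describes the ground truth and the measurement process for simulating
#' per-cell chromosome arm-length tables: true arm lengths per homolog pair,
#' satellite annotations, the number of metaphase cells, a per-cell
#' multiplicative condensation scale, and a per-arm multiplicative Gaussian
#' measurement error with coefficient of variation \code{noise_cv}.
#'
#' The default ground truth emulates a Miscanthus-like complement: 19 pairs,
#' total haploid length about 74 um (mean chromosome length about 3.9 um),
#' a longest/shortest ratio of about 2.33, seventeen metacentric pairs
#' (AR 1.07-1.22) and two submetacentric pairs (AR 2.2 and 2.35, pairs 5 and
#' 12), and a satellite on the long arm of pair 1. Five cells with
#' condensation scales 0.94-1.06 (mean 1) stand in for five measured
#' metaphase plates of varying condensation.
#'
#' @param n_pairs Number of homolog pairs (default 19).
#' @param true_short,true_long True arm lengths per pair, um. When NULL the
#'   default profile above is used (requires \code{n_pairs = 19}).
#' @param sat_pairs data.frame with columns \code{pair_id}, \code{arm}
#'   ("short"/"long"), \code{sat_len} (um); default: one satellite of
#'   0.4 um on the long arm of pair 1.
#' @param n_cells Number of metaphase cells (default 5).
#' @param condensation_scales Per-cell multiplicative factor > 0 applied to
#'   every arm; default evenly spaced over 0.94-1.06.
#' @param noise_cv Coefficient of variation of the per-arm measurement error
#'   (default 0.03).
#' @param seed Integer seed.
#' @return Object of class \code{"karyotype_spec"}.
#' @export
karyotype_spec <- function(n_pairs = 19L, true_short = NULL, true_long = NULL,
                           sat_pairs = NULL, n_cells = 5L,
                           condensation_scales = NULL, noise_cv = 0.03,
                           seed = 1L) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (is.null(true_short) || is.null(true_long)) {
    if (n_pairs != 19L)
      stop("the default arm-length profile is defined for 19 pairs; ",
           "supply true_short/true_long for other complements")
    totals <- seq(2.33, 1, length.out = 19)
    totals <- totals / sum(totals) * 74   # TCL ~ 74 um, ratio 2.33
    AR <- numeric(19)
    AR[c(5, 12)] <- c(2.2, 2.35)                    # submetacentric pairs
    AR[AR == 0] <- seq(1.07, 1.22, length.out = 17) # metacentric pairs
    true_short <- totals / (1 + AR)
    true_long <- totals - true_short
  }
  stopifnot(length(true_short) == n_pairs, length(true_long) == n_pairs)
  if (any(true_short <= 0) || any(true_long <= 0))
    stop("true arm lengths must be positive")
  if (is.null(sat_pairs))
    sat_pairs <- data.frame(pair_id = 1L, arm = "long", sat_len = 0.4)
  if (nrow(sat_pairs) && (any(!sat_pairs$pair_id %in% seq_len(n_pairs)) ||
                          any(!sat_pairs$arm %in% c("short", "long")) ||
                          any(sat_pairs$sat_len <= 0)))
    stop("invalid sat_pairs annotation")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (is.null(condensation_scales))
    condensation_scales <- if (n_cells == 1) 1 else
      seq(0.94, 1.06, length.out = n_cells)
  stopifnot(length(condensation_scales) == n_cells)
  if (any(condensation_scales <= 0))
    stop("condensation scales must be positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(n_pairs = as.integer(n_pairs),
                 true_short = as.numeric(true_short),
                 true_long = as.numeric(true_long),
                 sat_pairs = sat_pairs,
                 n_cells = as.integer(n_cells),
                 condensation_scales = as.numeric(condensation_scales),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "karyotype_spec")
}

# one noisy positive draw: value * (1 + N(0, cv)), resampled while <= 0
noisy_length <- function(value, cv, max_tries = 100L) {
  if (cv == 0) return(value)
  for (i in seq_len(max_tries)) {
    x <- value * (1 + stats::rnorm(1, 0, cv))
    if (x > 0) return(x)
  }
  stop("could not draw a positive length after ", max_tries,
       " tries (noise_cv too large?)")
}

#' Simulate a per-cell chromosome measurement table
#'
#' Draws, for every cell, pair and homolog, measured arm lengths
#' \code{true length x cell scale x (1 + N(0, noise_cv))} (independent
#' across arms and cells; non-positive draws are resampled with bounded
#' retries). Satellite segments are drawn the same way on their annotated
#' arm of both homologs. Measured arms are orientation-labelled (short =
#' smaller of the two draws), with the satellite annotation following its
#' physical arm.
#'
#' @param spec A \code{\link{karyotype_spec}}.
#' @return List with \code{measurements} (a measurement data.frame accepted
#'   by \code{\link{karyotype}}), \code{truth} (per-pair ground-truth ledger
#'   with true RL, AR, CI) and \code{spec}.
#' @export
simulate_measurements <- function(spec) {
  stopifnot(inherits(spec, "karyotype_spec"))
  set.seed(spec$seed)
  rows <- vector("list", spec$n_cells * spec$n_pairs * 2L)
  k <- 0L
  sat_arm_of <- rep("none", spec$n_pairs)
  sat_len_of <- rep(0, spec$n_pairs)
  if (nrow(spec$sat_pairs)) {
    sat_arm_of[spec$sat_pairs$pair_id] <- spec$sat_pairs$arm
    sat_len_of[spec$sat_pairs$pair_id] <- spec$sat_pairs$sat_len
  }
  for (ci in seq_len(spec$n_cells)) {
    sc <- spec$condensation_scales[ci]
    for (p in seq_len(spec$n_pairs)) {
      for (h in 1:2) {
        a_short <- noisy_length(spec$true_short[p] * sc, spec$noise_cv)
        a_long <- noisy_length(spec$true_long[p] * sc, spec$noise_cv)
        sarm <- sat_arm_of[p]
        slen <- if (sarm == "none") 0 else
          noisy_length(sat_len_of[p] * sc, spec$noise_cv)
        if (a_short > a_long) {  # noise swapped the arms
          tmp <- a_short; a_short <- a_long; a_long <- tmp
          sarm <- switch(sarm, short = "long", long = "short", none = "none")
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          cell_id = sprintf("cell%02d", ci), pair_id = p, homolog = h,
          short_arm_um = a_short, long_arm_um = a_long,
          satellite_um = slen, satellite_arm = sarm,
          stringsAsFactors = FALSE)
      }
    }
  }
  meas <- do.call(rbind, rows)
  totals <- spec$true_short + spec$true_long
  truth <- data.frame(
    pair_id = seq_len(spec$n_pairs),
    true_short = spec$true_short,
    true_long = spec$true_long,
    total_len = totals,
    RL = 100 * totals / sum(totals),
    AR = spec$true_long / spec$true_short,
    CI = 100 * spec$true_short / totals,
    sat = sat_arm_of != "none",
    sat_arm = sat_arm_of,
    sat_len = sat_len_of,
    stringsAsFactors = FALSE
  )
  list(measurements = meas, truth = truth, spec = spec)
}

#' Specification of a synthetic gapped alignment
#'
#' Describes an alignment with exactly controlled Table-4-style statistics:
#' the number of variable and parsimony-informative columns, the number of
#' indel events, the transition/transversion event counts and the ancestral
#' GC fraction. Each variable column is biallelic and carries exactly one
#' substitution event, so \code{ts + tv} must equal \code{n_variable};
#' infeasible combinations fail loudly naming the violated inequality.
#'
#' @param n_taxa Number of taxa (>= 4 when informative sites are requested).
#' @param length Alignment length in columns.
#' @param group_labels Named character vector mapping taxon name -> group.
#'   When NULL, taxa t01..tNN in one group "g1".
#' @param n_variable,n_informative Target variable / informative column
#'   counts (informative <= variable <= length).
#' @param n_indel_events Number of gap events (maximal same-pattern runs).
#' @param ts,tv Target transition / transversion event counts
#'   (ts + tv = n_variable).
#' @param gc_target Ancestral GC fraction in (0, 1).
#' @param informative_clades Optional list of taxon sets (each of size 2 to
#'   n_taxa - 2) used round-robin as the derived-state carriers of
#'   informative columns; default: the groups of \code{group_labels} that
#'   qualify.
#' @param singleton_taxa Optional character vector cycled as carriers of
#'   singleton columns; default all taxa.
#' @param indel_cols Optional integer vector of columns where indel events
#'   may be placed (default: anywhere).
#' @param indel_max_len Maximal indel run length in columns (default 3).
#' @param regions Optional region annotation data.frame
#'   (\code{region}, \code{start}, \code{end}; 0-based half-open) carried
#'   into the ledger.
#' @param seed Integer seed.
#' @return Object of class \code{"alignment_spec"}.
#' @export
alignment_spec <- function(n_taxa, length, group_labels = NULL,
                           n_variable = 0L, n_informative = 0L,
                           n_indel_events = 0L, ts = NULL, tv = NULL,
                           gc_target = 0.55, informative_clades = NULL,
                           singleton_taxa = NULL, indel_cols = NULL,
                           indel_max_len = 3L, regions = NULL, seed = 1L) {
  if (is.null(group_labels)) {
    taxa <- sprintf("t%02d", seq_len(n_taxa))
    group_labels <- stats::setNames(rep("g1", n_taxa), taxa)
  }
  if (length(group_labels) != n_taxa)
    stop("group_labels must name all ", n_taxa, " taxa")
  taxa <- names(group_labels)
  if (is.null(ts) && is.null(tv)) { ts <- n_variable; tv <- 0L }
  if (any(c(n_variable, n_informative, n_indel_events, ts, tv) < 0))
    stop("counts must be non-negative")
  if (n_informative > n_variable)
    stop("infeasible targets: n_informative (", n_informative,
         ") > n_variable (", n_variable, ")")
  if (n_variable > length)
    stop("infeasible targets: n_variable (", n_variable, ") > length (",
         length, ")")
  if (ts + tv != n_variable)
    stop("infeasible targets: ts + tv (", ts + tv, ") != n_variable (",
         n_variable,
         "); each biallelic variable column carries exactly one event")
  if (n_informative > 0 && n_taxa < 4)
    stop("infeasible targets: parsimony-informative sites need >= 4 taxa")
  if (is.null(informative_clades)) {
    grp <- split(taxa, group_labels)
    informative_clades <- Filter(function(g)
      length(g) >= 2 && length(g) <= n_taxa - 2, grp)
  }
  if (n_informative > 0 && !length(informative_clades))
    stop("infeasible targets: no clade of size 2..n_taxa-2 available for ",
         "informative sites")
  for (cl in informative_clades) {
    if (length(cl) < 2 || length(cl) > n_taxa - 2 || !all(cl %in% taxa))
      stop("informative clade must hold 2..n_taxa-2 known taxa")
  }
  if (is.null(singleton_taxa)) singleton_taxa <- taxa
  if (!all(singleton_taxa %in% taxa)) stop("unknown singleton taxa")
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must be in (0, 1)")
  # generous feasibility bound: every event needs its run plus a spacer
  if (n_variable + n_indel_events * (indel_max_len + 1) > length)
    stop("infeasible targets: n_variable + indel space exceeds length")
  if (!is.null(regions))
    stopifnot(all(c("region", "start", "end") %in% names(regions)))
  structure(list(n_taxa = as.integer(n_taxa), length = as.integer(length),
                 group_labels = group_labels,
                 n_variable = as.integer(n_variable),
                 n_informative = as.integer(n_informative),
                 n_indel_events = as.integer(n_indel_events),
                 ts = as.integer(ts), tv = as.integer(tv),
                 gc_target = gc_target,
                 informative_clades = informative_clades,
                 singleton_taxa = singleton_taxa,
                 indel_cols = indel_cols,
                 indel_max_len = as.integer(indel_max_len),
                 regions = regions, seed = as.integer(seed)),
            class = "alignment_spec")
}

#' Simulate a gapped alignment with a ground-truth ledger
#'
#' Builds an ancestral sequence at the target GC fraction, then plants
#' exactly \code{n_variable} biallelic variable columns (the first
#' \code{n_informative} of them informative, carried by whole clades; the
#' rest singletons), with exactly \code{ts} transition and \code{tv}
#' transversion events, and exactly \code{n_indel_events} gap events on
#' otherwise conserved columns (events never touch variable columns and are
#' separated by at least one gap-free column, so event counting is
#' unambiguous). Realized counts equal the spec targets by construction.
#'
#' @param spec An \code{\link{alignment_spec}}.
#' @return List with \code{alignment} (character matrix) and \code{ledger}
#'   (realized per-column classes, event types, indel events, counts and
#'   realized GC).
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "alignment_spec"))
  set.seed(spec$seed)
  taxa <- names(spec$group_labels)
  L <- spec$length
  p <- c((1 - spec$gc_target) / 2, spec$gc_target / 2,
         spec$gc_target / 2, (1 - spec$gc_target) / 2)
  anc <- sample(BASES, L, replace = TRUE, prob = p)
  aln <- matrix(rep(anc, each = length(taxa)), nrow = length(taxa),
                dimnames = list(taxa, NULL))

  var_cols <- if (spec$n_variable > 0) sort(sample.int(L, spec$n_variable))
              else integer(0)
  classes <- rep("variable_singleton", spec$n_variable)
  if (spec$n_informative > 0) {
    inf_idx <- sample.int(spec$n_variable, spec$n_informative)
    classes[inf_idx] <- "variable_informative"
  }
  events <- rep(NA_character_, spec$n_variable)
  if (spec$n_variable > 0)
    events[sample.int(spec$n_variable, spec$ts)] <- "ts"
  events[is.na(events)] <- "tv"

  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partner <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  carriers <- vector("list", spec$n_variable)
  ic <- 0L  # informative clade cursor
  sc <- 0L  # singleton taxon cursor
  for (v in seq_along(var_cols)) {
    j <- var_cols[v]
    base <- anc[j]
    derived <- if (events[v] == "ts") ts_partner[[base]]
               else sample(tv_partner[[base]], 1)
    who <- if (classes[v] == "variable_informative") {
      ic <- ic %% length(spec$informative_clades) + 1L
      spec$informative_clades[[ic]]
    } else {
      sc <- sc %% length(spec$singleton_taxa) + 1L
      spec$singleton_taxa[sc]
    }
    aln[who, j] <- derived
    carriers[[v]] <- who
  }

  # indel events: runs on conserved columns, pairwise separated by >= 1
  # untouched column and never adjacent to each other
  allowed <- setdiff(seq_len(L), var_cols)
  if (!is.null(spec$indel_cols)) allowed <- intersect(allowed, spec$indel_cols)
  blocked <- logical(L)
  blocked[var_cols] <- TRUE
  groups <- split(taxa, spec$group_labels)
  sub_groups <- Filter(function(g) length(g) < length(taxa), groups)
  indel_events <- list()
  if (spec$n_indel_events > 0) {
    for (e in seq_len(spec$n_indel_events)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        len <- sample.int(spec$indel_max_len, 1)
        start <- sample(allowed, 1)
        run <- start:(start + len - 1L)
        guard <- max(1L, start - 1L):min(L, start + len)
        if (max(run) > L || !all(run %in% allowed) || any(blocked[guard]))
          next
        who <- if (length(sub_groups) && stats::runif(1) < 0.3)
          sub_groups[[sample.int(length(sub_groups), 1)]]
        else sample(taxa, 1)
        aln[who, run] <- "-"
        blocked[guard] <- TRUE
        indel_events[[e]] <- list(cols = run, taxa = who)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("infeasible targets: could not place indel event ", e,
             " (not enough free columns)")
    }
  }

  col_df <- data.frame(col = var_cols, class = classes, event = events,
                       stringsAsFactors = FALSE)
  gap_cols <- sort(unique(unlist(lapply(indel_events, `[[`, "cols"))))
  counts <- list(
    n_variable = spec$n_variable,
    n_informative = spec$n_informative,
    n_singleton = spec$n_variable - spec$n_informative,
    n_gap = length(gap_cols),
    n_indel_events = spec$n_indel_events,
    transitions = spec$ts,
    transversions = spec$tv,
    ratio = paste0(spec$ts, ":", spec$tv)
  )
  per_region <- NULL
  if (!is.null(spec$regions)) {
    per_region <- do.call(rbind, lapply(seq_len(nrow(spec$regions)), function(i) {
      lo <- spec$regions$start[i] + 1L; hi <- spec$regions$end[i]
      inreg <- col_df$col >= lo & col_df$col <= hi
      data.frame(
        region = spec$regions$region[i],
        variable_sites = sum(inreg),
        informative_sites = sum(inreg & col_df$class == "variable_informative"),
        transitions = sum(inreg & col_df$event == "ts"),
        transversions = sum(inreg & col_df$event == "tv"),
        indels = sum(vapply(indel_events, function(ev)
          ev$cols[1] >= lo && ev$cols[1] <= hi, logical(1))),
        stringsAsFactors = FALSE)
    }))
  }
  ledger <- list(columns = col_df, carriers = carriers,
                 indel_events = indel_events, counts = counts,
                 per_region = per_region,
                 realized_gc = mean(apply(aln, 1, gc_content)),
                 group_labels = spec$group_labels)
  list(alignment = aln, ledger = ledger, spec = spec)
}

#' Deterministic packaged study fixture
#'
#' A fixed-seed synthetic data set shaped like a four-species Miscanthus
#' study: (i) a 19-pair, five-cell measurement table with a satellite pair
#' and a CI-44-like profile; (ii) a marker set with one 45S rDNA pair on arm
#' 1L (proximal, di about 25.5\%), its co-localized CPD band, and DAPI bands
#' on pairs 10, 12 and 19 (one of them on a single homologue); (iii) a
#' 660-column ITS1-5.8S-ITS2-like alignment of 24 ingroup accessions (four
#' species of six accessions each) plus one outgroup, with 16 variable
#' columns (8 informative, allocated to the two species groups and two
#' species), three indel events outside the constant-length 5.8S region, and
#' a 4:12 transition:transversion split.
#'
#' @return List with \code{measurements}, \code{truth}, \code{markers},
#'   \code{alignment}, \code{aln_ledger}, \code{regions},
#'   \code{group_labels}, \code{outgroup}, \code{karyotype_spec},
#'   \code{alignment_spec}.
#' @export
miscanthus_fixture <- function() {
  kspec <- karyotype_spec(seed = 101L)
  sim <- simulate_measurements(kspec)

  markers <- cyto_markers(data.frame(
    marker_class = c("rDNA_45S", "CPD_band", "DAPI_band", "DAPI_band",
                     "DAPI_band", "DAPI_band"),
    pair_id = c(1L, 1L, 10L, 12L, 19L, 19L),
    arm = c("L", "L", NA, "L", NA, "L"),
    position_class = c("PROX", "PROX", "CEN", "PCEN", "CEN", "PROX"),
    band_len_um = c(0.69, 0.69, 0.40, 0.48, 0.35, 0.40),
    homologs_present = c("both", "both", "both", "both", "both", "one"),
    d_um = c(0.2553 * kspec$true_long[1], NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE))

  species <- c("Msin", "Mflo", "Msac", "Mlut")
  taxa <- c(unlist(lapply(species, function(s) sprintf("%s_%02d", s, 1:6))),
            "Icyl")
  groups <- stats::setNames(c(rep(species, each = 6), "outgroup"), taxa)
  group_i <- taxa[groups %in% c("Msin", "Mflo")]
  group_ii <- taxa[groups %in% c("Msac", "Mlut")]
  clades <- list(group_i, group_ii, group_i, group_ii, group_i, group_ii,
                 taxa[groups == "Msin"], taxa[groups == "Msac"])
  regions <- data.frame(region = c("ITS1", "5.8S", "ITS2"),
                        start = c(0L, 260L, 417L),
                        end = c(260L, 417L, 660L),
                        stringsAsFactors = FALSE)
  aspec <- alignment_spec(
    n_taxa = length(taxa), length = 660L, group_labels = groups,
    n_variable = 16L, n_informative = 8L, n_indel_events = 3L,
    ts = 4L, tv = 12L, gc_target = 0.62,
    informative_clades = clades,
    singleton_taxa = c(rep("Icyl", 6), "Msin_02", "Mlut_03"),
    indel_cols = c(1:260, 418:660),  # keep 5.8S constant-length
    regions = regions, seed = 7L)
  asim <- simulate_alignment(aspec)

  list(measurements = sim$measurements, truth = sim$truth,
       markers = markers,
       alignment = asim$alignment, aln_ledger = asim$ledger,
       regions = regions, group_labels = groups, outgroup = "Icyl",
       group_i = group_i, group_ii = group_ii,
       karyotype_spec = kspec, alignment_spec = aspec)
}
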