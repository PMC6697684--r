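#' Romero-Zarco intrachromosomal asymmetry index (A1)
#'
#' A1 = 1 - mean(b/B) over homolog-pair means, where b and B are the mean
#' short- and long-arm lengths of each pair. 0 for a perfectly metacentric
#' complement; approaches 1 as centromeres become terminal.
#'
#' @param x A \code{karyotype} object.
#' @return A number in [0, 1).
#' @export
a1_intra <- function(x) {
  stopifnot(inherits(x, "karyotype"))
  1 - mean(x$pairs$mean_short / x$pairs$mean_long)
}

#' Romero-Zarco interchromosomal asymmetry index (A2)
#'
#' A2 = s / mean of the pair total lengths (the coefficient of variation of
#' chromosome length, as a fraction). Sample (n-1) standard deviation.
#'
#' @param x A \code{karyotype} object with >= 2 pairs.
#' @return A non-negative number.
#' @export
a2_inter <- function(x) {
  stopifnot(inherits(x, "karyotype"))
  if (nrow(x$pairs) < 2) stop("A2 needs at least two pairs")
  stats::sd(x$pairs$total_len) / mean(x$pairs$total_len)
}

#' As K%: long-arm share of the complement
#'
#' 100 * (sum of long arms) / (total complement length). 50 for a fully
#' metacentric complement, approaching 100 for a fully telocentric one.
#' Identity: AsK = 100 - 100 * sum(short) / sum(total).
#'
#' @param x A \code{karyotype} object.
#' @return A percentage in (50, 100] when all AR >= 1.
#' @export
as_k_percent <- function(x) {
  stopifnot(inherits(x, "karyotype"))
  100 * sum(x$pairs$mean_long) / sum(x$pairs$total_len)
}

#' Paszko asymmetry index (AI)
#'
#' AI = (CV_CL x CV_CI) / 100, where CV_CL is the percent coefficient of
#' variation of the pair total lengths and CV_CI that of the pair centromeric
#' indices (sample standard deviations). Sensitive to joint heterogeneity of
#' chromosome length and centromere position.
#'
#' @param x A \code{karyotype} object with >= 2 pairs.
#' @return A non-negative number.
#' @export
paszko_ai <- function(x) {
  stopifnot(inherits(x, "karyotype"))
  if (nrow(x$pairs) < 2) stop("AI needs at least two pairs")
  cv_cl <- 100 * stats::sd(x$pairs$total_len) / mean(x$pairs$total_len)
  cv_ci <- 100 * stats::sd(x$pairs$CI) / mean(x$pairs$CI)
  cv_cl * cv_ci / 100
}

#' Stebbins karyotype symmetry category
#'
#' Two-way category: a letter from the longest/shortest chromosome ratio
#' (A: < 2, B: 2-4, C: > 4; boundary values 2 and 4 fall in B) and a digit
#' from the proportion p of chromosomes with arm ratio strictly > 2
#' (1: p = 0; 2: 0 < p <= 0.5; 3: 0.5 < p < 1; 4: p = 1). Returned as
#' digit + letter, e.g. \code{"2B"}.
#'
#' @param x A \code{karyotype} object.
#' @return A 2-character string.
#' @export
stebbins_category <- function(x) {
  stopifnot(inherits(x, "karyotype"))
  eps <- 1e-9   # guard: boundary calls must not flip on arithmetic noise
  ratio <- max(x$pairs$total_len) / min(x$pairs$total_len)
  letter <- if (ratio < 2 - eps) "A" else if (ratio <= 4 + eps) "B" else "C"
  p <- mean(x$pairs$AR > 2 + eps)  # pair-level AR holds for both chromosomes
  digit <- if (p == 0) "1" else if (p <= 0.5) "2" else if (p < 1) "3" else "4"
  paste0(digit, letter)
}

#' Complement-level karyotype indices
#'
#' Bundles the asymmetry statistics and descriptive parameters reported per
#' species in comparative karyotype tables: TCL, mean and SD of the
#' centromeric index, A1, A2, As K%, AI (with its component CVs), the
#' Stebbins category and the relative-length range. The CI spread is taken
#' over the 2n individual chromosomes of the mean cell (per-homolog arm
#' means), matching the "CI +/- SD" reporting style; CI_mean is the mean of
#' the pair centromeric indices.
#'
#' @param x A \code{karyotype} object.
#' @return An object of class \code{"karyotype_indices"} (also returned by
#'   \code{summary()} on a karyotype): a list with elements \code{TCL},
#'   \code{TCL_sd}, \code{CI_mean}, \code{CI_sd}, \code{A1}, \code{A2},
#'   \code{AsK}, \code{AI}, \code{CV_CL}, \code{CV_CI}, \code{stebbins},
#'   \code{RRL_min}, \code{RRL_max}, \code{length_ratio}, \code{formula}.
#' @export
karyotype_indices <- function(x) {
  stopifnot(inherits(x, "karyotype"))
  structure(list(
    species = x$species,
    formula = x$formula,
    two_n = x$two_n,
    TCL = x$TCL,
    TCL_sd = x$TCL_sd,
    CI_mean = mean(x$pairs$CI),
    CI_sd = stats::sd(x$chromosomes$CI),
    A1 = a1_intra(x),
    A2 = a2_inter(x),
    AsK = as_k_percent(x),
    AI = paszko_ai(x),
    CV_CL = 100 * stats::sd(x$pairs$total_len) / mean(x$pairs$total_len),
    CV_CI = 100 * stats::sd(x$pairs$CI) / mean(x$pairs$CI),
    stebbins = stebbins_category(x),
    RRL_min = min(x$pairs$RL),
    RRL_max = max(x$pairs$RL),
    length_ratio = length_ratio(x)
  ), class = "karyotype_indices")
}

#' @export
summary.karyotype <- function(object, ...) {
  karyotype_indices(object)
}

#' @export
print.karyotype_indices <- function(x, ...) {
  cat("Karyotype indices for", x$species, "\n")
  cat("  ", x$formula, "\n")
  cat(sprintf("  TCL %.2f%s um   RRL %.2f~%.2f %%   CI %.2f +/- %.2f\n",
              x$TCL, if (is.na(x$TCL_sd)) "" else sprintf(" +/- %.2f", x$TCL_sd),
              x$RRL_min, x$RRL_max, x$CI_mean, x$CI_sd))
  cat(sprintf("  A1 %.2f   A2 %.2f   As K%% %.2f   AI %.2f   Stebbins %s\n",
              x$A1, x$A2, x$AsK, x$AI, x$stebbins))
  invisible(x)
}
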