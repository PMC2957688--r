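# Closed-form error-rate model for choosing the RHS cutoff --------------
#
# An autozygous segment transmitted through a consanguinity loop of
# m + n meioses is interrupted by crossovers at rate lambda = (m+n)/100
# per cM (Haldane), so its genetic length is exponential with that rate.
# Inter-heterozygote spacings in non-autozygous chromatin are likewise
# modeled as exponential with rate N_het / L_autosome. Both rates feed the
# closed-form false-negative and false-positive rate curves from which the
# RHS genetic-length cutoff c is chosen.

#' Autozygous-segment length density
#'
#' Exponential density of the genetic length of an autozygous segment for
#' a subject `m + n` meioses around the consanguinity loop:
#' `lambda * exp(-lambda * x)` with `lambda = (m + n)/100` per cM. A good
#' approximation when segments are much shorter than the chromosome.
#'
#' @param m_plus_n total meioses in the loop (>= 2; 6 for the offspring of
#'   a first-cousin marriage).
#' @param x_cm genetic length(s) in cM, >= 0.
#' @return density value(s).
#' @export
as_length_pdf <- function(m_plus_n, x_cm) {
  if (m_plus_n < 2) stop("m_plus_n must be >= 2")
  if (any(x_cm < 0)) stop("x_cm must be >= 0")
  lam <- m_plus_n / 100
  lam * exp(-lam * x_cm)
}

#' False-negative rate of RHS detection at a given cutoff
#'
#' Length-weighted fraction of autozygous segments shorter than the cutoff
#' and therefore missed: `1 - exp(-lambda*c) * (1 + lambda*c)` with
#' `lambda = (m + n)/100`.
#'
#' @inheritParams as_length_pdf
#' @param cutoff_cm RHS genetic-length cutoff c in cM, >= 0 (vectorized).
#' @return rate in `[0, 1)`.
#' @export
false_negative_rate <- function(m_plus_n, cutoff_cm) {
  if (m_plus_n < 2) stop("m_plus_n must be >= 2")
  if (any(cutoff_cm < 0)) stop("cutoff_cm must be >= 0")
  lc <- m_plus_n / 100 * cutoff_cm
  1 - exp(-lc) * (1 + lc)
}

#' Type A false-positive rate
#'
#' Expected fraction of the autosomes covered by runs of homozygous SNPs
#' that contain no autozygous segment, assuming heterozygous SNPs fall as
#' a Poisson process of rate `lambda = n_het / l_autosome_cm` per cM:
#' `(1 + lambda*c) * exp(-lambda*c)`.
#'
#' @param n_het number of heterozygous SNPs genome-wide (after error
#'   correction), >= 1.
#' @param l_autosome_cm total autosomal genetic length in cM.
#' @param cutoff_cm cutoff c in cM (vectorized).
#' @return rate in `(0, 1]`.
#' @export
type_a_false_positive_rate <- function(n_het, l_autosome_cm, cutoff_cm) {
  if (n_het < 1) stop("n_het must be >= 1")
  if (l_autosome_cm <= 0) stop("l_autosome_cm must be > 0")
  lc <- n_het / l_autosome_cm * cutoff_cm
  (1 + lc) * exp(-lc)
}

#' Type B false-positive rate
#'
#' Each detected RHS is assumed to overhang a contained autozygous segment
#' by on average half an inter-heterozygote spacing,
#' `L_autosome / (2 * n_het)` cM, at each end; the summed overhang as a
#' fraction of the autosomes is `n_rhs / n_het`. Deliberately an
#' overestimate (every RHS is assumed to contain a segment), which is
#' preferable to an underestimate when choosing the cutoff.
#'
#' @param n_rhs observed number of RHSs.
#' @param n_het number of heterozygous SNPs genome-wide, >= 1.
#' @return rate, >= 0.
#' @export
type_b_false_positive_rate <- function(n_rhs, n_het) {
  if (n_het < 1) stop("n_het must be >= 1")
  if (any(n_rhs < 0)) stop("n_rhs must be >= 0")
  n_rhs / n_het
}

#' Combined false-positive rate
#'
#' Sum of [type_a_false_positive_rate()] and
#' [type_b_false_positive_rate()].
#'
#' @inheritParams type_a_false_positive_rate
#' @inheritParams type_b_false_positive_rate
#' @export
false_positive_rate <- function(n_het, l_autosome_cm, cutoff_cm, n_rhs) {
  type_a_false_positive_rate(n_het, l_autosome_cm, cutoff_cm) +
    type_b_false_positive_rate(n_rhs, n_het)
}

#' Expected zygosity counts from mean allele frequencies
#'
#' Under Hardy-Weinberg proportions with mean major/minor allele
#' frequencies across the array, the expected numbers of homozygous and
#' heterozygous SNPs among `n_pt` successfully genotyped SNPs.
#'
#' @param mean_major_freq,mean_minor_freq mean allele frequencies; must sum
#'   to 1.
#' @param n_pt number of SNPs successfully genotyped.
#' @return named vector `c(n_hom, n_het)`; the two sum to `n_pt`.
#' @export
expected_zygosity_counts <- function(mean_major_freq, mean_minor_freq, n_pt) {
  if (abs(mean_major_freq + mean_minor_freq - 1) > 1e-9) {
    stop("allele frequencies must sum to 1")
  }
  if (mean_major_freq < 0 || mean_minor_freq < 0) {
    stop("allele frequencies must be non-negative")
  }
  c(n_hom = (mean_major_freq^2 + mean_minor_freq^2) * n_pt,
    n_het = 2 * mean_major_freq * mean_minor_freq * n_pt)
}

#' Error-rate table over a grid of candidate cutoffs
#'
#' Evaluates the false-negative and false-positive curves on a cutoff grid,
#' either from explicitly supplied summaries or directly from a sample's
#' call table (in which case `n_het` and the per-cutoff RHS counts are
#' measured from the data; run error correction first). The bundled
#' default cutoff used throughout the package is 0.6 cM, at which the
#' false-negative rate for a first-cousin offspring is about 6e-4.
#'
#' @param calls optional [as_calls()] table to measure `n_het`,
#'   `l_autosome_cm` and RHS counts from.
#' @param m_plus_n meioses in the loop for the false-negative curve.
#' @param c_grid cutoff grid in cM.
#' @param n_het,l_autosome_cm,run_lengths_cm summaries used when `calls` is
#'   not given; `run_lengths_cm` are the genetic lengths of all maximal
#'   homozygous runs (the RHS count at cutoff c is `sum(run_lengths_cm > c)`).
#' @param chrom_lengths_cm optional named per-chromosome lengths (cM) used
#'   when measuring from `calls`.
#' @return data frame with columns `cutoff_cm`, `r_false_negative`,
#'   `r_type_a`, `r_type_b`, `r_false_positive`.
#' @export
cutoff_table <- function(calls = NULL, m_plus_n = 6,
                         c_grid = seq(0, 3, by = 0.01),
                         n_het = NULL, l_autosome_cm = NULL,
                         run_lengths_cm = NULL, chrom_lengths_cm = NULL) {
  if (!is.null(calls)) {
    n_het <- zygosity_counts(calls)$n_het
    l_autosome_cm <- .genome_length_cm(calls, chrom_lengths_cm)
    runs <- .candidate_runs(calls, chrom_lengths_cm)
    run_lengths_cm <- runs$end_cm - runs$start_cm
  }
  if (is.null(n_het) || is.null(l_autosome_cm)) {
    stop("supply calls, or n_het and l_autosome_cm")
  }
  n_rhs <- if (is.null(run_lengths_cm)) {
    rep(0, length(c_grid))
  } else {
    vapply(c_grid, function(cc) sum(run_lengths_cm > cc), numeric(1))
  }
  data.frame(
    cutoff_cm = c_grid,
    r_false_negative = false_negative_rate(m_plus_n, c_grid),
    r_type_a = type_a_false_positive_rate(n_het, l_autosome_cm, c_grid),
    r_type_b = type_b_false_positive_rate(n_rhs, n_het),
    r_false_positive = false_positive_rate(n_het, l_autosome_cm, c_grid,
                                           n_rhs))
}
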