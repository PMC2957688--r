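# Genotyping-error correction -------------------------------------------
#
# A mistyped heterozygous call inside a long homozygous run sits much
# further from its neighbouring heterozygous SNPs than chance allows.
# With inter-heterozygote gaps modeled as independent Exp(lambda), the
# combined flanking distance d = x + y around a heterozygous SNP is
# Erlang-2, so P(distance >= d by chance) = (1 + lambda*d) * exp(-lambda*d).
# Calls below a probability threshold are removed (set to no-call).

#' Chance probability of an observed inter-heterozygote spacing
#'
#' Survival probability that the sum of the two flanking gaps around a
#' heterozygous SNP reaches `gap_cm` under independent exponential gaps:
#' `(1 + lambda*d) * exp(-lambda*d)`.
#'
#' @param lambda_het genome-wide heterozygous-SNP density per cM (> 0).
#' @param gap_cm observed flanking distance d = x + y in cM (vectorized).
#' @return probability in `(0, 1]`.
#' @export
p_distance_by_chance <- function(lambda_het, gap_cm) {
  if (lambda_het <= 0) stop("lambda_het must be > 0")
  if (any(gap_cm < 0)) stop("gap_cm must be >= 0")
  ld <- lambda_het * gap_cm
  (1 + ld) * exp(-ld)
}

#' Genome-wide heterozygote density of a sample
#'
#' `n_het / L` per cM, with `L` the genetic length of the chromosomes the
#' sample covers.
#'
#' @inheritParams detect_rhs
#' @export
lambda_het <- function(calls, chrom_lengths_cm = NULL) {
  L <- .genome_length_cm(calls, chrom_lengths_cm)
  if (L <= 0) stop("genome length is 0")
  zygosity_counts(calls)$n_het / L
}

#' Remove likely-mistyped heterozygous calls
#'
#' For every heterozygous SNP the distance from the previous heterozygous
#' SNP (or the chromosome start) to the next one (or the chromosome map
#' end), measured in the observed data, is scored with
#' [p_distance_by_chance()]; every call below `threshold` is set to
#' no-call, simultaneously. Distances are deliberately not re-measured
#' among the survivors: a removed call's flanking distance would accrue
#' wholesale to its neighbour, pushing it below any threshold in turn, so
#' re-scanning diverges and removes every heterozygote on the chromosome.
#' Under observed-data distances the single pass is its own fixpoint.
#' `lambda` is the genome-wide density before any removal. Only
#' heterozygous-to-no-call transitions ever occur.
#'
#' @param calls a [as_calls()] table.
#' @param threshold removal cutoff on the chance probability (default 0.01).
#' @param lambda heterozygote density per cM; default [lambda_het()]
#'   measured from `calls` before any removal.
#' @param chrom_lengths_cm optional named chromosome lengths (cM).
#' @return list with `calls` (corrected table) and `report`, a data frame
#'   of removed SNPs (`snp_id`, `chrom`, `pos_bp`, `pos_cm`, `p_chance`)
#'   with attributes `lambda` and `threshold`.
#' @export
correct_calls <- function(calls, threshold = 0.01, lambda = NULL,
                          chrom_lengths_cm = NULL) {
  empty <- data.frame(snp_id = character(), chrom = integer(),
                      pos_bp = numeric(), pos_cm = numeric(),
                      p_chance = numeric())
  if (zygosity_counts(calls)$n_het == 0) {
    attr(empty, "lambda") <- lambda
    attr(empty, "threshold") <- threshold
    return(list(calls = calls, report = empty))
  }
  if (is.null(lambda)) lambda <- lambda_het(calls, chrom_lengths_cm)
  rem_idx <- integer(0)
  rem_p <- numeric(0)
  for (ch in sort(unique(calls$chrom))) {
    idx <- which(calls$chrom == ch)
    cm <- calls$pos_cm[idx]
    L <- if (is.null(chrom_lengths_cm)) max(cm) else
      chrom_lengths_cm[[as.character(ch)]]
    hets <- which(calls$call[idx] == "AB")
    if (length(hets) == 0) next
    hcm <- cm[hets]
    k <- length(hets)
    d <- c(hcm[-1], L) - c(0, hcm[-k])
    p <- p_distance_by_chance(lambda, d)
    bad <- p < threshold
    if (any(bad)) {
      rem_idx <- c(rem_idx, idx[hets[bad]])
      rem_p <- c(rem_p, p[bad])
      calls$call[idx[hets[bad]]] <- "NC"
    }
  }
  report <- if (length(rem_idx) > 0) {
    data.frame(snp_id = calls$snp_id[rem_idx], chrom = calls$chrom[rem_idx],
               pos_bp = calls$pos_bp[rem_idx],
               pos_cm = calls$pos_cm[rem_idx], p_chance = rem_p)
  } else {
    empty
  }
  attr(report, "lambda") <- lambda
  attr(report, "threshold") <- threshold
  list(calls = calls, report = report)
}

#' Inject genotyping errors
#'
#' Selects `floor(n_called * error_rate)` successfully genotyped SNPs
#' uniformly without replacement and flips each to a different call drawn
#' uniformly from the remaining two genotypes. Used to emulate array
#' mistyping (error rate 0.003 for a high-density array) when validating
#' the correction.
#'
#' @param calls a [as_calls()] table.
#' @param error_rate per-SNP error probability in `[0, 1]`.
#' @param seed optional integer seed for reproducible selection.
#' @return list with `calls` (corrupted table) and `n_injected`.
#' @export
inject_errors <- function(calls, error_rate = 0.003, seed = NULL) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  called <- which(calls$call != "NC")
  k <- floor(length(called) * error_rate)
  if (k > 0) {
    pick <- called[sample.int(length(called), k)]
    other <- list(AA = c("AB", "BB"), AB = c("AA", "BB"),
                  BB = c("AA", "AB"))
    flip <- vapply(calls$call[pick],
                   function(g) other[[g]][sample.int(2L, 1L)], character(1),
                   USE.NAMES = FALSE)
    calls$call[pick] <- flip
  }
  list(calls = calls, n_injected = k)
}
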