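# RHS detection and consanguinity estimation ----------------------------

# Maximal stretches without a heterozygous call, per chromosome.
# Bounds: genetic bounds at the flanking heterozygous SNPs (or chromosome
# map ends, [0, L]); physical bounds at the outermost homozygous SNPs
# (0-based half-open). No-calls are ignored throughout. Returns every
# candidate run containing at least one homozygous SNP, with its count.
.candidate_runs <- function(calls, chrom_lengths_cm = NULL) {
  out <- list()
  l_total <- 0
  for (ch in sort(unique(calls$chrom))) {
    d <- calls[calls$chrom == ch & calls$call != "NC", , drop = FALSE]
    L <- if (is.null(chrom_lengths_cm)) {
      if (nrow(d) > 0) max(d$pos_cm) else 0
    } else {
      Lc <- chrom_lengths_cm[[as.character(ch)]]
      if (is.null(Lc) || is.na(Lc)) stop("no length for chromosome ", ch)
      Lc
    }
    l_total <- l_total + L
    if (nrow(d) == 0) next
    het <- which(d$call == "AB")
    lo <- c(0L, het)             # left flanking het index (0 = chrom start)
    hi <- c(het, nrow(d) + 1L)   # right flanking het index
    n_hom <- hi - lo - 1L
    sel <- n_hom >= 1L
    if (!any(sel)) next
    start_cm <- c(0, d$pos_cm[het])[sel]
    end_cm <- c(d$pos_cm[het], L)[sel]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch,
      start_bp = d$pos_bp[lo[sel] + 1L] - 1,
      end_bp = d$pos_bp[hi[sel] - 1L],
      start_cm = start_cm,
      end_cm = end_cm,
      n_snps = n_hom[sel])
  }
  runs <- if (length(out) > 0) {
    do.call(rbind, out)
  } else {
    data.frame(chrom = integer(), start_bp = numeric(), end_bp = numeric(),
               start_cm = numeric(), end_cm = numeric(), n_snps = integer())
  }
  attr(runs, "l_autosome_cm") <- l_total
  runs
}

#' Detect runs of homozygous SNPs (RHSs)
#'
#' An RHS is a maximal stretch of calls containing no heterozygous SNP,
#' with at least `min_snps` homozygous SNPs, whose genetic length is
#' strictly greater than `cutoff_cm`. Genetic bounds extend to the
#' flanking heterozygous SNPs (or the chromosome map ends), matching the
#' end-overhang accounting of the type B false-positive model; physical
#' bounds come from the outermost homozygous SNPs. No-calls neither break
#' nor extend a run. Run genotyping-error correction
#' ([correct_calls()]) first.
#'
#' @param calls a [as_calls()] table (one sample).
#' @param cutoff_cm RHS genetic-length cutoff in cM (default 0.6).
#' @param min_snps minimum homozygous SNPs per run (default 1).
#' @param chrom_lengths_cm optional named vector of chromosome genetic
#'   lengths (cM); defaults to each chromosome's last marker position.
#' @return a [as_segments()] table of kind `RHS`, with the sample's total
#'   autosomal genetic length attached for [estimate_f()].
#' @export
detect_rhs <- function(calls, cutoff_cm = 0.6, min_snps = 1,
                       chrom_lengths_cm = NULL) {
  if (cutoff_cm < 0) stop("cutoff_cm must be >= 0")
  if (min_snps < 1) stop("min_snps must be >= 1")
  runs <- .candidate_runs(calls, chrom_lengths_cm)
  sel <- (runs$end_cm - runs$start_cm) > cutoff_cm & runs$n_snps >= min_snps
  runs <- runs[sel, , drop = FALSE]
  runs$kind <- rep("RHS", nrow(runs))
  as_segments(runs, sample_id = attr(calls, "sample_id"),
              l_autosome_cm = attr(runs, "l_autosome_cm"))
}

#' Genetic length of the longest RHS
#'
#' The longest run is an index of the most recent inbreeding in the
#' family: the expected segment length shrinks as 100/(m+n) cM with the
#' number of meioses in the loop.
#'
#' @param segments a [as_segments()] table.
#' @return length in cM; 0 when there are no segments.
#' @export
longest_rhs_cm <- function(segments) {
  if (nrow(segments) == 0) return(0)
  max(genetic_length_cm(segments))
}

#' Estimate the coefficient of consanguinity from RHSs
#'
#' `F` is estimated as the total genetic length of the RHSs divided by the
#' total genetic length of the autosomes; for the offspring of a
#' first-cousin marriage the pedigree expectation is 1/16.
#'
#' @param segments a [as_segments()] table of RHSs.
#' @param l_autosome_cm total autosomal length in cM; defaults to the
#'   attribute recorded by [detect_rhs()], else the bundled table.
#' @return estimate in `[0, 1]`.
#' @export
estimate_f <- function(segments, l_autosome_cm = NULL) {
  L <- l_autosome_cm %||% attr(segments, "l_autosome_cm") %||%
    total_autosome_cm()
  if (L <= 0) stop("l_autosome_cm must be > 0")
  sum(genetic_length_cm(segments)) / L
}
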