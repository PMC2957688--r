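# Shared fixtures and independent oracles used across the suite.

# Build a one-sample call table from parallel vectors.
toy_calls <- function(call, pos_cm, chrom = 1, pos_bp = NULL,
                      sample_id = "toy") {
  n <- length(call)
  if (is.null(pos_bp)) pos_bp <- round(pos_cm * 1e6) + seq_len(n)
  as_calls(data.frame(snp_id = sprintf("s%03d", seq_len(n)),
                      chrom = rep_len(chrom, n), pos_bp = pos_bp,
                      pos_cm = pos_cm, call = call),
           sample_id = sample_id)
}

# Random single-chromosome track for oracle comparisons.
random_track <- function(n, L = 5,
                         probs = c(AA = 0.35, AB = 0.2, BB = 0.35,
                                   NC = 0.1)) {
  cm <- sort(runif(n, 0, L))
  toy_calls(sample(names(probs), n, replace = TRUE, prob = probs), cm)
}

# Exhaustive RHS oracle: tests every sub-interval [i, j] of the called
# SNPs of a single-chromosome track for being a maximal heterozygote-free
# run, then applies the length and SNP-count rules. O(n^2), independent of
# the detection code path.
oracle_rhs <- function(calls, cutoff_cm, min_snps, L) {
  d <- as.data.frame(calls)
  d <- d[d$call != "NC", , drop = FALSE]
  n <- nrow(d)
  if (n == 0) {
    return(data.frame(start_cm = numeric(), end_cm = numeric(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer()))
  }
  I <- rep(seq_len(n), times = n)
  J <- rep(seq_len(n), each = n)
  keep <- J >= I
  I <- I[keep]
  J <- J[keep]
  hc <- cumsum(d$call == "AB")
  no_het <- (hc[J] - c(0, hc)[I]) == 0
  left_max <- I == 1 | d$call[pmax(I - 1, 1)] == "AB"
  right_max <- J == n | d$call[pmin(J + 1, n)] == "AB"
  sel <- no_het & left_max & right_max
  I <- I[sel]
  J <- J[sel]
  lo <- ifelse(I == 1, 0, d$pos_cm[pmax(I - 1, 1)])
  hi <- ifelse(J == n, L, d$pos_cm[pmin(J + 1, n)])
  ok <- (hi - lo) > cutoff_cm & (J - I + 1) >= min_snps
  out <- data.frame(start_cm = as.numeric(lo[ok]),
                    end_cm = as.numeric(hi[ok]),
                    start_bp = as.numeric(d$pos_bp[I[ok]] - 1),
                    end_bp = as.numeric(d$pos_bp[J[ok]]),
                    n_snps = as.integer(J[ok] - I[ok] + 1))
  out[order(out$start_cm), , drop = FALSE]
}

# Upper-tail standard normal probability by direct quadrature of the
# density, independent of pnorm.
oracle_normal_tail <- function(u) {
  vapply(u, function(z) {
    stats::integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi), z, Inf,
                     rel.tol = 1e-13, abs.tol = 1e-16)$value
  }, numeric(1))
}

# Summed genetic length of each truth segment covered by a segment set.
covered_length_cm <- function(truth, segs) {
  vapply(seq_len(nrow(truth)), function(i) {
    r <- segs[segs$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(r) == 0) return(0)
    sum(pmax(0, pmin(r$end_cm, truth$end_cm[i]) -
               pmax(r$start_cm, truth$start_cm[i])))
  }, numeric(1))
}

# A small synthetic configuration for fast end-to-end tests.
small_config <- function(...) {
  synth_config(n_snps_per_chrom = 1500, chrom_lengths_cm = rep(60, 2), ...)
}
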