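# RHS overlap across patients and case-control prioritization -----------

# normalize a segment table to the columns the interval algebra needs
.seg_core <- function(s) {
  as.data.frame(s)[c("chrom", "start_bp", "end_bp", "start_cm", "end_cm")]
}

.intersect2 <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    A <- a[a$chrom == ch, , drop = FALSE]
    B <- b[b$chrom == ch, , drop = FALSE]
    g <- expand.grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
    st <- pmax(A$start_cm[g$i], B$start_cm[g$j])
    en <- pmin(A$end_cm[g$i], B$end_cm[g$j])
    keep <- en > st
    if (!any(keep)) next
    # genetic bounds are authoritative; physical bounds are the
    # intersection of the contributors', padded to 1 bp when a sliver
    # overlap in cM has no shared homozygous SNP span
    sbp <- pmax(A$start_bp[g$i], B$start_bp[g$j])[keep]
    ebp <- pmin(A$end_bp[g$i], B$end_bp[g$j])[keep]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start_bp = sbp, end_bp = pmax(ebp, sbp + 1),
      start_cm = st[keep], end_cm = en[keep])
  }
  if (length(out) > 0) {
    do.call(rbind, out)
  } else {
    a[0, , drop = FALSE]
  }
}

#' Intersect RHS sets across patients
#'
#' Maximal intervals covered by an RHS in every input set, in genetic
#' coordinates (half-open). A single input set is returned unchanged.
#'
#' @param region_sets list of [as_segments()] tables, one per patient,
#'   called with identical pipeline parameters.
#' @return a [as_segments()] table of kind `OVERLAP` (`n_snps` is `NA`).
#' @export
intersect_regions <- function(region_sets) {
  if (length(region_sets) == 0) stop("need at least one region set")
  if (length(region_sets) == 1) return(region_sets[[1]])
  acc <- .seg_core(region_sets[[1]])
  for (s in region_sets[-1]) {
    acc <- .intersect2(acc, .seg_core(s))
  }
  acc$n_snps <- rep(NA_integer_, nrow(acc))
  acc$kind <- rep("OVERLAP", nrow(acc))
  as_segments(acc)
}

# which SNP genetic positions are covered by a (disjoint, sorted) segment
# set; half-open [start_cm, end_cm)
.covered <- function(chrom, pos_cm, segs) {
  out <- logical(length(pos_cm))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ss <- segs[segs$chrom == ch, , drop = FALSE]
    if (nrow(ss) == 0) next
    ss <- ss[order(ss$start_cm), , drop = FALSE]
    i <- findInterval(pos_cm[sel], ss$start_cm)
    out[sel] <- i > 0 & pos_cm[sel] < ss$end_cm[pmax(i, 1L)]
  }
  out
}

#' Per-SNP RHS sharing counts in cases and controls
#'
#' For each SNP, counts the patients (`x1` of `n1`) and controls (`x2` of
#' `n2`) whose RHS set covers the SNP's genetic position.
#'
#' @param snps data frame with columns `snp_id`, `chrom`, `pos_cm`.
#' @param patient_sets,control_sets lists of [as_segments()] tables
#'   computed with identical pipeline parameters.
#' @return data frame `snp_id`, `chrom`, `pos_cm`, `x1`, `n1`, `x2`, `n2`.
#' @export
sharing_counts <- function(snps, patient_sets, control_sets) {
  count_over <- function(sets) {
    if (length(sets) == 0) return(integer(nrow(snps)))
    rowSums(vapply(sets,
                   function(s) .covered(snps$chrom, snps$pos_cm, s),
                   logical(nrow(snps))))
  }
  data.frame(snp_id = snps$snp_id, chrom = snps$chrom, pos_cm = snps$pos_cm,
             x1 = count_over(patient_sets), n1 = length(patient_sets),
             x2 = count_over(control_sets), n2 = length(control_sets))
}

#' Case-control sharing statistic
#'
#' Two-proportion z statistic with +0.5 continuity corrections:
#' `p1* = (x1 + 0.5)/(n1 + 1)`, `p2* = (x2 + 0.5)/(n2 + 1)`,
#' `p* = (x1 + x2 + 0.5)/(n1 + n2 + 1)`,
#' `u = (p1* - p2*) / sqrt(p*(1 - p*)(1/n1 + 1/n2))`,
#' with a one-sided upper-tail standard normal P value and `-log10(P)`.
#'
#' @param x1 patients sharing an RHS at the SNP (or a data frame from
#'   [sharing_counts()], in which case the remaining count arguments are
#'   taken from its columns).
#' @param n1 total patients.
#' @param x2 controls sharing an RHS at the SNP.
#' @param n2 total controls.
#' @param n1_only_variance use `(1/n1 + 1/n1)` in the variance instead of the
#'   standard `(1/n1 + 1/n2)`.
#' @return data frame with columns `u`, `p_value`, `neg_log10_p` (plus the
#'   input columns when a data frame was supplied).
#' @export
u_statistic <- function(x1, n1 = NULL, x2 = NULL, n2 = NULL,
                        n1_only_variance = FALSE) {
  counts <- NULL
  if (is.data.frame(x1)) {
    counts <- x1
    n1 <- counts$n1
    x2 <- counts$x2
    n2 <- counts$n2
    x1 <- counts$x1
  }
  if (any(x1 < 0 | x1 > n1) || any(x2 < 0 | x2 > n2)) {
    stop("need 0 <= x <= n")
  }
  if (any(n1 < 1) || any(n2 < 1)) stop("n1 and n2 must be >= 1")
  p1 <- (x1 + 0.5) / (n1 + 1)
  p2 <- (x2 + 0.5) / (n2 + 1)
  pp <- (x1 + x2 + 0.5) / (n1 + n2 + 1)
  stopifnot(all(pp > 0 & pp < 1))
  v <- pp * (1 - pp) * (1 / n1 + if (n1_only_variance) 1 / n1 else 1 / n2)
  u <- (p1 - p2) / sqrt(v)
  lp <- stats::pnorm(u, lower.tail = FALSE, log.p = TRUE)
  res <- data.frame(u = u, p_value = exp(lp), neg_log10_p = -lp / log(10))
  if (!is.null(counts)) cbind(counts, res) else res
}

#' Rank RHS overlaps by their case-control evidence
#'
#' Annotates each overlap with the maximum `-log10(P)` over the SNPs it
#' contains and sorts descending; ties break by genetic length (longer
#' first), then genomic coordinate. Overlaps containing no scored SNP rank
#' last.
#'
#' @param overlaps a [as_segments()] table from [intersect_regions()].
#' @param snp_stats data frame with columns `chrom`, `pos_cm`,
#'   `neg_log10_p` (e.g. [u_statistic()] on [sharing_counts()]).
#' @return the overlap table with `max_neg_log10_p` and `rank` columns,
#'   sorted by rank.
#' @export
rank_overlaps <- function(overlaps, snp_stats) {
  df <- as.data.frame(overlaps)
  score <- vapply(seq_len(nrow(df)), function(i) {
    s <- snp_stats[snp_stats$chrom == df$chrom[i] &
                     snp_stats$pos_cm >= df$start_cm[i] &
                     snp_stats$pos_cm < df$end_cm[i], , drop = FALSE]
    if (nrow(s) == 0) -Inf else max(s$neg_log10_p)
  }, numeric(1))
  df$max_neg_log10_p <- score
  len <- df$end_cm - df$start_cm
  ord <- order(-score, -len, df$chrom, df$start_cm)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
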