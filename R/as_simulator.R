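# Monte Carlo simulation of autozygous segments -------------------------
#
# The consanguinity loop is modeled with a common-ancestor couple (four
# founder haplotypes). The subject's paternal homolog is the composition
# of m Haldane-model meioses down the paternal side of the loop, the
# maternal homolog of n meioses down the maternal side; autozygous
# segments (ASs) are the intervals where both homologs carry the same
# founder haplotype. Crossovers are an interference-free Poisson process
# at 1 per 100 cM per meiosis. The heavy lifting is done in compiled code.

#' Consanguinity-loop configuration
#'
#' @param m,n meioses from the common-ancestor couple to the subject on
#'   the paternal and maternal side (>= 1 each; first-cousin parents give
#'   m = n = 3).
#' @param chrom_lengths_cm chromosome genetic lengths in cM; defaults to
#'   the bundled sex-averaged autosome table.
#' @param n_events for [longest_as_distribution()]: number of events with
#'   at least one AS to accumulate (default 100,000).
#' @param seed optional integer seed.
#' @return object of class `qhm_loop_config`.
#' @export
loop_config <- function(m, n, chrom_lengths_cm = autosome_lengths_cm(),
                        n_events = 100000, seed = NULL) {
  if (m < 1 || n < 1) stop("m and n must be >= 1")
  if (m != round(m) || n != round(n)) stop("m and n must be integers")
  if (any(chrom_lengths_cm <= 0)) stop("chromosome lengths must be > 0")
  if (n_events < 1) stop("n_events must be >= 1")
  if (is.null(names(chrom_lengths_cm))) {
    names(chrom_lengths_cm) <- as.character(seq_along(chrom_lengths_cm))
  }
  structure(list(m = as.integer(m), n = as.integer(n),
                 chrom_lengths_cm = chrom_lengths_cm,
                 n_events = as.integer(n_events), seed = seed),
            class = "qhm_loop_config")
}

#' Simulate one meiotic crossover mosaic
#'
#' Haldane model: crossover breakpoints form a Poisson process at rate
#' 1/100 per cM along the chromosome, and the starting phase (which of the
#' two parental homologs the gamete begins on) is a fair coin.
#'
#' @param length_cm chromosome genetic length in cM (> 0).
#' @return list with sorted `breakpoints` (cM) and `start_phase` (0 or 1).
#' @export
simulate_meiosis_mosaic <- function(length_cm) {
  if (length_cm <= 0) stop("length_cm must be > 0")
  k <- stats::rpois(1, length_cm / 100)
  list(breakpoints = sort(stats::runif(k, 0, length_cm)),
       start_phase = stats::rbinom(1, 1, 0.5))
}

# chromosome labels for a config (names of the length vector)
.loop_chroms <- function(config) {
  as.integer(names(config$chrom_lengths_cm))
}

#' Simulate one descent through the consanguinity loop
#'
#' Draws the founder-origin label mosaics of the subject's two homologs on
#' every chromosome and extracts the autozygous segments. Physical
#' coordinates use the toy scale 1 cM = 1 Mb.
#'
#' @param config a [loop_config()].
#' @param seed optional seed.
#' @return a [as_segments()] table of kind `AS`, with attribute `mosaic`:
#'   one data frame per chromosome with the joint founder labels
#'   (`start_cm`, `end_cm`, `lab_p`, `lab_m`; 0 = outside the loop,
#'   1-4 = founder haplotypes).
#' @export
simulate_loop_event <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mos <- cpp_loop_mosaic(config$m, config$n,
                         unname(config$chrom_lengths_cm))
  names(mos) <- names(config$chrom_lengths_cm)
  chroms <- .loop_chroms(config)
  segs <- list()
  for (i in seq_along(mos)) {
    p <- mos[[i]]
    hit <- p$lab_p > 0 & p$lab_p == p$lab_m
    if (!any(hit)) next
    segs[[length(segs) + 1L]] <- data.frame(
      chrom = chroms[i], start_cm = p$start_cm[hit], end_cm = p$end_cm[hit])
  }
  df <- if (length(segs) > 0) {
    do.call(rbind, segs)
  } else {
    data.frame(chrom = integer(), start_cm = numeric(), end_cm = numeric())
  }
  df$start_bp <- floor(df$start_cm * 1e6)
  df$end_bp <- pmax(ceiling(df$end_cm * 1e6), df$start_bp + 1)
  df$n_snps <- rep(NA_integer_, nrow(df))
  df$kind <- rep("AS", nrow(df))
  out <- as_segments(df, l_autosome_cm = sum(config$chrom_lengths_cm))
  attr(out, "mosaic") <- mos
  out
}

#' Batch simulation of loop events
#'
#' Runs `n_events` independent descents and reports per-event AS counts
#' and genetic lengths. Optionally keeps the AS endpoints on one
#' chromosome for distributional checks.
#'
#' @param config a [loop_config()].
#' @param n_events number of events (default from `config`).
#' @param keep_chrom 1-based index into `chrom_lengths_cm` of a chromosome
#'   whose AS endpoints to return (0 = none).
#' @param seed optional seed (default from `config`).
#' @return data frame with one row per event (`n_as`, `total_cm`,
#'   `max_cm`). When `keep_chrom > 0`, attribute `segments` holds a data
#'   frame (`event`, `start_cm`, `end_cm`) and attribute `chrom_length_cm`
#'   that chromosome's length.
#' @export
simulate_loop_events <- function(config, n_events = config$n_events,
                                 keep_chrom = 0, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  r <- cpp_loop_events(config$m, config$n, unname(config$chrom_lengths_cm),
                       as.integer(n_events), as.integer(keep_chrom))
  out <- data.frame(n_as = r$stats[, 1], total_cm = r$stats[, 2],
                    max_cm = r$stats[, 3])
  if (keep_chrom > 0) {
    attr(out, "segments") <- data.frame(event = r$seg_event,
                                        start_cm = r$seg_start,
                                        end_cm = r$seg_end)
    attr(out, "chrom_length_cm") <- config$chrom_lengths_cm[[keep_chrom]]
  }
  out
}

#' Distribution of the longest autozygous segment
#'
#' Repeats loop descents until `config$n_events` events with at least one
#' AS have been observed, and summarizes the per-event longest-AS lengths.
#' The lower end of the central 95% range (the 2.5% quantile) is the
#' benchmark against which an observed longest RHS is judged: for a
#' first-cousin offspring (m + n = 6) a longest RHS below about 21 cM
#' makes the reported family history unlikely.
#'
#' @param config a [loop_config()].
#' @param probs quantile levels to report.
#' @param seed optional seed (default from `config`).
#' @return object of class `qhm_as_summary`: list with `mean_count`,
#'   `mean_length_cm`, `max_length_samples` (per-event longest AS, length
#'   `n_events`), `autozygous_fraction` (mean total AS length over all
#'   events, including AS-free ones, divided by genome length),
#'   `quantiles_cm`, and the config.
#' @export
longest_as_distribution <- function(config,
                                    probs = c(0.01, 0.025, 0.05, 0.25, 0.5,
                                              0.75, 0.95, 0.975, 0.99),
                                    seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  want <- config$n_events
  lens <- unname(config$chrom_lengths_cm)
  mx <- cnt <- tot <- numeric(0)
  n_all <- 0L
  tot_all <- 0
  guard <- 0L
  while (length(mx) < want) {
    todo <- want - length(mx)
    batch <- max(1000L, ceiling(todo * 1.2))
    r <- cpp_loop_events(config$m, config$n, lens, batch, 0L)
    s <- r$stats
    n_all <- n_all + nrow(s)
    tot_all <- tot_all + sum(s[, 2])
    q <- s[, 1] >= 1
    mx <- c(mx, s[q, 3])
    cnt <- c(cnt, s[q, 1])
    tot <- c(tot, s[q, 2])
    guard <- guard + 1L
    if (guard > 1000L && length(mx) == 0) {
      stop("no events with an autozygous segment after ", n_all, " trials")
    }
  }
  mx <- mx[seq_len(want)]
  cnt <- cnt[seq_len(want)]
  tot <- tot[seq_len(want)]
  structure(list(
    mean_count = mean(cnt),
    mean_length_cm = sum(tot) / sum(cnt),
    max_length_samples = mx,
    autozygous_fraction = tot_all / (n_all * sum(lens)),
    quantiles_cm = stats::quantile(mx, probs),
    n_events = want, m = config$m, n = config$n,
    chrom_lengths_cm = config$chrom_lengths_cm),
    class = "qhm_as_summary")
}

#' Check an observed longest RHS against the simulated AS distribution
#'
#' Compares the longest RHS of a sample to the central `1 - 2*alpha` range
#' of the simulated longest-AS distribution for the reported pedigree.
#' A value below the range suggests the reported inbreeding is too recent
#' (or absent); above, that inbreeding is more recent than reported.
#'
#' @param longest_rhs_cm observed longest RHS genetic length in cM.
#' @param sim a [longest_as_distribution()] result, or a numeric vector of
#'   simulated longest-AS lengths.
#' @param alpha tail level on each side (default 0.025, the central 95%
#'   range).
#' @return list with `verdict` (one of `consistent`,
#'   `shorter-than-expected`, `longer-than-expected`), `percentile` of the
#'   observation in the simulated distribution, and the range bounds.
#' @export
history_consistency <- function(longest_rhs_cm, sim, alpha = 0.025) {
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  s <- if (is.numeric(sim)) sim else sim$max_length_samples
  lo <- unname(stats::quantile(s, alpha))
  hi <- unname(stats::quantile(s, 1 - alpha))
  verdict <- if (longest_rhs_cm < lo) {
    "shorter-than-expected"
  } else if (longest_rhs_cm > hi) {
    "longer-than-expected"
  } else {
    "consistent"
  }
  list(verdict = verdict,
       percentile = 100 * mean(s <= longest_rhs_cm),
       lower_cm = lo, upper_cm = hi, alpha = alpha)
}

#' @export
print.qhm_as_summary <- function(x, ...) {
  cat("<qhm_as_summary> m =", x$m, ", n =", x$n, ",", x$n_events,
      "events with >= 1 AS\n")
  cat("  mean AS count:", signif(x$mean_count, 4),
      " mean AS length:", signif(x$mean_length_cm, 4), "cM\n")
  cat("  autozygous fraction:", signif(x$autozygous_fraction, 4), "\n")
  print(signif(x$quantiles_cm, 4))
  invisible(x)
}
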