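# End-to-end orchestration ----------------------------------------------

#' Run the full homozygosity-mapping pipeline
#'
#' Chains the five analysis steps over in-memory call tables:
#' error correction of every sample, RHS detection, an optional
#' inbreeding-history check of each case against the simulated longest-AS
#' distribution, intersection of the case RHS sets, case-control scoring
#' of SNPs inside the overlaps, and the gene-localization probabilities.
#' Controls are processed with the identical correction and RHS
#' parameters as cases.
#'
#' @param cases list of [as_calls()] tables (the patients).
#' @param controls optional list of [as_calls()] tables.
#' @param p_allele disease-allele population frequency (disease-specific;
#'   no default is meaningful, supply it).
#' @param cutoff_cm RHS genetic-length cutoff (default 0.6 cM).
#' @param threshold error-correction removal threshold (default 0.01).
#' @param min_snps minimum homozygous SNPs per RHS.
#' @param chrom_lengths_cm optional named chromosome lengths (cM);
#'   defaults to the last marker position per chromosome of the first
#'   case.
#' @param m,n loop meioses for the false-negative rate and the history
#'   check (default first-cousin parents).
#' @param check_history simulate the longest-AS distribution and attach a
#'   [history_consistency()] verdict per case.
#' @param history_events events with >= 1 AS for the history simulation.
#' @param stat_mode score SNPs inside the overlaps only (default) or all
#'   SNPs.
#' @param out_dir if given, write per-sample RHS BED files, the overlap
#'   BED, the per-SNP statistic TSV, the case summary TSV and a run
#'   manifest there (a rerun with the same inputs and seed is
#'   byte-identical).
#' @param seed optional seed (history simulation).
#' @return list with `summary` (per-case data frame: `sample`, `n_rhs`,
#'   `total_cm`, `longest_cm`, `f_hat`, `p_gene_in_rhs`, and the history
#'   verdict when requested), `rhs_cases`, `rhs_controls`, `overlap`,
#'   `snp_stats`, `ranked_overlaps`, `p_gene_in_overlap`, `history`, and
#'   `params`.
#' @export
run_pipeline <- function(cases, controls = list(), p_allele,
                         cutoff_cm = 0.6, threshold = 0.01, min_snps = 1,
                         chrom_lengths_cm = NULL, m = 3, n = 3,
                         check_history = FALSE, history_events = 2000,
                         stat_mode = c("overlaps", "all"),
                         out_dir = NULL, seed = NULL) {
  stat_mode <- match.arg(stat_mode)
  if (length(cases) == 0) stop("no case samples supplied")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chrom_lengths_cm)) {
    chrom_lengths_cm <- vapply(split(cases[[1]]$pos_cm, cases[[1]]$chrom),
                               max, numeric(1))
  }
  correct1 <- function(x) correct_calls(x, threshold = threshold,
                                        chrom_lengths_cm = chrom_lengths_cm)
  corr_cases <- lapply(cases, correct1)
  corr_controls <- lapply(controls, correct1)
  rhs1 <- function(cc) detect_rhs(cc$calls, cutoff_cm = cutoff_cm,
                                  min_snps = min_snps,
                                  chrom_lengths_cm = chrom_lengths_cm)
  rhs_cases <- lapply(corr_cases, rhs1)
  rhs_controls <- lapply(corr_controls, rhs1)

  l_autosome <- sum(chrom_lengths_cm)
  f_hat <- vapply(rhs_cases, estimate_f, numeric(1),
                  l_autosome_cm = l_autosome)
  r_fn <- false_negative_rate(m + n, cutoff_cm)
  p_rhs <- p_gene_in_rhs(f_hat, p_allele, r_fn)
  summary <- data.frame(
    sample = vapply(cases, function(x) attr(x, "sample_id") %||% "?",
                    character(1)),
    n_rhs = vapply(rhs_cases, nrow, integer(1)),
    total_cm = vapply(rhs_cases, function(s) sum(genetic_length_cm(s)),
                      numeric(1)),
    longest_cm = vapply(rhs_cases, longest_rhs_cm, numeric(1)),
    f_hat = f_hat,
    p_gene_in_rhs = p_rhs)

  history <- NULL
  if (check_history) {
    sim <- longest_as_distribution(
      loop_config(m, n, chrom_lengths_cm, n_events = history_events))
    history <- lapply(summary$longest_cm, history_consistency, sim = sim)
    summary$history <- vapply(history, `[[`, character(1), "verdict")
  }

  overlap <- intersect_regions(rhs_cases)
  snp_stats <- NULL
  ranked <- NULL
  if (length(controls) > 0 && nrow(overlap) > 0) {
    snps <- as.data.frame(cases[[1]])[c("snp_id", "chrom", "pos_cm")]
    if (stat_mode == "overlaps") {
      snps <- snps[.covered(snps$chrom, snps$pos_cm, overlap), ,
                   drop = FALSE]
    }
    counts <- sharing_counts(snps, rhs_cases, rhs_controls)
    snp_stats <- u_statistic(counts)
    ranked <- rank_overlaps(overlap, snp_stats)
  }
  p_overlap <- p_gene_in_overlap(p_rhs)

  res <- list(summary = summary, rhs_cases = rhs_cases,
              rhs_controls = rhs_controls, overlap = overlap,
              snp_stats = snp_stats, ranked_overlaps = ranked,
              p_gene_in_overlap = p_overlap, history = history,
              params = list(p_allele = p_allele, cutoff_cm = cutoff_cm,
                            threshold = threshold, min_snps = min_snps,
                            m = m, n = n, seed = seed,
                            chrom_lengths_cm = chrom_lengths_cm))
  if (!is.null(out_dir)) .write_pipeline_artifacts(res, out_dir)
  res
}

.write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(res$rhs_cases)) {
    write_regions(res$rhs_cases[[i]],
                  file.path(out_dir, sprintf("rhs_%s.bed",
                                             res$summary$sample[i])))
  }
  write_regions(res$overlap, file.path(out_dir, "overlap.bed"))
  utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$snp_stats)) {
    utils::write.table(res$snp_stats, file.path(out_dir, "snp_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$ranked_overlaps)) {
    utils::write.table(res$ranked_overlaps,
                       file.path(out_dir, "ranked_overlaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  p <- res$params
  manifest <- c(
    paste0("package: qhmap ", as.character(utils::packageVersion("qhmap"))),
    paste0("p_allele: ", p$p_allele),
    paste0("cutoff_cm: ", p$cutoff_cm),
    paste0("threshold: ", p$threshold),
    paste0("min_snps: ", p$min_snps),
    paste0("m: ", p$m), paste0("n: ", p$n),
    paste0("seed: ", p$seed %||% "NULL"),
    paste0("p_gene_in_overlap: ", res$p_gene_in_overlap))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
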