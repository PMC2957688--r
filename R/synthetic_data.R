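# Truth-annotated synthetic genotype data -------------------------------
#
# Emulates an inbred-pedigree genome at desk scale: founder haplotypes
# drawn per-SNP from sampled major-allele frequencies (linkage
# equilibrium), descent through the consanguinity loop via the Haldane
# meiosis model, genotypes as unordered allele pairs, and the true
# autozygous segments recorded from the founder-label process. Real-array
# features NOT modeled: linkage disequilibrium / haplotype blocks (so
# synthetic false-positive rates undershoot real data) and population
# substructure.

#' Synthetic-dataset configuration
#'
#' Defaults describe a compact four-chromosome genome dense enough
#' (0.02 cM mean marker spacing) for the heterozygote-gap statistics that
#' drive error correction and RHS detection to behave as on a high-density
#' array.
#'
#' @param n_snps_per_chrom markers per chromosome (>= 2).
#' @param chrom_lengths_cm chromosome genetic lengths in cM.
#' @param maj_freq_sampler function drawing per-SNP major-allele
#'   frequencies; default Uniform(0.5, 0.95).
#' @param pedigree a [loop_config()] for inbred samples (default
#'   first-cousin parents, m = n = 3), or `NULL` for outbred only.
#' @param error_rate genotyping error rate used by callers of
#'   [inject_errors()] (array default 0.003).
#' @param no_call_rate fraction of markers set to no-call (default 0.01).
#' @param seed optional integer seed.
#' @return object of class `qhm_synth_config`.
#' @export
synth_config <- function(n_snps_per_chrom = 5000,
                         chrom_lengths_cm = rep(100, 4),
                         maj_freq_sampler = function(n) runif(n, 0.5, 0.95),
                         pedigree = loop_config(3, 3, chrom_lengths_cm),
                         error_rate = 0.003, no_call_rate = 0.01,
                         seed = NULL) {
  if (n_snps_per_chrom < 2) stop("need >= 2 SNPs per chromosome")
  if (any(chrom_lengths_cm <= 0)) stop("chromosome lengths must be > 0")
  if (error_rate < 0 || error_rate > 1 || no_call_rate < 0 ||
      no_call_rate > 1) {
    stop("rates must be in [0, 1]")
  }
  if (is.null(names(chrom_lengths_cm))) {
    names(chrom_lengths_cm) <- as.character(seq_along(chrom_lengths_cm))
  }
  if (!is.null(pedigree) &&
      !isTRUE(all.equal(unname(pedigree$chrom_lengths_cm),
                        unname(chrom_lengths_cm)))) {
    stop("pedigree chromosome lengths must match chrom_lengths_cm")
  }
  structure(list(n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 chrom_lengths_cm = chrom_lengths_cm,
                 maj_freq_sampler = maj_freq_sampler,
                 pedigree = pedigree, error_rate = error_rate,
                 no_call_rate = no_call_rate, seed = seed),
            class = "qhm_synth_config")
}

#' Generate a synthetic marker map
#'
#' Marker genetic positions are uniform on each chromosome; physical
#' positions follow the toy scale 1 cM = 1 Mb (kept strictly increasing).
#' Each marker carries its sampled major-allele frequency.
#'
#' @param config a [synth_config()].
#' @param seed optional seed (default from `config`).
#' @return data frame `snp_id`, `chrom`, `pos_bp`, `pos_cm`, `maj_freq`,
#'   sorted by (chrom, pos_bp).
#' @export
generate_map <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_snps_per_chrom
  maps <- lapply(seq_along(config$chrom_lengths_cm), function(i) {
    L <- config$chrom_lengths_cm[[i]]
    cm <- sort(stats::runif(n, 0, L))
    data.frame(
      snp_id = sprintf("s%s_%06d", names(config$chrom_lengths_cm)[i],
                       seq_len(n)),
      chrom = as.integer(names(config$chrom_lengths_cm)[i]),
      pos_bp = round(cm * 1e6) + seq_len(n),
      pos_cm = cm,
      maj_freq = config$maj_freq_sampler(n))
  })
  do.call(rbind, maps)
}

# genotypes + truth segments from a pre-drawn founder-label mosaic
.genotypes_from_mosaic <- function(map, mos, config, sample_id) {
  nm <- nrow(map)
  freq <- map$maj_freq
  founder <- matrix(stats::runif(4 * nm) < rep(freq, each = 4), nrow = 4)
  allele_p <- allele_m <- logical(nm)
  truth <- list()
  chroms <- as.integer(names(config$chrom_lengths_cm))
  for (i in seq_along(mos)) {
    sel <- which(map$chrom == chroms[i])
    part <- mos[[i]]
    k <- findInterval(map$pos_cm[sel], part$start_cm)
    k[k < 1L] <- 1L
    labp <- part$lab_p[k]
    labm <- part$lab_m[k]
    rnd_p <- stats::runif(length(sel)) < freq[sel]
    rnd_m <- stats::runif(length(sel)) < freq[sel]
    allele_p[sel] <- ifelse(labp > 0,
                            founder[cbind(pmax(labp, 1L), sel)], rnd_p)
    allele_m[sel] <- ifelse(labm > 0,
                            founder[cbind(pmax(labm, 1L), sel)], rnd_m)
    hit <- which(part$lab_p > 0 & part$lab_p == part$lab_m)
    if (length(hit) > 0) {
      inside <- tabulate(k, nbins = nrow(part))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chroms[i],
        start_cm = part$start_cm[hit], end_cm = part$end_cm[hit],
        n_snps = inside[hit])
    }
  }
  call <- ifelse(allele_p & allele_m, "AA",
                 ifelse(!allele_p & !allele_m, "BB", "AB"))
  calls <- as_calls(data.frame(snp_id = map$snp_id, chrom = map$chrom,
                               pos_bp = map$pos_bp, pos_cm = map$pos_cm,
                               call = call),
                    sample_id = sample_id)
  tr <- if (length(truth) > 0) {
    do.call(rbind, truth)
  } else {
    data.frame(chrom = integer(), start_cm = numeric(), end_cm = numeric(),
               n_snps = integer())
  }
  tr$start_bp <- floor(tr$start_cm * 1e6)
  tr$end_bp <- pmax(ceiling(tr$end_cm * 1e6), tr$start_bp + 1)
  tr$kind <- rep("AS", nrow(tr))
  truth_segs <- as_segments(tr, sample_id = sample_id,
                            l_autosome_cm = sum(config$chrom_lengths_cm))
  list(calls = calls, truth = truth_segs)
}

.apply_no_calls <- function(calls, rate) {
  if (rate > 0) {
    nc <- stats::runif(nrow(calls)) < rate
    calls$call[nc] <- "NC"
  }
  calls
}

#' Generate one inbred sample with known autozygous segments
#'
#' Founder haplotypes are drawn per SNP from the map's major-allele
#' frequencies (linkage equilibrium); the subject's two homologs descend
#' through the configured consanguinity loop; genotypes are the unordered
#' allele pairs. Inside every true autozygous segment all calls are
#' homozygous by construction (before no-calls and before any
#' [inject_errors()]).
#'
#' @param config a [synth_config()] with a pedigree.
#' @param map a [generate_map()] table; generated from `config` if `NULL`.
#' @param sample_id sample identifier.
#' @param seed optional seed.
#' @return list with `calls` (a [as_calls()] table) and `truth`
#'   (a [as_segments()] table of kind `AS`).
#' @export
generate_inbred_sample <- function(config, map = NULL, sample_id = "case",
                                   seed = NULL) {
  if (is.null(config$pedigree)) stop("config has no pedigree")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) map <- generate_map(config, seed = NULL)
  mos <- cpp_loop_mosaic(config$pedigree$m, config$pedigree$n,
                         unname(config$chrom_lengths_cm))
  r <- .genotypes_from_mosaic(map, mos, config, sample_id)
  r$calls <- .apply_no_calls(r$calls, config$no_call_rate)
  r
}

#' Generate one outbred control sample
#'
#' Genotypes are independent Hardy-Weinberg draws per SNP; there are no
#' true autozygous segments.
#'
#' @inheritParams generate_inbred_sample
#' @return list with `calls` and an empty `truth` table.
#' @export
generate_outbred_sample <- function(config, map = NULL,
                                    sample_id = "control", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) map <- generate_map(config, seed = NULL)
  nm <- nrow(map)
  a1 <- stats::runif(nm) < map$maj_freq
  a2 <- stats::runif(nm) < map$maj_freq
  call <- ifelse(a1 & a2, "AA", ifelse(!a1 & !a2, "BB", "AB"))
  calls <- as_calls(data.frame(snp_id = map$snp_id, chrom = map$chrom,
                               pos_bp = map$pos_bp, pos_cm = map$pos_cm,
                               call = call),
                    sample_id = sample_id)
  calls <- .apply_no_calls(calls, config$no_call_rate)
  truth <- as_segments(data.frame(chrom = integer(), start_bp = numeric(),
                                  end_bp = numeric(), start_cm = numeric(),
                                  end_cm = numeric(), n_snps = integer(),
                                  kind = character()),
                       sample_id = sample_id,
                       l_autosome_cm = sum(config$chrom_lengths_cm))
  list(calls = calls, truth = truth)
}

#' Build a case-control benchmark with a planted disease locus
#'
#' Cases are inbred samples conditioned (by rejection sampling on the
#' founder-label mosaic) to be autozygous at the planted locus, emulating
#' patients sharing a recessive disease gene; controls are outbred. Truth
#' annotations allow end-to-end scoring of locus recovery.
#'
#' @param config a [synth_config()] with a pedigree.
#' @param n_cases,n_controls sample counts.
#' @param planted_chrom,planted_cm locus position; default the middle of
#'   the first chromosome.
#' @param max_tries rejection budget per case (the acceptance probability
#'   per draw is the pedigree's consanguinity coefficient, e.g. 1/16).
#' @param seed optional seed.
#' @return list with `map`, `cases` / `case_truth` (lists), `controls`
#'   (list), and `planted` (list with `chrom`, `pos_cm`).
#' @export
make_benchmark <- function(config, n_cases = 5, n_controls = 20,
                           planted_chrom = NULL, planted_cm = NULL,
                           max_tries = 1000, seed = NULL) {
  if (is.null(config$pedigree)) stop("config has no pedigree")
  if (!is.null(seed)) set.seed(seed)
  chroms <- as.integer(names(config$chrom_lengths_cm))
  if (is.null(planted_chrom)) planted_chrom <- chroms[1]
  ci <- match(planted_chrom, chroms)
  if (is.na(ci)) stop("planted_chrom not in the configured genome")
  if (is.null(planted_cm)) planted_cm <- config$chrom_lengths_cm[[ci]] / 2
  if (planted_cm < 0 || planted_cm > config$chrom_lengths_cm[[ci]]) {
    stop("planted_cm outside the chromosome")
  }
  map <- generate_map(config, seed = NULL)
  cases <- case_truth <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      mos <- cpp_loop_mosaic(config$pedigree$m, config$pedigree$n,
                             unname(config$chrom_lengths_cm))
      part <- mos[[ci]]
      k <- max(findInterval(planted_cm, part$start_cm), 1L)
      if (part$lab_p[k] > 0 && part$lab_p[k] == part$lab_m[k]) {
        r <- .genotypes_from_mosaic(map, mos, config,
                                    sample_id = paste0("case", i))
        cases[[i]] <- .apply_no_calls(r$calls, config$no_call_rate)
        case_truth[[i]] <- r$truth
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("rejection budget exhausted for case ", i,
           "; increase max_tries")
    }
  }
  controls <- lapply(seq_len(n_controls), function(i) {
    generate_outbred_sample(config, map,
                            sample_id = paste0("control", i))$calls
  })
  list(map = map, cases = cases, case_truth = case_truth,
       controls = controls,
       planted = list(chrom = planted_chrom, pos_cm = planted_cm))
}
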