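# Genotype-call tables --------------------------------------------------

.call_codes <- c("AA", "AB", "BB", "NC")

#' Construct a genotype-call table
#'
#' A call table holds one sample's autosomal SNP genotypes: one row per
#' marker, with the marker's physical position (`pos_bp`, 1-based) and
#' genetic position (`pos_cm`, cM from the telomere of the short arm) and a
#' call in `AA`, `AB`, `BB` or `NC` (no-call). Rows are sorted by
#' chromosome then physical position; duplicate physical positions on a
#' chromosome are an error, and `pos_cm` must be non-decreasing along each
#' chromosome.
#'
#' No-calls take no part in any downstream computation: they neither extend
#' nor break homozygous runs and are excluded from all SNP counts.
#'
#' @param df data frame with columns `snp_id`, `chrom`, `pos_bp`, `pos_cm`,
#'   `call`.
#' @param sample_id sample identifier, stored as an attribute.
#' @param drop_nonautosomal drop rows whose chromosome is not 1-22, with a
#'   message giving the count; if `FALSE`, such rows are an error.
#' @return A data frame of class `qhm_calls`.
#' @export
as_calls <- function(df, sample_id = "sample", drop_nonautosomal = TRUE) {
  need <- c("snp_id", "chrom", "pos_bp", "pos_cm", "call")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  df$snp_id <- as.character(df$snp_id)
  df$call <- as.character(df$call)
  chrom <- sub("^chr", "", as.character(df$chrom))
  auto <- chrom %in% as.character(1:22)
  if (any(!auto)) {
    if (!drop_nonautosomal) stop("non-autosomal rows present")
    message(sum(!auto), " non-autosomal row(s) dropped")
    df <- df[auto, , drop = FALSE]
    chrom <- chrom[auto]
  }
  df$chrom <- as.integer(chrom)
  bad <- !(df$call %in% .call_codes)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("invalid call '", df$call[i], "' at row ", i)
  }
  if (any(df$pos_bp < 1)) stop("pos_bp must be >= 1")
  if (any(df$pos_cm < 0)) stop("pos_cm must be >= 0")
  ord <- order(df$chrom, df$pos_bp)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("rows were not sorted by (chrom, pos_bp); sorting")
    df <- df[ord, , drop = FALSE]
  }
  dup <- duplicated(df[c("chrom", "pos_bp")])
  if (any(dup)) {
    stop("duplicate pos_bp on chromosome ", df$chrom[which(dup)[1]])
  }
  if (nrow(df) > 0) {
    bad_cm <- vapply(split(df$pos_cm, df$chrom),
                     function(x) any(diff(x) < 0), logical(1))
    if (any(bad_cm)) {
      stop("pos_cm must be non-decreasing within a chromosome")
    }
  }
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, class = c("qhm_calls", "data.frame"))
}

#' Read genotype calls
#'
#' Two on-disk flavours are supported. The native format is a tab-separated
#' file with a header row and columns `snp_id`, `chrom`, `pos_bp`, `pos_cm`,
#' `call` (calls in `AA`/`AB`/`BB`/`NC`). The PLINK-like flavour pairs a
#' `.map` file (columns chrom, id, cM, bp, whitespace-separated, no header)
#' with a one-column file of calls in map order. Non-autosomal rows are
#' dropped with a message; rows with unparseable positions raise an error
#' naming the offending line.
#'
#' @param path path to the native TSV or to the `.map` file.
#' @param format `"native"` or `"plink"`.
#' @param sample_id sample identifier; default: the file base name.
#' @param calls_path for `format = "plink"`, the per-sample call column.
#' @return A [as_calls()] table.
#' @export
read_calls <- function(path, format = c("native", "plink"),
                       sample_id = NULL, calls_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "native") {
    raw <- utils::read.delim(path, sep = "\t", colClasses = "character")
    need <- c("snp_id", "chrom", "pos_bp", "pos_cm", "call")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
    }
    pb <- suppressWarnings(as.numeric(raw$pos_bp))
    if (anyNA(pb)) stop("malformed pos_bp at line ", which(is.na(pb))[1] + 1L)
    pc <- suppressWarnings(as.numeric(raw$pos_cm))
    if (anyNA(pc)) stop("malformed pos_cm at line ", which(is.na(pc))[1] + 1L)
    df <- data.frame(snp_id = raw$snp_id, chrom = raw$chrom, pos_bp = pb,
                     pos_cm = pc, call = raw$call)
  } else {
    if (is.null(calls_path)) stop("plink format requires calls_path")
    mp <- utils::read.table(path, header = FALSE,
                            col.names = c("chrom", "snp_id", "pos_cm", "pos_bp"),
                            colClasses = c("character", "character",
                                           "numeric", "numeric"))
    cl <- readLines(calls_path)
    if (length(cl) != nrow(mp)) {
      stop("calls file has ", length(cl), " lines but map has ", nrow(mp))
    }
    df <- data.frame(snp_id = mp$snp_id, chrom = mp$chrom, pos_bp = mp$pos_bp,
                     pos_cm = mp$pos_cm, call = cl)
  }
  as_calls(df, sample_id = sample_id)
}

#' Write genotype calls in the native TSV format
#'
#' @param calls a [as_calls()] table.
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-sample zygosity counts
#'
#' Counts only SNPs successfully genotyped (non-no-call): `n_pt` genotyped,
#' `n_hom` homozygous and `n_het` heterozygous.
#'
#' @param calls a [as_calls()] table.
#' @return list with `n_pt`, `n_hom`, `n_het`.
#' @export
zygosity_counts <- function(calls) {
  cl <- calls$call
  list(n_pt = sum(cl != "NC"),
       n_hom = sum(cl == "AA" | cl == "BB"),
       n_het = sum(cl == "AB"))
}

#' @export
print.qhm_calls <- function(x, ...) {
  z <- zygosity_counts(x)
  cat("<qhm_calls> sample", attr(x, "sample_id") %||% "?",
      "-", nrow(x), "SNPs on", length(unique(x$chrom)), "autosome(s);",
      z$n_het, "het /", z$n_hom, "hom /", nrow(x) - z$n_pt, "no-call\n")
  invisible(x)
}

# total genetic length (cM) of the chromosomes a sample covers; an explicit
# named length vector wins over the per-chromosome maximum marker position
.genome_length_cm <- function(calls, chrom_lengths_cm = NULL) {
  chs <- sort(unique(calls$chrom))
  if (is.null(chrom_lengths_cm)) {
    return(sum(vapply(split(calls$pos_cm, calls$chrom), max, numeric(1))))
  }
  len <- chrom_lengths_cm[as.character(chs)]
  if (anyNA(len)) {
    stop("chrom_lengths_cm missing chromosome(s): ",
         paste(chs[is.na(len)], collapse = ", "))
  }
  sum(len)
}
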