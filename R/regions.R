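# Genomic segment tables (AS / RHS / OVERLAP) ---------------------------

.segment_kinds <- c("AS", "RHS", "OVERLAP")

#' Construct a segment table
#'
#' Segments are genomic intervals carried in both coordinate systems:
#' physical positions are 0-based half-open (`start_bp`, `end_bp`), genetic
#' positions are cM from pter (`start_cm`, `end_cm`, half-open likewise).
#' `n_snps` counts the homozygous SNPs inside (may be `NA` for overlaps)
#' and `kind` is one of `AS` (true autozygous segment), `RHS` (detected
#' run of homozygous SNPs) or `OVERLAP` (multi-sample intersection).
#' Segments must be non-overlapping within a chromosome.
#'
#' @param df data frame with columns `chrom`, `start_bp`, `end_bp`,
#'   `start_cm`, `end_cm`, `n_snps`, `kind`.
#' @param sample_id optional sample identifier attribute.
#' @param l_autosome_cm optional total autosomal genetic length (cM) of the
#'   genome the segments were called on, kept as an attribute for
#'   [estimate_f()].
#' @return A data frame of class `qhm_segments`, sorted by (chrom, start_bp).
#' @export
as_segments <- function(df, sample_id = NULL, l_autosome_cm = NULL) {
  need <- c("chrom", "start_bp", "end_bp", "start_cm", "end_cm",
            "n_snps", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  df$chrom <- as.integer(df$chrom)
  if (nrow(df) > 0) {
    if (!all(df$kind %in% .segment_kinds)) {
      stop("kind must be one of ", paste(.segment_kinds, collapse = ", "))
    }
    if (any(df$end_cm < df$start_cm)) stop("end_cm < start_cm")
    if (any(df$end_bp <= df$start_bp)) stop("end_bp must exceed start_bp")
    df <- df[order(df$chrom, df$start_bp), , drop = FALSE]
    ovl <- vapply(split(df, df$chrom), function(d) {
      nrow(d) > 1 && any(d$start_bp[-1] < d$end_bp[-nrow(d)])
    }, logical(1))
    if (any(ovl)) {
      stop("overlapping segments on chromosome ",
           paste(names(ovl)[ovl], collapse = ", "))
    }
  }
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, l_autosome_cm = l_autosome_cm,
            class = c("qhm_segments", "data.frame"))
}

#' Genetic lengths of segments
#'
#' @param segments a [as_segments()] table.
#' @return numeric vector of `end_cm - start_cm`.
#' @export
genetic_length_cm <- function(segments) {
  segments$end_cm - segments$start_cm
}

#' Write segments as a BED-style file
#'
#' Emits chrom, 0-based half-open `start_bp`/`end_bp`, then extra columns
#' `start_cm`, `end_cm`, `genetic_length_cm`, `n_snps`, `kind`, sorted by
#' (chrom, start_bp). A single `#`-prefixed header line names the columns;
#' an empty segment set yields a header-only file.
#'
#' @param segments a [as_segments()] table.
#' @param path output path.
#' @export
write_regions <- function(segments, path) {
  out <- data.frame(chrom = segments$chrom,
                    start_bp = segments$start_bp,
                    end_bp = segments$end_bp,
                    start_cm = segments$start_cm,
                    end_cm = segments$end_cm,
                    genetic_length_cm = genetic_length_cm(segments),
                    n_snps = segments$n_snps,
                    kind = segments$kind)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
  if (nrow(out) > 0) {
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a segments BED file written by [write_regions()]
#'
#' @param path input path.
#' @inheritParams as_segments
#' @export
read_regions <- function(path, sample_id = NULL, l_autosome_cm = NULL) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(lines) > 1) {
    df <- utils::read.table(text = lines[-1], header = FALSE, sep = "\t",
                            col.names = cols)
  } else {
    df <- data.frame(chrom = integer(), start_bp = numeric(),
                     end_bp = numeric(), start_cm = numeric(),
                     end_cm = numeric(), n_snps = integer(),
                     kind = character())
  }
  as_segments(df[c("chrom", "start_bp", "end_bp", "start_cm", "end_cm",
                   "n_snps", "kind")],
              sample_id = sample_id, l_autosome_cm = l_autosome_cm)
}
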