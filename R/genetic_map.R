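# Reference genetic maps and autosome lengths ---------------------------

# Sex-averaged genetic lengths of the 22 human autosomes (cM), rounded
# deCODE-style reference values; total 3,548 cM.
.autosome_cm <- setNames(
  c(276, 263, 224, 212, 209, 194, 187, 169, 167, 174,
    161, 176, 131, 125, 132, 133, 137, 126, 110, 108, 62, 72),
  as.character(1:22))

#' Bundled sex-averaged autosome genetic lengths
#'
#' Reference genetic lengths (cM) of autosomes 1-22, used as the default
#' chromosome set of the autozygous-segment simulator and as the default
#' total autosomal length. Any reference map supplied by the user takes
#' precedence.
#'
#' @return named numeric vector, names `"1"`..`"22"`.
#' @export
autosome_lengths_cm <- function() .autosome_cm

#' Total autosomal genetic length
#'
#' @param map a [reference_map()], or `NULL` for the bundled length table.
#' @param require_all error (listing the missing chromosomes) unless all 22
#'   autosomes are present.
#' @return total genetic length in cM of the autosomes covered.
#' @export
total_autosome_cm <- function(map = NULL, require_all = FALSE) {
  len <- if (is.null(map)) .autosome_cm else map$chrom_length_cm
  if (require_all) {
    miss <- setdiff(as.character(1:22), names(len))
    if (length(miss) > 0) {
      stop("autosome(s) missing from map: ", paste(miss, collapse = ", "))
    }
  }
  sum(len)
}

#' Build a reference genetic map
#'
#' Anchors give known (bp, cM) pairs per chromosome, e.g. from a published
#' sex-averaged map; marker genetic positions are obtained from them by
#' piecewise-linear interpolation ([interpolate_cm()]).
#'
#' @param anchors data frame with columns `chrom`, `pos_bp`, `pos_cm`;
#'   within a chromosome the anchors must be strictly increasing in both
#'   coordinates.
#' @param chrom_lengths_cm optional named vector of chromosome genetic
#'   lengths (cM); defaults to each chromosome's last anchor. Must not be
#'   smaller than the last anchor.
#' @return object of class `qhm_refmap`.
#' @export
reference_map <- function(anchors, chrom_lengths_cm = NULL) {
  need <- c("chrom", "pos_bp", "pos_cm")
  miss <- setdiff(need, names(anchors))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  anchors <- as.data.frame(anchors)[need]
  anchors$chrom <- as.character(sub("^chr", "", anchors$chrom))
  anchors <- anchors[order(anchors$chrom, anchors$pos_bp), , drop = FALSE]
  sp <- split(anchors[c("pos_bp", "pos_cm")], anchors$chrom)
  for (ch in names(sp)) {
    a <- sp[[ch]]
    if (any(diff(a$pos_bp) <= 0) || any(diff(a$pos_cm) <= 0)) {
      stop("anchors must be strictly increasing on chromosome ", ch)
    }
  }
  last_cm <- vapply(sp, function(a) a$pos_cm[nrow(a)], numeric(1))
  if (is.null(chrom_lengths_cm)) {
    chrom_lengths_cm <- last_cm
  } else {
    chrom_lengths_cm <- chrom_lengths_cm[names(sp)]
    if (anyNA(chrom_lengths_cm) || any(chrom_lengths_cm < last_cm)) {
      stop("chrom_lengths_cm must cover every chromosome and be >= the ",
           "last anchor")
    }
  }
  structure(list(anchors = sp, chrom_length_cm = chrom_lengths_cm),
            class = "qhm_refmap")
}

#' Read a reference map TSV (columns chrom, pos_bp, pos_cm)
#'
#' @param path input path.
#' @inheritParams reference_map
#' @export
read_genetic_map <- function(path, chrom_lengths_cm = NULL) {
  reference_map(utils::read.delim(path), chrom_lengths_cm = chrom_lengths_cm)
}

#' Interpolate genetic positions from a reference map
#'
#' Piecewise-linear interpolation between the bracketing anchors; beyond
#' the outermost anchors the line through the two nearest anchors is
#' extended, floored at 0 cM. The result is exact at anchors and monotone
#' non-decreasing in `pos_bp`.
#'
#' @param map a [reference_map()].
#' @param chrom chromosome label (must exist in the map, with at least two
#'   anchors).
#' @param pos_bp physical positions to interpolate (vectorized).
#' @return genetic positions in cM.
#' @export
interpolate_cm <- function(map, chrom, pos_bp) {
  a <- map$anchors[[as.character(sub("^chr", "", chrom))]]
  if (is.null(a)) stop("chromosome ", chrom, " not in map")
  if (nrow(a) < 2) stop("need at least 2 anchors on chromosome ", chrom)
  x <- a$pos_bp
  y <- a$pos_cm
  i <- findInterval(pos_bp, x)
  i <- pmin(pmax(i, 1L), length(x) - 1L)
  cm <- y[i] + (pos_bp - x[i]) * (y[i + 1L] - y[i]) / (x[i + 1L] - x[i])
  pmax(cm, 0)
}
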