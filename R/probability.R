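# Gene-localization probabilities ---------------------------------------

#' Probability that the disease gene lies in an autozygous segment
#'
#' For a recessive patient with coefficient of consanguinity `f` and
#' disease-allele population frequency `p`, the disease locus is
#' autozygous with probability `f / ((1 - f) * p + f)`. For an inbred
#' patient and a rare allele this approaches 1, the premise of
#' homozygosity mapping.
#'
#' @param f coefficient of consanguinity in `[0, 1]` (vectorized).
#' @param p disease-allele frequency in `(0, 1]`.
#' @return probability in `[0, 1]`.
#' @export
p_as <- function(f, p) {
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(p == 0 & f == 0)) stop("f = 0 and p = 0 leaves p_as undefined")
  f / ((1 - f) * p + f)
}

#' Probability that the disease gene lies in a detected RHS
#'
#' [p_as()] damped by the false-negative rate of RHS detection:
#' `(1 - r_fn) * p_as(f, p)`. Use the data-driven `F` estimate
#' ([estimate_f()]) where available, falling back to the pedigree value
#' (e.g. 1/16 for first-cousin parents).
#'
#' @inheritParams p_as
#' @param r_fn false-negative rate from [false_negative_rate()].
#' @export
p_gene_in_rhs <- function(f, p, r_fn) {
  if (any(r_fn < 0 | r_fn > 1)) stop("r_fn must be in [0, 1]")
  (1 - r_fn) * p_as(f, p)
}

#' Probability that the disease gene lies in the RHS overlap
#'
#' Product of the per-patient [p_gene_in_rhs()] values over all patients
#' contributing to the overlap.
#'
#' @param per_patient numeric vector of per-patient probabilities.
#' @export
p_gene_in_overlap <- function(per_patient) {
  if (length(per_patient) == 0) stop("no patients supplied")
  if (any(per_patient < 0 | per_patient > 1)) {
    stop("probabilities must be in [0, 1]")
  }
  prod(per_patient)
}
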