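# Base-call error model and allele-sampling mixtures.

#' Probability of a base call given the true sampled allele
#'
#' Errors are unbiased: the sequencer reports the true allele with
#' probability 1 - eps and each of the three other alleles with
#' probability eps/3.
#'
#' @param z Called allele ("A".."T" or index 1..4).
#' @param y True sampled allele.
#' @param eps Error probability in (0, 1].
#' @return P(Z = z | Y = y).
#' @export
base_call_probability <- function(z, y, eps) {
  if (any(eps <= 0 | eps > 1)) stop("error probability out of (0, 1]: ", eps[eps <= 0 | eps > 1][1])
  z <- allele_index(z)
  y <- allele_index(y)
  ifelse(z == y, 1 - eps, eps / 3)
}

#' Allele sampling frequencies of a pure diploid genotype
#'
#' At a homozygous locus xx reads sample allele x with frequency 1; at a
#' heterozygous locus xy each of x and y is sampled with frequency 1/2.
#'
#' @param g Genotype ("AC", index, etc.).
#' @return Named numeric vector of length 4 summing to 1.
#' @export
mixture_for_genotype <- function(g) {
  MIXTURES[genotype_index(g), ]
}

#' Allele sampling frequencies of an impure tumor sample
#'
#' Reads from an impure tumor sample draw from the tumor genotype with
#' probability omega (the tumor purity) and from the contaminating normal
#' genotype with probability 1 - omega:
#' rho[y] = (1 - omega) * rho_N[y] + omega * rho_T[y].
#' When the two genotypes are identical the result does not depend on omega.
#'
#' @param gN Normal genotype.
#' @param gT Tumor genotype.
#' @param omega Tumor purity in [0, 1].
#' @return Named numeric vector of length 4 summing to 1.
#' @export
impure_mixture <- function(gN, gT, omega) {
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega < 0 || omega > 1) {
    stop("tumor purity omega out of [0, 1]: ", omega)
  }
  (1 - omega) * MIXTURES[genotype_index(gN), ] + omega * MIXTURES[genotype_index(gT), ]
}
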