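# Parental genotype priors, substitution kernels, Mendelian inheritance,
# and the combined mutation-plus-inheritance kernel chi'.

# chi(gF', gM' -> gN): Mendelian transmission probabilities, 10 x 10 x 10.
# Each parent contributes one of its two alleles with probability 1/2.
CHI_TABLE <- local({
  arr <- array(0, c(10L, 10L, 10L))
  for (f in 1:10) for (m in 1:10) {
    for (fa in GT_PAIRS[f, ]) for (ma in GT_PAIRS[m, ]) {
      k <- GT_INDEX[fa, ma]
      arr[f, m, k] <- arr[f, m, k] + 0.25
    }
  }
  arr
})

# minimum number of allele changes between two unordered genotypes
# (the nu -> 0 limit of the expected substitution count)
MIN_SUBS <- local({
  m <- matrix(0, 10L, 10L)
  for (g in 1:10) for (h in 1:10) {
    a <- GT_PAIRS[g, 1]; b <- GT_PAIRS[g, 2]
    c_ <- GT_PAIRS[h, 1]; d <- GT_PAIRS[h, 2]
    m[g, h] <- min((a != c_) + (b != d), (a != d) + (b != c_))
  }
  m
})

#' Prior allele frequencies from reference divergence
#'
#' Jukes-Cantor divergence from the reference assembly: the reference
#' allele has prior frequency 1 - v and each other allele v/3.
#'
#' @param ref Reference allele.
#' @param divergence Per-allele divergence v in [0, 1).
#' @return Named numeric vector of length 4 summing to 1.
#' @export
allele_prior <- function(ref, divergence) {
  if (!is.numeric(divergence) || length(divergence) != 1L || is.na(divergence) ||
      divergence < 0 || divergence >= 1) {
    stop("divergence out of [0, 1): ", divergence)
  }
  r <- allele_index(ref)
  p <- rep(divergence / 3, 4)
  p[r] <- 1 - divergence
  names(p) <- ALLELES
  p
}

#' Diploid genotype prior with heterozygosity adjustment
#'
#' Hardy-Weinberg genotype frequencies adjusted by a parameter gamma <= 1
#' (numerically analogous to the inbreeding F-statistic):
#' phi(xx) = pi[x]^2 + gamma * pi[x] * (1 - pi[x]),
#' phi(xy) = 2 * (1 - gamma) * pi[x] * pi[y].
#' gamma = 0 recovers Hardy-Weinberg; gamma = 1 removes all heterozygote
#' mass; negative gamma is accepted as long as every phi stays
#' non-negative. The implied haploid allele frequencies equal pi at any
#' gamma.
#'
#' @param pi Numeric vector of 4 allele frequencies summing to 1.
#' @param gamma Heterozygosity adjustment, gamma <= 1.
#' @return Named numeric vector over the 10 genotypes, summing to 1.
#' @export
genotype_prior <- function(pi, gamma) {
  if (length(pi) != 4L || any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("pi must be a length-4 probability vector")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma > 1) {
    stop("gamma must be a single number <= 1")
  }
  a <- GT_PAIRS[, 1]; b <- GT_PAIRS[, 2]
  phi <- ifelse(GT_IS_HOM,
                pi[a]^2 + gamma * pi[a] * (1 - pi[a]),
                2 * (1 - gamma) * pi[a] * pi[b])
  if (any(phi < -1e-12)) {
    stop("parameter combination yields a negative genotype prior (gamma = ", gamma, ")")
  }
  phi <- pmax(phi, 0)
  names(phi) <- GT_LABELS
  phi
}

#' Jukes-Cantor allele substitution kernel
#'
#' Single-parameter substitution model: an allele stays put with
#' probability 1 - nu and changes to each of the other three alleles with
#' probability nu/3.
#'
#' @param rate Substitution probability nu in [0, 1).
#' @return 4 x 4 row-stochastic matrix, rows = source allele.
#' @export
jukes_cantor_kernel <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0 || rate >= 1) {
    stop("substitution rate out of [0, 1): ", rate)
  }
  m <- matrix(rate / 3, 4L, 4L, dimnames = list(ALLELES, ALLELES))
  diag(m) <- 1 - rate
  m
}

#' Mendelian transmission probability
#'
#' Probability that a child of parents gF x gM has genotype gN under
#' random gamete choice; always one of 0, 1/4, 1/2 or 1.
#'
#' @param gF,gM,gN Genotypes.
#' @return Transmission probability.
#' @export
mendelian_chi <- function(gF, gM, gN) {
  CHI_TABLE[cbind(genotype_index(gF), genotype_index(gM), genotype_index(gN))]
}

as_allele_kernel <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(4L, 4L)) || any(x < 0) || any(abs(rowSums(x) - 1) > 1e-9)) {
      stop("allele kernel must be a 4x4 row-stochastic matrix")
    }
    return(x)
  }
  jukes_cantor_kernel(x)
}

#' Diploid genotype mutation kernel
#'
#' Lifts an allele-level substitution kernel to unordered diploid
#' genotypes: both alleles mutate independently, and the two ordered
#' target assignments of a heterozygous result are summed so every row is
#' exactly stochastic.
#'
#' @param rate Jukes-Cantor rate, or a 4x4 allele kernel matrix.
#' @return 10 x 10 row-stochastic matrix over genotypes.
#' @export
genotype_mutation_kernel <- function(rate) {
  K4 <- as_allele_kernel(rate)
  K <- matrix(0, 10L, 10L, dimnames = list(GT_LABELS, GT_LABELS))
  for (g in 1:10) {
    a <- GT_PAIRS[g, 1]; b <- GT_PAIRS[g, 2]
    for (h in 1:10) {
      c_ <- GT_PAIRS[h, 1]; d <- GT_PAIRS[h, 2]
      K[g, h] <- if (c_ == d) {
        K4[a, c_] * K4[b, c_]
      } else {
        K4[a, c_] * K4[b, d] + K4[a, d] * K4[b, c_]
      }
    }
  }
  K
}

# Expected number of allele substitutions between unordered genotypes,
# conditional on source g and target g' under the given kernel. Used by the
# EM rate update; converges to MIN_SUBS as the rate goes to 0.
expected_substitutions <- function(rate) {
  K4 <- as_allele_kernel(rate)
  num <- matrix(0, 10L, 10L)
  den <- matrix(0, 10L, 10L)
  for (g in 1:10) {
    a <- GT_PAIRS[g, 1]; b <- GT_PAIRS[g, 2]
    for (h in 1:10) {
      c_ <- GT_PAIRS[h, 1]; d <- GT_PAIRS[h, 2]
      if (c_ == d) {
        w <- K4[a, c_] * K4[b, c_]
        num[g, h] <- ((a != c_) + (b != c_)) * w
        den[g, h] <- w
      } else {
        w1 <- K4[a, c_] * K4[b, d]
        w2 <- K4[a, d] * K4[b, c_]
        num[g, h] <- ((a != c_) + (b != d)) * w1 + ((a != d) + (b != c_)) * w2
        den[g, h] <- w1 + w2
      }
    }
  }
  out <- MIN_SUBS
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  dimnames(out) <- list(GT_LABELS, GT_LABELS)
  out
}

#' Combined germline-mutation and inheritance kernel
#'
#' chi'(gF, gM -> gN) marginalizes the mutated parental germline genotypes:
#' chi'(gF, gM -> gN) = sum over (gF', gM') of
#' nuF(gF -> gF') * nuM(gM -> gM') * chi(gF', gM' -> gN).
#' Precomputed once per EM iteration; every (gF, gM) row sums to 1.
#'
#' @param nu_f,nu_m Germline substitution rates (or 4x4 allele kernels) for
#'   the paternal and maternal lineages.
#' @return 10 x 10 x 10 array indexed (gF, gM, gN).
#' @export
combined_inheritance <- function(nu_f, nu_m) {
  KF <- genotype_mutation_kernel(nu_f)
  KM <- genotype_mutation_kernel(nu_m)
  arr <- array(0, c(10L, 10L, 10L),
               dimnames = list(GT_LABELS, GT_LABELS, GT_LABELS))
  for (gN in 1:10) {
    arr[, , gN] <- KF %*% CHI_TABLE[, , gN] %*% t(KM)
  }
  arr
}
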