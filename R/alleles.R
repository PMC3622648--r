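# Allele and diploid-genotype state space shared by every layer of the model.

ALLELES <- c("A", "C", "G", "T")

# The 10 unordered diploid genotypes in canonical order:
# AA AC AG AT CC CG CT GG GT TT
GT_PAIRS <- local({
  out <- matrix(0L, 10L, 2L)
  k <- 0L
  for (i in 1:4) for (j in i:4) {
    k <- k + 1L
    out[k, ] <- c(i, j)
  }
  out
})

GT_LABELS <- paste0(ALLELES[GT_PAIRS[, 1]], ALLELES[GT_PAIRS[, 2]])

# (i, j) allele-index pair -> genotype index, symmetric
GT_INDEX <- local({
  m <- matrix(0L, 4L, 4L)
  for (k in 1:10) {
    m[GT_PAIRS[k, 1], GT_PAIRS[k, 2]] <- k
    m[GT_PAIRS[k, 2], GT_PAIRS[k, 1]] <- k
  }
  m
})

GT_IS_HOM <- GT_PAIRS[, 1] == GT_PAIRS[, 2]

# genotype -> pure allele sampling frequencies rho (10 x 4)
MIXTURES <- local({
  m <- matrix(0, 10L, 4L, dimnames = list(GT_LABELS, ALLELES))
  for (k in 1:10) {
    m[k, GT_PAIRS[k, 1]] <- m[k, GT_PAIRS[k, 1]] + 0.5
    m[k, GT_PAIRS[k, 2]] <- m[k, GT_PAIRS[k, 2]] + 0.5
  }
  m
})

#' The four nucleotide alleles
#'
#' @return Character vector `c("A", "C", "G", "T")`, the canonical allele
#'   ordering used throughout the package.
#' @export
alleles <- function() ALLELES

#' The ten unordered diploid genotypes
#'
#' Genotypes are unordered allele pairs over \{A, C, G, T\}; phase is never
#' modeled, so there are exactly 10 states, enumerated in canonical order
#' (AA, AC, AG, AT, CC, CG, CT, GG, GT, TT).
#'
#' @return Character vector of the 10 two-letter genotype labels.
#' @export
genotypes <- function() GT_LABELS

## internal coercions ------------------------------------------------------

allele_index <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(x < 1L | x > 4L)) stop("allele index out of range 1..4")
    return(x)
  }
  i <- match(toupper(x), ALLELES)
  if (anyNA(i)) stop("unknown allele: ", paste(x[is.na(i)], collapse = ", "))
  i
}

# accepts "AC", c("A","C"), or an index 1..10; order-insensitive
genotype_index <- function(g) {
  if (is.numeric(g)) {
    g <- as.integer(g)
    if (any(g < 1L | g > 10L)) stop("genotype index out of range 1..10")
    return(g)
  }
  g <- toupper(g)
  if (all(nchar(g) == 2L)) {
    a <- allele_index(substr(g, 1L, 1L))
    b <- allele_index(substr(g, 2L, 2L))
    return(GT_INDEX[cbind(a, b)])
  }
  if (length(g) == 2L && all(nchar(g) == 1L)) {
    return(GT_INDEX[allele_index(g[1]), allele_index(g[2])])
  }
  stop("cannot interpret genotype: ", paste(g, collapse = ""))
}

genotype_label <- function(k) GT_LABELS[k]

#' Convert a Phred quality score to an error probability
#'
#' Phred score q encodes a base-call error probability 10^(-q/10). Quality 0
#' maps to exactly 1.0, keeping the error in the half-open interval (0, 1];
#' qualities are restricted to the Sanger-encoding range 0..93.
#'
#' @param q Integer Phred score(s) in 0..93.
#' @return Numeric error probabilities in (0, 1].
#' @examples
#' error_from_quality(c(0, 10, 20)) # 1, 0.1, 0.01
#' @export
error_from_quality <- function(q) {
  if (!is.numeric(q) || anyNA(q)) stop("quality must be numeric and non-missing")
  if (any(q < 0 | q > 93)) {
    bad <- q[q < 0 | q > 93][1]
    stop("Phred quality out of range [0, 93]: ", bad)
  }
  10^(-q / 10)
}

#' Convert a posterior probability to a Phred-scaled quality
#'
#' Returns round(-10 * log10(1 - p)), capped at 99; the conventional
#' quality of a call whose posterior probability is p.
#'
#' @param p Probability (or vector) in [0, 1].
#' @return Integer quality score(s) in 0..99.
#' @export
phred_quality <- function(p) {
  if (!is.numeric(p) || anyNA(p)) stop("probability must be numeric and non-missing")
  if (any(p < -1e-9 | p > 1 + 1e-9)) stop("probability out of [0, 1]: ", p[p < -1e-9 | p > 1 + 1e-9][1])
  p <- pmin(pmax(p, 0), 1)  # absorb float round-off from posterior sums
  q <- round(-10 * log10(1 - p))
  q[!is.finite(q) | q > 99] <- 99L
  as.integer(q)
}
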