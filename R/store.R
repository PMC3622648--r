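# Per-sample, per-locus read likelihoods via the T_beta subproduct
# factorization, and the compact partial-likelihood store.
#
# For a call set {(z_k, eps_k)} and an allele mixture rho, the read
# likelihood factorizes over called alleles: L(rho) = prod_z T_{rho[z]}[z]
# with T_beta[z] = prod_{k: z_k = z} f(beta, eps_k) and
# f(beta, eps) = beta + eps * (1 - 4 beta) / 3. Only nine values of
# beta ever occur: 0 (off-genotype allele), 1 (homozygote), 1/2
# (heterozygote), and six purity-dependent values for divergent
# normal-tumor genotype mixtures. Normalizing by E[z] = T_0[z] and the
# scale E = prod_z E[z] = prod_k eps_k / 3, each likelihood is a product
# of a handful of stored values. Subproducts are accumulated and stored
# as logarithms: the scale E alone underflows past ~150 reads in double
# precision.

# the eight stored beta values (beta = 0 normalizes to 1 and is implicit):
# slot 1 = 1 (C'), slot 2 = 1/2 (H'), slots 3..8 the six impure values
store_betas <- function(omega) {
  c(1, 0.5,
    0.5 - omega / 2, 1 - omega, omega / 2,
    1 - omega / 2, omega, 0.5 + omega / 2)
}

N_BETA <- 8L

# Column of the (locus x 32) store matrix holding log T'_beta[allele].
store_col <- function(slot, allele) (slot - 1L) * 4L + allele

# Static slot assignment for every (gN, gT) pair: which (slot, allele)
# log-subproducts multiply into L(gN, gT). The mapping is determined by
# the mutation pattern alone, so it is computed once at a generic purity
# and reused for every omega. Pair index p = (gT - 1) * 10 + gN.
PAIR_COLS <- local({
  w0 <- 0.37
  betas0 <- store_betas(w0)
  stopifnot(!anyDuplicated(betas0))
  out <- vector("list", 100L)
  for (gT in 1:10) for (gN in 1:10) {
    rho <- (1 - w0) * MIXTURES[gN, ] + w0 * MIXTURES[gT, ]
    cols <- integer(0)
    for (a in 1:4) {
      if (rho[a] > 1e-12) {
        slot <- which(abs(betas0 - rho[a]) < 1e-9)
        stopifnot(length(slot) == 1L)
        cols <- c(cols, store_col(slot, a))
      }
    }
    out[[(gT - 1L) * 10L + gN]] <- cols
  }
  out
})

# columns for pure diploid genotypes (= PAIR_COLS of the diagonal)
DIP_COLS <- lapply(1:10, function(g) PAIR_COLS[[(g - 1L) * 10L + g]])

#' Per-read likelihood factor
#'
#' f(beta, eps) = beta + eps * (1 - 4 beta) / 3: the probability that a
#' read calls an allele whose sampling frequency is beta, under the
#' unbiased error model with error probability eps. f(0, eps) = eps/3,
#' f(1, eps) = 1 - eps, f(1/2, eps) = 1/2 - eps/3.
#'
#' @param beta Called-allele sampling frequency in [0, 1].
#' @param eps Base-call error probability in (0, 1].
#' @return The factor, vectorized over either argument.
#' @export
f_factor <- function(beta, eps) {
  beta + eps * (1 - 4 * beta) / 3
}

## batch store -------------------------------------------------------------

# calls: list(locus = int, allele = int 1..4, qual = int 0..93) or NULL.
# Returns list(logE = numeric(n), logT = n x 32 matrix) where
# logT[, store_col(s, a)] = log T'_{beta_s}[a] and logE = log E.
build_store_batch <- function(calls, n, omega, mu = NULL) {
  logE <- numeric(n)
  logT <- matrix(0, n, 4L * N_BETA)
  if (is.null(calls) || length(calls$locus) == 0L) {
    return(list(logE = logE, logT = logT))
  }
  # canonical accumulation order: call order must not affect any
  # likelihood, bit for bit
  o <- order(calls$locus, calls$allele, calls$qual, method = "radix")
  calls <- list(locus = calls$locus[o], allele = calls$allele[o],
                qual = calls$qual[o])
  eps <- if (is.null(mu)) 10^(-calls$qual / 10) else mu[calls$qual + 1L]
  le <- log(eps / 3)
  rs <- rowsum(le, calls$locus)
  logE[as.integer(rownames(rs))] <- rs
  betas <- store_betas(omega)
  for (a in 1:4) {
    sel <- calls$allele == a
    if (!any(sel)) next
    eps_a <- eps[sel]
    le_a <- le[sel]
    loc_a <- calls$locus[sel]
    for (s in seq_len(N_BETA)) {
      v <- log(pmax(f_factor(betas[s], eps_a), 0)) - le_a
      rs <- rowsum(v, loc_a)
      logT[as.integer(rownames(rs)), store_col(s, a)] <- rs
    }
  }
  list(logE = logE, logT = logT)
}

# n x 10 matrix of log L(g) for pure diploid genotypes
batch_diploid_loglik <- function(store) {
  out <- matrix(0, length(store$logE), 10L)
  for (g in 1:10) {
    cols <- DIP_COLS[[g]]
    out[, g] <- store$logE + if (length(cols) == 1L) store$logT[, cols] else
      store$logT[, cols[1]] + store$logT[, cols[2]]
  }
  out
}

# n x 100 matrix of log L(gN, gT) for the impure tumor sample,
# pair index p = (gT - 1) * 10 + gN
batch_pair_loglik <- function(store) {
  out <- matrix(0, length(store$logE), 100L)
  for (p in 1:100) {
    cols <- PAIR_COLS[[p]]
    acc <- store$logE
    for (cc in cols) acc <- acc + store$logT[, cc]
    out[, p] <- acc
  }
  out
}

## single-locus user surface ------------------------------------------------

as_call_frame <- function(calls) {
  if (is.null(calls)) return(NULL)
  if (is.data.frame(calls)) {
    if (nrow(calls) == 0L) return(NULL)
    a <- allele_index(calls$allele)
    q <- as.integer(calls$quality %||% calls$qual)
    if (anyNA(q) || any(q < 0 | q > 93)) stop("Phred quality out of range [0, 93]")
    return(list(allele = a, qual = q))
  }
  stop("calls must be a data.frame with columns allele and quality")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the partial-likelihood store for one sample at one locus
#'
#' Condenses a multiset of (allele, quality) base calls into the
#' 1 + 8m log-scale values (scale E plus, per called allele, the
#' normalized subproducts C', H' and the six purity-dependent T'_beta)
#' from which every pure-diploid and impure normal-tumor likelihood is a
#' product of stored terms. The order of calls never affects the store.
#'
#' @param calls data.frame with columns `allele` and `quality` (integer
#'   Phred scores 0..93); zero rows or NULL give the empty store.
#' @param omega Tumor purity used for the six mixture subproducts.
#' @param mu Optional calibrated quality map (numeric vector of 94 error
#'   probabilities indexed by quality 0..93); default canonical Phred.
#' @return Object of class `"pl_store"` with elements `log_scale` (log E),
#'   `logC`, `logH` (length-4, log C'/H' per allele), `logT` (8 x 4 matrix
#'   of log T'_beta), `called` (logical 4), `m` (number of calls) and
#'   `omega`.
#' @export
build_store <- function(calls, omega = 1, mu = NULL) {
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega < 0 || omega > 1) {
    stop("tumor purity omega out of [0, 1]: ", omega)
  }
  cf <- as_call_frame(calls)
  b <- build_store_batch(
    if (is.null(cf)) NULL else list(locus = rep(1L, length(cf$allele)),
                                    allele = cf$allele, qual = cf$qual),
    n = 1L, omega = omega, mu = mu)
  logT <- matrix(b$logT[1, ], N_BETA, 4L, byrow = TRUE,
                 dimnames = list(NULL, ALLELES))
  called <- rep(FALSE, 4); names(called) <- ALLELES
  if (!is.null(cf)) called[unique(cf$allele)] <- TRUE
  structure(list(
    log_scale = b$logE[1],
    logC = logT[1, ],
    logH = logT[2, ],
    logT = logT,
    called = called,
    m = if (is.null(cf)) 0L else length(cf$allele),
    omega = omega
  ), class = "pl_store")
}

#' @export
print.pl_store <- function(x, ...) {
  cat("Partial-likelihood store: ", x$m, " calls, alleles {",
      paste(ALLELES[x$called], collapse = ","), "}, log E = ",
      format(x$log_scale, digits = 6), ", omega = ", x$omega, "\n", sep = "")
  invisible(x)
}

#' Read likelihood of a pure diploid genotype
#'
#' L(yy) = C'[y] * E for homozygotes and L(yy') = H'[y] * H'[y'] * E for
#' heterozygotes, reconstructed from the store.
#'
#' @param store A `"pl_store"` from [build_store()].
#' @param g Genotype.
#' @param log Return the log-likelihood instead?
#' @return The read likelihood (1 for an empty call set).
#' @export
diploid_likelihood <- function(store, g, log = FALSE) {
  stopifnot(inherits(store, "pl_store"))
  g <- genotype_index(g)
  cols <- DIP_COLS[[g]]
  tv <- t(store$logT)  # flattened in store_col order
  ll <- store$log_scale + sum(tv[cols])
  if (log) ll else exp(ll)
}

#' Read likelihood of an impure normal-tumor genotype pair
#'
#' Dispatches on the somatic mutation pattern gN -> gT: for identical
#' genotypes the purity is immaterial and the pure diploid likelihood is
#' returned; otherwise the up-to-four called-allele frequencies of the
#' omega-mixture select the matching stored T'_beta subproducts.
#'
#' @param store A `"pl_store"` built at the same omega.
#' @param gN,gT Normal and tumor genotypes.
#' @param omega Tumor purity; must equal the store's omega.
#' @param log Return the log-likelihood instead?
#' @return The read likelihood.
#' @export
tumor_pair_likelihood <- function(store, gN, gT, omega, log = FALSE) {
  stopifnot(inherits(store, "pl_store"))
  if (abs(omega - store$omega) > 1e-12) {
    stop("store was built at omega = ", store$omega,
         " but likelihood requested at omega = ", omega,
         "; rebuild the store")
  }
  gN <- genotype_index(gN)
  gT <- genotype_index(gT)
  cols <- PAIR_COLS[[(gT - 1L) * 10L + gN]]
  tv <- t(store$logT)
  ll <- store$log_scale + sum(tv[cols])
  if (log) ll else exp(ll)
}

#' Canonical key for a base-call multiset
#'
#' Sorts calls by allele then quality and run-length encodes
#' (allele, quality, count) triples. Identical multisets give identical
#' keys, which lets recurrent low-coverage pileup columns share one
#' store. The key is only used when it stays compact: with more than 64
#' calls, or an encoding over 32 bytes, `NA` is returned and the call set
#' is treated as unique.
#'
#' @param calls data.frame with columns `allele`, `quality` (or NULL).
#' @return A single string, `""` for an empty set, or `NA_character_`
#'   when the encoding exceeds the byte budget.
#' @export
encode_call_set <- function(calls) {
  cf <- as_call_frame(calls)
  if (is.null(cf)) return("")
  m <- length(cf$allele)
  if (m > 64L) return(NA_character_)
  o <- order(cf$allele, cf$qual)
  code <- paste0(ALLELES[cf$allele[o]], cf$qual[o])
  r <- rle(code)
  key <- paste0(r$values, "x", r$lengths, collapse = ";")
  if (nchar(key, type = "bytes") > 32L) return(NA_character_)
  key
}

# Store lookup through the recurrent-call cache: `cache` is an environment
# keyed by encode_call_set(); uncacheable sets are built directly.
build_store_cached <- function(calls, omega, cache, mu = NULL) {
  key <- encode_call_set(calls)
  if (is.na(key)) return(build_store(calls, omega, mu))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  st <- build_store(calls, omega, mu)
  assign(key, st, envir = cache)
  st
}
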