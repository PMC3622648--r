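# Independent brute-force oracles used to validate the factorized
# likelihood machinery, plus small fixture generators.

ALL4 <- c("A", "C", "G", "T")
GT10 <- quartetcall::genotypes()

rand_calls <- function(m, quals = c(10, 20, 30, 40), prob = NULL) {
  if (m == 0L) return(data.frame(allele = character(0), quality = integer(0)))
  data.frame(allele = sample(ALL4, m, replace = TRUE, prob = prob),
             quality = sample(quals, m, replace = TRUE))
}

# direct per-read evaluation of the read likelihood for an allele mixture:
# L(rho) = prod_k sum_y P(z_k | y) rho[y], in log space
oracle_read_loglik <- function(calls, rho) {
  if (NROW(calls) == 0L) return(0)
  z <- match(calls$allele, ALL4)
  eps <- 10^(-calls$quality / 10)
  per_read <- rho[z] * (1 - eps) + (1 - rho[z]) * eps / 3
  sum(log(per_read))
}

# pure-genotype and impure normal/tumor read log-likelihood via the oracle
oracle_dip_loglik <- function(calls, g) {
  oracle_read_loglik(calls, quartetcall::mixture_for_genotype(g))
}
oracle_pair_loglik <- function(calls, gN, gT, omega) {
  oracle_read_loglik(calls, quartetcall::impure_mixture(gN, gT, omega))
}

# naive six-hidden-variable summation of the complete quartet likelihood
# (10^6 terms, primed parental genotypes explicit), in log space
oracle_joint_loglik <- function(locus, params) {
  ns <- asNamespace("quartetcall")
  CHI <- get("CHI_TABLE", ns)
  PHI <- quartetcall::genotype_prior(
    quartetcall::allele_prior(locus$ref, params$divergence), params$gamma)
  KF <- quartetcall::genotype_mutation_kernel(params$nu_f)
  KM <- quartetcall::genotype_mutation_kernel(params$nu_m)
  KT <- quartetcall::genotype_mutation_kernel(params$nu_t)
  LF <- vapply(1:10, function(g) oracle_dip_loglik(locus$father, g), 0)
  LM <- vapply(1:10, function(g) oracle_dip_loglik(locus$mother, g), 0)
  LN <- vapply(1:10, function(g) oracle_dip_loglik(locus$normal, g), 0)
  LT <- outer(1:10, 1:10, Vectorize(function(gn, gt)
    oracle_pair_loglik(locus$tumor, gn, gt, params$omega)))
  grid <- expand.grid(gF = 1:10, gM = 1:10, gFp = 1:10, gMp = 1:10,
                      gN = 1:10, gT = 1:10)
  lp <- log(PHI[grid$gF]) + log(PHI[grid$gM]) +
    log(KF[cbind(grid$gF, grid$gFp)]) + log(KM[cbind(grid$gM, grid$gMp)]) +
    log(CHI[cbind(grid$gFp, grid$gMp, grid$gN)]) +
    log(KT[cbind(grid$gN, grid$gT)]) +
    LF[grid$gF] + LM[grid$gM] + LN[grid$gN] + LT[cbind(grid$gN, grid$gT)]
  m <- max(lp[is.finite(lp)])
  m + log(sum(exp(lp - m), na.rm = TRUE))
}

# naive restricted summation: joint posterior over (gN, gT)
oracle_pair_posterior <- function(locus, params) {
  ns <- asNamespace("quartetcall")
  CHI <- get("CHI_TABLE", ns)
  PHI <- quartetcall::genotype_prior(
    quartetcall::allele_prior(locus$ref, params$divergence), params$gamma)
  KF <- quartetcall::genotype_mutation_kernel(params$nu_f)
  KM <- quartetcall::genotype_mutation_kernel(params$nu_m)
  KT <- quartetcall::genotype_mutation_kernel(params$nu_t)
  LF <- vapply(1:10, function(g) exp(oracle_dip_loglik(locus$father, g)), 0)
  LM <- vapply(1:10, function(g) exp(oracle_dip_loglik(locus$mother, g)), 0)
  LN <- vapply(1:10, function(g) exp(oracle_dip_loglik(locus$normal, g)), 0)
  LT <- outer(1:10, 1:10, Vectorize(function(gn, gt)
    exp(oracle_pair_loglik(locus$tumor, gn, gt, params$omega))))
  # chi-prime by direct triple sum
  chiP <- array(0, c(10, 10, 10))
  for (gF in 1:10) for (gM in 1:10) for (gN in 1:10) {
    chiP[gF, gM, gN] <- sum(outer(KF[gF, ], KM[gM, ]) * CHI[, , gN])
  }
  post <- matrix(0, 10, 10)
  for (gN in 1:10) for (gT in 1:10) {
    U <- sum(outer(PHI * LF, PHI * LM) * chiP[, , gN])
    post[gN, gT] <- U * LN[gN] * KT[gN, gT] * LT[gN, gT]
  }
  post / sum(post)
}

rand_locus <- function(depths = c(8, 8, 8, 8), quals = c(10, 20, 30, 40)) {
  list(ref = sample(ALL4, 1),
       father = rand_calls(rpois(1, depths[1]), quals),
       mother = rand_calls(rpois(1, depths[2]), quals),
       normal = rand_calls(rpois(1, depths[3]), quals),
       tumor = rand_calls(rpois(1, depths[4]), quals))
}

rand_params <- function() {
  quartetcall::quartet_params(
    divergence = runif(1, 1e-4, 0.05),
    gamma = runif(1, 0, 0.5),
    nu_f = runif(1, 1e-6, 0.01),
    nu_m = runif(1, 1e-6, 0.01),
    nu_t = runif(1, 1e-6, 0.02),
    omega = runif(1, 0.05, 0.95))
}
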