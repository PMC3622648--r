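# The O(G^3) quartet likelihood decomposition and posterior machinery.
#
# For each locus the full likelihood
#   L = sum over (gF, gM, gF', gM', gN, gT) of prior x mutation x
#       inheritance x read-likelihood terms
# is computed through the three-stage decomposition
#   LN[g]      = L_N(g) * sum_gT nuT(g -> gT) * L_T(g, gT)
#   LFM[g, g'] = sum_gN chi'(g, g' -> gN) * LN[gN]
#   L          = sum_{g, g'} phiF(g) L_F(g) phiM(g') L_M(g') LFM[g, g']
# with the germline mutations folded into chi'. All tables are kept in
# log space with per-locus max-subtraction; the implementation is
# vectorized across loci (matrices with one row per locus).

PF_IDX <- rep(1:10, times = 10)       # pair p = (gM - 1) * 10 + gF
PM_IDX <- rep(1:10, each = 10)
DIAG100 <- (0:9) * 10L + 1:10         # p with gN == gT

row_max <- function(m) {
  r <- m[, 1]
  for (j in 2:ncol(m)) r <- pmax(r, m[, j])
  r
}

# per-iteration parameter tables shared across loci
param_tables <- function(params) {
  PHI <- t(vapply(1:4, function(r)
    genotype_prior(allele_prior(r, params$divergence), params$gamma),
    numeric(10)))
  chiP <- combined_inheritance(params$nu_f, params$nu_m)
  Chi2 <- matrix(chiP, 100L, 10L)               # row p = (gM-1)*10 + gF
  mask0 <- matrix(CHI_TABLE == 0, 100L, 10L)    # Mendelian-impossible (unmutated)
  KT <- genotype_mutation_kernel(params$nu_t)
  list(
    logPHI = log(PHI),
    Chi2 = Chi2,
    Chi2_masked = Chi2 * mask0,
    ChiRaw2 = matrix(CHI_TABLE, 100L, 10L),     # row q = (gM'-1)*10 + gF'
    KF = genotype_mutation_kernel(params$nu_f),
    KM = genotype_mutation_kernel(params$nu_m),
    logKTflat = as.vector(log(KT)),             # col p = (gT-1)*10 + gN
    mu = params_mu(params)
  )
}

# stores: list(father, mother, normal, tumor) of batch stores (or NULL);
# ref: integer reference alleles; want: "loglik", "em" or "post".
engine_run <- function(stores, ref, tabs, want = "loglik", chunk = 4096L) {
  n <- length(ref)
  dip <- function(s) if (is.null(s)) matrix(0, n, 10L) else batch_diploid_loglik(s)
  llF <- dip(stores$father)
  llM <- dip(stores$mother)
  llN <- dip(stores$normal)
  llT <- if (is.null(stores$tumor)) matrix(0, n, 100L) else batch_pair_loglik(stores$tumor)

  logAF <- llF + tabs$logPHI[ref, , drop = FALSE]
  sF <- row_max(logAF)
  AF <- exp(logAF - sF)
  logAM <- llM + tabs$logPHI[ref, , drop = FALSE]
  sM <- row_max(logAM)
  AM <- exp(logAM - sM)
  rm(logAF, logAM, llF, llM)

  logNT <- llN[, rep(1:10, times = 10), drop = FALSE] + llT
  logNT <- sweep(logNT, 2L, tabs$logKTflat, "+")
  rm(llT, llN)
  sNT <- row_max(logNT)
  ENT <- exp(logNT - sNT)
  rm(logNT)
  TN <- vapply(1:10, function(g) rowSums(ENT[, g + 10L * (0:9), drop = FALSE]),
               numeric(n))
  if (n == 1L) TN <- matrix(TN, 1L)

  M1 <- TN %*% t(tabs$Chi2)
  W <- AF[, PF_IDX, drop = FALSE] * AM[, PM_IDX, drop = FALSE]
  WM <- W * M1
  Lsc <- rowSums(WM)
  if (any(!is.finite(Lsc) | Lsc <= 0)) {
    bad <- which(!is.finite(Lsc) | Lsc <= 0)[1]
    stop("all-zero or non-finite joint likelihood at locus ", bad)
  }
  loglik <- sF + sM + sNT + log(Lsc)
  out <- list(loglik = loglik)
  if (want == "loglik") return(out)

  U <- W %*% tabs$Chi2

  if (want == "em") {
    pFM <- WM / Lsc
    pF <- vapply(1:10, function(g) rowSums(pFM[, g + 10L * (0:9), drop = FALSE]),
                 numeric(n))
    pM <- vapply(1:10, function(g) rowSums(pFM[, (g - 1L) * 10L + 1:10, drop = FALSE]),
                 numeric(n))
    if (n == 1L) { pF <- matrix(pF, 1L); pM <- matrix(pM, 1L) }
    rm(pFM, WM, M1)
    agg_ref <- function(p) t(vapply(1:4, function(r)
      colSums(p[ref == r, , drop = FALSE]), numeric(10)))
    V <- U / Lsc
    S_NT <- t(vapply(1:10, function(g)
      colSums(V[, g] * ENT[, g + 10L * (0:9), drop = FALSE]), numeric(10)))
    B <- TN %*% t(tabs$ChiRaw2)
    AM2 <- AM %*% tabs$KM
    D <- vapply(1:10, function(gp) rowSums(AM2 * B[, gp + 10L * (0:9), drop = FALSE]),
                numeric(n))
    if (n == 1L) D <- matrix(D, 1L)
    S_F <- tabs$KF * (t(AF / Lsc) %*% D)
    AF2 <- AF %*% tabs$KF
    Dm <- vapply(1:10, function(gp) rowSums(AF2 * B[, (gp - 1L) * 10L + 1:10, drop = FALSE]),
                 numeric(n))
    if (n == 1L) Dm <- matrix(Dm, 1L)
    S_M <- tabs$KM * (t(AM / Lsc) %*% Dm)
    out$S_F <- S_F; out$S_M <- S_M; out$S_NT <- S_NT
    out$PrF <- agg_ref(pF); out$PrM <- agg_ref(pM)
    out$n <- n
    return(out)
  }

  ## want == "post": per-locus posteriors, MAP quadruple, mutation posteriors
  pFM <- WM / Lsc
  pF <- vapply(1:10, function(g) rowSums(pFM[, g + 10L * (0:9), drop = FALSE]), numeric(n))
  pM <- vapply(1:10, function(g) rowSums(pFM[, (g - 1L) * 10L + 1:10, drop = FALSE]), numeric(n))
  pN <- U * TN / Lsc
  pT <- vapply(1:10, function(g) rowSums(U * ENT[, (g - 1L) * 10L + 1:10, drop = FALSE]),
               numeric(n)) / Lsc
  if (n == 1L) { pF <- matrix(pF, 1L); pM <- matrix(pM, 1L); pT <- matrix(pT, 1L) }
  p_som <- 1 - rowSums(U * ENT[, DIAG100, drop = FALSE]) / Lsc
  p_den <- rowSums(W * (TN %*% t(tabs$Chi2_masked))) / Lsc
  p_som <- pmin(pmax(p_som, 0), 1)
  p_den <- pmin(pmax(p_den, 0), 1)

  # MAP joint assignment (gF, gM, gN, gT), chunked to bound memory
  mapF <- mapM <- mapN <- mapT <- integer(n)
  p_map <- numeric(n)
  chiflat <- as.vector(tabs$Chi2)   # col-major: (gN - 1) * 100 + p
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    ii <- lo:hi
    nc <- length(ii)
    valT <- matrix(0, nc, 10L)
    idxT <- matrix(0L, nc, 10L)
    for (g in 1:10) {
      sub <- ENT[ii, g + 10L * (0:9), drop = FALSE]
      idxT[, g] <- max.col(sub, ties.method = "first")
      valT[, g] <- sub[cbind(seq_len(nc), idxT[, g])]
    }
    A3 <- W[ii, rep(1:100, times = 10), drop = FALSE] *
      valT[, rep(1:10, each = 100), drop = FALSE]
    A3 <- sweep(A3, 2L, chiflat, "*")
    best <- max.col(A3, ties.method = "first")
    p_map[ii] <- A3[cbind(seq_len(nc), best)] / Lsc[ii]
    gN <- (best - 1L) %/% 100L + 1L
    p <- (best - 1L) %% 100L + 1L
    mapF[ii] <- (p - 1L) %% 10L + 1L
    mapM[ii] <- (p - 1L) %/% 10L + 1L
    mapN[ii] <- gN
    mapT[ii] <- idxT[cbind(seq_len(nc), gN)]
  }
  p_map <- pmin(pmax(p_map, 0), 1)

  out$pF <- pF; out$pM <- pM; out$pN <- pN; out$pT <- pT
  out$pair_joint <- U[, rep(1:10, times = 10), drop = FALSE] * ENT / Lsc
  out$p_somatic <- p_som
  out$p_denovo <- p_den
  out$map <- cbind(father = mapF, mother = mapM, normal = mapN, tumor = mapT)
  out$p_map <- p_map
  out
}

## single-locus user surface ------------------------------------------------

as_single_locus <- function(locus) {
  if (inherits(locus, "quartet_loci")) {
    if (locus$n != 1L) stop("expected a single locus; got ", locus$n)
    return(locus)
  }
  stopifnot(is.list(locus), !is.null(locus$ref))
  calls <- list()
  for (s in SAMPLES) {
    cs <- locus[[s]]
    if (is.null(cs) || NROW(cs) == 0L) next
    cs$locus <- 1L
    calls[[s]] <- cs
  }
  quartet_loci(chrom = locus$chrom %||% "locus", pos = locus$pos %||% 1L,
               ref = locus$ref, calls = calls)
}

#' Joint quartet likelihood at one locus
#'
#' Computes the full-quartet likelihood by the O(G^3) decomposition, with
#' germline mutations folded into the combined inheritance kernel and the
#' tumor sample handled through the purity mixture. Missing samples
#' contribute a factor of 1.
#'
#' @param locus Either a single-locus [quartet_loci()] object or a list
#'   with elements `ref` and (optionally) `father`, `mother`, `normal`,
#'   `tumor` call data.frames (columns `allele`, `quality`).
#' @param params A [quartet_params()] object.
#' @param log Return the log-likelihood?
#' @return The likelihood (a positive real; 1 when all samples are empty).
#' @export
joint_likelihood <- function(locus, params, log = FALSE) {
  loci <- as_single_locus(locus)
  tabs <- param_tables(params)
  stores <- build_all_stores(loci, params$omega, params$mu)
  ll <- unname(engine_run(stores, loci$ref, tabs, want = "loglik")$loglik)
  if (log) ll else exp(ll)
}

#' Joint and marginal genotype posteriors at one locus
#'
#' Runs the same dynamic-programming tables as [joint_likelihood()] and
#' returns marginal genotype posteriors for all four samples, the joint
#' (normal, tumor) genotype posterior, the maximum-a-posteriori joint
#' assignment, and the de novo / somatic mutation posteriors.
#'
#' @inheritParams joint_likelihood
#' @return Object of class `"quartet_posterior"`: list with
#'   `log_likelihood`, `marginal` (4 x 10 matrix, rows father/mother/
#'   normal/tumor), `pair_joint` (10 x 10 over (gN, gT)), `joint_map`
#'   (named genotype labels), `map_posterior`, `p_denovo`, `p_somatic`.
#' @export
genotype_posteriors <- function(locus, params) {
  loci <- as_single_locus(locus)
  tabs <- param_tables(params)
  stores <- build_all_stores(loci, params$omega, params$mu)
  e <- engine_run(stores, loci$ref, tabs, want = "post")
  marg <- rbind(father = e$pF[1, ], mother = e$pM[1, ],
                normal = e$pN[1, ], tumor = e$pT[1, ])
  colnames(marg) <- GT_LABELS
  pj <- matrix(e$pair_joint[1, ], 10L, 10L, dimnames = list(GT_LABELS, GT_LABELS))
  structure(list(
    log_likelihood = e$loglik[1],
    likelihood = exp(e$loglik[1]),
    marginal = marg,
    pair_joint = pj,
    joint_map = stats::setNames(GT_LABELS[e$map[1, ]], SAMPLES),
    map_posterior = e$p_map[1],
    p_denovo = e$p_denovo[1],
    p_somatic = e$p_somatic[1]
  ), class = "quartet_posterior")
}

#' @export
print.quartet_posterior <- function(x, ...) {
  cat("Quartet posterior (log L = ", format(x$log_likelihood, digits = 6), ")\n", sep = "")
  cat("  MAP: ", paste(names(x$joint_map), x$joint_map, sep = "=", collapse = " "),
      "  (p = ", format(x$map_posterior, digits = 4), ")\n", sep = "")
  cat("  P(de novo) = ", format(x$p_denovo, digits = 4),
      "   P(somatic) = ", format(x$p_somatic, digits = 4), "\n", sep = "")
  invisible(x)
}

#' De novo and somatic mutation posteriors
#'
#' Extracts the two mutation posteriors from a [genotype_posteriors()]
#' result: the somatic posterior is the (gN, gT) posterior mass off the
#' diagonal, and the de novo posterior is the trio posterior mass on
#' assignments where the child's normal genotype is Mendelian-impossible
#' from the (unmutated) parental genotypes.
#'
#' @param posterior A `"quartet_posterior"` object.
#' @return Named numeric vector `c(p_denovo = , p_somatic = )`.
#' @export
mutation_posteriors <- function(posterior) {
  stopifnot(inherits(posterior, "quartet_posterior"))
  c(p_denovo = posterior$p_denovo,
    p_somatic = 1 - sum(diag(posterior$pair_joint)))
}
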