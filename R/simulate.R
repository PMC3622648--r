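# Generative quartet simulator: the probabilistic model run forwards.
#
# Per locus: reference allele uniform; parental genotypes from the
# gamma-adjusted Hardy-Weinberg prior at divergence v; per-allele
# Jukes-Cantor germline mutation of each parental genotype; Mendelian
# transmission to the child's normal genotype; per-allele Jukes-Cantor
# tumor mutation; per-sample Poisson read depth; reads sample the pure
# genotype mixture (tumor: the omega purity mixture) and are corrupted by
# the unbiased Phred-scaled error model.

mutate_alleles <- function(a, nu) {
  n <- length(a)
  hit <- stats::runif(n) < nu
  if (any(hit)) {
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    a[hit] <- ((a[hit] - 1L + shift) %% 4L) + 1L
  }
  a
}

gamete <- function(g) {
  pick <- sample.int(2L, length(g), replace = TRUE)
  GT_PAIRS[cbind(g, pick)]
}

sample_genotypes_from_prior <- function(ref, params) {
  n <- length(ref)
  g <- integer(n)
  for (r in 1:4) {
    idx <- which(ref == r)
    if (length(idx) == 0L) next
    phi <- genotype_prior(allele_prior(r, params$divergence), params$gamma)
    g[idx] <- sample.int(10L, length(idx), replace = TRUE, prob = phi)
  }
  g
}

# sample one read allele per row: genotype pair + purity
sample_read_alleles <- function(gN, gT, omega) {
  use_t <- stats::runif(length(gN)) < omega
  src <- ifelse(use_t, gT, gN)
  gamete(src)
}

#' Simulate a quartet sequencing experiment with known truth
#'
#' Draws hidden genotypes and base calls from the full generative model,
#' returning both the truth table and a [quartet_loci()] call set (plus,
#' optionally, pileup text). Defaults mirror the study conditions the
#' model targets: low per-sample exome coverage (mean depth 6), human-like
#' reference divergence 0.001, heterozygosity adjustment 0.1, germline
#' rate 1e-4, tumor rate 1e-3, tumor purity 0.6, and a mixed Phred
#' quality profile.
#'
#' @param n_loci Number of independent loci.
#' @param params A [quartet_params()] object holding the truth parameters.
#' @param depth Mean Poisson read depth per sample; a single number or a
#'   named vector over father/mother/normal/tumor.
#' @param quality_profile Named numeric vector: names are Phred scores,
#'   values their sampling weights.
#' @param seed Mandatory RNG seed (integer).
#' @param chrom Contig name for the synthetic loci.
#' @return Object of class `"quartet_sim"`: list with `truth` (data.frame:
#'   ref, genotypes gF, gM, gFp, gMp, gN, gT, flags is_denovo/is_somatic),
#'   `loci` (a `quartet_loci`), and `params`.
#' @export
simulate_quartet <- function(n_loci, params = quartet_params(),
                             depth = c(father = 6, mother = 6, normal = 6, tumor = 6),
                             quality_profile = c("20" = 0.25, "30" = 0.5, "40" = 0.25),
                             seed, chrom = "chrS") {
  if (missing(seed) || !is.numeric(seed)) stop("a numeric seed is required")
  stopifnot(n_loci >= 1L, inherits(params, "quartet_params"))
  if (length(depth) == 1L) depth <- stats::setNames(rep(depth, 4L), SAMPLES)
  depth <- depth[SAMPLES]
  if (anyNA(depth) || any(depth < 0)) stop("depth must give a non-negative mean per sample")
  qs <- as.integer(names(quality_profile))
  if (anyNA(qs) || any(qs < 0L | qs > 93L) || any(quality_profile < 0) ||
      sum(quality_profile) <= 0) {
    stop("quality_profile must map Phred scores 0..93 to non-negative weights")
  }
  set.seed(as.integer(seed))
  mu <- params_mu(params)

  ref <- sample.int(4L, n_loci, replace = TRUE)
  gF <- sample_genotypes_from_prior(ref, params)
  gM <- sample_genotypes_from_prior(ref, params)
  gFp <- GT_INDEX[cbind(mutate_alleles(GT_PAIRS[gF, 1], params$nu_f),
                        mutate_alleles(GT_PAIRS[gF, 2], params$nu_f))]
  gMp <- GT_INDEX[cbind(mutate_alleles(GT_PAIRS[gM, 1], params$nu_m),
                        mutate_alleles(GT_PAIRS[gM, 2], params$nu_m))]
  gN <- GT_INDEX[cbind(gamete(gFp), gamete(gMp))]
  gT <- GT_INDEX[cbind(mutate_alleles(GT_PAIRS[gN, 1], params$nu_t),
                       mutate_alleles(GT_PAIRS[gN, 2], params$nu_t))]

  calls <- list()
  for (si in 1:4) {
    s <- SAMPLES[si]
    d <- stats::rpois(n_loci, depth[[s]])
    loc <- rep(seq_len(n_loci), d)
    if (length(loc) == 0L) next
    y <- if (s == "tumor") sample_read_alleles(gN[loc], gT[loc], params$omega)
         else if (s == "normal") gamete(gN[loc])
         else if (s == "father") gamete(gF[loc])
         else gamete(gM[loc])
    q <- qs[sample.int(length(qs), length(loc), replace = TRUE,
                       prob = quality_profile)]
    z <- y
    err <- stats::runif(length(loc)) < mu[q + 1L]
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      z[err] <- ((z[err] - 1L + shift) %% 4L) + 1L
    }
    calls[[s]] <- data.frame(locus = loc, allele = z, quality = q)
  }

  truth <- data.frame(
    chrom = chrom, pos = seq_len(n_loci), ref = ALLELES[ref],
    gF = GT_LABELS[gF], gM = GT_LABELS[gM],
    gFp = GT_LABELS[gFp], gMp = GT_LABELS[gMp],
    gN = GT_LABELS[gN], gT = GT_LABELS[gT],
    is_denovo = CHI_TABLE[cbind(gF, gM, gN)] == 0,
    is_somatic = gN != gT
  )
  loci <- quartet_loci(chrom = chrom, pos = seq_len(n_loci), ref = ref, calls = calls)
  structure(list(truth = truth, loci = loci, params = params, seed = seed),
            class = "quartet_sim")
}

#' @export
print.quartet_sim <- function(x, ...) {
  s <- summarize_truth(x$truth)
  cat("Simulated quartet data: ", nrow(x$truth), " loci (seed ", x$seed, ")\n", sep = "")
  cat("  het (normal): ", s[["het_normal"]],
      ", de novo: ", s[["denovo"]], ", somatic: ", s[["somatic"]], "\n", sep = "")
  invisible(x)
}

#' Summarize a simulation truth table
#'
#' @param truth The `truth` data.frame of a [simulate_quartet()] result.
#' @return Named integer vector: counts of loci, heterozygous normal
#'   genotypes, homozygous non-reference normal genotypes, de novo and
#'   somatic loci.
#' @export
summarize_truth <- function(truth) {
  if (NROW(truth) == 0L) {
    return(c(n = 0L, het_normal = 0L, hom_nonref = 0L, denovo = 0L, somatic = 0L))
  }
  gN <- genotype_index(truth$gN)
  het <- !GT_IS_HOM[gN]
  hom_nonref <- GT_IS_HOM[gN] & GT_LABELS[gN] != paste0(truth$ref, truth$ref)
  c(n = nrow(truth),
    het_normal = sum(het),
    hom_nonref = sum(hom_nonref),
    denovo = sum(truth$is_denovo),
    somatic = sum(truth$is_somatic))
}
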