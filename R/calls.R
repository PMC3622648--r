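# Greedy ambiguity-aware genotype calls and VCF v4.1 output.

# genotype-contains-allele indicator (10 x 4)
CONTAINS_GT <- local({
  m <- matrix(FALSE, 10L, 4L)
  for (k in 1:10) m[k, unique(GT_PAIRS[k, ])] <- TRUE
  m
})

# Row-wise argmax with the package's deterministic tie-break: ties go to
# the column "containing" the reference allele first, then to canonical
# order. `contains` is an ncol x 4 logical (per reference allele).
map_with_tiebreak <- function(p, ref, contains) {
  n <- nrow(p)
  out <- integer(n)
  for (r in 1:4) {
    rows <- which(ref == r)
    if (length(rows) == 0L) next
    ordc <- order(!contains[, r], seq_len(ncol(p)))
    j <- max.col(p[rows, ordc, drop = FALSE], ties.method = "first")
    out[rows] <- ordc[j]
  }
  out
}

# Greedy calls for one sample across loci. p: n x 10 marginal posteriors.
# Returns list(a1, a2 (allele index or NA), gq, level).
greedy_calls <- function(p, ref, min_gq) {
  n <- nrow(p)
  g_map <- map_with_tiebreak(p, ref, CONTAINS_GT)
  gq_full <- phred_quality(p[cbind(seq_len(n), g_map)])
  q_allele <- p %*% CONTAINS_GT                     # P(genotype contains a)
  a_map <- map_with_tiebreak(q_allele, ref, diag(4) == 1)
  gq_half <- phred_quality(pmin(q_allele[cbind(seq_len(n), a_map)], 1))
  full <- gq_full >= min_gq
  half <- !full & gq_half >= min_gq
  a1 <- ifelse(full, GT_PAIRS[g_map, 1], ifelse(half, a_map, NA_integer_))
  a2 <- ifelse(full, GT_PAIRS[g_map, 2], NA_integer_)
  gq <- ifelse(full, gq_full, gq_half)   # ./. keeps the half-call stage gq
  list(a1 = a1, a2 = a2, gq = as.integer(gq),
       level = ifelse(full, "full", ifelse(half, "half", "none")))
}

#' Greedy ambiguity-introducing genotype calls at one locus
#'
#' For each sample, the MAP genotype x/y is emitted when its Phred
#' quality meets `min_gq`; otherwise the best half-call x/. (posterior of
#' all genotypes containing x) is tried; otherwise ./. is emitted
#' carrying the half-call-stage quality. Ties break toward genotypes
#' containing the reference allele, then canonical order.
#'
#' @param posterior A `"quartet_posterior"` from [genotype_posteriors()].
#' @param min_gq Minimum genotype quality for a (half-)call; default 30.
#' @param ref Reference allele of the locus (used for tie-breaking;
#'   default "A").
#' @return data.frame with one row per sample: `sample`, `call`
#'   (e.g. "A/C", "A/.", "./."), `gq`.
#' @export
call_genotypes <- function(posterior, min_gq = 30L, ref = "A") {
  stopifnot(inherits(posterior, "quartet_posterior"), min_gq >= 0)
  r <- allele_index(ref)
  gc <- greedy_calls(posterior$marginal, rep(r, 4L), min_gq)
  fmt <- function(a1, a2, lev) {
    if (lev == "full") paste0(ALLELES[a1], "/", ALLELES[a2])
    else if (lev == "half") paste0(ALLELES[a1], "/.")
    else "./."
  }
  data.frame(sample = SAMPLES,
             call = mapply(fmt, gc$a1, gc$a2, gc$level),
             gq = gc$gq,
             row.names = NULL)
}

#' Call genotypes across a set of quartet loci
#'
#' Runs the joint posterior engine over all loci and produces per-sample
#' greedy genotype calls, joint quality, and mutation posteriors — the
#' record set consumed by [write_vcf()].
#'
#' @param loci A [quartet_loci()] object.
#' @param params A [quartet_params()] object.
#' @param min_gq Minimum per-sample genotype quality (Phred) for a call.
#' @return Object of class `"quartet_calls"`: a data.frame with one row
#'   per locus (chrom, pos, ref, qual, p_somatic, p_denovo, per-sample
#'   genotype call strings and GQ, MAP genotype labels) with the fitted
#'   parameters in `attr(, "params")`.
#' @export
quartet_call <- function(loci, params, min_gq = 30L) {
  stopifnot(inherits(loci, "quartet_loci"))
  tabs <- param_tables(params)
  stores <- build_all_stores(loci, params$omega, params$mu)
  e <- engine_run(stores, loci$ref, tabs, want = "post")
  n <- loci$n
  post <- list(father = e$pF, mother = e$pM, normal = e$pN, tumor = e$pT)
  df <- data.frame(chrom = loci$chrom, pos = loci$pos, ref = ALLELES[loci$ref],
                   qual = phred_quality(e$p_map),
                   p_somatic = e$p_somatic, p_denovo = e$p_denovo)
  support <- matrix(0, n, 4L)
  for (s in SAMPLES) {
    gc <- greedy_calls(post[[s]], loci$ref, min_gq)
    gt <- ifelse(gc$level == "full",
                 paste0(ALLELES[gc$a1], "/", ALLELES[gc$a2]),
                 ifelse(gc$level == "half", paste0(ALLELES[gc$a1], "/."), "./."))
    df[[paste0(s, "_gt")]] <- gt
    df[[paste0(s, "_gq")]] <- gc$gq
    df[[paste0(s, "_map")]] <- GT_LABELS[map_with_tiebreak(post[[s]], loci$ref, CONTAINS_GT)]
    support <- support + post[[s]] %*% CONTAINS_GT
  }
  attr(df, "params") <- params
  attr(df, "allele_support") <- support
  class(df) <- c("quartet_calls", "data.frame")
  df
}

## VCF v4.1 ----------------------------------------------------------------

vcf_header <- function(chroms, omega) {
  c("##fileformat=VCFv4.1",
    paste0("##source=quartetcall"),
    paste0("##contig=<ID=", unique(chroms), ">"),
    "##INFO=<ID=SOMATIC_P,Number=1,Type=Float,Description=\"Posterior probability of a somatic mutation (normal and tumor genotypes differ)\">",
    "##INFO=<ID=DENOVO_P,Number=1,Type=Float,Description=\"Posterior probability of a de novo germline mutation (child normal genotype Mendelian-inconsistent with parents)\">",
    paste0("##INFO=<ID=OMEGA,Number=1,Type=Float,Description=\"Tumor purity used for calling\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality (Phred)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
          "FATHER", "MOTHER", "NORMAL", "TUMOR", sep = "\t"))
}

#' Write quartet genotype calls as VCF v4.1
#'
#' Emits one record per locus passing the emission rule: by default a
#' locus is written when its joint quality is at least `min_qual` and at
#' least one emitted genotype contains a non-reference allele, or when
#' the somatic / de novo posterior exceeds its report threshold.
#' ALT lists every non-reference allele appearing in an emitted genotype,
#' ordered by posterior support; FILTER is always "." (filtering is
#' expressed through QUAL/GQ only).
#'
#' @param calls A `"quartet_calls"` object from [quartet_call()].
#' @param path Output file path, or NULL to return the lines.
#' @param min_qual Joint-quality emission threshold (default 30).
#' @param somatic_p,denovo_p Report thresholds on the mutation posteriors.
#' @param emit_all Emit every locus regardless of thresholds?
#' @return Character vector of VCF lines, invisibly.
#' @export
write_vcf <- function(calls, path = NULL, min_qual = 30, somatic_p = 0.5,
                      denovo_p = 0.5, emit_all = FALSE) {
  stopifnot(inherits(calls, "quartet_calls"))
  params <- attr(calls, "params")
  support <- attr(calls, "allele_support")
  n <- nrow(calls)
  refi <- allele_index(calls$ref)

  # which alleles appear in emitted genotypes, per record
  used <- matrix(FALSE, n, 4L)
  for (s in SAMPLES) {
    gt <- calls[[paste0(s, "_gt")]]
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    for (a in 1:4) used[, a] <- used[, a] | a1 == ALLELES[a] | a2 == ALLELES[a]
  }
  nonref <- used & (col(used) != refi)
  has_var <- rowSums(nonref) > 0
  emit <- if (emit_all) rep(TRUE, n) else {
    (calls$qual >= min_qual & has_var) |
      calls$p_somatic > somatic_p | calls$p_denovo > denovo_p
  }

  body <- character(sum(emit))
  k <- 0L
  for (i in which(emit)) {
    alts <- which(nonref[i, ])
    if (length(alts) > 1L) alts <- alts[order(-support[i, alts], alts)]
    alt_str <- if (length(alts)) paste(ALLELES[alts], collapse = ",") else "."
    idx_of <- integer(4L)
    idx_of[refi[i]] <- 0L
    if (length(alts)) idx_of[alts] <- seq_along(alts)
    gt_code <- function(gt) {
      a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
      c1 <- if (a1 == ".") "." else idx_of[allele_index(a1)]
      c2 <- if (a2 == ".") "." else idx_of[allele_index(a2)]
      paste0(c1, "/", c2)
    }
    fmt <- vapply(SAMPLES, function(s)
      paste0(gt_code(calls[[paste0(s, "_gt")]][i]), ":", calls[[paste0(s, "_gq")]][i]),
      "")
    info <- sprintf("SOMATIC_P=%.6g;DENOVO_P=%.6g;OMEGA=%.6g",
                    calls$p_somatic[i], calls$p_denovo[i], params$omega)
    k <- k + 1L
    body[k] <- paste(calls$chrom[i], calls$pos[i], ".", calls$ref[i], alt_str,
                     calls$qual[i], ".", info, "GT:GQ",
                     fmt[1], fmt[2], fmt[3], fmt[4], sep = "\t")
  }
  lines <- c(vcf_header(calls$chrom, params$omega), body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
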