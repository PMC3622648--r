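# Per-locus aligned base calls for up to four samples.

#' Assemble a set of quartet loci
#'
#' The in-memory container for per-locus base calls of the four samples
#' (father, mother, normal, tumor). Any sample may be absent, globally or
#' at individual loci; absent call sets contribute a likelihood factor
#' of 1.
#'
#' @param chrom Character vector of sequence names.
#' @param pos Integer vector of 1-based positions.
#' @param ref Reference alleles ("A".."T" or indices).
#' @param calls Named list with (optional) elements `father`, `mother`,
#'   `normal`, `tumor`; each a data.frame with columns `locus` (index into
#'   `pos`), `allele` and `quality`.
#' @return Object of class `"quartet_loci"`.
#' @export
quartet_loci <- function(chrom, pos, ref, calls = list()) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  ref <- allele_index(ref)
  stopifnot(length(ref) == n)
  cl <- vector("list", 4L)
  names(cl) <- SAMPLES
  for (s in SAMPLES) {
    cs <- calls[[s]]
    if (is.null(cs) || NROW(cs) == 0L) next
    loc <- as.integer(cs$locus)
    if (any(loc < 1L | loc > n)) stop("call locus index out of range for sample ", s)
    q <- as.integer(cs$quality %||% cs$qual)
    if (anyNA(q) || any(q < 0L | q > 93L)) stop("Phred quality out of range [0, 93] for sample ", s)
    cl[[s]] <- list(locus = loc, allele = allele_index(cs$allele), qual = q)
  }
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 calls = cl, n = n),
            class = "quartet_loci")
}

#' @export
print.quartet_loci <- function(x, ...) {
  depth <- vapply(SAMPLES, function(s)
    if (is.null(x$calls[[s]])) 0 else length(x$calls[[s]]$locus) / x$n, 0)
  cat("Quartet loci: ", x$n, " sites on ",
      length(unique(x$chrom)), " sequence(s)\n", sep = "")
  cat("  mean depth  ",
      paste(sprintf("%s %.1fx", SAMPLES, depth), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# build the four batch stores at a given omega / quality map
build_all_stores <- function(loci, omega, mu = NULL) {
  out <- vector("list", 4L)
  names(out) <- SAMPLES
  for (s in SAMPLES) {
    cs <- loci$calls[[s]]
    if (is.null(cs)) next
    out[[s]] <- build_store_batch(cs, loci$n,
                                  omega = if (s == "tumor") omega else 1,
                                  mu = mu)
  }
  out
}

## pileup text format -------------------------------------------------------
#
# Tab-separated, one locus per line:
#   chrom  pos  ref  F_calls F_quals  M_calls M_quals  N_calls N_quals  T_calls T_quals
# Call strings are bases (ACGT; N dropped), quality strings the matching
# Phred+33 characters; "*" marks an absent sample at that locus.

#' Read a quartet pileup file
#'
#' Parses the package's tab-separated pileup projection (one locus per
#' line: chrom, pos, ref, then call/quality string pairs for father,
#' mother, normal, tumor). Qualities are decoded from Phred+33; `N` or
#' other ambiguous base calls are dropped (a count is reported via
#' `message()`); records with a non-ACGT reference are skipped with a
#' warning.
#'
#' @param path File path, or a character vector of pileup lines.
#' @return A [quartet_loci()] object.
#' @export
read_pileup <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty pileup input")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 11L)) {
    stop("malformed pileup line ", which(nf != 11L)[1], ": expected 11 fields, got ",
         nf[nf != 11L][1])
  }
  m <- matrix(unlist(fields), ncol = 11L, byrow = TRUE)
  refs <- toupper(m[, 3])
  ok <- refs %in% ALLELES
  if (!all(ok)) {
    warning(sum(!ok), " record(s) with non-ACGT reference skipped")
    m <- m[ok, , drop = FALSE]
    refs <- refs[ok]
  }
  n <- nrow(m)
  if (n == 0L) stop("no usable pileup records")
  dropped <- 0L
  calls <- list()
  for (si in 1:4) {
    bs <- m[, 2L + 2L * si]
    qs <- m[, 3L + 2L * si]
    present <- bs != "*"
    if (any(nchar(bs[present]) != nchar(qs[present]))) {
      bad <- which(present & nchar(bs) != nchar(qs))[1]
      stop("pileup line ", bad, ": call and quality strings differ in length for sample ",
           SAMPLES[si])
    }
    idx <- which(present & nzchar(bs))
    if (length(idx) == 0L) next
    nb <- nchar(bs[idx])
    loc <- rep(idx, nb)
    base <- toupper(unlist(strsplit(bs[idx], "", fixed = TRUE)))
    qual <- utf8ToInt(paste(qs[idx], collapse = "")) - 33L
    keep <- base %in% ALLELES
    dropped <- dropped + sum(!keep)
    if (any(qual[keep] < 0L | qual[keep] > 93L)) {
      stop("quality character outside Phred+33 range [0, 93] for sample ", SAMPLES[si])
    }
    calls[[SAMPLES[si]]] <- data.frame(locus = loc[keep],
                                       allele = base[keep],
                                       quality = qual[keep])
  }
  if (dropped > 0L) message(dropped, " ambiguous base call(s) dropped")
  quartet_loci(chrom = m[, 1], pos = as.integer(m[, 2]), ref = refs, calls = calls)
}

#' Write quartet loci as pileup text
#'
#' Inverse of [read_pileup()]: serializes the call sets back to the
#' tab-separated pileup projection.
#'
#' @param loci A [quartet_loci()] object.
#' @param path Output file path, or NULL to return the lines invisibly.
#' @return The character vector of lines, invisibly.
#' @export
write_pileup <- function(loci, path = NULL) {
  stopifnot(inherits(loci, "quartet_loci"))
  n <- loci$n
  cols <- matrix("*", n, 8L)
  for (si in 1:4) {
    cs <- loci$calls[[SAMPLES[si]]]
    if (is.null(cs)) next
    o <- order(cs$locus)
    b <- vapply(split(ALLELES[cs$allele[o]], factor(cs$locus[o], levels = 1:n)),
                paste, "", collapse = "")
    q <- vapply(split(intToUtf8(cs$qual[o] + 33L, multiple = TRUE),
                      factor(cs$locus[o], levels = 1:n)),
                paste, "", collapse = "")
    has <- nzchar(b)
    cols[has, 2L * si - 1L] <- b[has]
    cols[has, 2L * si] <- q[has]
  }
  lines <- paste(loci$chrom, loci$pos, ALLELES[loci$ref],
                 cols[, 1], cols[, 2], cols[, 3], cols[, 4],
                 cols[, 5], cols[, 6], cols[, 7], cols[, 8],
                 sep = "\t")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
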