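# The user-facing model fit: EM training wrapped in a classed object
# with the standard modelling methods.

#' Fit the quartet genotyping model
#'
#' Trains all model parameters (reference divergence, heterozygosity
#' adjustment, germline and tumor substitution rates, tumor purity, and
#' optionally the quality map) on a set of quartet loci by
#' expectation-maximization, and returns a fitted-model object.
#'
#' @param loci A [quartet_loci()] object (from [read_pileup()] or
#'   [simulate_quartet()]).
#' @param init Initial parameter values, a [quartet_params()] object.
#' @param control Fitting settings, a [quartet_control()] object.
#' @return Object of class `"quartet_fit"` with components
#'   `params` (fitted [quartet_params()]), `coefficients` (named numeric
#'   vector), `trace` (per-iteration log-likelihood and parameters),
#'   `loglik`, `converged`, `n`, `loci`, and `call`.
#' @seealso [predict.quartet_fit()] for genotype calling,
#'   [simulate.quartet_fit()] for generating data at the fitted
#'   parameters.
#' @examples
#' sim <- simulate_quartet(300, depth = 20, seed = 7)
#' fit <- quartet_fit(sim$loci, control = quartet_control(max_iter = 5))
#' coef(fit)
#' @export
quartet_fit <- function(loci, init = quartet_params(), control = quartet_control()) {
  stopifnot(inherits(loci, "quartet_loci"))
  res <- run_em(loci, init, control)
  p <- res$params
  structure(list(
    params = p,
    coefficients = c(divergence = p$divergence, gamma = p$gamma,
                     nu_f = p$nu_f, nu_m = p$nu_m, nu_t = p$nu_t,
                     omega = p$omega),
    trace = res$trace,
    loglik = res$loglik,
    converged = res$converged,
    iterations = res$iterations,
    n = loci$n,
    loci = loci,
    control = control,
    call = match.call()
  ), class = "quartet_fit")
}

#' @export
print.quartet_fit <- function(x, ...) {
  cat("Quartet genotyping model fit (", x$n, " loci, ",
      x$iterations, " EM iterations",
      if (x$converged) ", converged" else "", ")\n", sep = "")
  print(round(x$coefficients, 8))
  cat("log-likelihood:", format(x$loglik, digits = 10), "\n")
  invisible(x)
}

#' @export
summary.quartet_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.quartet_fit")
}

#' @export
print.summary.quartet_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  tr <- f$trace
  cat("\nEM trace (", nrow(tr), " recorded steps):\n", sep = "")
  show <- tr[unique(c(1:min(3, nrow(tr)), max(1, nrow(tr) - 2):nrow(tr))), ]
  print(show, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
coef.quartet_fit <- function(object, ...) object$coefficients

#' @export
logLik.quartet_fit <- function(object, ...) {
  df <- 4L + (if (object$control$tie_germline) 1L else 2L) +
    (if (is.null(object$params$mu)) 0L else 94L) - 1L
  structure(object$loglik, df = df, nobs = object$n, class = "logLik")
}

#' Genotype calls and posteriors from a fitted quartet model
#'
#' @param object A [quartet_fit()] object.
#' @param newdata Optional [quartet_loci()] to call on (default: the
#'   training loci).
#' @param type `"calls"` for the per-locus genotype-call record set
#'   (see [quartet_call()]), `"posterior"` for a list of per-locus
#'   posterior summaries.
#' @param min_gq Minimum per-sample genotype quality.
#' @param ... Unused.
#' @return A `"quartet_calls"` data.frame, or a data.frame of posterior
#'   summaries.
#' @export
predict.quartet_fit <- function(object, newdata = NULL,
                                type = c("calls", "posterior"),
                                min_gq = 30L, ...) {
  type <- match.arg(type)
  loci <- newdata %||% object$loci
  out <- quartet_call(loci, object$params, min_gq = min_gq)
  if (type == "calls") return(out)
  out[, c("chrom", "pos", "ref", "qual", "p_somatic", "p_denovo",
          grep("_map$", names(out), value = TRUE))]
}

#' Simulate quartet data from a fitted model
#'
#' @param object A [quartet_fit()] object.
#' @param nsim Number of replicate data sets.
#' @param seed RNG seed (required for the first replicate; subsequent
#'   replicates increment it).
#' @param n_loci Loci per replicate (default: the training size).
#' @param ... Passed to [simulate_quartet()] (e.g. `depth`).
#' @return A `"quartet_sim"`, or a list of them when `nsim > 1`.
#' @export
simulate.quartet_fit <- function(object, nsim = 1, seed = 1, n_loci = object$n, ...) {
  sims <- lapply(seq_len(nsim), function(i)
    simulate_quartet(n_loci, params = object$params, seed = seed + i - 1L, ...))
  if (nsim == 1) sims[[1]] else sims
}
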