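# Model parameters and EM control settings.

SAMPLES <- c("father", "mother", "normal", "tumor")

#' Model parameters for quartet genotype inference
#'
#' Bundles every trainable parameter of the model: reference divergence v,
#' heterozygosity adjustment gamma, paternal/maternal germline substitution
#' rates, tumor substitution rate, tumor purity omega, and the quality
#' calibration map mu (reported Phred score 0..93 -> error probability;
#' canonical 10^(-q/10) by default).
#'
#' @param divergence Per-allele divergence from the reference, in [0, 1).
#' @param gamma Heterozygosity adjustment, <= 1 (negative values allowed
#'   when all genotype priors stay non-negative).
#' @param nu_f,nu_m Paternal and maternal germline Jukes-Cantor rates.
#' @param nu_t Tumor (somatic) Jukes-Cantor rate.
#' @param omega Tumor purity in [0, 1].
#' @param mu Optional numeric vector of 94 error probabilities in (0, 1]
#'   indexed by quality 0..93; NULL for the canonical Phred map.
#' @return Object of class `"quartet_params"`.
#' @export
quartet_params <- function(divergence = 0.001, gamma = 0.1,
                           nu_f = 1e-4, nu_m = nu_f, nu_t = 1e-3,
                           omega = 0.6, mu = NULL) {
  chk_rate <- function(x, nm, hi = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= hi + 1e-15) {
      stop(nm, " out of range: ", x)
    }
  }
  chk_rate(divergence, "divergence")
  chk_rate(nu_f, "nu_f"); chk_rate(nu_m, "nu_m"); chk_rate(nu_t, "nu_t")
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega < 0 || omega > 1) {
    stop("omega out of [0, 1]: ", omega)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma > 1) {
    stop("gamma must be a single number <= 1")
  }
  # validates that phi >= 0 for every reference allele
  for (r in 1:4) genotype_prior(allele_prior(r, divergence), gamma)
  if (!is.null(mu)) {
    if (length(mu) != 94L || any(mu <= 0) || any(mu > 1)) {
      stop("mu must map qualities 0..93 to error probabilities in (0, 1]")
    }
  }
  structure(list(divergence = divergence, gamma = gamma,
                 nu_f = nu_f, nu_m = nu_m, nu_t = nu_t,
                 omega = omega, mu = mu),
            class = "quartet_params")
}

#' @export
print.quartet_params <- function(x, ...) {
  cat("Quartet model parameters:\n")
  cat(sprintf("  divergence v      : %g\n", x$divergence))
  cat(sprintf("  heterozygosity g  : %g\n", x$gamma))
  cat(sprintf("  germline nu (F/M) : %g / %g\n", x$nu_f, x$nu_m))
  cat(sprintf("  tumor nu          : %g\n", x$nu_t))
  cat(sprintf("  tumor purity omega: %g\n", x$omega))
  cat(sprintf("  quality map       : %s\n",
              if (is.null(x$mu)) "canonical Phred" else "calibrated"))
  invisible(x)
}

# error map actually in force
params_mu <- function(params) {
  if (is.null(params$mu)) 10^(-(0:93) / 10) else params$mu
}

#' EM fitting control settings
#'
#' @param tol Relative log-likelihood change below which the inner EM
#'   loop stops.
#' @param max_iter Maximum inner EM iterations per outer round.
#' @param fit_omega Re-estimate tumor purity (rebuilds tumor stores in an
#'   outer loop)?
#' @param fit_mu Re-calibrate the quality map (off by default; requires
#'   retained raw calls)?
#' @param tie_germline Share a single germline rate between the parental
#'   lineages?
#' @param omega_tol Absolute tolerance of the golden-section purity search.
#' @param max_outer Maximum outer (omega/mu) rounds.
#' @param verbose Print per-iteration progress?
#' @return Object of class `"quartet_control"`.
#' @export
quartet_control <- function(tol = 1e-6, max_iter = 100L,
                            fit_omega = TRUE, fit_mu = FALSE,
                            tie_germline = TRUE,
                            omega_tol = 1e-3, max_outer = 5L,
                            verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1L, omega_tol > 0, max_outer >= 1L)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 fit_omega = isTRUE(fit_omega), fit_mu = isTRUE(fit_mu),
                 tie_germline = isTRUE(tie_germline),
                 omega_tol = omega_tol, max_outer = as.integer(max_outer),
                 verbose = isTRUE(verbose)),
            class = "quartet_control")
}
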