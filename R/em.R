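# Expectation-Maximization over all loci for divergence, heterozygosity,
# germline and tumor mutation rates, tumor purity, and the quality map.

RATE_FLOOR <- 1e-10  # keeps rates off the absorbing state at exactly 0

#' Jukes-Cantor rate update from genotype-pair posteriors
#'
#' The M-step for a substitution rate: nu-hat equals the posterior-expected
#' number of allele substitutions between source and target genotypes,
#' summed over loci and divided by 2N (two alleles per locus). The
#' substitution count alpha(g, g') is the expected number of allele
#' changes conditional on the unordered pair under the current kernel
#' (its rate -> 0 limit is the minimum-pairing count: alpha(AA,AC) = 1,
#' alpha(AA,CC) = 2, alpha(AC,AC) = 0).
#'
#' @param pair_posterior Either a single 10 x 10 matrix of summed
#'   (source, target) genotype-pair posteriors across loci, or a list of
#'   per-locus 10 x 10 matrices.
#' @param n_loci Number of loci N (defaults to the list length).
#' @param rate Current rate used to evaluate the expected substitution
#'   counts (0 gives the minimum-pairing counts).
#' @return The updated rate in [0, 1].
#' @export
update_mutation_rate <- function(pair_posterior, n_loci = NULL, rate = 0) {
  if (is.list(pair_posterior) && !is.matrix(pair_posterior)) {
    if (length(pair_posterior) == 0L) stop("empty pair posterior input")
    if (is.null(n_loci)) n_loci <- length(pair_posterior)
    pair_posterior <- Reduce(`+`, pair_posterior)
  }
  if (is.null(n_loci)) stop("n_loci required when passing a summed posterior matrix")
  if (n_loci < 1L) stop("empty pair posterior input")
  stopifnot(is.matrix(pair_posterior), all(dim(pair_posterior) == c(10L, 10L)))
  alpha <- expected_substitutions(rate)
  nu <- sum(alpha * pair_posterior) / (2 * n_loci)
  min(max(nu, 0), 1)
}

# E-step tables of the zygosity/divergence decomposition machine.
# The machine takes a Hardy-Weinberg genotype h (at divergence v) and
# flips a heterozygote to either homozygote with probability gamma/2
# each. Given the observed (posterior) genotype g it returns, per
# reference allele r and genotype g:
#   e_nonref[r, g] = E[# non-reference alleles in h | g]
#   e_flip[r, g]   = P(the machine flipped | g)
#   e_het[r, g]    = P(h heterozygous | g)
prior_machine_tables <- function(divergence, gamma) {
  gamma <- max(gamma, 0)
  e_nonref <- e_flip <- e_het <- matrix(0, 4L, 10L)
  for (r in 1:4) {
    pi <- allele_prior(r, divergence)
    for (g in 1:10) {
      a <- GT_PAIRS[g, 1]; b <- GT_PAIRS[g, 2]
      if (a != b) {            # heterozygote observed: h = g, no flip
        e_nonref[r, g] <- (a != r) + (b != r)
        e_het[r, g] <- 1
      } else {                 # homozygote xx: h = xx, or a flipped het xy
        w_h <- numeric(0); nr_h <- numeric(0); het_h <- numeric(0)
        w_h <- pi[a]^2; nr_h <- 2 * (a != r); het_h <- 0
        for (y in setdiff(1:4, a)) {
          w <- gamma * pi[a] * pi[y]       # 2 pi_a pi_y * gamma/2
          w_h <- c(w_h, w)
          nr_h <- c(nr_h, (a != r) + (y != r))
          het_h <- c(het_h, 1)
        }
        z <- sum(w_h)
        if (z > 0) {
          e_nonref[r, g] <- sum(w_h * nr_h) / z
          e_flip[r, g] <- sum(w_h * het_h) / z
          e_het[r, g] <- sum(w_h * het_h) / z
        } else {
          e_nonref[r, g] <- 2 * (a != r)
        }
      }
    }
  }
  list(nonref = e_nonref, flip = e_flip, het = e_het)
}

#' Divergence and heterozygosity update from parental posteriors
#'
#' M-step of the zygosity/divergence decomposition: the Hardy-Weinberg
#' input genotype of the heterozygote-flipping machine is treated as a
#' hidden variable. The expected count of non-reference alleles in the
#' hidden genotype yields the divergence update; the expected fraction of
#' heterozygous inputs that were flipped to homozygotes yields the
#' heterozygosity update. Estimation constrains gamma to [0, 1) (the
#' machine realizes the prior only for non-negative gamma).
#'
#' @param parent_posterior Per-locus parental genotype posteriors: an
#'   n x 10 matrix (rows = loci) for one parent, or a list of such
#'   matrices for both parents.
#' @param ref Integer or character reference alleles, length n.
#' @param divergence,gamma Current parameter values (define the E-step).
#' @return Named numeric vector `c(divergence = , gamma = )`.
#' @export
update_prior_params <- function(parent_posterior, ref, divergence, gamma) {
  if (!is.list(parent_posterior) || is.matrix(parent_posterior)) {
    parent_posterior <- list(parent_posterior)
  }
  ref <- allele_index(ref)
  tabs <- prior_machine_tables(divergence, gamma)
  tot_nonref <- 0; tot_flip <- 0; tot_het <- 0; n_obs <- 0
  for (p in parent_posterior) {
    stopifnot(is.matrix(p), ncol(p) == 10L, nrow(p) == length(ref))
    # collapse loci by reference allele: 4 x 10 expected posterior mass
    Pr <- t(vapply(1:4, function(r) colSums(p[ref == r, , drop = FALSE]), numeric(10)))
    tot_nonref <- tot_nonref + sum(Pr * tabs$nonref)
    tot_flip <- tot_flip + sum(Pr * tabs$flip)
    tot_het <- tot_het + sum(Pr * tabs$het)
    n_obs <- n_obs + nrow(p)
  }
  v_hat <- tot_nonref / (2 * n_obs)
  g_hat <- if (tot_het > 0) tot_flip / tot_het else 0
  c(divergence = min(max(v_hat, 0), 1 - 1e-9),
    gamma = min(max(g_hat, 0), 1 - 1e-9))
}

# same update from the engine's ref-collapsed 4 x 10 aggregates
update_prior_from_agg <- function(PrF, PrM, n_obs, divergence, gamma) {
  tabs <- prior_machine_tables(divergence, gamma)
  Pr <- PrF + PrM
  v_hat <- sum(Pr * tabs$nonref) / (2 * n_obs)
  th <- sum(Pr * tabs$het)
  g_hat <- if (th > 0) sum(Pr * tabs$flip) / th else 0
  c(divergence = min(max(v_hat, RATE_FLOOR), 1 - 1e-9),
    gamma = min(max(g_hat, 0), 1 - 1e-9))
}

total_loglik <- function(loci, stores, params) {
  tabs <- param_tables(params)
  sum(engine_run(stores, loci$ref, tabs, want = "loglik")$loglik)
}

#' Estimate tumor purity by profile-likelihood search
#'
#' Maximizes the total log-likelihood over omega in [0, 1] by
#' golden-section search, rebuilding the tumor partial-likelihood stores
#' at each candidate purity (the non-tumor stores are reused). When the
#' normal and tumor genotypes agree everywhere the likelihood is flat in
#' omega and the initial value is returned.
#'
#' @param loci A [quartet_loci()] object (the tumor sample's raw calls
#'   must be present).
#' @param params Current [quartet_params()].
#' @param tol Absolute search tolerance on omega.
#' @return The maximizing omega (with the attained total log-likelihood
#'   in `attr(, "loglik")`); the input omega with a warning when no tumor
#'   sample is present.
#' @export
estimate_purity <- function(loci, params, tol = 1e-3) {
  stopifnot(inherits(loci, "quartet_loci"))
  if (is.null(loci$calls$tumor)) {
    warning("no tumor sample present; purity left at ", params$omega)
    return(params$omega)
  }
  mu <- params$mu
  fixed <- build_all_stores(loci, params$omega, mu)
  obj <- function(w) {
    st <- fixed
    st$tumor <- build_store_batch(loci$calls$tumor, loci$n, omega = w, mu = params_mu(params))
    p <- params; p$omega <- w
    total_loglik(loci, st, p)
  }
  gr <- (sqrt(5) - 1) / 2
  a <- 0; b <- 1
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- obj(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- obj(x1)
    }
  }
  w_hat <- if (f1 > f2) x1 else x2
  ll_hat <- max(f1, f2)
  # keep the incumbent when the search cannot improve on it (flat profile)
  ll_cur <- obj(params$omega)
  if (ll_cur >= ll_hat) {
    w_hat <- params$omega
    ll_hat <- ll_cur
  }
  attr(w_hat, "loglik") <- ll_hat
  w_hat
}

#' Re-calibrate the quality-to-error map
#'
#' For each reported Phred score q, the calibrated error mu-hat(q) is the
#' posterior probability, averaged over all calls reported at q, that the
#' call differs from the allele the read actually sampled. The sampled
#' allele is integrated over the per-sample posterior allele mixture
#' (tumor: the purity mixture of the normal and tumor posteriors).
#' Bins with fewer than 100 calls keep the canonical value; estimates are
#' floored at 1e-6.
#'
#' @param loci A [quartet_loci()] object with retained raw calls.
#' @param params Current [quartet_params()].
#' @param min_calls Minimum bin occupancy for re-estimation.
#' @return Numeric vector of 94 calibrated error probabilities.
#' @export
calibrate_quality_map <- function(loci, params, min_calls = 100L) {
  stopifnot(inherits(loci, "quartet_loci"))
  tabs <- param_tables(params)
  stores <- build_all_stores(loci, params$omega, params$mu)
  e <- engine_run(stores, loci$ref, tabs, want = "post")
  mixN <- e$pN %*% MIXTURES
  mix <- list(father = e$pF %*% MIXTURES, mother = e$pM %*% MIXTURES,
              normal = mixN,
              tumor = (1 - params$omega) * mixN + params$omega * (e$pT %*% MIXTURES))
  mu0 <- params_mu(params)
  num <- den <- numeric(94L)
  for (s in SAMPLES) {
    cs <- loci$calls[[s]]
    if (is.null(cs)) next
    pz <- mix[[s]][cbind(cs$locus, cs$allele)]      # posterior mass of the called allele
    eps <- mu0[cs$qual + 1L]
    pm <- ((1 - pz) * eps / 3) / (pz * (1 - eps) + (1 - pz) * eps / 3)
    rs <- rowsum(pm, cs$qual)
    num[as.integer(rownames(rs)) + 1L] <- num[as.integer(rownames(rs)) + 1L] + rs
    den <- den + tabulate(cs$qual + 1L, nbins = 94L)
  }
  mu <- 10^(-(0:93) / 10)
  ok <- den >= min_calls
  mu[ok] <- pmin(pmax(num[ok] / den[ok], 1e-6), 1)
  mu
}

#' Fit all model parameters by EM
#'
#' Iterates the E-step (posterior aggregation across all loci, reusing
#' the cached partial-likelihood stores) and M-step (divergence and
#' heterozygosity via the decomposition machine, germline and tumor
#' rates via the substitution-count update). Purity and quality-map
#' updates run in an outer loop because they invalidate the stores.
#' The total log-likelihood trace is checked to be non-decreasing
#' (absolute slack 1e-8); a larger decrease raises an error with an
#' iteration dump.
#'
#' @param loci A [quartet_loci()] object.
#' @param init Initial [quartet_params()].
#' @param control A [quartet_control()] object.
#' @return List with `params` (fitted), `trace` (data.frame of
#'   per-iteration log-likelihood and parameter snapshots), `loglik`,
#'   `iterations`, `converged`.
#' @export
run_em <- function(loci, init = quartet_params(), control = quartet_control()) {
  stopifnot(inherits(loci, "quartet_loci"), loci$n >= 1L)
  params <- init
  n <- loci$n
  trace <- list()
  it_total <- 0L
  ll_prev_global <- -Inf
  converged <- FALSE

  record <- function(ll, stage) {
    trace[[length(trace) + 1L]] <<- data.frame(
      iter = it_total, stage = stage, loglik = ll,
      divergence = params$divergence, gamma = params$gamma,
      nu_f = params$nu_f, nu_m = params$nu_m, nu_t = params$nu_t,
      omega = params$omega)
    if (ll < ll_prev_global - 1e-8) {
      stop("EM log-likelihood decreased at iteration ", it_total,
           " (", stage, "): ", ll_prev_global, " -> ", ll,
           "\nparameters: ", paste(deparse(unclass(params)[1:6]), collapse = " "))
    }
    ll_prev_global <<- ll
  }

  for (outer in seq_len(control$max_outer)) {
    stores <- build_all_stores(loci, params$omega, params$mu)
    ll_prev <- -Inf
    for (it in seq_len(control$max_iter)) {
      it_total <- it_total + 1L
      tabs <- param_tables(params)
      e <- engine_run(stores, loci$ref, tabs, want = "em")
      ll <- sum(e$loglik)
      record(ll, "em")
      if (control$verbose) {
        message(sprintf("iter %3d  logL %.4f  v %.3g g %.3g nuF %.3g nuT %.3g w %.3g",
                        it_total, ll, params$divergence, params$gamma,
                        params$nu_f, params$nu_t, params$omega))
      }
      # M-step
      pr <- update_prior_from_agg(e$PrF, e$PrM, 2 * n, params$divergence, params$gamma)
      params$divergence <- pr[["divergence"]]
      params$gamma <- pr[["gamma"]]
      if (control$tie_germline) {
        nu_g <- update_mutation_rate((e$S_F + e$S_M) / 2, n, rate = params$nu_f)
        params$nu_f <- params$nu_m <- max(nu_g, RATE_FLOOR)
      } else {
        params$nu_f <- max(update_mutation_rate(e$S_F, n, rate = params$nu_f), RATE_FLOOR)
        params$nu_m <- max(update_mutation_rate(e$S_M, n, rate = params$nu_m), RATE_FLOOR)
      }
      params$nu_t <- max(update_mutation_rate(e$S_NT, n, rate = params$nu_t), RATE_FLOOR)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < control$tol * (abs(ll) + 1)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    improved_outer <- FALSE
    if (control$fit_omega && !is.null(loci$calls$tumor)) {
      w_hat <- estimate_purity(loci, params, tol = control$omega_tol)
      if (abs(w_hat - params$omega) > control$omega_tol / 2) improved_outer <- TRUE
      params$omega <- as.numeric(w_hat)
      it_total <- it_total + 1L
      record(attr(w_hat, "loglik"), "omega")
    }
    if (control$fit_mu) {
      mu_new <- calibrate_quality_map(loci, params)
      p_try <- params; p_try$mu <- mu_new
      st_try <- build_all_stores(loci, p_try$omega, mu_new)
      ll_try <- total_loglik(loci, st_try, p_try)
      if (ll_try >= ll_prev_global) {   # accept only non-decreasing updates
        params <- p_try
        improved_outer <- TRUE
        it_total <- it_total + 1L
        record(ll_try, "mu")
      }
    }
    if (!improved_outer || (!control$fit_omega && !control$fit_mu)) break
  }

  trace <- do.call(rbind, trace)
  list(params = params, trace = trace, loglik = ll_prev_global,
       iterations = it_total, converged = converged)
}
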