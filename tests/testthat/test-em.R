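# EM parameter updates and the full fitting loop.

test_that("mutation-rate update counts expected allele substitutions over 2N", {
  same <- diag(10) * 0.1  # all mass on identical pairs across 10 loci
  expect_equal(update_mutation_rate(same, n_loci = 1), 0)
  one <- matrix(0, 10, 10); one[1, 2] <- 1  # AA -> AC
  expect_equal(update_mutation_rate(one, n_loci = 1), 0.5)
  two <- matrix(0, 10, 10); two[1, 5] <- 1  # AA -> CC
  expect_equal(update_mutation_rate(two, n_loci = 1), 1)
  expect_equal(update_mutation_rate(list(one, two)), 0.75)  # (1 + 2) / (2 * 2)
  expect_error(update_mutation_rate(list()), "empty")
  set.seed(301)
  for (rep in 1:10) {
    p <- matrix(rgamma(100, 1), 10); p <- p / sum(p) * 7
    nu <- update_mutation_rate(p, n_loci = 7, rate = runif(1, 0, 0.1))
    expect_gte(nu, 0); expect_lte(nu, 1)
  }
})

test_that("prior updates recover divergence and heterozygosity from the flip machine", {
  # all posterior mass on ref/ref homozygotes: zero divergence
  n <- 50L
  ref <- rep(1L, n)
  p_refhom <- matrix(0, n, 10); p_refhom[, 1] <- 1  # AA with ref A
  v <- 0.01; gm <- 0.1
  for (i in 1:60) {
    up <- update_prior_params(p_refhom, ref, divergence = v, gamma = gm)
    v <- up[["divergence"]]; gm <- up[["gamma"]]
  }
  expect_lt(v, 1e-8)  # iterated updates drive divergence to zero
  # forward-simulate the machine and re-estimate from exact posteriors
  ns <- asNamespace("quartetcall")
  pairs <- get("GT_PAIRS", ns); gtidx <- get("GT_INDEX", ns)
  simulate_machine <- function(n, v, gamma) {
    ref <- sample.int(4L, n, replace = TRUE)
    g <- integer(n)
    for (r in 1:4) {
      idx <- which(ref == r)
      h <- sample.int(10L, length(idx), replace = TRUE,
                      prob = genotype_prior(allele_prior(r, v), 0))
      flip <- !get("GT_IS_HOM", ns)[h] & runif(length(idx)) < gamma
      pick <- sample.int(2L, length(idx), replace = TRUE)
      hom <- pairs[cbind(h, pick)]
      g <- replace(g, idx, ifelse(flip, gtidx[cbind(hom, hom)], h))
    }
    list(ref = ref, g = g)
  }
  est_from <- function(sim, v0, g0, iters = 25) {
    post <- matrix(0, length(sim$g), 10)
    post[cbind(seq_along(sim$g), sim$g)] <- 1
    v <- v0; gm <- g0
    for (i in seq_len(iters)) {
      up <- update_prior_params(post, sim$ref, v, gm)
      v <- up[["divergence"]]; gm <- up[["gamma"]]
    }
    c(v, gm)
  }
  set.seed(302)
  # gamma = 0 truth: estimate collapses to ~0
  s0 <- simulate_machine(1e5, 0.01, 0)
  e0 <- est_from(s0, 0.02, 0.3)
  expect_lt(e0[2], 3 * sqrt(0.01 / (1e5 * 2 * 0.01)))  # ~3 SE of the flip fraction
  # joint recovery at (v, gamma) = (0.01, 0.3)
  s1 <- simulate_machine(1e5, 0.01, 0.3)
  e1 <- est_from(s1, 0.02, 0.1)
  se_v <- sqrt(0.01 * 0.99 / (2e5)); se_g <- sqrt(0.3 * 0.7 / (1e5 * 2 * 0.01))
  expect_lt(abs(e1[1] - 0.01), 3 * se_v)
  expect_lt(abs(e1[2] - 0.3), 3 * se_g)
})

test_that("purity is recovered by profile likelihood and left alone when flat", {
  set.seed(303)
  truth <- quartet_params(omega = 0.6)
  sim <- simulate_quartet(10000, params = truth, depth = 30, seed = 304)
  w <- estimate_purity(sim$loci, truth)
  expect_gte(as.numeric(w), 0.55)
  expect_lte(as.numeric(w), 0.65)
  # pure-tumor simulation: estimate near 1
  sim1 <- simulate_quartet(6000, params = quartet_params(omega = 1), depth = 30,
                           seed = 305)
  w1 <- estimate_purity(sim1$loci, quartet_params(omega = 1))
  expect_gt(as.numeric(w1), 0.9)
  # no somatic divergence anywhere: likelihood flat, initial value returned
  flat_sim <- simulate_quartet(500, params = quartet_params(nu_t = 0, omega = 0.4),
                               depth = 10, seed = 306)
  expect_equal(as.numeric(estimate_purity(flat_sim$loci, quartet_params(nu_t = 0, omega = 0.4))),
               0.4, tolerance = 1e-9)
  # missing tumor sample: warning, unchanged
  no_t <- flat_sim$loci
  no_t$calls$tumor <- NULL
  expect_warning(w_nt <- estimate_purity(no_t, quartet_params(omega = 0.25)), "tumor")
  expect_equal(as.numeric(w_nt), 0.25)
})

test_that("quality-map calibration tracks the true error scale", {
  set.seed(307)
  # inflated truth: reads reported at q = 20 actually err at 3x the canonical rate
  mu_true <- 10^(-(0:93) / 10)
  mu_true[21] <- 0.03
  truth <- quartet_params(mu = mu_true)
  sim <- simulate_quartet(2500, params = truth, depth = 30,
                          quality_profile = c("20" = 0.5, "30" = 0.5), seed = 308)
  start <- quartet_params()  # canonical map
  mu_hat <- calibrate_quality_map(sim$loci, start)
  expect_lt(abs(mu_hat[21] - 0.03), 0.005)
  # canonical bin stays near canonical
  expect_lt(abs(mu_hat[31] - 1e-3), 5e-4)
  # empty bins keep the canonical value exactly
  expect_identical(mu_hat[61], 10^(-60 / 10))
})

test_that("EM increases the likelihood and the fit object behaves like a model", {
  sim <- simulate_quartet(1500, depth = 12, seed = 309)
  fit <- quartet_fit(sim$loci, init = quartet_params(divergence = 0.005, gamma = 0.3,
                                                     nu_f = 5e-4, nu_t = 5e-3, omega = 0.4),
                     control = quartet_control(max_iter = 15, max_outer = 2))
  tr <- fit$trace
  expect_true(all(diff(tr$loglik) >= -1e-8))
  expect_named(coef(fit), c("divergence", "gamma", "nu_f", "nu_m", "nu_t", "omega"))
  expect_s3_class(fit, "quartet_fit")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_identical(attr(ll, "nobs"), 1500L)
  expect_output(print(fit), "Quartet genotyping model fit")
  expect_output(print(summary(fit)), "EM trace")
  calls <- predict(fit)
  expect_s3_class(calls, "quartet_calls")
  expect_identical(nrow(calls), 1500L)
  post <- predict(fit, type = "posterior")
  expect_true(all(c("p_somatic", "p_denovo") %in% names(post)))
  # simulate() round-trips the fitted parameters deterministically
  s1 <- simulate(fit, seed = 99, n_loci = 50)
  s2 <- simulate(fit, seed = 99, n_loci = 50)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$params$omega, fit$params$omega)
})

test_that("germline rates can be estimated separately when untied", {
  sim <- simulate_quartet(1200, depth = 10, seed = 310)
  fit <- quartet_fit(sim$loci,
                     control = quartet_control(max_iter = 5, fit_omega = FALSE,
                                               tie_germline = FALSE))
  expect_true(is.finite(fit$params$nu_f) && is.finite(fit$params$nu_m))
  fit_tied <- quartet_fit(sim$loci,
                          control = quartet_control(max_iter = 5, fit_omega = FALSE))
  expect_identical(fit_tied$params$nu_f, fit_tied$params$nu_m)
})
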