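# The O(G^3) quartet likelihood decomposition, posteriors, mutation
# probabilities and greedy genotype calls.

test_that("decomposed joint likelihood equals the naive six-variable summation", {
  set.seed(201)
  for (rep in 1:12) {
    locus <- rand_locus()
    params <- rand_params()
    ll_fast <- joint_likelihood(locus, params, log = TRUE)
    ll_naive <- oracle_joint_loglik(locus, params)
    expect_equal(ll_fast, ll_naive, tolerance = 1e-9)
  }
})

test_that("empty samples give unit likelihood; absent and empty samples agree", {
  params <- quartet_params()
  expect_equal(joint_likelihood(list(ref = "A"), params), 1, tolerance = 1e-12)
  # removing a sample's store is identical to a unit likelihood factor
  set.seed(202)
  partial <- list(ref = "G",
                  father = rand_calls(10),
                  normal = rand_calls(12))
  with_empty <- partial
  with_empty$mother <- data.frame(allele = character(0), quality = integer(0))
  with_empty$tumor <- data.frame(allele = character(0), quality = integer(0))
  expect_equal(joint_likelihood(partial, params, log = TRUE),
               joint_likelihood(with_empty, params, log = TRUE))
})

test_that("with child samples absent the likelihood factorizes over the parents", {
  set.seed(203)
  params <- rand_params()
  locus <- list(ref = "C", father = rand_calls(9), mother = rand_calls(11))
  phi <- genotype_prior(allele_prior(locus$ref, params$divergence), params$gamma)
  lf <- sum(phi * sapply(1:10, function(g) exp(oracle_dip_loglik(locus$father, g))))
  lm <- sum(phi * sapply(1:10, function(g) exp(oracle_dip_loglik(locus$mother, g))))
  expect_equal(joint_likelihood(locus, params, log = TRUE), log(lf) + log(lm),
               tolerance = 1e-10)
})

test_that("overwhelming unanimous coverage pins every marginal on the truth", {
  deep <- function(a) data.frame(allele = rep(a, 100), quality = 30L)
  post <- genotype_posteriors(list(ref = "A", father = deep("A"), mother = deep("A"),
                                   normal = deep("A"), tumor = deep("A")),
                              quartet_params())
  for (s in rownames(post$marginal)) expect_gt(post$marginal[s, "AA"], 0.999)
  expect_equal(unname(rowSums(post$marginal)), rep(1, 4), tolerance = 1e-9)
  expect_identical(unname(post$joint_map), rep("AA", 4))
})

test_that("joint (normal, tumor) posterior matches the naive restricted summation", {
  set.seed(204)
  for (rep in 1:5) {
    locus <- rand_locus(depths = c(6, 6, 6, 6))
    params <- rand_params()
    post <- genotype_posteriors(locus, params)
    expect_equal(unname(post$pair_joint), oracle_pair_posterior(locus, params),
                 tolerance = 1e-9)
    expect_equal(sum(post$pair_joint), 1, tolerance = 1e-9)
    # marginals consistent with the joint table
    expect_equal(unname(rowSums(post$pair_joint)), unname(post$marginal["normal", ]),
                 tolerance = 1e-9)
    expect_equal(unname(colSums(post$pair_joint)), unname(post$marginal["tumor", ]),
                 tolerance = 1e-9)
  }
})

test_that("somatic posterior complements the genotype-agreement mass", {
  set.seed(205)
  locus <- rand_locus()
  post <- genotype_posteriors(locus, rand_params())
  mp <- mutation_posteriors(post)
  expect_equal(unname(mp["p_somatic"]) + sum(diag(post$pair_joint)), 1,
               tolerance = 1e-12)
  expect_equal(unname(mp["p_somatic"]), post$p_somatic, tolerance = 1e-9)
  # identical deep normal and tumor call sets: essentially no somatic mass
  deep <- data.frame(allele = rep(c("A", "C"), 60), quality = 30L)
  same <- genotype_posteriors(list(ref = "A", normal = deep, tumor = deep),
                              quartet_params())
  expect_lt(same$p_somatic, 1e-3)
})

test_that("a forced zero tumor rate eliminates somatic posterior mass", {
  set.seed(206)
  params <- quartet_params(nu_t = 0)
  for (rep in 1:5) {
    post <- genotype_posteriors(rand_locus(), params)
    expect_equal(post$p_somatic, 0, tolerance = 1e-12)
  }
})

test_that("clear trio inconsistency yields a confident de novo posterior", {
  deep <- function(a) data.frame(allele = rep(a, 100), quality = 30L)
  het <- data.frame(allele = rep(c("A", "C"), 50), quality = 30L)
  post <- genotype_posteriors(list(ref = "A", father = deep("A"), mother = deep("A"),
                                   normal = het, tumor = het),
                              quartet_params())
  expect_gt(post$p_denovo, 0.99)
  expect_identical(unname(post$joint_map[c("father", "mother", "normal")]),
                   c("AA", "AA", "AC"))
  # a Mendelian-consistent deep trio has essentially no de novo mass
  consistent <- genotype_posteriors(list(ref = "A", father = het, mother = deep("A"),
                                         normal = het, tumor = het),
                                    quartet_params())
  expect_lt(consistent$p_denovo, 1e-3)
})

test_that("greedy calling backs off from full call to half call to no-call", {
  mk_post <- function(marg) {
    m <- matrix(rep(marg, 4), 4, 10, byrow = TRUE,
                dimnames = list(c("father", "mother", "normal", "tumor"), genotypes()))
    structure(list(marginal = m), class = "quartet_posterior")
  }
  conf <- rep(0, 10); conf[1] <- 0.9999; conf[2] <- 1e-4
  calls <- call_genotypes(mk_post(conf), min_gq = 30, ref = "A")
  expect_identical(unique(calls$call), "A/A")
  expect_identical(unique(calls$gq), 40L)
  # MAP too weak but one allele is near-certain: half call
  amb <- rep(0, 10); amb[1] <- 0.5; amb[2] <- 0.45; amb[5] <- 0.05
  half <- call_genotypes(mk_post(amb), min_gq = 13, ref = "A")
  expect_identical(unique(half$call), "A/.")
  expect_true(all(half$gq >= 13))
  # flat posterior: withhold everything
  flat <- call_genotypes(mk_post(rep(0.1, 10)), min_gq = 30, ref = "A")
  expect_identical(unique(flat$call), "./.")
})

test_that("call ties break toward the reference allele then canonical order", {
  ns <- asNamespace("quartetcall")
  tie <- get("map_with_tiebreak", ns)
  p <- matrix(0.25, 1, 10)
  # all equal: reference-containing genotype first, canonical among those
  expect_identical(tie(p, 3L, get("CONTAINS_GT", ns)), 3L)  # ref G -> AG
  expect_identical(tie(p, 1L, get("CONTAINS_GT", ns)), 1L)  # ref A -> AA
})
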