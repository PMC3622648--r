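# Partial-likelihood stores: the T_beta factorization against direct
# per-read evaluation, and the recurrent-call-set encoding.

test_that("per-read factor matches its closed forms", {
  eps <- c(0.001, 0.01, 0.3, 1)
  expect_equal(f_factor(0, eps), eps / 3)
  expect_equal(f_factor(1, eps), 1 - eps)
  expect_equal(f_factor(0.5, eps), 0.5 - eps / 3)
  for (w in c(0.2, 0.63)) {
    expect_equal(f_factor(w / 2, eps), w / 2 - eps * (2 * w / 3 - 1 / 3))
  }
})

test_that("store of an empty call set is the unit store", {
  st <- build_store(NULL, omega = 0.5)
  expect_equal(st$log_scale, 0)
  expect_equal(unname(exp(st$logC)), rep(1, 4))
  expect_equal(unname(exp(st$logH)), rep(1, 4))
  expect_equal(st$m, 0L)
  for (g in genotypes()) expect_equal(diploid_likelihood(st, g), 1)
})

test_that("single-call store reproduces hand-computed subproducts", {
  # one A call with eps = 0.03 (quality ~ 15.23 is not integral, so build
  # the same store through a custom quality map at q = 15)
  mu <- 10^(-(0:93) / 10); mu[16] <- 0.03
  st <- build_store(data.frame(allele = "A", quality = 15L), omega = 0.5, mu = mu)
  expect_equal(exp(st$log_scale), 0.01)
  expect_equal(unname(exp(st$logC["A"])), 97)   # (1 - 0.03) / 0.01
  expect_equal(unname(exp(st$logH["A"])), 49)   # (0.5 - 0.01) / 0.01
})

test_that("ten unanimous calls give the closed-form homozygote likelihood ratio", {
  calls <- data.frame(allele = rep("A", 10), quality = 20L)
  st <- build_store(calls, omega = 1)
  eps <- 0.01
  ratio <- diploid_likelihood(st, "AA", log = TRUE) -
    diploid_likelihood(st, "CC", log = TRUE)
  expect_equal(ratio, 10 * log((1 - eps) / (eps / 3)), tolerance = 1e-12)
})

test_that("store-based likelihoods equal direct per-read evaluation", {
  set.seed(101)
  n_checked <- 0L
  for (rep in 1:15) {
    calls <- rand_calls(sample(0:25, 1))
    omega <- runif(1)
    st <- build_store(calls, omega = omega)
    for (g in GT10) {
      expect_equal(diploid_likelihood(st, g, log = TRUE),
                   oracle_dip_loglik(calls, g), tolerance = 1e-11)
    }
    # all 100 (gN, gT) pairs, covering each of the seven somatic patterns
    for (gN in GT10) for (gT in GT10) {
      expect_equal(tumor_pair_likelihood(st, gN, gT, omega, log = TRUE),
                   oracle_pair_loglik(calls, gN, gT, omega), tolerance = 1e-11)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 1000L)
})

test_that("identical normal-tumor genotypes make the purity immaterial", {
  set.seed(31)
  calls <- rand_calls(20)
  for (g in c("AA", "AC", "GT")) {
    vals <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(w) {
      st <- build_store(calls, omega = w)
      tumor_pair_likelihood(st, g, g, w, log = TRUE)
    })
    expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
    st <- build_store(calls, omega = 0.42)
    expect_equal(tumor_pair_likelihood(st, g, g, 0.42, log = TRUE),
                 diploid_likelihood(st, g, log = TRUE))
  }
})

test_that("purity endpoints reduce to the pure-sample likelihoods", {
  set.seed(32)
  calls <- rand_calls(15)
  st1 <- build_store(calls, omega = 1)
  st0 <- build_store(calls, omega = 0)
  for (gN in GT10) for (gT in GT10) {
    expect_equal(tumor_pair_likelihood(st1, gN, gT, 1, log = TRUE),
                 diploid_likelihood(st1, gT, log = TRUE), tolerance = 1e-10)
    expect_equal(tumor_pair_likelihood(st0, gN, gT, 0, log = TRUE),
                 diploid_likelihood(st0, gN, log = TRUE), tolerance = 1e-10)
  }
})

test_that("a purity mismatch between store and query is a usage error", {
  st <- build_store(rand_calls(5), omega = 0.3)
  expect_error(tumor_pair_likelihood(st, "AA", "AC", 0.7), "rebuild")
})

test_that("likelihoods are invariant to call order and monotone in support", {
  set.seed(33)
  calls <- rand_calls(18)
  perm <- calls[sample(nrow(calls)), ]
  w <- 0.55
  st1 <- build_store(calls, omega = w)
  st2 <- build_store(perm, omega = w)
  for (g in GT10) {
    expect_identical(diploid_likelihood(st1, g, log = TRUE),
                     diploid_likelihood(st2, g, log = TRUE))
  }
  expect_identical(tumor_pair_likelihood(st1, "AC", "GG", w, log = TRUE),
                   tumor_pair_likelihood(st2, "AC", "GG", w, log = TRUE))
  # adding one more A call never increases L(CC)/L(AA)
  for (q in c(2, 10, 30)) {
    more <- rbind(calls, data.frame(allele = "A", quality = q))
    stm <- build_store(more, omega = w)
    r0 <- diploid_likelihood(st1, "CC", log = TRUE) - diploid_likelihood(st1, "AA", log = TRUE)
    r1 <- diploid_likelihood(stm, "CC", log = TRUE) - diploid_likelihood(stm, "AA", log = TRUE)
    expect_lte(r1, r0 + 1e-12)
  }
})

test_that("call-set encoding canonicalizes and respects the byte budget", {
  a <- data.frame(allele = c("A", "C", "A", "A"), quality = c(20L, 30L, 20L, 25L))
  b <- a[c(3, 1, 4, 2), ]
  expect_identical(encode_call_set(a), encode_call_set(b))
  expect_identical(encode_call_set(NULL), "")
  expect_identical(encode_call_set(a[0, ]), "")
  # 200 calls with 50 distinct qualities: beyond both budgets
  set.seed(9)
  big <- data.frame(allele = sample(ALL4, 200, replace = TRUE),
                    quality = sample(20:69, 200, replace = TRUE))
  expect_identical(encode_call_set(big), NA_character_)
  # wide quality spread at modest coverage exceeds the 32-byte budget only
  wide <- data.frame(allele = sample(ALL4, 40, replace = TRUE),
                     quality = sample(10:80, 40, replace = TRUE))
  expect_identical(encode_call_set(wide), NA_character_)
})

test_that("likelihoods through the recurrent-call cache equal direct computation", {
  ns <- asNamespace("quartetcall")
  cached <- get("build_store_cached", ns)
  cache <- new.env()
  set.seed(12)
  for (rep in 1:20) {
    calls <- rand_calls(sample(0:8, 1), quals = c(20, 30))
    st_direct <- build_store(calls, omega = 0.4)
    st_cached <- cached(calls, 0.4, cache)
    expect_equal(st_cached$log_scale, st_direct$log_scale)
    expect_equal(st_cached$logT, st_direct$logT)
  }
  expect_gt(length(ls(cache)), 0)
})
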