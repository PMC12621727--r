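test_that("LCP penalty matches its definition on boundary and random cases", {
  cfg <- lcp_config(window = 16, p_min = 8)
  expect_identical(lcp_penalty(1:16, cfg, 20), 0)

  tiny_pc <- lcp_config(window = 16, p_min = 8, pseudocount = 1e-9)
  expect_equal(lcp_penalty(rep(3L, 16), tiny_pc, 20), 49, tolerance = 1e-4)

  set.seed(2)
  for (r in 1:5) {
    s <- sample.int(6, 30, replace = TRUE)
    cfg2 <- lcp_config(window = 10, p_min = 4, pseudocount = 0.1)
    expect_equal(lcp_penalty(s, cfg2, 6), naive_lcp(s, cfg2, 6),
                 tolerance = 1e-10)
  }
  expect_error(lcp_penalty(1:4, cfg, 20), "window")
})

test_that("composite energy is the audited sum of its two components", {
  m <- make_random_potts(20, 4, edge_density = 0.2, seed = 7)
  set.seed(8)
  s <- sample.int(4, 20, replace = TRUE)
  off <- lcp_config(enabled = FALSE)
  expect_identical(composite_energy(m, s, off), potts_energy(m, s))
  zero_w <- lcp_config(window = 8, p_min = 3, lambda = 0)
  expect_equal(composite_energy(m, s, zero_w), potts_energy(m, s))
  on <- lcp_config(window = 8, p_min = 3, lambda = 1.7)
  expect_equal(composite_energy(m, s, on),
               potts_energy(m, s) + 1.7 * lcp_penalty(s, on, 4),
               tolerance = 1e-10)
  zero_m <- potts_model(matrix(0, 20, 4), alphabet = m$alphabet)
  expect_equal(composite_energy(zero_m, rep(2L, 20), on),
               1.7 * lcp_penalty(rep(2L, 20), on, 4), tolerance = 1e-10)
})

test_that("samplers are deterministic under a fixed seed", {
  m <- make_random_potts(5, 4, edge_density = 0.5, seed = 3)
  cfg <- sampler_config(seed = 99)
  expect_identical(dlmc_sample(m, 40, cfg)$samples,
                   dlmc_sample(m, 40, cfg)$samples)
  expect_identical(gibbs_sample(m, 40, cfg)$samples,
                   gibbs_sample(m, 40, cfg)$samples)
  # different seeds decorrelate
  expect_false(identical(dlmc_sample(m, 40, cfg)$samples,
                         dlmc_sample(m, 40, sampler_config(seed = 100))$samples))
})

test_that("both samplers hit the uniform distribution on a flat target", {
  z <- potts_model(matrix(0, 4, 3), alphabet = toy_alphabet(3))
  s <- dlmc_sample(z, 5e4, sampler_config(seed = 1))$samples
  expect_lt(total_variation(empirical_dist(s, 3), rep(1 / 81, 81)), 0.02)
  g <- gibbs_sample(z, 5e4, sampler_config(seed = 2))$samples
  expect_lt(total_variation(empirical_dist(g, 3), rep(1 / 81, 81)), 0.02)
})

test_that("long-run empirical distributions match enumeration (composite target)", {
  # plain Potts target
  m <- make_random_potts(4, 4, edge_density = 0.5, seed = 5)
  ex <- enumerate_distribution(m)$prob
  d <- dlmc_sample(m, 4e4, sampler_config(seed = 1, thinning = 3))$samples
  g <- gibbs_sample(m, 4e4, sampler_config(seed = 1))$samples
  expect_lt(total_variation(empirical_dist(d, 4), ex), 0.025)
  expect_lt(total_variation(empirical_dist(g, 4), ex), 0.025)
  # cross-sampler agreement on marginals
  expect_lt(total_variation(empirical_dist(d, 4), empirical_dist(g, 4)), 0.03)

  # with the LCP restraint the chains must target the composite law
  m2 <- make_random_potts(4, 3, 0.5, 0.5, 0.5, seed = 2,
                          alphabet = toy_alphabet(3))
  lc <- lcp_config(window = 3, p_min = 2.5, lambda = 1, pseudocount = 0.1)
  states <- ensdesign:::all_states(4, 3)
  comp <- apply(states, 1, composite_energy, model = m2, lcp = lc)
  target <- exp(-comp - ensdesign:::log_sum_exp(-comp))
  d2 <- dlmc_sample(m2, 3e4, sampler_config(seed = 3, thinning = 3), lc)$samples
  g2 <- gibbs_sample(m2, 3e4, sampler_config(seed = 3), lc)$samples
  expect_lt(total_variation(empirical_dist(d2, 3), target), 0.025)
  expect_lt(total_variation(empirical_dist(g2, 3), target), 0.025)
})

test_that("mean sampled energy is non-increasing as temperature drops", {
  m <- make_random_potts(6, 4, edge_density = 0.5, seed = 8)
  means <- sapply(c(2, 1, 0.5), function(temp) {
    mean(dlmc_sample(m, 4000,
                     sampler_config(temperature = temp, seed = 1))$trace$energy)
  })
  expect_true(means[1] > means[2] - 0.05)
  expect_true(means[2] > means[3] - 0.05)
})

test_that("LCP sampling suppresses homopolymer windows on a biased model", {
  a4 <- toy_alphabet(4)
  h <- matrix(0, 20, 4)
  h[, 1] <- -1.5
  m <- potts_model(h, alphabet = a4)
  homo_frac <- function(samples, w = 8) {
    mean(apply(samples, 1, function(s) {
      any(vapply(seq_len(length(s) - w + 1), function(i) {
        length(unique(s[i:(i + w - 1)])) == 1
      }, logical(1)))
    }))
  }
  lcp_on <- lcp_config(window = 8, p_min = 3, lambda = 2)
  off_rates <- on_rates <- numeric(5)
  for (sd in 1:5) {
    off_rates[sd] <- homo_frac(dlmc_sample(m, 300,
                                           sampler_config(seed = sd))$samples)
    on_rates[sd] <- homo_frac(dlmc_sample(m, 300, sampler_config(seed = sd),
                                          lcp_on)$samples)
  }
  expect_gt(mean(off_rates), 0)
  expect_lt(mean(on_rates), mean(off_rates))
})

test_that("sampling targets the product of experts, not the mixture", {
  a3 <- toy_alphabet(3)
  m1 <- make_random_potts(3, 3, 1, 1, 1, seed = 4, alphabet = a3)
  m2 <- make_random_potts(3, 3, 1, 1, 1, seed = 5, alphabet = a3)
  poe <- enumerate_distribution(average_models(list(m1, m2)))$prob
  mixture <- (enumerate_distribution(m1)$prob +
                enumerate_distribution(m2)$prob) / 2
  # the two laws differ substantially on this fixture...
  expect_gt(total_variation(poe, mixture), 0.1)
  # ...and the sampler follows the PoE, not the mixture
  s <- gibbs_sample(average_models(list(m1, m2)), 3e4,
                    sampler_config(seed = 6))$samples
  emp <- empirical_dist(s, 3)
  expect_lt(total_variation(emp, poe), 0.02)
  expect_gt(total_variation(emp, mixture), 0.05)
})

test_that("geometric mean combination equals softmax of mean logits", {
  l <- c(0.3, -1.2, 2.0)
  expect_equal(geometric_mean_combine(rbind(l)), exp(l) / sum(exp(l)),
               tolerance = 1e-12)
  expect_equal(geometric_mean_combine(rbind(l, l, l)),
               geometric_mean_combine(rbind(l)), tolerance = 1e-12)
  expect_equal(geometric_mean_combine(rbind(c(0, 1), c(1, 0))), c(0.5, 0.5),
               tolerance = 1e-12)
  # explicit geometric-mean-then-normalize oracle on fuzzed inputs
  set.seed(12)
  for (r in 1:20) {
    K <- sample(1:4, 1); A <- sample(2:6, 1)
    logits <- matrix(rnorm(K * A, 0, 3), K, A)
    w <- runif(K); w <- w / sum(w)
    p <- geometric_mean_combine(logits, w)
    dists <- exp(logits - apply(logits, 1, ensdesign:::log_sum_exp))
    gm <- apply(dists, 2, function(col) prod(col^w))
    expect_equal(p, gm / sum(gm), tolerance = 1e-12)
  }
  expect_error(geometric_mean_combine(matrix(numeric(0), 0, 3)), "empty")
  expect_error(geometric_mean_combine(rbind(c(Inf, 0))), "finite")
})

test_that("tied decoding draws from the combined conditionals", {
  a2 <- toy_alphabet(2)
  mA <- make_random_potts(2, 2, 1, 1, 1, seed = 6, alphabet = a2)
  mB <- make_random_potts(2, 2, 1, 1, 1, seed = 7, alphabet = a2)
  # first decoded site: no context, combined marginal is softmax of mean -h
  expected <- geometric_mean_combine(rbind(-mA$h[1, ], -mB$h[1, ]))
  draws <- vapply(1:4000, function(i) {
    tied_conditional_decode(list(mA, mB), c(1, 2),
                            sampler_config(seed = i))[1]
  }, 0L)
  expect_lt(abs(mean(draws == 1) - expected[1]), 0.03)
  # zero single model decodes i.i.d. uniform
  z <- potts_model(matrix(0, 6, 2), alphabet = a2)
  s <- vapply(1:2000, function(i) {
    tied_conditional_decode(list(z), cfg = sampler_config(seed = i))[3]
  }, 0L)
  expect_lt(abs(mean(s == 1) - 0.5), 0.05)
  # K identical models behave like K = 1 at the same seed
  expect_identical(
    tied_conditional_decode(list(mA, mA), c(2, 1), sampler_config(seed = 5)),
    tied_conditional_decode(list(mA), c(2, 1), sampler_config(seed = 5)))
  expect_error(tied_conditional_decode(list(mA), c(1, 1)), "permutation")
})

test_that("trace records energies, acceptance and chain geometry", {
  m <- make_random_potts(5, 3, 0.5, seed = 1, alphabet = toy_alphabet(3))
  out <- dlmc_sample(m, 25, sampler_config(seed = 2, burn_in = 10,
                                           thinning = 4))
  expect_length(out$trace$energy, 25)
  expect_gte(out$trace$acceptance_rate, 0)
  expect_lte(out$trace$acceptance_rate, 1)
  expect_equal(out$trace$energy[1],
               potts_energy(m, out$samples[1, ]), tolerance = 1e-9)
  expect_error(sampler_config(thinning = 0))
  expect_error(sampler_config(temperature = -1))
})
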