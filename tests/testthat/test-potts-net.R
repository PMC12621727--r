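net_fixture <- function(L = 8, hidden = 32, seed = 1, k = L - 1) {
  fcfg <- featurizer_config(k_neighbors = k)
  cfg <- network_config(hidden_dim = hidden, alphabet = toy_alphabet(4))
  params <- init_network(cfg, seed = seed, feat_cfg = fcfg)
  g <- featurize(make_toy_backbone(L, "perturbed", seed = 7), fcfg)
  list(params = params, g = g, fcfg = fcfg, cfg = cfg)
}

# give the zero-initialized readout nonzero weights so predictions vary
randomize_readout <- function(params, seed = 5) {
  withr::with_seed(seed, {
    params$readout$Wh <- matrix(rnorm(length(params$readout$Wh), 0, 0.1),
                                nrow(params$readout$Wh))
    params$readout$Wj <- matrix(rnorm(length(params$readout$Wj), 0, 0.1),
                                nrow(params$readout$Wj))
  })
  params
}

test_that("initialization is seed-deterministic and presets set the shapes", {
  cfg <- network_config()
  expect_identical(cfg$n_encoder_layers, 3L)
  expect_identical(cfg$n_decoder_layers, 3L)
  expect_identical(cfg$hidden_dim, 128L)
  expect_false(cfg$causal_mask)
  big <- network_config(preset = "L")
  expect_identical(big$n_encoder_layers, 5L)
  expect_identical(big$n_decoder_layers, 5L)
  expect_identical(big$hidden_dim, 256L)

  p1 <- init_network(cfg, seed = 11)
  p2 <- init_network(cfg, seed = 11)
  expect_identical(p1$weights, p2$weights)
  expect_length(p1$weights$layers, 6)
  expect_identical(dim(p1$weights$layers[[1]]$Wm), c(384L, 128L))
})

test_that("predicted models obey the coupling symmetry convention", {
  fx <- net_fixture()
  params <- randomize_readout(fx$params)
  m <- predict_potts(params, fx$g)
  expect_identical(m$L, 8L)
  for (pair in list(c(1, 5), c(2, 7), c(3, 4))) {
    expect_equal(coupling_block(m, pair[1], pair[2]),
                 t(coupling_block(m, pair[2], pair[1])))
  }
})

test_that("prediction is invariant to rigid motion and neighbor order", {
  fx <- net_fixture()
  params <- randomize_readout(fx$params)
  m <- predict_potts(params, fx$g)
  bb2 <- rotate_structure(make_toy_backbone(8, "perturbed", seed = 7))
  m2 <- predict_potts(params, featurize(bb2, fx$fcfg))
  expect_lt(max(abs(m$h - m2$h)), 1e-5)
  expect_lt(max(mapply(function(x, y) max(abs(x - y)), m$J, m2$J)), 1e-5)

  # permute each node's neighbor list: aggregation must not care
  g_perm <- fx$g
  set.seed(3)
  for (i in seq_len(g_perm$L)) {
    ord <- sample(ncol(g_perm$neighbors))
    g_perm$neighbors[i, ] <- g_perm$neighbors[i, ord]
    g_perm$edge_features[i, , ] <- g_perm$edge_features[i, ord, ]
  }
  m3 <- predict_potts(params, g_perm)
  expect_lt(max(abs(m$h - m3$h)), 1e-6)
  expect_lt(max(mapply(function(x, y) max(abs(x - y)), m$J, m3$J)), 1e-6)
})

test_that("forward-pass counting instruments every prediction", {
  fx <- net_fixture()
  expect_identical(forward_pass_count(fx$params), 0L)
  invisible(predict_potts(fx$params, fx$g))
  invisible(predict_potts(fx$params, fx$g))
  expect_identical(forward_pass_count(fx$params), 2L)
  reset_forward_pass_count(fx$params)
  expect_identical(forward_pass_count(fx$params), 0L)
})

test_that("pseudolikelihood loss matches enumeration-based conditionals", {
  z <- potts_model(matrix(0, 5, 4), alphabet = toy_alphabet(4))
  expect_equal(pseudolikelihood_loss(z, c(1, 2, 3, 4, 1)), log(4),
               tolerance = 1e-12)

  # L = 1: conditional equals the exact marginal
  m1 <- potts_model(matrix(c(0, 0.7, -0.3), 1, 3),
                    alphabet = toy_alphabet(3))
  ex1 <- enumerate_distribution(m1)
  expect_equal(pseudolikelihood_loss(m1, 2L), -log(ex1$prob[2]),
               tolerance = 1e-12)

  m <- make_random_potts(4, 3, edge_density = 0.7, seed = 11,
                         alphabet = toy_alphabet(3))
  ex <- enumerate_distribution(m)
  set.seed(12)
  for (r in 1:3) {
    s <- sample.int(3, 4, replace = TRUE)
    # enumeration oracle for the conditionals
    ll <- 0
    for (i in 1:4) {
      mask <- rep(TRUE, nrow(ex$states))
      for (j in setdiff(1:4, i)) mask <- mask & ex$states[, j] == s[j]
      p <- ex$prob[mask] / sum(ex$prob[mask])
      ll <- ll - log(p[ex$states[mask, i] == s[i]])
    }
    expect_equal(pseudolikelihood_loss(m, s), ll / 4, tolerance = 1e-9)
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  fx <- net_fixture(hidden = 32)
  true_m <- make_random_potts(8, 4, edge_density = 0.3, field_scale = 0.3,
                              coupling_scale = 1, seed = 42)
  ex <- enumerate_distribution(true_m)
  seqs <- withr::with_seed(43, {
    ex$states[sample.int(length(ex$prob), 60, TRUE, ex$prob), ]
  })
  ds <- lapply(seq_len(nrow(seqs)), function(i) {
    list(graph = fx$g, seq = seqs[i, ])
  })
  cfg <- train_config(learning_rate = 0.02, epochs = 50, seed = 1)
  fit <- train_potts_net(fx$params, ds, cfg)
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
  # identical seed, identical result
  fit2 <- train_potts_net(init_network(fx$cfg, seed = 1, feat_cfg = fx$fcfg),
                          ds, cfg)
  expect_identical(fit$params$readout, fit2$params$readout)
  expect_error(train_potts_net(fx$params, list()), "length")
})

test_that("training recovers above-chance held-out recovery on rule data", {
  ds <- make_structure_sequence_dataset(n = 40, length = 30, seed = 11)
  fcfg <- featurizer_config(k_neighbors = 12)
  params <- init_network(network_config(alphabet = ds$alphabet),
                         seed = 1, feat_cfg = fcfg)
  items <- lapply(ds$train, function(it) {
    list(graph = featurize(it$backbone, fcfg), seq = it$seq)
  })
  fit <- train_potts_net(params, items,
                         train_config(learning_rate = 0.02, epochs = 80,
                                      seed = 1))
  rec <- vapply(ds$holdout, function(it) {
    conditional_recovery(predict_potts(fit$params, featurize(it$backbone,
                                                             fcfg)),
                         it$seq)
  }, 0)
  # >= 2x chance (chance = 1/4 on the rule alphabet)
  expect_gte(mean(rec), 0.5)
})

test_that("ensemble design runs exactly K forward passes and averages", {
  fx <- net_fixture(L = 12, k = 6)
  params <- randomize_readout(fx$params)
  bb <- make_toy_backbone(12, "perturbed", seed = 9)

  single <- design_for_ensemble(params, structure_ensemble(bb), fx$fcfg)
  expect_identical(single$forward_pass_count, 1L)
  direct <- predict_potts(params, featurize(bb, fx$fcfg))
  expect_equal(single$model$h, direct$h, tolerance = 1e-12)

  # K identical conformers: averaging is idempotent
  dup <- structure_ensemble(bb, list(bb, bb, bb))
  dd <- design_for_ensemble(params, dup, fx$fcfg)
  expect_identical(dd$forward_pass_count, 4L)
  expect_equal(dd$model$h, direct$h, tolerance = 1e-6)
  expect_equal(dd$model$J, direct$J, tolerance = 1e-6)

  # count is K regardless of downstream sample count
  ens <- gaussian_ensemble(bb, 0.5, K = 5, seed = 2)
  des <- design_for_ensemble(params, ens, fx$fcfg)
  expect_identical(des$forward_pass_count, 5L)
  invisible(dlmc_sample(des$model, 50, sampler_config(seed = 1)))
  expect_identical(des$forward_pass_count, 5L)
})

test_that("checkpoints round-trip bit-exactly", {
  fx <- net_fixture(hidden = 16)
  params <- randomize_readout(fx$params)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(params, path)
  r <- load_checkpoint(path)
  expect_identical(r$weights, params$weights)
  expect_identical(r$readout, params$readout)
  expect_identical(r$config, params$config)
  m1 <- predict_potts(params, fx$g)
  m2 <- predict_potts(r, fx$g)
  expect_identical(m1$h, m2$h)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
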