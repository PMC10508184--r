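test_that("training is deterministic given the seed and the loss decreases", {
  d <- make_overlap_dataset(synthetic_scenario(n = 120, overlap = 0.4,
                                               seed = 2))
  cfg <- nn_config("mlp", hidden = 6, epochs = 60)
  m1 <- train_base(cfg, d$features, d$labels, seed = 5)
  m2 <- train_base(cfg, d$features, d$labels, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_identical(predict_prob(m1, d$features), predict_prob(m2, d$features))
  expect_lt(mean(tail(m1$loss, 5)), mean(head(m1$loss, 5)))
  m3 <- train_base(cfg, d$features, d$labels, seed = 6)
  expect_false(identical(m1$params, m3$params))
})

test_that("a separable problem is learned to high training accuracy", {
  d <- make_overlap_dataset(synthetic_scenario(n = 500, overlap = 0.15,
                                               seed = 3))
  m <- train_base(nn_config("mlp", hidden = 8, epochs = 150), d$features,
                  d$labels, seed = 1)
  expect_gt(mean((predict_prob(m, d$features) >= 0.5) == d$labels), 0.95)
})

test_that("single-class training data raises a degenerate-fit warning", {
  x <- matrix(rnorm(40), 20, 2)
  expect_warning(train_base(nn_config("identity", epochs = 5), x,
                            rep(1L, 20), seed = 1),
                 "single class")
  expect_error(train_base(nn_config("identity", epochs = 5), x,
                          rep(2, 20), seed = 1), "0/1")
})

test_that("MC dropout sampling is seeded and degenerates correctly", {
  fx <- tiny_trained_model(seed = 4)
  m <- fx$model
  x <- fx$data$features
  s1 <- mc_dropout_sample(m, x, draws = 30, seed = 9)
  s2 <- mc_dropout_sample(m, x, draws = 30, seed = 9)
  expect_identical(s1$samples, s2$samples)
  expect_equal(s1$source, "mc_dropout")

  # rate 0: all draws equal the deterministic pass; epistemic metrics vanish
  s0 <- mc_dropout_sample(m, x, draws = 20, rate = 0, seed = 9)
  r0 <- uncertainty_report(s0)
  expect_true(all(r0$mi == 0))
  expect_true(all(r0$vr == 0))
  expect_true(all(r0$epistemic_var == 0))
  expect_equal(s0$samples[, 1], predict_prob(m, x))

  # T = 1 is a single stochastic pass
  expect_equal(n_draws(mc_dropout_sample(m, x, draws = 1, seed = 2)), 1L)
})

test_that("higher test-time dropout widens the predictive distribution", {
  wins <- 0L
  for (seed in 1:10) {
    fx <- tiny_trained_model(seed = seed, n = 120, epochs = 60)
    e_hi <- mean(variance_decomposition(
      mc_dropout_sample(fx$model, fx$data$features, 60, rate = 0.5,
                        seed = seed + 1))$epistemic_var)
    e_lo <- mean(variance_decomposition(
      mc_dropout_sample(fx$model, fx$data$features, 60, rate = 0.1,
                        seed = seed + 2))$epistemic_var)
    wins <- wins + (e_hi > e_lo)
  }
  expect_equal(wins, 10L)
})

test_that("ensembles reduce to the base model at M = 1 and spread at M > 1", {
  d <- make_overlap_dataset(synthetic_scenario(n = 120, overlap = 0.5,
                                               seed = 6))
  cfg <- nn_config("mlp", hidden = 6, epochs = 60)
  ens1 <- train_ensemble(cfg, d$features, d$labels, ensemble_spec(1))
  base <- train_base(cfg, d$features, d$labels, seed = 1)
  s1 <- ensemble_sample(ens1, d$features)
  expect_equal(n_draws(s1), 1L)
  expect_equal(s1$samples[, 1], predict_prob(base, d$features))
  r1 <- uncertainty_report(s1)
  expect_true(all(r1$mi == 0 & r1$vr == 0 & r1$epistemic_var == 0))

  ens5 <- train_ensemble(nn_config("mlp", hidden = 8, epochs = 40,
                                   init_scale = 6, l2 = 0),
                         d$features, d$labels, ensemble_spec(5))
  # evaluate where members can plausibly differ: a fresh, noisier cloud
  held <- make_overlap_dataset(synthetic_scenario(n = 400, overlap = 1.2,
                                                  seed = 7))
  s_held <- ensemble_sample(ens5, held$features)
  r5 <- uncertainty_report(s_held)
  # member disagreement on some instance implies positive VR there
  disagree <- apply(s_held$samples >= 0.5, 1,
                    function(z) length(unique(z)) > 1)
  expect_true(any(disagree))
  expect_true(all(r5$vr[disagree] > 0))
  # VR granularity: at most M + 1 distinct values
  expect_lte(length(unique(r5$vr)), 6L)
  expect_error(ensemble_spec(3, seeds = c(1, 1, 2)), "distinct")
})

test_that("the variational head recovers the separating direction", {
  d <- make_overlap_dataset(synthetic_scenario(n = 600, overlap = 0.3,
                                               seed = 8))
  fit <- train_bbb(nn_config("identity"), d$features, d$labels,
                   bayesian_head_spec(steps = 1200), seed = 1)
  g <- suppressWarnings(stats::glm(d$labels ~ d$features,
                                   family = stats::binomial))
  w <- fit$mu[1:2]
  v <- unname(stats::coef(g)[2:3])
  expect_gt(sum(w * v) / sqrt(sum(w^2) * sum(v^2)), 0.9)
  # ELBO improves over training
  expect_gt(mean(tail(fit$elbo, 50)), mean(head(fit$elbo, 50)))
  # seeded sampling is reproducible
  s1 <- bbb_sample(fit, d$features, draws = 50, seed = 3)
  s2 <- bbb_sample(fit, d$features, draws = 50, seed = 3)
  expect_identical(s1$samples, s2$samples)
})

test_that("a vanishing prior dominates the variational posterior", {
  d <- make_overlap_dataset(synthetic_scenario(n = 300, overlap = 0.3,
                                               seed = 9))
  fit <- train_bbb(nn_config("identity"), d$features, d$labels,
                   bayesian_head_spec(weight_var = 1e-6, bias_var = 1e-6,
                                      steps = 800), seed = 1)
  expect_lt(max(abs(fit$mu)), 0.01)
})

test_that("the variational-head ensemble reduces to one member at M = 1", {
  d <- make_overlap_dataset(synthetic_scenario(n = 150, overlap = 0.4,
                                               seed = 10))
  hs <- bayesian_head_spec(steps = 300, mc_samples = 80)
  be <- bbb_ensemble(nn_config("identity"), d$features, d$labels,
                     spec = ensemble_spec(1), head_spec = hs)
  single <- train_bbb(nn_config("identity"), d$features, d$labels, hs,
                      seed = 1)
  expect_equal(be$samples$samples[, 1],
               predictive_mean(bbb_sample(single, d$features, seed = 1)))
  # M = 5 columns bound downstream VR granularity by M + 1
  be5 <- bbb_ensemble(nn_config("identity"), d$features, d$labels,
                      spec = ensemble_spec(5), head_spec = hs)
  expect_equal(n_draws(be5$samples), 5L)
  expect_lte(length(unique(variation_ratio(be5$samples))), 6L)
})

test_that("the bag-of-embeddings encoder learns a planted vocabulary signal", {
  sc <- synthetic_scenario(n = 300, seed = 5)
  tk <- make_token_dataset(sc, vocab_size = 60, length = 60)
  cfg <- nn_config("boe", vocab_size = 60, embed_dim = 8, epochs = 200,
                   dropout = 0)
  m <- train_base(cfg, tk$tokens, tk$labels, seed = 1)
  held <- make_token_dataset(synthetic_scenario(n = 300, seed = 6005),
                             vocab_size = 60, length = 60)
  expect_gt(mean((predict_prob(m, held$tokens) >= 0.5) == held$labels), 0.9)
})
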