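test_that("ordering is by descending score with index tie-break", {
  expect_equal(rank_for_referral(c(0.9, 0.1, 0.9)), c(1L, 3L, 2L))
  # optimal: errors occupy the first positions, in index order
  report <- data.frame(instance_id = paste0("i", 1:10),
                       label = c(1, 0, 0, 1, 0, 1, 0, 0, 1, 0),
                       mean = seq(0.05, 0.95, by = 0.1))
  truth <- c(0, 0, 1, 1, 0, 1, 0, 0, 1, 0)
  pol <- referral_policy("optimal")
  sel <- refer(report, pol, rate = 0.2, truth = truth)
  expect_setequal(sel$referred, c(1L, 3L))
  # with k beyond the error count, ties fill in by ascending index
  expect_setequal(refer(report, pol, rate = 0.3, truth = truth)$referred,
                  c(1L, 2L, 3L))
  # random: seeded and reproducible
  pr <- referral_policy("random", seed = 7)
  s1 <- refer(report, pr, 0.5)
  s2 <- refer(report, pr, 0.5)
  expect_identical(s1$referred, s2$referred)
})

test_that("referred/retained partition follows the rounding rule", {
  set.seed(2)
  report <- uncertainty_report(matrix(runif(100), 10, 10))
  pol <- referral_policy("model_uncertainty", metric = "pe")
  expect_length(refer(report, pol, 0)$referred, 0)
  expect_length(refer(report, pol, 1)$retained, 0)
  # round half away from zero: 0.25 * 10 = 2.5 -> 3
  sel <- refer(report, pol, 0.25)
  expect_length(sel$referred, 3L)
  expect_setequal(c(sel$referred, sel$retained), 1:10)
  expect_length(intersect(sel$referred, sel$retained), 0)
})

test_that("policies validate their inputs", {
  expect_error(referral_policy("model_uncertainty", rates = c(0.5, 0.1)),
               "sorted")
  expect_error(referral_policy("model_uncertainty", rates = c(0, 1.2)),
               "\\[0, 1\\]")
  expect_error(referral_policy("model_uncertainty", alpha = -1),
               "non-negative")
  report <- uncertainty_report(matrix(runif(30), 10, 3))
  expect_error(refer(report, referral_policy("optimal"), 0.1),
               "theoretical upper bound")
  expect_error(refer(report, referral_policy("model_minus_human"), 0.1),
               "multi-annotator")
  # combined strategies default to the VR metric (shared [0, 0.5] scale)
  expect_equal(referral_policy("model_minus_human")$metric, "vr")
  expect_equal(referral_policy("model_uncertainty")$metric, "pe")
})

test_that("the optimal curve bounds every policy and is monotone", {
  set.seed(31)
  truth <- rbinom(400, 1, 0.5)
  ps <- make_predictive_samples(truth, error_rate = 0.12, coupling = 0.6,
                                draws = 30, seed = 31)
  report <- uncertainty_report(ps)
  err <- mean(report$label != truth)
  c_opt <- referral_curve_non_referred(report, truth,
                                       referral_policy("optimal"))
  others <- list(
    referral_curve_non_referred(report, truth,
                                referral_policy("model_uncertainty",
                                                metric = "pe")),
    referral_curve_non_referred(report, truth,
                                referral_policy("model_uncertainty",
                                                metric = "vr")),
    referral_curve_non_referred(report, truth,
                                referral_policy("random", seed = 99)))
  for (cv in others) {
    expect_true(all(c_opt$accuracy >= cv$accuracy))
  }
  expect_true(all(c_opt$accuracy[c_opt$rate >= err] == 1))
  below_one <- c_opt$accuracy < 1
  expect_true(all(diff(c_opt$accuracy[below_one]) >= 0))
  expect_match(attr(c_opt, "note"), "upper bound")
})

test_that("random referral preserves the full-dataset accuracy in expectation", {
  set.seed(17)
  truth <- rbinom(400, 1, 0.5)
  ps <- make_predictive_samples(truth, error_rate = 0.15, coupling = 0.5,
                                draws = 20, seed = 17)
  report <- uncertainty_report(ps)
  full <- mean(report$label == truth)
  pol <- function(s) referral_policy("random", rates = 0.3, seed = s)
  accs <- vapply(1:100, function(s) {
    referral_curve_non_referred(report, truth, pol(s + 1000))$accuracy
  }, numeric(1))
  se <- sd(accs) / sqrt(100)
  expect_lt(abs(mean(accs) - full), 2 * se + 1e-3)
})

test_that("rate 0 reproduces full-dataset metrics; empty retained set is missing", {
  set.seed(23)
  truth <- rbinom(100, 1, 0.5)
  report <- uncertainty_report(
    make_predictive_samples(truth, 0.1, 0.5, 20, seed = 23))
  pol <- referral_policy("model_uncertainty", metric = "pe",
                         rates = c(0, 0.5, 1))
  cv <- referral_curve_non_referred(report, truth, pol)
  full <- classification_metrics(report$label, truth, probs = report$mean)
  expect_equal(cv$accuracy[1], full$accuracy)
  expect_equal(cv$f1[1], full$f1)
  expect_true(is.na(cv$accuracy[3]))        # rate 1: nothing retained
  expect_match(attr(cv, "log"), "empty retained", all = FALSE)
})

test_that("single-class retained sets log an undefined ROC-AUC", {
  # all errors are on class 1; high rates retain only class 0
  report <- data.frame(instance_id = paste0("i", 1:20),
                       label = rep(0L, 20),
                       mean = rep(0.1, 20),
                       pe = binary_entropy(seq(0.05, 0.45, length.out = 20)),
                       ee = 0, mi = 0, vr = 0)
  truth <- c(rep(1L, 4), rep(0L, 16))
  pol <- referral_policy("model_uncertainty", metric = "pe",
                         rates = c(0, 0.9))
  cv <- referral_curve_non_referred(report, truth, pol)
  expect_true(is.na(cv$roc_auc[2]))
  expect_match(attr(cv, "log"), "ROC-AUC undefined", all = FALSE)
})

test_that("dataset-level evaluation blends model and human predictions", {
  sc <- make_complementary_scenario(n = 400, seed = 3)
  report <- uncertainty_report(sc$samples)
  truth <- majority_labels(sc$annotations)
  pol <- referral_policy("model_uncertainty", metric = "vr",
                         rates = c(0, 1))
  cv <- referral_curve_dataset_level(report, sc$annotations, pol)
  # rate 0: model alone; rate 1: human alone = 1 - disagreement_rate
  expect_equal(cv$accuracy[1], mean(report$label == truth))
  expect_equal(cv$accuracy[2], 1 - disagreement_rate(sc$annotations))
})

test_that("the combined score reduces to the single-label score at alpha 0", {
  sc <- make_complementary_scenario(n = 300, seed = 5)
  report <- uncertainty_report(sc$samples)
  hu <- human_uncertainties(sc$annotations)
  expect_equal(multi_label_score(report$vr, hu, alpha = 0), report$vr)
  expect_equal(multi_label_score(0.4, 0.4, alpha = 1), 0)
  expect_equal(multi_label_score(0.3, 0.2, alpha = 1, variant = "plus"), 0.5)
  # with no human uncertainty anywhere the orderings coincide
  hu0 <- rep(0, nrow(report))
  expect_equal(rank_for_referral(multi_label_score(report$vr, hu0)),
               rank_for_referral(report$vr))
  c0 <- referral_curve_dataset_level(
    report, sc$annotations,
    referral_policy("model_minus_human", metric = "vr", alpha = 0))
  c1 <- referral_curve_dataset_level(
    report, sc$annotations,
    referral_policy("model_uncertainty", metric = "vr"))
  expect_equal(c0$accuracy, c1$accuracy)
})

test_that("the combined strategy beats the single-label strategy per rate (F1)", {
  sel <- function(cv) cv$rate > 1e-9 & cv$rate <= 0.3 + 1e-9
  wins <- matrix(NA, 20, 6)
  for (seed in 1:20) {
    sc <- make_complementary_scenario(n = 800, seed = seed)
    report <- uncertainty_report(sc$samples)
    cs <- referral_curve_dataset_level(
      report, sc$annotations,
      referral_policy("model_uncertainty", metric = "vr"))
    cm <- referral_curve_dataset_level(
      report, sc$annotations,
      referral_policy("model_minus_human", metric = "vr"))
    wins[seed, ] <- cm$f1[sel(cm)] > cs$f1[sel(cs)]
  }
  for (j in 1:6) {
    expect_lt(stats::binom.test(sum(wins[, j]), 20,
                                alternative = "greater")$p.value, 0.05)
  }
})

test_that("referral curves round-trip through CSV with a policy sidecar", {
  set.seed(41)
  truth <- rbinom(60, 1, 0.5)
  report <- uncertainty_report(
    make_predictive_samples(truth, 0.1, 0.6, 20, seed = 41))
  pol <- referral_policy("model_uncertainty", metric = "mi",
                         rates = seq(0, 0.4, 0.1))
  cv <- referral_curve_non_referred(report, truth, pol)
  f <- tempfile(fileext = ".csv")
  write_referral_curve(cv, f)
  back <- read_referral_curve(f)
  expect_equal(back$accuracy, cv$accuracy)
  expect_equal(names(back), c("rate", "n_referred", "mode", "accuracy",
                              "f1", "roc_auc", "precision", "recall"))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", f))
  expect_equal(meta$strategy, "model_uncertainty")
  expect_equal(meta$metric, "mi")
})
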