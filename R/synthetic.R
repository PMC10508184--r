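#' Synthetic scenario configuration
#'
#' Bundles the knobs of the synthetic generators that emulate the
#' statistical structure of small clinical text corpora: binary labels with
#' class imbalance, about three annotators per instance with about 10%
#' disagreement, class overlap controlling aleatoric noise, an excluded
#' input region controlling epistemic gaps, and a coupling between instance
#' difficulty and model error.
#'
#' Defaults mirror the reference corpora: `class_balance = 255/474`
#' (positive fraction of the dementia transcript corpus; the depression
#' EHR corpus alternative is `222/813 ~ 0.27`), `annotators = 3` and
#' `disagreement_rate = 0.10` (the EHR corpus averages three labels per
#' record with roughly 10% disagreement).
#'
#' @param n number of instances.
#' @param class_balance positive-class fraction.
#' @param overlap common standard deviation of the two class clouds in
#'   [make_overlap_dataset()] (means are fixed at distance 2, so the Bayes
#'   error is about `pnorm(-1 / overlap)`).
#' @param sparsity fraction of the angular input space excluded from
#'   training sampling (the epistemic gap).
#' @param annotators number of annotators per instance (K).
#' @param disagreement_rate fraction of instances with annotator
#'   disagreement.
#' @param error_rate target model error rate for [make_predictive_samples()].
#' @param coupling strength of the uncertainty-error link, in `[0, 1]`.
#' @param draws Monte-Carlo draws per instance (T).
#' @param seed RNG seed.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n = 500L, class_balance = 255 / 474,
                               overlap = 0.6, sparsity = 0,
                               annotators = 3L, disagreement_rate = 0.10,
                               error_rate = 0.10, coupling = 0.6,
                               draws = 50L, seed = 1L) {
  for (nm in c("class_balance", "sparsity", "disagreement_rate",
               "error_rate", "coupling")) {
    assert_rate(get(nm), nm)
  }
  stopifnot(n >= 1L, annotators >= 1L, draws >= 1L, overlap >= 0)
  structure(list(n = as.integer(n), class_balance = class_balance,
                 overlap = overlap, sparsity = sparsity,
                 annotators = as.integer(annotators),
                 disagreement_rate = disagreement_rate,
                 error_rate = error_rate, coupling = coupling,
                 draws = as.integer(draws), seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Two-dimensional class-overlap dataset
#'
#' Draws two isotropic Gaussian class clouds with means `(-1, 0)` and
#' `(1, 0)` and standard deviation `scenario$overlap`. Small overlap gives
#' a nearly separable problem (Bayes error near zero); large overlap pushes
#' any classifier towards the class-prior baseline: the aleatoric regime.
#' With `sparsity > 0`, a wedge of the angular input space (centred on the
#' vertical axis, covering `sparsity` of all directions) is excluded from
#' the training sample by rejection, and probe points inside the wedge are
#' returned separately: a model sees no training data there, so its
#' epistemic uncertainty should be elevated on the probes.
#'
#' @param scenario a [synthetic_scenario()].
#' @param n_probe number of probe points inside the wedge (when
#'   `sparsity > 0`).
#' @return A list with `features` (n x 2 matrix, columns `x1`, `x2`),
#'   `labels` (0/1), `probe_features` (matrix or `NULL`) and the scenario.
#' @export
make_overlap_dataset <- function(scenario, n_probe = 200L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n
    labels <- stats::rbinom(n, 1L, scenario$class_balance)
    half_width <- scenario$sparsity * pi   # wedge total angle (two-sided)
    in_wedge <- function(x) {
      if (scenario$sparsity == 0) return(rep(FALSE, nrow(x)))
      ang <- atan2(x[, 2], x[, 1])
      abs(ang - pi / 2) < half_width / 2 | abs(ang + pi / 2) < half_width / 2
    }
    draw <- function(lab) {
      mu <- cbind(ifelse(lab == 1, 1, -1), 0)
      mu + matrix(stats::rnorm(2 * length(lab), 0, scenario$overlap),
                  ncol = 2)
    }
    features <- draw(labels)
    bad <- in_wedge(features)
    while (any(bad)) {                     # rejection: keep training dense
      features[bad, ] <- draw(labels[bad])
      bad <- in_wedge(features)
    }
    colnames(features) <- c("x1", "x2")
    probe <- NULL
    if (scenario$sparsity > 0) {
      side <- sample(c(-1, 1), n_probe, replace = TRUE)
      ang <- side * pi / 2 +
        stats::runif(n_probe, -half_width / 2, half_width / 2)
      r <- stats::runif(n_probe, 0.5, 1.5)
      probe <- cbind(x1 = r * cos(ang), x2 = r * sin(ang))
    }
    list(features = features, labels = labels, probe_features = probe,
         scenario = scenario)
  })
}

#' Token-sequence dataset with class-dependent vocabulary diversity
#'
#' Emulates the linguistic signature that motivates text-based screening:
#' the positive class draws its tokens from a lower-entropy unigram
#' distribution (a smaller effective vocabulary), the way dementia reduces
#' vocabulary diversity in picture-description transcripts. Negative-class
#' sequences follow a Zipf distribution over the full vocabulary; positive
#' sequences mix that distribution with one concentrated on the top
#' quarter of the vocabulary, with mixing weight `divergence`. At
#' `divergence = 0` the classes are indistinguishable.
#'
#' @param scenario a [synthetic_scenario()].
#' @param vocab_size vocabulary size.
#' @param length mean sequence length (the reference transcript corpora
#'   average roughly 109 and 208 words; sequence lengths are Poisson
#'   around this mean).
#' @param divergence class-distribution divergence in `[0, 1]`.
#' @return A list with `tokens` (list of integer vectors in
#'   `1..vocab_size`), `labels` (0/1) and the scenario.
#' @export
make_token_dataset <- function(scenario, vocab_size = 60L, length = 109L,
                               divergence = 0.8) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  assert_rate(divergence, "divergence")
  with_seed(scenario$seed, {
    n <- scenario$n
    labels <- stats::rbinom(n, 1L, scenario$class_balance)
    zipf <- (1 / seq_len(vocab_size))
    p_neg <- zipf / sum(zipf)
    reduced <- numeric(vocab_size)
    top <- max(1L, floor(vocab_size / 4))
    reduced[seq_len(top)] <- zipf[seq_len(top)] / sum(zipf[seq_len(top)])
    p_pos <- (1 - divergence) * p_neg + divergence * reduced
    lens <- pmax(5L, stats::rpois(n, length))
    tokens <- lapply(seq_len(n), function(i) {
      p <- if (labels[i] == 1) p_pos else p_neg
      sample.int(vocab_size, lens[i], replace = TRUE, prob = p)
    })
    list(tokens = tokens, labels = labels, scenario = scenario)
  })
}

#' Multi-annotator labels with a controlled disagreement rate
#'
#' Gives every instance `k` annotator labels equal to the truth, then flips
#' one randomly chosen annotator on exactly `round(disagreement_rate * n)`
#' randomly chosen instances (rounding half away from zero). With odd `k`
#' a single flip never changes the majority, so the majority label equals
#' the truth everywhere and the realised disagreement rate matches its
#' target exactly.
#'
#' @param truth ground-truth 0/1 labels.
#' @param k annotators per instance.
#' @param disagreement_rate target fraction of disagreement instances.
#' @param seed RNG seed.
#' @return An [annotation_matrix].
#' @examples
#' m <- make_annotations(rbinom(100, 1, 0.5), k = 3,
#'                       disagreement_rate = 0.1, seed = 1)
#' disagreement_rate(m)  # exactly 0.1
#' @export
make_annotations <- function(truth, k = 3L, disagreement_rate = 0.10,
                             seed = 1L) {
  assert_binary(truth, "truth")
  assert_rate(disagreement_rate, "disagreement_rate")
  stopifnot(k >= 1L)
  n <- length(truth)
  with_seed(seed, {
    labels <- lapply(truth, function(t) rep(as.integer(t), k))
    m <- as.integer(round_half_away(disagreement_rate * n))
    if (m > 0L && k > 1L) {
      flip <- sample.int(n, m)
      for (i in flip) {
        j <- sample.int(k, 1L)
        labels[[i]][j] <- 1L - labels[[i]][j]
      }
    }
    annotation_matrix(labels)
  })
}

# Clamp raw draws to [0, 1]; clamping can drag a near-threshold row mean
# across 0.5, so rows whose hardened mean disagrees with the planted label
# are mirrored (p -> 1 - p, preserving the spread) to keep the realised
# label exactly as planted.
clamp_to_predicted <- function(raw, predicted) {
  s <- pmin(pmax(raw, 0), 1)
  lab <- as.integer(rowMeans(s) >= 0.5)
  wrong <- lab != predicted
  s[wrong, ] <- 1 - s[wrong, ]
  s
}

#' Predictive sample sets with a controlled uncertainty-error link
#'
#' Generates Monte-Carlo predictive samples directly -- no training
#' required -- so referral strategies can be studied under a known coupling
#' between uncertainty and misclassification. Each instance receives a
#' difficulty `d ~ Uniform(0, 1)`; exactly `round(error_rate * n)`
#' instances are drawn as model errors, selected with probability
#' proportional to a logistic function of difficulty whose slope grows
#' with `coupling` (at `coupling = 0` errors are uniform, so uncertainty
#' carries no information about them). The sample centre sits on the
#' predicted-label side of 0.5 with a margin shrinking in difficulty, and
#' the sample spread grows with difficulty, so predictive entropy and
#' variation ratio increase with difficulty -- and, when `coupling > 0`,
#' with the probability of error, reproducing the empirical link between
#' uncertainty and misclassification that referral learning exploits.
#'
#' @param truth ground-truth 0/1 labels.
#' @param error_rate target model error rate; realised exactly up to the
#'   rounding of `error_rate * n`.
#' @param coupling uncertainty-error coupling in `[0, 1]`.
#' @param draws Monte-Carlo draws per instance.
#' @param seed RNG seed.
#' @return A [predictive_samples] object with attributes `difficulty`
#'   (the latent difficulties) and `errors` (indices of the planted model
#'   errors).
#' @export
make_predictive_samples <- function(truth, error_rate = 0.10, coupling = 0.6,
                                    draws = 50L, seed = 1L) {
  assert_binary(truth, "truth")
  assert_rate(error_rate, "error_rate")
  assert_rate(coupling, "coupling")
  stopifnot(draws >= 1L)
  n <- length(truth)
  with_seed(seed, {
    difficulty <- stats::runif(n)
    slope <- 8 * coupling
    m <- as.integer(round_half_away(error_rate * n))
    weights <- if (slope == 0) rep(1, n) else {
      # calibrate the intercept so the mean error probability hits the target
      f <- function(b0) mean(stats::plogis(b0 + slope * difficulty)) -
        error_rate
      b0 <- if (error_rate %in% c(0, 1)) 0 else
        stats::uniroot(f, c(-40, 40))$root
      stats::plogis(b0 + slope * difficulty)
    }
    err_idx <- if (m > 0L) sample.int(n, m, prob = weights) else integer(0)
    predicted <- truth
    predicted[err_idx] <- 1L - predicted[err_idx]
    margin <- 0.02 + 0.46 * (1 - difficulty)
    centre <- 0.5 + (2 * predicted - 1) * margin
    spread <- 0.02 + 0.25 * difficulty
    raw <- matrix(stats::rnorm(n * draws), n, draws) * spread
    raw <- raw - rowMeans(raw) + centre    # centre the draws exactly
    s <- clamp_to_predicted(raw, predicted)
    ps <- predictive_samples(s, source = "external")
    attr(ps, "difficulty") <- difficulty
    attr(ps, "errors") <- sort(err_idx)
    ps
  })
}

#' Complementary model/human scenario
#'
#' Builds the regime in which combining model and human uncertainty pays
#' off: the model and the simulated human have similar overall accuracy
#' (about 90% each), but their errors live in different places, so each can
#' cover the other's weaknesses.
#'
#' Instances fall into three regions:
#'
#' * *grey cases* (fraction 0.10): high model uncertainty, model correct
#'   only half the time, and annotator disagreement (the simulated human is
#'   wrong here) -- hard for both parties;
#' * *model-hard / human-easy* (fraction 0.25): the same high model
#'   uncertainty, a modest model error rate, unanimous annotators -- the
#'   region a good referral policy should hand over;
#' * *easy* (the rest): a confident, correct model and unanimous
#'   annotators.
#'
#' The two uncertain regions share one uncertainty distribution, so the
#' single-label strategy cannot tell them apart and its dataset-level curve
#' stays flat; the combined model-minus-human score ranks the human-easy
#' uncertain region first and dominates at low referral rates. Region
#' sizes and error rates satisfy exact bookkeeping: model accuracy
#' `1 - (0.5 * 0.10 + 0.2 * 0.25) = 0.90` in expectation, human accuracy
#' `0.90` exactly.
#'
#' @param n number of instances.
#' @param seed RNG seed.
#' @param k annotators per instance.
#' @param draws Monte-Carlo draws per instance.
#' @return A list with `samples` (a [predictive_samples]), `annotations`
#'   (an [annotation_matrix]), `truth` (majority ground truth), and
#'   `region` (factor: `"grey"`, `"model_hard"`, `"easy"`).
#' @export
make_complementary_scenario <- function(n = 800L, seed = 1L, k = 3L,
                                        draws = 50L) {
  stopifnot(n >= 20L, k >= 3L, k %% 2L == 1L)
  with_seed(seed, {
    truth <- stats::rbinom(n, 1L, 0.5)
    n_grey <- as.integer(round_half_away(0.10 * n))
    n_hard <- as.integer(round_half_away(0.25 * n))
    region <- rep("easy", n)
    pick <- sample.int(n, n_grey + n_hard)
    region[pick[seq_len(n_grey)]] <- "grey"
    region[pick[seq.int(n_grey + 1L, n_grey + n_hard)]] <- "model_hard"
    region <- factor(region, levels = c("grey", "model_hard", "easy"))

    err_prob <- c(grey = 0.5, model_hard = 0.2, easy = 0)[as.character(region)]
    error <- stats::rbinom(n, 1L, err_prob) == 1L
    predicted <- ifelse(error, 1L - truth, truth)

    uncertain <- region %in% c("grey", "model_hard")
    margin <- ifelse(uncertain, stats::runif(n, 0.06, 0.30), 0.45)
    spread <- ifelse(uncertain, 0.20, 0.03)
    centre <- 0.5 + (2 * predicted - 1) * margin
    raw <- matrix(stats::rnorm(n * draws), n, draws) * spread
    raw <- raw - rowMeans(raw) + centre
    samples <- predictive_samples(clamp_to_predicted(raw, predicted),
                                  source = "external")

    labels <- lapply(seq_len(n), function(i) {
      lab <- rep(as.integer(truth[i]), k)
      if (region[i] == "grey") lab[sample.int(k, 1L)] <- 1L - lab[1L]
      lab
    })
    annotations <- annotation_matrix(labels)
    list(samples = samples, annotations = annotations,
         truth = as.integer(truth), region = region)
  })
}
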