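#' Configuration for the small reference classifiers
#'
#' The package ships deliberately small binary classifiers (at most tens of
#' thousands of parameters, CPU-seconds training) that exist to *generate*
#' predictive sample sets; the uncertainty and referral machinery accepts
#' samples from any external model. Each classifier is an encoder followed
#' by a single linear (logistic) head, with a dropout site on the encoder
#' output, i.e. immediately before the final linear layer:
#'
#' * `"identity"` -- the features are used as the representation directly
#'   (a Bayesian logistic regression when combined with [train_bbb()]);
#' * `"mlp"` -- one tanh hidden layer of `hidden` units over a feature
#'   vector;
#' * `"boe"` -- mean bag-of-embeddings over a token sequence: trainable
#'   `vocab_size x embed_dim` embeddings averaged over the sequence.
#'
#' Training minimises binary cross-entropy with full-batch Adam plus a small
#' L2 penalty; all stochastic steps are governed by an explicit seed.
#'
#' @param encoder encoder family.
#' @param hidden hidden width of the `"mlp"` encoder.
#' @param vocab_size vocabulary size (required for `"boe"`).
#' @param embed_dim embedding dimension for `"boe"`.
#' @param dropout dropout rate at the pre-head site, in `[0, 1)`; used
#'   during training and, by default, for Monte-Carlo dropout sampling.
#' @param epochs,lr,l2 full-batch Adam epochs, learning rate, L2 penalty.
#' @param init_scale multiplier on the random weight-initialisation scale.
#'   Values above 1 start each network at a sharper random function, which
#'   increases the functional diversity of independently seeded members --
#'   the source of a deep ensemble's spread.
#' @return An object of class `nn_config`.
#' @export
nn_config <- function(encoder = c("mlp", "identity", "boe"),
                      hidden = 16L, vocab_size = NULL, embed_dim = 16L,
                      dropout = 0.2, epochs = 300L, lr = 0.02, l2 = 1e-4,
                      init_scale = 1) {
  encoder <- match.arg(encoder)
  if (dropout < 0 || dropout >= 1) {
    stop("`dropout` must lie in [0, 1)", call. = FALSE)
  }
  if (encoder == "boe" && is.null(vocab_size)) {
    stop("the 'boe' encoder requires `vocab_size`", call. = FALSE)
  }
  stopifnot(hidden >= 1L, epochs >= 1L, lr > 0, l2 >= 0, init_scale > 0)
  structure(list(encoder = encoder, hidden = as.integer(hidden),
                 vocab_size = if (!is.null(vocab_size)) as.integer(vocab_size),
                 embed_dim = as.integer(embed_dim), dropout = dropout,
                 epochs = as.integer(epochs), lr = lr, l2 = l2,
                 init_scale = init_scale),
            class = "nn_config")
}

# ---- internal engine ------------------------------------------------------

# Convert raw inputs to the design matrix the encoder consumes.
# For "boe" the input is a list of integer token vectors; rows of the
# returned matrix are length-normalised term frequencies, so D %*% E is the
# mean embedding of the sequence.
encode_input <- function(config, x) {
  if (config$encoder == "boe") {
    if (!is.list(x)) stop("'boe' inputs must be a list of token vectors",
                          call. = FALSE)
    v <- config$vocab_size
    d <- matrix(0, length(x), v)
    for (i in seq_along(x)) {
      tk <- x[[i]]
      if (length(tk) == 0L || any(tk < 1L | tk > v)) {
        stop(sprintf("token sequence %d is empty or outside 1..%d", i, v),
             call. = FALSE)
      }
      d[i, ] <- tabulate(tk, nbins = v) / length(tk)
    }
    d
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

init_params <- function(config, input_dim) {
  h <- rep_width(config, input_dim)
  sc <- config$init_scale
  head <- list(w = stats::rnorm(h, 0, 0.1 * sc), b = 0)
  enc <- switch(config$encoder,
    identity = list(),
    mlp = list(W1 = matrix(stats::rnorm(input_dim * config$hidden, 0,
                                        sc * sqrt(1 / input_dim)),
                           input_dim, config$hidden),
               b1 = stats::rnorm(config$hidden, 0, 0.1 * sc)),
    boe = list(E = matrix(stats::rnorm(config$vocab_size * config$embed_dim,
                                       0, 0.3),
                          config$vocab_size, config$embed_dim)))
  c(enc, head)
}

# Width of the representation the head sees.
rep_width <- function(config, input_dim) {
  switch(config$encoder,
         identity = input_dim,
         mlp = config$hidden,
         boe = config$embed_dim)
}

encoder_forward <- function(config, params, x_mat) {
  switch(config$encoder,
         identity = x_mat,
         mlp = tanh(sweep(x_mat %*% params$W1, 2, params$b1, "+")),
         boe = x_mat %*% params$E)
}

# Gradients of the loss w.r.t. encoder parameters given dL/dH.
encoder_backward <- function(config, params, x_mat, h_mat, d_h, l2) {
  switch(config$encoder,
    identity = list(),
    mlp = {
      d_z1 <- d_h * (1 - h_mat^2)
      list(W1 = crossprod(x_mat, d_z1) + l2 * params$W1,
           b1 = colSums(d_z1))
    },
    boe = list(E = crossprod(x_mat, d_h) + l2 * params$E))
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    m_hat <- state$m[[nm]] / (1 - beta1^state$t)
    v_hat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
  }
  list(state = state, params = params)
}

dropout_mask <- function(n, h, rate) {
  matrix(stats::rbinom(n * h, 1L, 1 - rate), n, h) / (1 - rate)
}

# ---- deterministic base model --------------------------------------------

#' Train a reference classifier
#'
#' Trains the encoder + logistic head of `config` by full-batch Adam on the
#' binary cross-entropy loss, with (ordinary, inverted) dropout active at
#' the pre-head site during training when `config$dropout > 0`. Training is
#' bit-reproducible given `(config, seed)`. The per-epoch loss trace is
#' stored on the fitted model.
#'
#' @param config an [nn_config()].
#' @param x feature matrix (rows = instances) or, for the `"boe"` encoder,
#'   a list of integer token vectors.
#' @param y binary 0/1 labels.
#' @param seed integer RNG seed for initialisation and dropout.
#' @return An object of class `uq_model` with elements `config`, `params`,
#'   `loss` (per-epoch trace) and `seed`.
#' @examples
#' d <- make_overlap_dataset(synthetic_scenario(n = 200, overlap = 0.3))
#' m <- train_base(nn_config("mlp", hidden = 8, epochs = 100), d$features,
#'                 d$labels, seed = 1)
#' mean((predict_prob(m, d$features) >= 0.5) == d$labels)
#' @export
train_base <- function(config, x, y, seed = 1L) {
  stopifnot(inherits(config, "nn_config"))
  assert_binary(y, "y")
  if (length(unique(y)) == 1L) {
    warning("degenerate fit: training labels contain a single class",
            call. = FALSE)
  }
  x_mat <- encode_input(config, x)
  n <- nrow(x_mat)
  if (n != length(y)) stop("`x` and `y` must be aligned", call. = FALSE)
  with_seed(seed, {
    params <- init_params(config, ncol(x_mat))
    state <- adam_init(params)
    loss <- numeric(config$epochs)
    h_width <- rep_width(config, ncol(x_mat))
    for (ep in seq_len(config$epochs)) {
      h_mat <- encoder_forward(config, params, x_mat)
      if (config$dropout > 0) {
        mask <- dropout_mask(n, h_width, config$dropout)
        h_drop <- h_mat * mask
      } else {
        h_drop <- h_mat
      }
      z <- drop(h_drop %*% params$w) + params$b
      p <- stats::plogis(z)
      loss[ep] <- bce_loss(p, y)
      g <- (p - y) / n
      grads <- c(
        encoder_backward(config, params, x_mat, h_mat,
                         (g %o% params$w) *
                           (if (config$dropout > 0) mask else 1),
                         config$l2),
        list(w = drop(crossprod(h_drop, g)) + config$l2 * params$w,
             b = sum(g)))
      upd <- adam_step(state, params, grads, config$lr)
      state <- upd$state
      params <- upd$params
    }
    structure(list(config = config, params = params, loss = loss,
                   seed = as.integer(seed)),
              class = "uq_model")
  })
}

#' Deterministic predicted probabilities from a trained model
#'
#' A single forward pass with every stochastic site disabled.
#'
#' @param model a fitted `uq_model` from [train_base()].
#' @param x inputs in the same format used for training.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "uq_model"))
  x_mat <- encode_input(model$config, x)
  h_mat <- encoder_forward(model$config, model$params, x_mat)
  stats::plogis(drop(h_mat %*% model$params$w) + model$params$b)
}

#' Monte-Carlo dropout sampling
#'
#' Keeps dropout active at test time: each of the `draws` forward passes
#' multiplies the pre-head representation by a fresh Bernoulli mask, so each
#' pass is a draw from an approximate posterior predictive. With `rate = 0`
#' every column is the same deterministic pass, and all epistemic metrics
#' (MI, VR, epistemic variance) downstream are exactly zero.
#'
#' @param model a fitted `uq_model`.
#' @param x inputs.
#' @param draws number of Monte-Carlo forward passes (T). The reference
#'   large-sample setting is 1,000 draws; smaller values are cheaper and
#'   coarser.
#' @param rate dropout rate at test time; defaults to the rate the model
#'   was trained with.
#' @param seed RNG seed; sampling is bit-reproducible given
#'   `(model, x, draws, rate, seed)`.
#' @param instance_ids optional instance identifiers for the sample set.
#' @return A [predictive_samples] object with `draws` columns,
#'   source `"mc_dropout"`.
#' @export
mc_dropout_sample <- function(model, x, draws = 1000L, rate = NULL,
                              seed = 1L, instance_ids = NULL) {
  stopifnot(inherits(model, "uq_model"), draws >= 1L)
  rate <- rate %||% model$config$dropout
  if (rate < 0 || rate >= 1) stop("`rate` must lie in [0, 1)", call. = FALSE)
  x_mat <- encode_input(model$config, x)
  h_mat <- encoder_forward(model$config, model$params, x_mat)
  n <- nrow(h_mat)
  s <- matrix(0, n, draws)
  if (rate == 0) {
    p <- stats::plogis(drop(h_mat %*% model$params$w) + model$params$b)
    s[] <- p
  } else {
    with_seed(seed, {
      for (t in seq_len(draws)) {
        mask <- dropout_mask(n, ncol(h_mat), rate)
        s[, t] <- stats::plogis(drop((h_mat * mask) %*% model$params$w) +
                                  model$params$b)
      }
    })
  }
  predictive_samples(s, instance_ids = instance_ids, source = "mc_dropout")
}

# ---- deep ensembles -------------------------------------------------------

#' Deep-ensemble specification
#'
#' An ensemble of `members` networks sharing architecture and training data,
#' each trained from a different random seed. Ensembles of 5 (default) or 10
#' members are the usual desk-scale choices; note that the downstream
#' variation ratio of an M-member ensemble can take at most M + 1 distinct
#' values, which produces the characteristic staircase granularity of
#' ensemble VR.
#'
#' @param members number of ensemble members (M >= 1).
#' @param seeds distinct member seeds; defaults to `1:members`.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(members = 5L, seeds = NULL) {
  members <- as.integer(members)
  stopifnot(members >= 1L)
  seeds <- as.integer(seeds %||% seq_len(members))
  if (length(seeds) != members || anyDuplicated(seeds)) {
    stop("`seeds` must be `members` distinct integers", call. = FALSE)
  }
  structure(list(members = members, seeds = seeds), class = "ensemble_spec")
}

#' Train a deep ensemble of reference classifiers
#'
#' Member m is trained exactly as [train_base()] with the m-th seed of the
#' specification.
#'
#' @param config an [nn_config()].
#' @param x,y training inputs and binary labels.
#' @param spec an [ensemble_spec()].
#' @return An object of class `uq_ensemble` (a list of fitted members).
#' @export
train_ensemble <- function(config, x, y, spec = ensemble_spec()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  models <- lapply(spec$seeds, function(s) train_base(config, x, y, seed = s))
  structure(list(models = models, spec = spec, config = config),
            class = "uq_ensemble")
}

#' Predictive samples from a deep ensemble
#'
#' Each column of the returned sample set is one member's deterministic
#' prediction, so T equals the member count M.
#'
#' @param ensemble a fitted `uq_ensemble`.
#' @param x inputs.
#' @param instance_ids optional instance identifiers.
#' @return A [predictive_samples] object with M columns, source
#'   `"ensemble"`.
#' @export
ensemble_sample <- function(ensemble, x, instance_ids = NULL) {
  stopifnot(inherits(ensemble, "uq_ensemble"))
  cols <- vapply(ensemble$models, predict_prob,
                 numeric(nrow(encode_input(ensemble$config, x))), x = x)
  predictive_samples(as.matrix(cols), instance_ids = instance_ids,
                     source = "ensemble")
}

# ---- mean-field variational final layer (Bayes-by-backprop) ---------------

#' Specification of the Bayesian (variational) final layer
#'
#' Only the final linear layer is made Bayesian; the encoder stays
#' deterministic and is co-trained. The prior over the head weights is
#' independent Gaussian with mean zero and variance `weight_var` (default 1),
#' and over the bias mean zero and variance `bias_var` (default 10; biases
#' range wider). The variational family is mean-field Gaussian with
#' learnable means and (softplus-parameterised) standard deviations, fitted
#' by maximising the evidence lower bound
#' \deqn{\mathrm{ELBO} = \mathrm{E}_q[\log p(y \mid x, w)] -
#'   \mathrm{KL}(q \,\|\, \mathrm{prior})}
#' with the Bernoulli likelihood and the closed-form Gaussian KL, using Adam.
#'
#' @param weight_var,bias_var prior variances (> 0).
#' @param elbo_samples Monte-Carlo samples of the ELBO gradient per step.
#' @param mc_samples default number of posterior predictive draws at test
#'   time (the reference setting is 1,000).
#' @param steps,lr Adam steps and learning rate.
#' @return An object of class `bayesian_head_spec`.
#' @export
bayesian_head_spec <- function(weight_var = 1, bias_var = 10,
                               elbo_samples = 1L, mc_samples = 1000L,
                               steps = 2000L, lr = 0.01) {
  stopifnot(weight_var > 0, bias_var > 0, elbo_samples >= 1L,
            mc_samples >= 1L, steps >= 1L, lr > 0)
  structure(list(weight_var = weight_var, bias_var = bias_var,
                 elbo_samples = as.integer(elbo_samples),
                 mc_samples = as.integer(mc_samples),
                 steps = as.integer(steps), lr = lr),
            class = "bayesian_head_spec")
}

softplus <- function(x) log1p(exp(pmin(x, 30))) + pmax(x - 30, 0)

#' Train a classifier with a variational (Bayes-by-backprop) final layer
#'
#' Maximises the ELBO by stochastic gradients: at each step one weight
#' configuration is drawn from the variational posterior by the
#' reparameterisation trick, the Bernoulli log-likelihood over the whole
#' dataset and its gradient are computed, and the closed-form Gaussian KL
#' pulls the posterior towards the prior. Encoder parameters (if any) are
#' co-trained deterministically through the sampled head. The ELBO trace is
#' stored; a non-finite ELBO aborts with diagnostics.
#'
#' @param config an [nn_config()] (its dropout is ignored here: the head's
#'   weight distribution is the stochastic site).
#' @param x,y training inputs and binary labels.
#' @param head_spec a [bayesian_head_spec()].
#' @param seed RNG seed; training is bit-reproducible given
#'   `(config, head_spec, seed)`.
#' @return An object of class `uq_bbb` with the variational means `mu`,
#'   raw scales `rho` (sd = softplus(rho)), encoder parameters, and the
#'   per-step `elbo` trace. The last `mu`/`rho` entry is the bias.
#' @examples
#' d <- make_overlap_dataset(synthetic_scenario(n = 200, overlap = 0.2))
#' fit <- train_bbb(nn_config("identity"), d$features, d$labels,
#'                  bayesian_head_spec(steps = 300), seed = 1)
#' s <- bbb_sample(fit, d$features, draws = 100, seed = 1)
#' @export
train_bbb <- function(config, x, y, head_spec = bayesian_head_spec(),
                      seed = 1L) {
  stopifnot(inherits(config, "nn_config"),
            inherits(head_spec, "bayesian_head_spec"))
  assert_binary(y, "y")
  x_mat <- encode_input(config, x)
  n <- nrow(x_mat)
  if (n != length(y)) stop("`x` and `y` must be aligned", call. = FALSE)
  with_seed(seed, {
    all_params <- init_params(config, ncol(x_mat))
    enc_params <- all_params[setdiff(names(all_params), c("w", "b"))]
    h_width <- rep_width(config, ncol(x_mat))
    k <- h_width + 1L                       # head weights + bias
    prior_sd <- c(rep(sqrt(head_spec$weight_var), h_width),
                  sqrt(head_spec$bias_var))
    params <- c(enc_params,
                list(mu = stats::rnorm(k, 0, 0.05),
                     rho = rep(log(expm1(0.1)), k)))  # init sd = 0.1
    state <- adam_init(params)
    elbo <- numeric(head_spec$steps)
    for (step in seq_len(head_spec$steps)) {
      grads_acc <- NULL
      elbo_acc <- 0
      sigma <- softplus(params$rho)
      kl <- sum(log(prior_sd / sigma) +
                  (sigma^2 + params$mu^2) / (2 * prior_sd^2) - 0.5)
      for (s in seq_len(head_spec$elbo_samples)) {
        eps <- stats::rnorm(k)
        wfull <- params$mu + sigma * eps
        w <- wfull[seq_len(h_width)]
        b <- wfull[k]
        h_mat <- encoder_forward(config, params, x_mat)
        z <- drop(h_mat %*% w) + b
        p <- stats::plogis(z)
        pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        loglik <- sum(y * log(pc) + (1 - y) * log(1 - pc))
        elbo_acc <- elbo_acc + loglik - kl
        g <- p - y                           # d(-loglik)/dz, summed form
        gw_full <- c(drop(crossprod(h_mat, g)), sum(g))
        g_sigma <- gw_full * eps + (sigma / prior_sd^2 - 1 / sigma)
        grads <- c(
          encoder_backward(config, params, x_mat, h_mat, g %o% w, 0),
          list(mu = gw_full + params$mu / prior_sd^2,
               rho = g_sigma * stats::plogis(params$rho)))
        grads_acc <- if (is.null(grads_acc)) grads else
          Map(`+`, grads_acc, grads)
      }
      grads_acc <- lapply(grads_acc, `/`, head_spec$elbo_samples)
      elbo[step] <- elbo_acc / head_spec$elbo_samples
      if (!is.finite(elbo[step])) {
        stop(sprintf(
          "ELBO became non-finite at step %d (last finite value %.3g); try a lower learning rate",
          step, if (step > 1) elbo[step - 1L] else NA_real_), call. = FALSE)
      }
      upd <- adam_step(state, params, grads_acc, head_spec$lr)
      state <- upd$state
      params <- upd$params
    }
    structure(list(config = config, head_spec = head_spec,
                   enc_params = params[setdiff(names(params), c("mu", "rho"))],
                   mu = params$mu, rho = params$rho,
                   elbo = elbo, seed = as.integer(seed)),
              class = "uq_bbb")
  })
}

#' Posterior predictive samples from a variational final layer
#'
#' Draws `draws` head configurations from the variational posterior and
#' runs the (deterministic) encoder + sampled head forward for each,
#' yielding the Monte-Carlo posterior predictive.
#'
#' @param model a fitted `uq_bbb`.
#' @param x inputs.
#' @param draws number of posterior draws; defaults to the head
#'   specification's `mc_samples`.
#' @param seed RNG seed.
#' @param instance_ids optional instance identifiers.
#' @return A [predictive_samples] object, source `"bbb"`.
#' @export
bbb_sample <- function(model, x, draws = NULL, seed = 1L,
                       instance_ids = NULL) {
  stopifnot(inherits(model, "uq_bbb"))
  draws <- as.integer(draws %||% model$head_spec$mc_samples)
  stopifnot(draws >= 1L)
  x_mat <- encode_input(model$config, x)
  h_mat <- encoder_forward(model$config, model$enc_params, x_mat)
  k <- length(model$mu)
  sigma <- softplus(model$rho)
  with_seed(seed, {
    eps <- matrix(stats::rnorm(k * draws), k, draws)
    wfull <- model$mu + sigma * eps          # k x draws, column-wise draws
    z <- cbind(h_mat, 1) %*% wfull
    predictive_samples(stats::plogis(z), instance_ids = instance_ids,
                       source = "bbb")
  })
}

#' Ensemble of variational-head classifiers
#'
#' Trains `spec$members` independently seeded Bayes-by-backprop models and
#' returns a sample set whose columns are the per-member predictive means
#' (each member's mean over its own posterior predictive draws). Downstream
#' variation ratios therefore take at most M + 1 distinct values.
#'
#' @param config an [nn_config()].
#' @param x,y training inputs and binary labels.
#' @param newx inputs to sample predictions for; defaults to `x`.
#' @param spec an [ensemble_spec()].
#' @param head_spec a [bayesian_head_spec()].
#' @param instance_ids optional instance identifiers.
#' @return A list with `samples` (a [predictive_samples] with M columns,
#'   source `"ensemble"`) and `models` (the fitted members).
#' @export
bbb_ensemble <- function(config, x, y, newx = x, spec = ensemble_spec(),
                         head_spec = bayesian_head_spec(),
                         instance_ids = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  models <- lapply(spec$seeds, function(s) {
    train_bbb(config, x, y, head_spec, seed = s)
  })
  cols <- vapply(seq_along(models), function(i) {
    predictive_mean(bbb_sample(models[[i]], newx, seed = spec$seeds[i]))
  }, numeric(nrow(encode_input(config, newx))))
  list(samples = predictive_samples(as.matrix(cols),
                                    instance_ids = instance_ids,
                                    source = "ensemble"),
       models = models)
}
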