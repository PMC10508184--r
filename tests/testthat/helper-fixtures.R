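# Shared fixtures built in code at test time.

# Random predictive sample sets with varying draw counts (T in 2..50).
random_sample_sets <- function(n_sets, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    t_draws <- sample(2:50, 1)
    matrix(runif(t_draws), nrow = 1)
  })
}

# Brute-force variation ratio by exhaustive mode counting over a 0/1 vector.
brute_force_vr <- function(labels) {
  counts <- table(factor(labels, levels = c(0, 1)))
  1 - max(counts) / length(labels)
}

# All binary vectors of a given length.
all_binary_vectors <- function(len) {
  grid <- expand.grid(rep(list(c(0L, 1L)), len))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# Small trained reference model on nearly separable 2D data.
tiny_trained_model <- function(seed = 1, n = 150, epochs = 80) {
  d <- make_overlap_dataset(synthetic_scenario(n = n, overlap = 0.3,
                                               seed = seed))
  list(model = train_base(nn_config("mlp", hidden = 6, epochs = epochs),
                          d$features, d$labels, seed = seed),
       data = d)
}
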