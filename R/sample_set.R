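#' Predictive sample sets
#'
#' A `predictive_samples` object holds the empirical posterior predictive of a
#' binary classifier: for each instance, `T` Monte-Carlo draws of the
#' positive-class probability. Draws may come from Monte-Carlo dropout (each
#' column is one stochastic forward pass), a deep ensemble (each column is one
#' member's prediction), a variational final layer (each column is one weight
#' draw), or any external sampler.
#'
#' @param samples numeric matrix of probabilities in `[0, 1]`,
#'   instances x draws. A vector is treated as a single-draw column.
#' @param instance_ids optional character vector of unique instance
#'   identifiers; defaults to `"i1", "i2", ...`.
#' @param source tag naming the generating method.
#'
#' @return An object of class `predictive_samples` with fields
#'   `instance_ids`, `samples` and `source`.
#' @examples
#' ps <- predictive_samples(matrix(c(0.1, 0.2, 0.9, 0.8), 2, 2))
#' predictive_mean(ps)
#' @export
predictive_samples <- function(samples, instance_ids = NULL,
                               source = c("external", "mc_dropout",
                                          "ensemble", "bbb")) {
  source <- match.arg(source)
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = length(samples), ncol = 1L)
  }
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L || ncol(samples) < 1L) {
    stop("a predictive sample set needs at least one instance and one draw",
         call. = FALSE)
  }
  assert_prob(samples, "samples")
  n <- nrow(samples)
  if (is.null(instance_ids)) {
    instance_ids <- paste0("i", seq_len(n))
  }
  instance_ids <- as.character(instance_ids)
  if (length(instance_ids) != n) {
    stop("`instance_ids` must have one entry per instance", call. = FALSE)
  }
  if (anyDuplicated(instance_ids)) {
    stop("`instance_ids` must be unique", call. = FALSE)
  }
  structure(
    list(instance_ids = instance_ids,
         samples = unname(samples),
         source = source),
    class = "predictive_samples"
  )
}

#' @export
print.predictive_samples <- function(x, ...) {
  cat(sprintf("<predictive_samples> %d instances x %d draws (source: %s)\n",
              n_instances(x), n_draws(x), x$source))
  invisible(x)
}

#' Number of instances / Monte-Carlo draws in a sample set
#' @param s a [predictive_samples] object.
#' @return An integer count.
#' @export
n_instances <- function(s) nrow(as_sample_matrix(s))

#' @rdname n_instances
#' @export
n_draws <- function(s) ncol(as_sample_matrix(s))

# Accept either a predictive_samples object or a bare probability matrix.
as_sample_matrix <- function(s) {
  if (inherits(s, "predictive_samples")) {
    return(s$samples)
  }
  if (is.vector(s) && is.numeric(s)) {
    s <- matrix(s, nrow = length(s))
  }
  m <- as.matrix(s)
  assert_prob(m, "samples")
  m
}

sample_ids <- function(s) {
  if (inherits(s, "predictive_samples")) s$instance_ids
  else paste0("i", seq_len(nrow(as_sample_matrix(s))))
}

#' Read and write predictive sample sets as long-form CSV
#'
#' The on-disk schema is one row per draw with columns
#' `instance_id,sample_index,prob`. The reader validates that every
#' probability lies in `[0, 1]` (reporting the offending file line) and that
#' every instance has the same number of draws.
#'
#' @param path file path.
#' @param source source tag to attach to the object read.
#' @return `read_predictive_samples()` returns a [predictive_samples] object;
#'   `write_predictive_samples()` returns `path` invisibly.
#' @export
read_predictive_samples <- function(path, source = "external") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("instance_id", "sample_index", "prob")
  if (!all(need %in% names(df))) {
    stop(sprintf("samples file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$prob) | df$prob < 0 | df$prob > 1)
  if (length(bad)) {
    stop(sprintf("samples file '%s': prob outside [0, 1] at line %d",
                 path, bad[1L] + 1L), call. = FALSE)  # +1 for the header line
  }
  ids <- unique(df$instance_id)
  rows <- split(seq_len(nrow(df)), factor(df$instance_id, levels = ids))
  counts <- lengths(rows)
  if (length(unique(counts)) != 1L) {
    stop(sprintf(
      "samples file '%s' is not rectangular: draw counts range from %d to %d",
      path, min(counts), max(counts)), call. = FALSE)
  }
  mat <- t(vapply(rows, function(r) {
    df$prob[r][order(df$sample_index[r])]
  }, numeric(counts[1L])))
  if (counts[1L] == 1L) mat <- matrix(mat, ncol = 1L)  # t() drops shape
  predictive_samples(mat, instance_ids = ids, source = source)
}

#' @rdname read_predictive_samples
#' @param s a [predictive_samples] object.
#' @export
write_predictive_samples <- function(s, path) {
  m <- as_sample_matrix(s)
  df <- data.frame(
    instance_id = rep(sample_ids(s), each = ncol(m)),
    sample_index = rep(seq_len(ncol(m)), times = nrow(m)),
    prob = as.vector(t(m))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
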