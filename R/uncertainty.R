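#' Binary entropy in bits
#'
#' \eqn{H(p) = -p \log_2 p - (1-p) \log_2 (1-p)}, with the continuity
#' convention \eqn{0 \log 0 = 0}. Entropies throughout the package are in
#' bits (base-2 logarithm) so the maximum binary entropy is exactly 1.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return Entropy values in bits, same shape as `p`.
#' @examples
#' binary_entropy(c(0, 0.25, 0.5, 1))
#' @export
binary_entropy <- function(p) {
  assert_prob(p, "p")
  q <- 1 - p
  term <- function(x) ifelse(x > 0, -x * log2(x), 0)
  out <- term(p) + term(q)
  dim(out) <- dim(p)
  out
}

#' Per-instance predictive mean
#'
#' Arithmetic mean of the Monte-Carlo draws of the positive-class
#' probability: the ensembled prediction.
#'
#' @param s a [predictive_samples] object (or a probability matrix,
#'   instances x draws).
#' @return Numeric vector of probabilities, one per instance.
#' @export
predictive_mean <- function(s) {
  rowMeans(as_sample_matrix(s))
}

#' Uncertainty metrics from Monte-Carlo predictive samples
#'
#' Four standard uncertainty measures for binary classification, all computed
#' from the draw matrix of a [predictive_samples] object:
#'
#' * `predictive_entropy()` (PE): entropy of the mean prediction,
#'   \eqn{H(\bar p)}; measures closeness of the ensembled prediction to the
#'   0.5 decision threshold.
#' * `expected_entropy()` (EE): mean over draws of the per-draw entropy,
#'   \eqn{\frac{1}{T}\sum_t H(p_t)}; an aleatoric-uncertainty proxy.
#' * `mutual_information()` (MI): `PE - EE`, the spread between draws
#'   (epistemic proxy; the BALD score). Non-negative by concavity of the
#'   entropy; values in `(-1e-12, 0)` arising from floating-point noise are
#'   clamped to zero, anything more negative raises an internal error.
#' * `variation_ratio()` (VR): harden each draw at `threshold` and report the
#'   fraction of draws outside the modal class; lies in `[0, 0.5]` for binary
#'   labels, with an even draw count and an exact tie giving 0.5.
#'
#' @param s a [predictive_samples] object (or probability matrix).
#' @param threshold hardening threshold for `variation_ratio()`; a draw is
#'   counted as class 1 when `sample >= threshold`.
#' @return Numeric vector with one value per instance (bits for the entropy
#'   measures, a fraction for VR).
#' @seealso [variance_decomposition()], [uncertainty_report()]
#' @examples
#' s <- predictive_samples(matrix(c(0.25, 0.75), 1, 2))
#' predictive_entropy(s)   # 1 bit: the mean is 0.5
#' expected_entropy(s)     # 0.811... bits
#' mutual_information(s)   # 0.188... bits
#' variation_ratio(s)      # 0.5: one draw on each side
#' @export
predictive_entropy <- function(s) {
  binary_entropy(predictive_mean(s))
}

#' @rdname predictive_entropy
#' @export
expected_entropy <- function(s) {
  rowMeans(binary_entropy(as_sample_matrix(s)))
}

#' @rdname predictive_entropy
#' @export
mutual_information <- function(s) {
  mi <- predictive_entropy(s) - expected_entropy(s)
  tiny <- mi < 0 & mi > -1e-12
  mi[tiny] <- 0
  if (any(mi < 0)) {
    stop(sprintf(
      "internal error: mutual information %.3e below the floating-point floor",
      min(mi)), call. = FALSE)
  }
  mi
}

#' @rdname predictive_entropy
#' @export
variation_ratio <- function(s, threshold = 0.5) {
  assert_rate(threshold, "threshold")
  m <- as_sample_matrix(s)
  t_draws <- ncol(m)
  n1 <- rowSums(m >= threshold)
  1 - pmax(n1, t_draws - n1) / t_draws
}

#' Law-of-total-variance decomposition of a Bernoulli prediction
#'
#' For predictive draws \eqn{p_t} with mean \eqn{\bar p}, the predictive
#' variance of the Bernoulli label decomposes into an epistemic part (the
#' variance of the draw means) and an aleatoric part (the mean of the
#' per-draw Bernoulli variances):
#' \deqn{\bar p (1 - \bar p) = \mathrm{Var}_t(p_t) + \mathrm{E}_t[p_t (1 - p_t)].}
#' The epistemic term uses the population variance (divide by `T`, not
#' `T - 1`) so the identity holds exactly.
#'
#' @param s a [predictive_samples] object (or probability matrix).
#' @return A data frame with columns `total_var`, `epistemic_var`,
#'   `aleatoric_var`, one row per instance; all values lie in `[0, 0.25]`.
#' @examples
#' variance_decomposition(predictive_samples(matrix(c(0, 1), 1, 2)))
#' @export
variance_decomposition <- function(s) {
  m <- as_sample_matrix(s)
  pbar <- rowMeans(m)
  msq <- rowMeans(m^2)
  epistemic <- pmax(msq - pbar^2, 0)   # population variance over draws
  aleatoric <- pmax(pbar - msq, 0)     # mean of p_t (1 - p_t)
  data.frame(total_var = pbar * (1 - pbar),
             epistemic_var = epistemic,
             aleatoric_var = aleatoric)
}

#' Hard label and confidence from the predictive mean
#'
#' The hard label is 1 when the predictive mean is at least 0.5 (the tie at
#' exactly 0.5 resolves to the positive class, the recall-preferring choice
#' for clinical screening); the confidence is the probability assigned to
#' the predicted class, `max(pbar, 1 - pbar)`.
#'
#' @param s a [predictive_samples] object (or probability matrix).
#' @return A data frame with columns `label` (0/1) and `confidence`.
#' @export
predict_and_confide <- function(s) {
  pbar <- predictive_mean(s)
  data.frame(label = as.integer(pbar >= 0.5),
             confidence = pmax(pbar, 1 - pbar))
}

#' Full per-instance uncertainty report
#'
#' Aggregates every uncertainty quantity the package computes into one data
#' frame: predictive mean, hard label, confidence, the four uncertainty
#' metrics (PE, EE, MI, VR) and the law-of-total-variance decomposition.
#'
#' @param s a [predictive_samples] object (or probability matrix).
#' @return A data frame of class `uncertainty_report` with columns
#'   `instance_id, mean, label, confidence, pe, ee, mi, vr, total_var,
#'   epistemic_var, aleatoric_var`.
#' @examples
#' s <- make_predictive_samples(rbinom(20, 1, 0.5), seed = 1)
#' head(uncertainty_report(s))
#' @export
uncertainty_report <- function(s) {
  pc <- predict_and_confide(s)
  vd <- variance_decomposition(s)
  out <- data.frame(
    instance_id = sample_ids(s),
    mean = predictive_mean(s),
    label = pc$label,
    confidence = pc$confidence,
    pe = predictive_entropy(s),
    ee = expected_entropy(s),
    mi = mutual_information(s),
    vr = variation_ratio(s),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, vd)
  class(out) <- c("uncertainty_report", "data.frame")
  out
}

report_columns <- c("instance_id", "mean", "label", "confidence", "pe", "ee",
                    "mi", "vr", "total_var", "epistemic_var", "aleatoric_var")

#' Read and write uncertainty reports as CSV
#'
#' One row per instance, columns exactly
#' `instance_id,mean,label,confidence,pe,ee,mi,vr,total_var,epistemic_var,aleatoric_var`.
#'
#' @param report an `uncertainty_report` data frame.
#' @param path file path.
#' @return `read_uncertainty_report()` returns the report data frame;
#'   `write_uncertainty_report()` returns `path` invisibly.
#' @export
write_uncertainty_report <- function(report, path) {
  stopifnot(all(report_columns %in% names(report)))
  utils::write.csv(report[report_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_uncertainty_report
#' @export
read_uncertainty_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(report_columns %in% names(df))) {
    stop(sprintf("report file '%s' must have columns %s", path,
                 paste(report_columns, collapse = ",")), call. = FALSE)
  }
  df <- df[report_columns]
  class(df) <- c("uncertainty_report", "data.frame")
  df
}
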