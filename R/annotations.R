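#' Multi-annotator binary label matrices
#'
#' Clinical corpora are often labelled by several independent expert teams,
#' and the experts disagree on "grey cases". An `annotation_matrix` stores,
#' per instance, a vector of binary labels (one per annotator; annotator
#' counts may vary across instances) together with the derived quantities the
#' referral machinery needs: the majority label (used as the ground-truth
#' proxy), the minority label (used as the simulated expert prediction on
#' disagreement cases), and the human uncertainty (the variation ratio of
#' the label vector).
#'
#' @param labels a list with one binary (0/1) vector per instance, each of
#'   length >= 1, or a matrix (instances x annotators) when all counts agree.
#' @param instance_ids optional unique identifiers; defaults to
#'   `"i1", "i2", ...`.
#' @return An object of class `annotation_matrix`.
#' @examples
#' m <- annotation_matrix(list(c(0, 0, 1), c(1, 1, 1)))
#' majority_labels(m)
#' human_uncertainties(m)
#' @export
annotation_matrix <- function(labels, instance_ids = NULL) {
  if (is.matrix(labels)) {
    labels <- lapply(seq_len(nrow(labels)), function(i) labels[i, ])
  }
  if (!is.list(labels) || length(labels) == 0L) {
    stop("`labels` must be a non-empty list of per-instance label vectors",
         call. = FALSE)
  }
  labels <- unname(lapply(labels, function(x) {
    assert_binary(x, "labels")
    as.integer(x)
  }))
  n <- length(labels)
  if (is.null(instance_ids)) instance_ids <- paste0("i", seq_len(n))
  instance_ids <- as.character(instance_ids)
  if (length(instance_ids) != n || anyDuplicated(instance_ids)) {
    stop("`instance_ids` must be unique, one per instance", call. = FALSE)
  }
  structure(list(instance_ids = instance_ids, labels = labels),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  k <- lengths(x$labels)
  cat(sprintf(
    "<annotation_matrix> %d instances, %s annotators each, disagreement rate %.3f\n",
    length(x$labels),
    if (length(unique(k)) == 1L) k[1L] else sprintf("%d-%d", min(k), max(k)),
    disagreement_rate(x)))
  invisible(x)
}

#' Majority, minority and human uncertainty of one label vector
#'
#' `majority_label()` returns the modal label; an exact tie (even annotator
#' count, equal split) resolves to 1, consistently with the package's
#' recall-preferring tie rule. `minority_label()` returns the complement of
#' the majority when any disagreement exists and the unanimous label
#' otherwise; it plays the simulated "junior doctor" prediction in referral
#' evaluation. `human_uncertainty()` is the variation ratio of the label
#' vector, `1 - (mode count) / (annotator count)`, in `[0, 0.5]`.
#'
#' @param labels a binary (0/1) vector with at least one element.
#' @return A single 0/1 label, or a fraction in `[0, 0.5]` for
#'   `human_uncertainty()`.
#' @examples
#' human_uncertainty(c(0, 0, 1))  # 1/3
#' majority_label(c(0, 0, 1))     # 0
#' minority_label(c(0, 0, 1))     # 1
#' @export
human_uncertainty <- function(labels) {
  assert_binary(labels, "labels")
  k <- length(labels)
  n1 <- sum(labels)
  1 - max(n1, k - n1) / k
}

#' @rdname human_uncertainty
#' @export
majority_label <- function(labels) {
  assert_binary(labels, "labels")
  k <- length(labels)
  if (2 * sum(labels) >= k) 1L else 0L   # tie -> 1
}

#' @rdname human_uncertainty
#' @export
minority_label <- function(labels) {
  assert_binary(labels, "labels")
  n1 <- sum(labels)
  if (n1 == 0L || n1 == length(labels)) {
    as.integer(labels[1L])               # unanimous: no minority view
  } else {
    1L - majority_label(labels)
  }
}

#' Per-instance derived quantities of an annotation matrix
#'
#' Vectorised forms of [majority_label()], [minority_label()] and
#' [human_uncertainty()], plus the dataset-level disagreement rate (the
#' fraction of instances with any annotator disagreement).
#'
#' @param m an [annotation_matrix].
#' @return An integer (0/1) or numeric vector with one entry per instance;
#'   `disagreement_rate()` returns a single fraction.
#' @export
majority_labels <- function(m) {
  vapply(m$labels, majority_label, integer(1))
}

#' @rdname majority_labels
#' @export
minority_labels <- function(m) {
  vapply(m$labels, minority_label, integer(1))
}

#' @rdname majority_labels
#' @export
human_uncertainties <- function(m) {
  vapply(m$labels, human_uncertainty, numeric(1))
}

#' @rdname majority_labels
#' @export
disagreement_rate <- function(m) {
  mean(human_uncertainties(m) > 0)
}

#' Simulated expert prediction from multiple annotations
#'
#' Returns the minority label on instances with disagreement and the
#' unanimous label elsewhere. Scored against the majority-label ground
#' truth, this simulated expert is wrong exactly on the disagreement
#' instances, so its accuracy is `1 - disagreement_rate(m)` -- the most
#' pessimistic expert consistent with the annotations (with 10%
#' disagreement, a 90%-accurate expert).
#'
#' @param m an [annotation_matrix].
#' @return Integer vector of 0/1 predictions, one per instance.
#' @export
simulate_human <- function(m) {
  minority_labels(m)
}

#' Read annotations from long-form CSV / write derived summary
#'
#' The input schema is one row per (instance, annotator) with columns
#' `instance_id,annotator_id,label`. The summary writer emits one row per
#' instance with the derived columns `majority,minority,human_uncertainty`.
#'
#' @param path file path.
#' @return `read_annotations()` returns an [annotation_matrix];
#'   `write_annotation_summary()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("instance_id", "annotator_id", "label")
  if (!all(need %in% names(df))) {
    stop(sprintf("annotations file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!df$label %in% c(0, 1))
  if (length(bad)) {
    stop(sprintf("annotations file '%s': non-binary label at line %d",
                 path, bad[1L] + 1L), call. = FALSE)
  }
  ids <- unique(df$instance_id)
  labs <- split(df$label, factor(df$instance_id, levels = ids))
  annotation_matrix(lapply(labs, as.integer), instance_ids = ids)
}

#' @rdname read_annotations
#' @param m an [annotation_matrix].
#' @export
write_annotations <- function(m, path) {
  k <- lengths(m$labels)
  df <- data.frame(
    instance_id = rep(m$instance_ids, times = k),
    annotator_id = unlist(lapply(k, seq_len)),
    label = unlist(m$labels)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_annotations
#' @export
write_annotation_summary <- function(m, path) {
  df <- data.frame(
    instance_id = m$instance_ids,
    majority = majority_labels(m),
    minority = minority_labels(m),
    human_uncertainty = human_uncertainties(m)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Learn to estimate human uncertainty from features (experimental)
#'
#' Fits a shallow linear regressor mapping per-instance features to the
#' annotator-disagreement target (human uncertainty in `[0, 0.5]`).
#' Predictions are clipped back to `[0, 0.5]`. Disagreement is typically
#' rare, so reliable estimation needs enough disagreement-positive
#' instances; below `min_disagreement` of them a warning is raised and
#' recorded in the fit's `log` attribute. This estimator is experimental:
#' on sparse clinical disagreement data it is not expected to produce
#' reliable estimates, and the referral machinery uses the ground-truth
#' disagreement instead.
#'
#' @param features data frame or matrix of per-instance features.
#' @param targets numeric vector of human uncertainties in `[0, 0.5]`.
#' @param min_disagreement minimum number of `targets > 0` instances below
#'   which the sparse-data warning is recorded.
#' @return An object of class `disagreement_predictor`.
#' @seealso [predict_disagreement()]
#' @export
fit_disagreement_predictor <- function(features, targets,
                                       min_disagreement = 10L) {
  features <- as.data.frame(features)
  if (nrow(features) != length(targets)) {
    stop("`features` and `targets` must be aligned", call. = FALSE)
  }
  if (any(targets < 0 | targets > 0.5)) {
    stop("`targets` must lie in [0, 0.5]", call. = FALSE)
  }
  log_msgs <- character()
  n_pos <- sum(targets > 0)
  if (n_pos < min_disagreement) {
    msg <- sprintf(
      "only %d disagreement-positive instances (< %d): estimates are unlikely to be reliable",
      n_pos, min_disagreement)
    warning(msg, call. = FALSE)
    log_msgs <- c(log_msgs, msg)
  }
  dat <- cbind(.target = targets, features)
  fit <- stats::lm(.target ~ ., data = dat)
  structure(list(fit = fit, n_disagreement = n_pos, log = log_msgs),
            class = "disagreement_predictor")
}

#' Predict human uncertainty for new instances
#'
#' @param predictor a fit from [fit_disagreement_predictor()].
#' @param features data frame or matrix of features, same columns as used
#'   in fitting.
#' @return Estimated human uncertainties, clipped to `[0, 0.5]`.
#' @export
predict_disagreement <- function(predictor, features) {
  stopifnot(inherits(predictor, "disagreement_predictor"))
  p <- stats::predict(predictor$fit, newdata = as.data.frame(features))
  pmin(pmax(unname(p), 0), 0.5)
}
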