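#' Referral policies
#'
#' A referral policy decides which instances a model hands to the human
#' expert:
#'
#' * `"model_uncertainty"` -- refer the instances of highest model
#'   uncertainty (the single-label strategy);
#' * `"model_minus_human"` -- refer instances of high model uncertainty
#'   minus `alpha` times human uncertainty: the human takes the cases the
#'   model is unsure about but the annotators agreed on, while the model
#'   keeps the grey cases;
#' * `"model_plus_human"` -- the variant where the human also takes the
#'   grey cases (high model *plus* human uncertainty);
#' * `"random"` -- refer a seeded random subset (baseline);
#' * `"optimal"` -- refer misclassified instances first. This requires the
#'   ground-truth labels and is a theoretical upper bound, not a deployable
#'   strategy; every output derived from it is tagged accordingly.
#'
#' The model uncertainty metric defaults to predictive entropy for the
#' single-label strategy. For the combined strategies it defaults to the
#' variation ratio so that the model and human uncertainties share the
#' `[0, 0.5]` scale of VR (human uncertainty *is* a VR); mixing an entropy
#' metric with human VR is allowed but then `alpha` carries the scale
#' conversion and must be chosen explicitly.
#'
#' @param strategy referral strategy.
#' @param metric model-uncertainty metric (`"pe"`, `"ee"`, `"mi"`, `"vr"`);
#'   default `"pe"`, or `"vr"` for the combined strategies.
#' @param alpha non-negative weight on human uncertainty.
#' @param rates referral-rate grid, sorted, within `[0, 1]`.
#' @param seed seed for the `"random"` strategy.
#' @return An object of class `referral_policy`.
#' @export
referral_policy <- function(strategy = c("model_uncertainty",
                                         "model_minus_human",
                                         "model_plus_human",
                                         "random", "optimal"),
                            metric = NULL, alpha = 1,
                            rates = seq(0, 0.95, by = 0.05), seed = 1L) {
  strategy <- match.arg(strategy)
  if (is.null(metric)) {
    metric <- if (strategy %in% c("model_minus_human", "model_plus_human"))
      "vr" else "pe"
  }
  metric <- match.arg(metric, c("pe", "ee", "mi", "vr"))
  if (alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
  if (any(rates < 0 | rates > 1)) {
    stop("`rates` must lie within [0, 1]", call. = FALSE)
  }
  if (is.unsorted(rates)) stop("`rates` must be sorted", call. = FALSE)
  structure(list(strategy = strategy, metric = metric, alpha = alpha,
                 rates = rates, seed = seed),
            class = "referral_policy")
}

#' Combined model/human referral score
#'
#' `u_model - alpha * u_human` (variant `"minus"`), or
#' `u_model + alpha * u_human` (variant `"plus"`). With `alpha = 0` both
#' reduce to the single-label model-uncertainty score.
#'
#' @param u_model per-instance model uncertainty.
#' @param u_human per-instance human uncertainty (annotator VR).
#' @param alpha non-negative weight on the human term.
#' @param variant `"minus"` or `"plus"`.
#' @return Numeric referral scores (higher = referred earlier).
#' @export
multi_label_score <- function(u_model, u_human, alpha = 1,
                              variant = c("minus", "plus")) {
  variant <- match.arg(variant)
  if (length(u_model) != length(u_human)) {
    stop("`u_model` and `u_human` must be aligned", call. = FALSE)
  }
  if (alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
  if (variant == "minus") u_model - alpha * u_human
  else u_model + alpha * u_human
}

# Per-instance referral scores for a policy. `report` supplies the model
# uncertainty; `human_unc` the annotator VR; `truth` the oracle labels.
policy_scores <- function(policy, report = NULL, human_unc = NULL,
                          truth = NULL, n = NULL) {
  switch(policy$strategy,
    model_uncertainty = {
      if (is.null(report)) stop("this strategy needs an uncertainty report",
                                call. = FALSE)
      report[[policy$metric]]
    },
    model_minus_human = ,
    model_plus_human = {
      if (is.null(report)) stop("this strategy needs an uncertainty report",
                                call. = FALSE)
      if (is.null(human_unc)) {
        stop(sprintf(
          "strategy '%s' requires human uncertainty from a multi-annotator matrix",
          policy$strategy), call. = FALSE)
      }
      multi_label_score(report[[policy$metric]], human_unc, policy$alpha,
                        if (policy$strategy == "model_minus_human") "minus"
                        else "plus")
    },
    random = {
      n <- n %||% nrow(report)
      if (is.null(n)) stop("the random strategy needs the instance count",
                           call. = FALSE)
      with_seed(policy$seed, stats::runif(n))
    },
    optimal = {
      if (is.null(truth)) {
        stop(paste("the optimal policy requires ground-truth labels;",
                   "it is a theoretical upper bound"), call. = FALSE)
      }
      if (is.null(report)) stop("the optimal policy needs the model labels",
                                call. = FALSE)
      as.numeric(report$label != truth)
    })
}

#' Referral ordering from per-instance scores
#'
#' Orders instances by descending score; ties are broken by ascending
#' instance index, so the ordering is deterministic.
#'
#' @param scores per-instance referral scores.
#' @return Integer permutation: the first element is referred first.
#' @examples
#' rank_for_referral(c(a = 0.9, b = 0.1, c = 0.9))  # 1, 3, 2
#' @export
rank_for_referral <- function(scores) {
  order(-scores, seq_along(scores))
}

# Number of instances referred at `rate` out of `n`, rounding half away
# from zero (rate 0.25 of 10 instances refers 3).
n_referred_at <- function(rate, n) {
  min(n, as.integer(round_half_away(rate * n)))
}

#' Split instances into referred and retained sets
#'
#' Computes the policy's per-instance scores, orders them, and refers the
#' top `round(rate * N)` instances (rounding half away from zero). Referred
#' and retained always partition the instance set.
#'
#' @param report an [uncertainty_report()] for the instances.
#' @param policy a [referral_policy()].
#' @param rate referral rate in `[0, 1]`.
#' @param annotations optional [annotation_matrix] (required by the
#'   combined strategies, which use its human uncertainty).
#' @param truth optional ground truth (required by the `"optimal"` policy).
#' @return A list with integer index vectors `referred` and `retained` and
#'   the corresponding `referred_ids` / `retained_ids`.
#' @export
refer <- function(report, policy, rate, annotations = NULL, truth = NULL) {
  assert_rate(rate, "rate")
  human_unc <- if (!is.null(annotations)) human_uncertainties(annotations)
  scores <- policy_scores(policy, report = report, human_unc = human_unc,
                          truth = truth, n = nrow(report))
  ord <- rank_for_referral(scores)
  k <- n_referred_at(rate, nrow(report))
  referred <- if (k > 0L) ord[seq_len(k)] else integer(0)
  retained <- if (k < nrow(report)) ord[seq.int(k + 1L, nrow(report))]
              else integer(0)
  list(referred = sort(referred), retained = sort(retained),
       referred_ids = report$instance_id[sort(referred)],
       retained_ids = report$instance_id[sort(retained)])
}

curve_row <- function(rate, k, mode, metrics) {
  data.frame(rate = rate, n_referred = k, mode = mode,
             accuracy = metrics$accuracy, f1 = metrics$f1,
             roc_auc = metrics$roc_auc, precision = metrics$precision,
             recall = metrics$recall)
}

empty_metrics <- list(accuracy = NA_real_, f1 = NA_real_,
                      roc_auc = NA_real_, precision = NA_real_,
                      recall = NA_real_, flags = character())

finish_curve <- function(rows, policy, mode, log) {
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  attr(curve, "policy") <- policy
  attr(curve, "mode") <- mode
  attr(curve, "log") <- log
  if (policy$strategy == "optimal") {
    attr(curve, "note") <-
      "optimal policy: theoretical upper bound (uses ground-truth labels)"
  }
  class(curve) <- c("referral_curve", "data.frame")
  curve
}

#' Referral curve, non-referred evaluation
#'
#' For every rate on the policy grid, refers the top fraction of the
#' ordering and evaluates the *model's* predictions on the retained
#' (non-referred) instances only -- the single-label evaluation mode, which
#' assumes the human handles referred cases perfectly and so measures how
#' well the uncertainty ordering concentrates the model's mistakes. At
#' rate 1 the retained set is empty and all metrics are reported missing.
#' ROC-AUC is reported missing (with the reason logged on the `"log"`
#' attribute) whenever the retained set contains a single class, the
#' pathology that produces sharp ROC-AUC declines at high referral rates.
#'
#' @param report an [uncertainty_report()].
#' @param truth ground-truth 0/1 labels, aligned with the report.
#' @param policy a [referral_policy()].
#' @return A data frame of class `referral_curve` with columns
#'   `rate, n_referred, mode, accuracy, f1, roc_auc, precision, recall`,
#'   one row per grid rate; the policy is attached as an attribute.
#' @export
referral_curve_non_referred <- function(report, truth, policy) {
  assert_binary(truth, "truth")
  stopifnot(nrow(report) == length(truth))
  log <- character()
  rows <- lapply(policy$rates, function(rate) {
    sel <- refer(report, policy, rate, truth = truth)
    if (length(sel$retained) == 0L) {
      log <<- c(log, sprintf("rate %.2f: empty retained set, metrics missing",
                             rate))
      return(curve_row(rate, length(sel$referred), "non_referred",
                       empty_metrics))
    }
    idx <- sel$retained
    m <- classification_metrics(report$label[idx], truth[idx],
                                probs = report$mean[idx])
    if (is.na(m$roc_auc)) {
      log <<- c(log, sprintf("rate %.2f: ROC-AUC undefined (%s)", rate,
                             m$flags[grepl("ROC-AUC", m$flags)][1] %||%
                               "degenerate retained set"))
    }
    curve_row(rate, length(sel$referred), "non_referred", m)
  })
  finish_curve(rows, policy, "non_referred", log)
}

#' Referral curve, dataset-level evaluation
#'
#' The multiple-labels evaluation mode: the model is evaluated on the
#' non-referred portion and the simulated human on the referred portion,
#' jointly against the majority-label ground truth. The human prediction is
#' the minority label on disagreement instances (a pessimistic
#' `1 - disagreement_rate`-accurate expert) and the unanimous label
#' elsewhere; human predictions on non-referred instances are never
#' consulted (triage semantics). For ROC-AUC the human predictions enter
#' as degenerate probabilities 0/1.
#'
#' @param report an [uncertainty_report()].
#' @param annotations an [annotation_matrix] aligned with the report; its
#'   majority labels are the ground truth.
#' @param policy a [referral_policy()].
#' @return A `referral_curve` data frame (see
#'   [referral_curve_non_referred()]), mode `"dataset_level"`.
#' @export
referral_curve_dataset_level <- function(report, annotations, policy) {
  stopifnot(inherits(annotations, "annotation_matrix"),
            nrow(report) == length(annotations$labels))
  truth <- majority_labels(annotations)
  human <- simulate_human(annotations)
  log <- character()
  rows <- lapply(policy$rates, function(rate) {
    sel <- refer(report, policy, rate, annotations = annotations,
                 truth = truth)
    labels <- report$label
    probs <- report$mean
    labels[sel$referred] <- human[sel$referred]
    probs[sel$referred] <- human[sel$referred]
    m <- classification_metrics(labels, truth, probs = probs)
    if (is.na(m$roc_auc)) {
      log <<- c(log, sprintf("rate %.2f: ROC-AUC undefined", rate))
    }
    curve_row(rate, length(sel$referred), "dataset_level", m)
  })
  finish_curve(rows, policy, "dataset_level", log)
}

#' Write a referral curve as CSV plus a JSON policy sidecar
#'
#' @param curve a `referral_curve` data frame.
#' @param path CSV output path.
#' @param json_path optional sidecar path for the policy metadata; defaults
#'   to `path` with a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_referral_curve <- function(curve, path, json_path = NULL) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  json_path <- json_path %||% sub("\\.csv$", ".json", path)
  pol <- attr(curve, "policy")
  meta <- list(strategy = pol$strategy, metric = pol$metric,
               alpha = pol$alpha, rates = pol$rates, seed = pol$seed,
               mode = attr(curve, "mode"),
               note = attr(curve, "note"),
               log = attr(curve, "log"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))], json_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a referral curve written by [write_referral_curve()]
#'
#' @param path CSV path.
#' @return A `referral_curve` data frame (without the policy attribute).
#' @export
read_referral_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("referral_curve", "data.frame")
  df
}
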