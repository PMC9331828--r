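#' Repeated train/test classification benchmark
#'
#' Mirrors the screening study's evaluation design: positives (confirmed or
#' planted FCS patients) against negatives drawn either from high rubric
#' scorers or at random from the background population, a stratified 50/50
#' train/test split repeated over seeded experiments, and AUC / accuracy /
#' sensitivity / specificity summarized by mean and standard deviation.
#'
#' @name ml_benchmark
NULL

#' Stratified train/test split of positives and negatives
#'
#' @param positives,negatives Disjoint vectors of patient ids (each with at
#'   least 2 members so both halves can contain both classes).
#' @param negative_mode How the negatives were selected
#'   (`"random_background"` or `"high_scorers"`); recorded on the result,
#'   the split itself is identical.
#' @param split_fraction Fraction assigned to the training half, per class.
#'   Default 0.5.
#' @param seed Split seed; identical seeds give identical splits.
#' @return List with `train` and `test`, each a list of `ids` and `labels`
#'   (1 positive / 0 negative), plus the recorded `negative_mode`.
#' @export
make_training_sets <- function(positives, negatives,
                               negative_mode = c("random_background",
                                                 "high_scorers"),
                               split_fraction = 0.5, seed = 0L) {
  negative_mode <- match.arg(negative_mode)
  if (length(positives) < 2L || length(negatives) < 2L)
    stop("need at least 2 members per class to stratify", call. = FALSE)
  if (length(intersect(positives, negatives)))
    stop("positives and negatives must be disjoint", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)", call. = FALSE)
  pick <- .with_seed(seed, function() {
    np <- max(1L, min(length(positives) - 1L,
                      round(split_fraction * length(positives))))
    nn <- max(1L, min(length(negatives) - 1L,
                      round(split_fraction * length(negatives))))
    list(pos = sample(positives, np), neg = sample(negatives, nn))
  })
  train_ids <- c(pick$pos, pick$neg)
  test_ids <- c(setdiff(positives, pick$pos), setdiff(negatives, pick$neg))
  list(
    train = list(ids = train_ids,
                 labels = as.numeric(train_ids %in% positives)),
    test = list(ids = test_ids,
                labels = as.numeric(test_ids %in% positives)),
    negative_mode = negative_mode)
}

#' Classification metrics from decision scores
#'
#' AUC follows the pair-counting definition (probability that a positive
#' outscores a negative, ties counted one half), computed via rank sums.
#' Sensitivity, specificity and accuracy are evaluated at the given score
#' threshold.
#'
#' @param scores Numeric decision values (probability-like by convention).
#' @param labels Binary 0/1 labels, same length.
#' @param threshold Decision threshold; default 0.5.
#' @return List with `auc`, `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length", call. = FALSE)
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  list(auc = auc,
       accuracy = (tp + tn) / length(labels),
       sensitivity = tp / n1,
       specificity = tn / n0)
}

.fit_method <- function(method, X, y, seed) {
  switch(method,
         gradient_boost = fit_gradient_boost(X, y, seed = seed),
         adaboost = fit_adaboost(X, y, seed = seed),
         svm = fit_kernel_machine(X, y, seed = seed),
         relu_net = fit_relu_net(X, y, seed = seed),
         stop("unknown method: ", method, call. = FALSE))
}

#' Run the repeated train/test benchmark for one method
#'
#' Experiment `i` uses seed `base_seed + i` for its split (and for any
#' method-internal randomness), fits on the training half, scores the test
#' half and computes [evaluate_scores()]; metric means and population
#' standard deviations over the experiments are returned.
#'
#' @param features Data frame or matrix of features with a `patient_id`
#'   column or rownames identifying patients.
#' @param labels Named binary vector (1 = FCS) covering all feature rows,
#'   or unnamed vector aligned with them.
#' @param method One of `"gradient_boost"`, `"adaboost"`, `"svm"`,
#'   `"relu_net"`.
#' @param n_experiments Number of repeated splits. Default 30.
#' @param split_fraction Training fraction. Default 0.5.
#' @param base_seed Base seed; experiment i uses `base_seed + i`.
#' @param threshold Decision threshold for the thresholded metrics.
#' @return An `eval_summary`: method, n_experiments, `mean_*` and `std_*`
#'   for auc/accuracy/sensitivity/specificity, the per-experiment metric
#'   table, and (for tree methods) the fitted ensembles in `models`.
#' @export
run_benchmark <- function(features, labels, method = c("gradient_boost",
                                                       "adaboost", "svm",
                                                       "relu_net"),
                          n_experiments = 30L, split_fraction = 0.5,
                          base_seed = 0L, threshold = 0.5) {
  method <- match.arg(method)
  features <- as.data.frame(features)
  if ("patient_id" %in% names(features)) {
    ids <- features$patient_id
    X <- as.matrix(features[, setdiff(names(features), "patient_id"),
                            drop = FALSE])
  } else {
    ids <- rownames(features)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
    X <- as.matrix(features)
  }
  rownames(X) <- ids
  if (!is.null(names(labels))) labels <- labels[ids]
  labels <- as.numeric(labels)
  if (anyNA(labels)) stop("labels missing for some patients", call. = FALSE)
  positives <- ids[labels == 1]
  negatives <- ids[labels == 0]

  metrics <- vector("list", n_experiments)
  models <- list()
  keep_models <- method %in% c("gradient_boost", "adaboost")
  for (i in seq_len(n_experiments)) {
    seed_i <- base_seed + i
    sets <- make_training_sets(positives, negatives,
                               split_fraction = split_fraction,
                               seed = seed_i)
    fit <- .fit_method(method, X[sets$train$ids, , drop = FALSE],
                       sets$train$labels, seed_i)
    p <- predict(fit, X[sets$test$ids, , drop = FALSE])
    metrics[[i]] <- evaluate_scores(p, sets$test$labels, threshold)
    if (keep_models) models[[i]] <- fit
  }
  mt <- do.call(rbind, lapply(metrics, as.data.frame))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- list(method = method, n_experiments = n_experiments,
              experiments = mt)
  for (m in c("auc", "accuracy", "sensitivity", "specificity")) {
    out[[paste0("mean_", m)]] <- mean(mt[[m]])
    out[[paste0("std_", m)]] <- pop_sd(mt[[m]])
  }
  if (keep_models) out$models <- models
  class(out) <- "eval_summary"
  out
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "<eval_summary> %s | Exp. %d | AUC %.3f (sd %.3f) | ACC %.3f (sd %.3f)\n",
    x$method, x$n_experiments, x$mean_auc, x$std_auc, x$mean_accuracy,
    x$std_accuracy))
  cat(sprintf("  sens %.3f (sd %.3f) | spec %.3f (sd %.3f)\n",
              x$mean_sensitivity, x$std_sensitivity, x$mean_specificity,
              x$std_specificity))
  invisible(x)
}

.tree_tables <- function(models) {
  if (inherits(models, c("fcs_gb", "fcs_ada"))) models <- list(models)
  if (inherits(models, "eval_summary")) models <- models$models
  unlist(lapply(models, function(m) m$trees), recursive = FALSE)
}

#' Assemble the default benchmark dataset from a synthetic cohort
#'
#' Positives are the planted FCS patients; negatives a seeded random sample
#' of the background stratum (class imbalance is left as sampled, mirroring
#' the screening study's "random individuals" design).
#'
#' @param cohort An `fcs_cohort` from [generate_cohort()].
#' @param n_negatives Background patients to sample. Default 100.
#' @param seed Seed for the negative sampling.
#' @param cfg An [fcs_config()] for the ICD feature groups.
#' @return List with `features` (data.table incl. `patient_id`), `labels`
#'   (named 0/1 vector), `positives`, `negatives`.
#' @export
benchmark_dataset <- function(cohort, n_negatives = 100L, seed = 0L,
                              cfg = fcs_config()) {
  feats <- build_feature_matrix(cohort$labs, cohort$diagnoses,
                                cohort$roster, cfg)
  pos <- cohort$truth$patient_id[cohort$truth$stratum == "FCS"]
  bg <- cohort$truth$patient_id[cohort$truth$stratum == "background"]
  neg <- .with_seed(seed, function()
    sample(bg, min(n_negatives, length(bg))))
  keep <- c(pos, neg)
  list(features = feats[match(keep, feats$patient_id), ],
       labels = stats::setNames(as.numeric(keep %in% pos), keep),
       positives = pos, negatives = neg)
}

#' Depth-weighted feature importance of tree ensembles
#'
#' Every split occurrence contributes `1 / (1 + depth)` (root splits weigh
#' 1) summed over all trees of all supplied ensembles; sums are rescaled so
#' the top feature is 100 and sorted descending (ties broken by feature
#' name).
#'
#' @param models A fitted `fcs_gb`/`fcs_ada` model, an `eval_summary`
#'   holding such models, or a list of any of these.
#' @return Data frame with `feature` and `importance` in `[0, 100]`
#'   (empty if no ensemble contains a split).
#' @export
rank_feature_importance <- function(models) {
  trees <- .tree_tables(models)
  if (!length(trees))
    return(data.frame(feature = character(), importance = numeric()))
  splits <- data.table::rbindlist(trees)[!is.na(feature)]
  if (!nrow(splits))
    return(data.frame(feature = character(), importance = numeric()))
  splits[, weight := 1 / (1 + depth)]
  imp <- splits[, list(importance = sum(weight)), by = "feature"]
  imp[, importance := 100 * importance / max(importance)]
  data.table::setorder(imp, -importance, feature)
  as.data.frame(imp)
}

#' Extract decision cuts from the first trees of a boosted ensemble
#'
#' Boosting learns its strongest structure first, so the early trees hold
#' the clinically readable cuts. Every split of the first `k_first_trees`
#' trees is emitted as (feature, threshold in canonical units, direction):
#' `"+"` when the high side of the cut carries the higher cover-weighted
#' mean leaf value (i.e. pushes toward FCS), `"-"` otherwise. Duplicate
#' (feature, threshold) pairs keep the earliest occurrence.
#'
#' @param model A fitted `fcs_gb` or `fcs_ada` model (or `eval_summary`
#'   whose first stored model is used).
#' @param k_first_trees Number of leading trees to read. Default 5.
#' @return Data frame with `feature`, `cut`, `direction`, `tree` (1-based
#'   index of the originating tree); empty if there are no splits.
#' @export
extract_decision_cuts <- function(model, k_first_trees = 5L) {
  if (inherits(model, "eval_summary")) model <- model$models[[1]]
  trees <- utils::head(model$trees, k_first_trees)
  rows <- list()
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    split_ids <- which(!is.na(tr$feature))
    for (s in split_ids) {
      branch_mean <- function(root) {
        ids <- root
        leaves <- c()
        while (length(ids)) {
          nd <- ids[1]; ids <- ids[-1]
          if (is.na(tr$feature[nd])) leaves <- c(leaves, nd)
          else ids <- c(ids, tr$left[nd], tr$right[nd])
        }
        sum(tr$value[leaves] * tr$cover[leaves]) /
          max(sum(tr$cover[leaves]), 1e-12)
      }
      hi <- branch_mean(tr$right[s])
      lo <- branch_mean(tr$left[s])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = tr$feature[s], cut = tr$threshold[s],
        direction = if (hi > lo) "+" else "-", tree = ti,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(feature = character(), cut = numeric(),
                      direction = character(), tree = integer()))
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("feature", "cut")]), , drop = FALSE]
}
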