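cfg <- fcs_config()

test_that("feature vector aggregates are exact and missingness explicit", {
  h <- patient_history("P1", birth_year = 1980L,
    labs = data.frame(date = as.Date("2010-01-01") + 0:2, analyte = "TG",
                      value = c(2, 4, 6), fasting = TRUE))
  fv <- build_feature_vector(h, cfg, analytes = c("TG", "AMYL"))
  expect_equal(fv$TG_highest, 6)
  expect_equal(fv$TG_lowest, 2)
  expect_equal(fv$TG_average, 4)
  expect_equal(fv$TG_fluctuation, 2)       # sample sd of 2,4,6
  expect_equal(fv$TG_count, 3)
  expect_true(is.na(fv$AMYL_highest))      # never measured
  expect_equal(fv$AMYL_count, 0)

  h1 <- patient_history("P2", labs = data.frame(
    date = as.Date("2010-01-01"), analyte = "TG", value = 5,
    fasting = TRUE))
  fv1 <- build_feature_vector(h1, cfg, analytes = "TG")
  expect_equal(fv1$TG_highest, 5)
  expect_equal(fv1$TG_lowest, 5)
  expect_true(is.na(fv1$TG_fluctuation))   # undefined below 2 values
})

test_that("feature matrix satisfies ordering invariants and ICD flags", {
  co <- generate_cohort(cohort_spec(300, fcs_fraction = 0.03, seed = 2))
  fm <- build_feature_matrix(co$labs, co$diagnoses, co$roster, cfg)
  expect_equal(fm$patient_id, co$roster$patient_id)
  for (a in c("TG", "GGT")) {
    hi <- fm[[paste0(a, "_highest")]]
    lo <- fm[[paste0(a, "_lowest")]]
    av <- fm[[paste0(a, "_average")]]
    fl <- fm[[paste0(a, "_fluctuation")]]
    ok <- !is.na(hi)
    expect_true(all(hi[ok] >= av[ok] & av[ok] >= lo[ok]))
    expect_true(all(fl[!is.na(fl)] >= 0))
  }
  expect_true(all(fm$icd_pancreatitis %in% c(0, 1)))
  panc_ids <- unique(co$diagnoses$patient_id[
    startsWith(co$diagnoses$icd10, "K85")])
  expect_equal(fm$patient_id[fm$icd_pancreatitis == 1],
               sort(panc_ids))
})

test_that("make_training_sets: stratified, disjoint, seeded", {
  pos <- sprintf("p%02d", 1:20)
  neg <- sprintf("n%03d", 1:100)
  s1 <- make_training_sets(pos, neg, split_fraction = 0.5, seed = 3)
  expect_equal(sum(s1$train$labels), 10)
  expect_equal(length(s1$train$ids), 60)
  expect_equal(length(s1$test$ids), 60)
  expect_length(intersect(s1$train$ids, s1$test$ids), 0)
  expect_setequal(c(s1$train$ids, s1$test$ids), c(pos, neg))
  s2 <- make_training_sets(pos, neg, split_fraction = 0.5, seed = 3)
  expect_identical(s1, s2)
  s3 <- make_training_sets(pos, neg, split_fraction = 0.5, seed = 4)
  expect_false(identical(s1$train$ids, s3$train$ids))
  expect_error(make_training_sets("p1", neg), "at least 2")
  expect_error(make_training_sets(pos, c(pos[1], neg)), "disjoint")
})

test_that("evaluate_scores matches hand-derived values", {
  m <- evaluate_scores(c(0.9, 0.8, 0.1), c(1, 0, 0))
  expect_equal(m$auc, 1.0)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 2 / 3)
  expect_equal(evaluate_scores(c(0.2, 0.9), c(1, 0))$auc, 0)
  expect_equal(evaluate_scores(rep(0.4, 6), c(1, 1, 0, 0, 0, 1))$auc, 0.5)
  expect_error(evaluate_scores(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC equals the pair-counting oracle on random instances", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_equal(evaluate_scores(scores, labels)$auc,
                 oracle_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(7)
  for (i in 1:20) {
    labels <- c(0, 1, sample(0:1, 10, replace = TRUE))
    scores <- runif(12)
    a0 <- evaluate_scores(scores, labels)$auc
    expect_equal(evaluate_scores(exp(3 * scores), labels)$auc, a0)
    expect_equal(evaluate_scores(rank(scores), labels)$auc, a0)
  }
})

# small, clearly separable synthetic features for learner tests
separable_features <- function(n_pos = 12, n_neg = 48, seed = 1) {
  set.seed(seed)
  X <- cbind(TG_highest = c(rnorm(n_pos, 25, 4), rnorm(n_neg, 3, 1.2)),
             TG_average = c(rnorm(n_pos, 15, 3), rnorm(n_neg, 1.5, 0.5)),
             noise1 = rnorm(n_pos + n_neg),
             noise2 = rnorm(n_pos + n_neg))
  rownames(X) <- sprintf("S%03d", seq_len(n_pos + n_neg))
  list(X = X, y = stats::setNames(rep(c(1, 0), c(n_pos, n_neg)),
                                  rownames(X)))
}

test_that("boosted trees ace a separable problem; one experiment has sd 0", {
  sf <- separable_features()
  s <- run_benchmark(sf$X, sf$y, "gradient_boost", n_experiments = 5,
                     base_seed = 0)
  expect_gte(s$mean_auc, 0.99)
  s1 <- run_benchmark(sf$X, sf$y, "adaboost", n_experiments = 1,
                      base_seed = 0)
  expect_equal(s1$std_auc, 0)
  expect_equal(s1$std_accuracy, 0)
  expect_equal(s1$n_experiments, 1L)
})

test_that("label permutation drives AUC to chance", {
  sf <- separable_features()
  set.seed(123)
  y_perm <- stats::setNames(sample(unname(sf$y)), names(sf$y))
  s <- run_benchmark(sf$X, y_perm, "adaboost", n_experiments = 30,
                     base_seed = 100)
  expect_lt(abs(s$mean_auc - 0.5), 0.15)
})

test_that("kernel machine and network learn the separable problem", {
  sf <- separable_features()
  for (m in c("svm", "relu_net")) {
    s <- run_benchmark(sf$X, sf$y, m, n_experiments = 3, base_seed = 0)
    expect_gte(s$mean_auc, 0.95)
  }
})

test_that("importance: single-feature ensembles, ties, normalization", {
  # ensemble that can only split on TG_highest
  sf <- separable_features()
  fit <- fit_gradient_boost(sf$X[, "TG_highest", drop = FALSE], sf$y,
                            n_trees = 10)
  imp <- rank_feature_importance(fit)
  expect_equal(imp$feature, "TG_highest")
  expect_equal(imp$importance, 100)

  # hand-built tie: two stumps on different features, same depth
  stump <- function(feat) data.table::data.table(
    node = 1:3, feature = c(feat, NA, NA), threshold = c(1, NA, NA),
    default_left = c(TRUE, NA, NA), left = c(2L, NA, NA),
    right = c(3L, NA, NA), value = c(NA, -1, 1), depth = c(0L, 1L, 1L),
    cover = c(2, 1, 1))
  fake <- structure(list(trees = list(stump("b_feat"), stump("a_feat"))),
                    class = "fcs_gb")
  imp2 <- rank_feature_importance(fake)
  expect_equal(imp2$importance, c(100, 100))
  expect_equal(imp2$feature, c("a_feat", "b_feat"))  # name tie-break

  expect_equal(nrow(rank_feature_importance(
    structure(list(trees = list()), class = "fcs_gb"))), 0L)
})

test_that("decision cuts read stump structure and directions", {
  stump <- function(feat, thr, hi_value) data.table::data.table(
    node = 1:3, feature = c(feat, NA, NA), threshold = c(thr, NA, NA),
    default_left = c(TRUE, NA, NA), left = c(2L, NA, NA),
    right = c(3L, NA, NA), value = c(NA, -hi_value, hi_value),
    depth = c(0L, 1L, 1L), cover = c(2, 1, 1))
  fake <- structure(list(trees = list(
    stump("TG_highest", 18, 1),        # high side positive  -> +
    stump("GGT_average", 35, -1),      # high side negative  -> -
    stump("TG_highest", 18, 1))),      # duplicate, merged
    class = "fcs_gb")
  cuts <- extract_decision_cuts(fake, k_first_trees = 5)
  expect_equal(nrow(cuts), 2L)
  expect_equal(cuts$direction[cuts$feature == "TG_highest"], "+")
  expect_equal(cuts$direction[cuts$feature == "GGT_average"], "-")
  expect_equal(cuts$cut[cuts$feature == "GGT_average"], 35)
  expect_equal(cuts$tree[cuts$feature == "TG_highest"], 1L)

  expect_equal(nrow(extract_decision_cuts(fake, k_first_trees = 0)), 0L)
})

test_that("cut directions on a planted cohort match the stratum contrasts", {
  co <- generate_cohort(cohort_spec(800, fcs_fraction = 0.03, seed = 2))
  ds <- benchmark_dataset(co, n_negatives = 60, seed = 2)
  X <- as.matrix(ds$features[, -1])
  rownames(X) <- ds$features$patient_id
  # triglyceride cuts push toward FCS
  fit <- fit_gradient_boost(X, ds$labels, seed = 0)
  cuts <- extract_decision_cuts(fit, k_first_trees = 5)
  tg_cuts <- cuts[startsWith(cuts$feature, "TG_"), ]
  expect_gt(nrow(tg_cuts), 0)
  expect_true(all(tg_cuts$direction == "+"))
  # liver enzymes / glucose push away from FCS (force the model onto them)
  keep <- grep("^(GGT|GPT|GLU)_(average|highest)$", colnames(X),
               value = TRUE)
  fit2 <- fit_gradient_boost(X[, keep], ds$labels, seed = 0)
  cuts2 <- extract_decision_cuts(fit2, k_first_trees = 5)
  expect_gt(nrow(cuts2), 0)
  expect_true(all(cuts2$direction == "-"))
})

test_that("label permutation collapses the TG importance dominance", {
  co <- generate_cohort(cohort_spec(800, fcs_fraction = 0.03, seed = 2))
  ds <- benchmark_dataset(co, n_negatives = 60, seed = 2)
  X <- as.matrix(ds$features[, -1])
  rownames(X) <- ds$features$patient_id
  # with true labels the top feature is TG-derived
  imp0 <- rank_feature_importance(fit_gradient_boost(X, ds$labels,
                                                     seed = 0))
  expect_true(startsWith(imp0$feature[1], "TG_"))
  top_tg <- vapply(1:10, function(i) {
    set.seed(1000 + i)
    yp <- sample(unname(ds$labels))
    imp <- rank_feature_importance(fit_gradient_boost(X, yp, seed = i))
    nrow(imp) > 0 && startsWith(imp$feature[1], "TG_")
  }, logical(1))
  expect_lt(mean(top_tg), 0.5)
})

test_that("learners tolerate missing values", {
  sf <- separable_features()
  X <- sf$X
  X[sample(length(X), 40)] <- NA
  for (fitter in list(
    function() fit_gradient_boost(X, sf$y, n_trees = 10),
    function() fit_kernel_machine(X, sf$y),
    function() fit_relu_net(X, sf$y, epochs = 30))) {
    fit <- fitter()
    p <- predict(fit, X)
    expect_length(p, nrow(X))
    expect_false(anyNA(p))
    expect_gte(evaluate_scores(p, sf$y)$auc, 0.9)
  }
})
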