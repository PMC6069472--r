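toy_stream_data <- function(n_per = 10, sep = 4, d = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * d), 2 * n_per, d)
  X[1:n_per, 1:2] <- X[1:n_per, 1:2] + sep
  list(X = X, y = rep(c("pain", "no_pain"), each = n_per))
}

test_that("stream classifiers separate a linearly separable toy deterministically", {
  td <- toy_stream_data()
  clf <- train_stream(td$X, td$y, config = list(d_out = 3))
  pr <- predict_stream(clf, td$X)
  expect_equal(pr$label, td$y)
  clf2 <- train_stream(td$X, td$y, config = list(d_out = 3))
  expect_identical(predict_stream(clf2, td$X)$score, pr$score)
  expect_equal(pr$confidence, abs(pr$score))
  expect_error(train_stream(td$X, rep("pain", 20)), "single class")
})

test_that("flipping labels negates decision scores on a balanced toy", {
  td <- toy_stream_data(seed = 4)
  y_flip <- ifelse(td$y == "pain", "no_pain", "pain")
  s1 <- predict_stream(train_stream(td$X, td$y, config = list(d_out = 2)), td$X)$score
  s2 <- predict_stream(train_stream(td$X, y_flip, config = list(d_out = 2)), td$X)$score
  expect_equal(s1, -s2, tolerance = 1e-6)
})

test_that("majority voting matches exhaustive enumeration and breaks ties by confidence", {
  # all 8 vote patterns of 3 voters against the brute-force oracle
  opts <- c("pain", "no_pain")
  for (a in opts) for (b in opts) for (c_ in opts) {
    votes <- c(a, b, c_)
    confs <- c(0.3, 0.2, 0.9)
    expect_equal(majority_vote(votes, confs), naive_majority(votes, confs))
  }
  expect_equal(majority_vote(c("pain", "pain", "no_pain"), c(.1, .1, .9)), "pain")
  # even split: the single most confident voter decides
  expect_equal(majority_vote(c("pain", "no_pain"), c(0.2, 0.9)), "no_pain")
  expect_equal(majority_vote(c("pain", "no_pain"), c(0.9, 0.2)), "pain")
  expect_equal(majority_vote("no_pain", 0.1), "no_pain")
  expect_error(majority_vote(character(0), numeric(0)), "at least one")
  expect_error(majority_vote(c("pain", "pain"), 1), "equal length")
})

test_that("trapezoidal AUC equals the rank statistic with half-credit ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c("no_pain", "no_pain", "pain", "pain")), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c("no_pain", "no_pain", "pain", "pain")), 0)
  s <- c(0.1, 0.4, 0.35, 0.8); l <- c("no_pain", "no_pain", "pain", "pain")
  expect_equal(roc_auc(s, l), naive_auc(s, l))
  expect_equal(roc_auc(s, l), 0.75)  # 3 of 4 pairs ranked correctly
  set.seed(10)
  s <- round(rnorm(40), 1)  # ties
  l <- sample(c("pain", "no_pain"), 40, TRUE)
  expect_equal(roc_auc(s, l), naive_auc(s, l))
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(roc_auc(s, l),
                 as.numeric(pROC::auc(pROC::roc(l, s, levels = c("no_pain", "pain"),
                                                direction = "<", quiet = TRUE))))
  }
  expect_error(roc_auc(1:3, rep("pain", 3)), "both classes")
})

make_instances <- function(n_subj = 6, per_subj = 4, d = 8, sep = 4, seed = 1,
                           random_labels = FALSE) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_subj)) {
    subj <- subject_record(sprintf("S%02d", i),
                           sample(c("male", "female"), 1),
                           runif(1, 31, 41),
                           sample(c("white", "black", "asian"), 1))
    pain_slots <- if (random_labels) sample(seq_len(per_subj)) else seq_len(per_subj)
    for (j in seq_len(per_subj)) {
      # random_labels permutes which epochs are pain but keeps the balanced
      # per-subject design, as a label-exchangeable null of the cohort layout
      pain <- pain_slots[j] <= per_subj / 2
      x <- rnorm(d) + if (pain && !random_labels) c(rep(sep, 2), rep(0, d - 2)) else 0
      out[[length(out) + 1L]] <- pain_instance(
        subj, paste0("T", (j - 1) %% 7),
        list(dface = x, dpose = rnorm(d)),
        nips_score = if (pain) sample(3:7, 1) else sample(0:2, 1))
    }
  }
  out
}

test_that("LOSO folds partition the instances with no subject leakage", {
  inst <- make_instances()
  res <- loso_evaluate(inst, streams = "dface", config = list(d_out = 3))
  expect_equal(nrow(res$predictions), length(inst))
  key <- paste(res$predictions$subject_id, res$predictions$epoch_id)
  expect_setequal(key, paste(
    vapply(inst, function(x) x$subject$subject_id, character(1)),
    vapply(inst, function(x) x$epoch_id, character(1))))
  expect_false(any(duplicated(key)))
  # high separation -> near-perfect subject-independent accuracy
  expect_gt(res$accuracy, 0.9)
})

test_that("single-stream fusion equals that stream's prediction", {
  inst <- make_instances(seed = 2)
  res <- loso_evaluate(inst, streams = "dface", config = list(d_out = 3))
  expect_equal(res$predictions$predicted, res$predictions$vote_dface)
})

test_that("random labels give chance-level AUC across repetitions", {
  aucs <- vapply(1:20, function(seed) {
    inst <- make_instances(n_subj = 6, per_subj = 4, seed = seed,
                           random_labels = TRUE)
    labs <- vapply(inst, function(x) x$label, character(1))
    subj <- vapply(inst, function(x) x$subject$subject_id, character(1))
    # regenerate until both classes occur in >= 2 subjects' training folds
    if (length(unique(labs)) < 2) return(NA_real_)
    r <- suppressWarnings(
      loso_evaluate(inst, streams = "dface", config = list(d_out = 3)))
    r$auc
  }, numeric(1))
  expect_equal(mean(aucs, na.rm = TRUE), 0.5, tolerance = 0.1)
})

test_that("degenerate folds are skipped with a warning and reported", {
  inst <- make_instances(n_subj = 3, per_subj = 2, seed = 3)
  # make subject S01 hold every pain instance except its own fold's labels:
  # give all other subjects a single class
  for (i in seq_along(inst)) {
    if (inst[[i]]$subject$subject_id != "S01") {
      inst[[i]] <- pain_instance(inst[[i]]$subject, inst[[i]]$epoch_id,
                                 inst[[i]]$streams, 0)
    }
  }
  expect_warning(res <- loso_evaluate(inst, streams = "dface",
                                      config = list(d_out = 2)),
                 "single-class")
  expect_true("S01" %in% res$skipped_folds)
})

test_that("subgroup filtering follows the 37-week cut and partitions by gender", {
  ages <- c(30, 36.9, 37, 40)
  inst <- unlist(lapply(seq_along(ages), function(i) {
    s <- subject_record(paste0("A", i), c("male", "female", "male", "unknown")[i],
                        ages[i], "white")
    list(pain_instance(s, "T1", list(dface = rnorm(3)), 5))
  }), recursive = FALSE)
  pre <- subgroup_filter(inst, "preterm")
  expect_setequal(vapply(pre, function(x) x$subject$subject_id, character(1)),
                  c("A1", "A2"))
  full <- subgroup_filter(inst, "fullterm")
  expect_setequal(vapply(full, function(x) x$subject$subject_id, character(1)),
                  c("A3", "A4"))
  # gender subgroups partition the dataset
  parts <- c(subgroup_filter(inst, "male"), subgroup_filter(inst, "female"),
             suppressWarnings(subgroup_filter(inst, "unknown_gender")))
  expect_equal(length(parts), length(inst))
  # idempotent
  expect_identical(subgroup_filter(pre, "preterm"), pre)
  expect_warning(subgroup_filter(inst, "asian"), "empty")
})
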