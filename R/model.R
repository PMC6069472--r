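#' Train a single-stream pain classifier
#'
#' Fits the SLPP embedding on one feature stream, then a support vector
#' machine on the embedded vectors. The decision function returns a signed
#' score whose sign gives the label (positive = pain) and whose magnitude
#' is used as the confidence in decision fusion. Kernel: radial basis with
#' width `1 / d_out` and unit regularization cost by default (both
#' config-overridable). Deterministic for fixed training data and
#' configuration.
#'
#' @param X n x d matrix of stream feature vectors (rows = instances).
#' @param y Labels, `"pain"` / `"no_pain"` (character or factor).
#' @param config Named list overriding defaults: `d_out`, `k`, `t_mode`,
#'   `pca_variance` (embedding); `kernel`, `gamma`, `cost` (SVM).
#' @param stream_name Stream label stored in the classifier.
#' @return An object of class `stream_classifier`.
#' @export
train_stream <- function(X, y, config = list(), stream_name = "stream") {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) {
    stop("training data for stream '", stream_name, "' has a single class")
  }
  cfg <- utils::modifyList(list(d_out = 30L, k = 5L, t_mode = "auto",
                                pca_variance = 0.98, kernel = "radial",
                                gamma = NULL, cost = 1), config)
  # cap the requested output dimension at the achievable rank
  d_req <- as.integer(cfg$d_out)
  emb <- tryCatch(
    fit_slpp(X, y, d_out = d_req, k = cfg$k, t_mode = cfg$t_mode,
             pca_variance = cfg$pca_variance),
    error = function(e) {
      rank <- achievable_rank(X, cfg$pca_variance)
      if (d_req > rank) {
        fit_slpp(X, y, d_out = rank, k = cfg$k, t_mode = cfg$t_mode,
                 pca_variance = cfg$pca_variance)
      } else {
        stop(e)
      }
    })
  E <- transform_slpp(emb, X)
  gamma <- cfg$gamma %||% (1 / emb$d_out)
  yf <- factor(y, levels = c("no_pain", "pain"))
  fit <- e1071::svm(E, yf, kernel = cfg$kernel, gamma = gamma,
                    cost = cfg$cost, scale = FALSE)
  # orientation of the decision values: positive should mean "pain"
  dv <- attr(stats::predict(fit, E, decision.values = TRUE), "decision.values")
  flip <- if (grepl("^pain", colnames(dv)[1])) 1 else -1
  structure(list(embedding = emb, svm = fit, flip = flip,
                 stream_name = stream_name, config = cfg),
            class = "stream_classifier")
}

achievable_rank <- function(X, pca_variance) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  sv <- svd(sweep(Z, 2, colMeans(Z)), nu = 0, nv = 0)
  pos <- sv$d > max(sv$d) * 1e-10
  var_expl <- cumsum(sv$d[pos]^2) / sum(sv$d[pos]^2)
  max(1L, min(which(var_expl >= pca_variance)))
}

#' Predict with a single-stream classifier
#'
#' @param clf A [train_stream()] classifier.
#' @param X Matrix of stream feature vectors (rows = instances).
#' @return Data frame with columns `label`, `score` (signed, positive =
#'   pain) and `confidence` (= `abs(score)`).
#' @export
predict_stream <- function(clf, X) {
  stopifnot(inherits(clf, "stream_classifier"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  E <- transform_slpp(clf$embedding, as.matrix(X))
  pr <- stats::predict(clf$svm, E, decision.values = TRUE)
  score <- clf$flip * as.numeric(attr(pr, "decision.values"))
  data.frame(label = ifelse(score > 0, "pain", "no_pain"),
             score = score, confidence = abs(score),
             stringsAsFactors = FALSE)
}

#' Majority-vote decision fusion
#'
#' Each stream classifier contributes one vote; the label held by more
#' than half the voters wins. On a tie (possible only with an even number
#' of voters), the label of the single most confident voter is chosen.
#'
#' @param votes Character vector of per-stream labels.
#' @param confidences Non-negative per-stream confidences, same length.
#' @return The fused label.
#' @export
majority_vote <- function(votes, confidences) {
  if (!length(votes)) stop("majority_vote needs at least one vote")
  if (length(confidences) != length(votes)) {
    stop("votes and confidences must have equal length")
  }
  tab <- table(votes)
  top <- tab[tab > length(votes) / 2]
  if (length(top) == 1L) return(names(top))
  votes[which.max(confidences)]
}

#' Fused confidence score of a vote set
#'
#' Signed score used to build ROC curves from fused decisions: each voter
#' contributes `+confidence` for a pain vote and `-confidence` otherwise;
#' the sum is monotone in the vote margin. An artifact convention (the
#' fusion rule itself only outputs a label).
#'
#' @inheritParams majority_vote
#' @return A signed numeric score (positive leans pain).
#' @export
fused_score <- function(votes, confidences) {
  sum(ifelse(votes == "pain", 1, -1) * confidences)
}

#' Trapezoidal ROC AUC
#'
#' Area under the ROC curve of a score against binary labels, computed as
#' the Mann-Whitney ranking probability with half credit for ties - the
#' exact area of the trapezoidal ROC polygon.
#'
#' @param scores Numeric scores (larger = more pain-like).
#' @param labels Labels, `"pain"` / `"no_pain"` (or a logical/0-1 vector
#'   with `TRUE`/1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels) || is.numeric(labels)) {
    pos <- as.logical(labels)
  } else {
    pos <- labels == "pain"
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-subject-out evaluation with decision fusion
#'
#' One cross-validation fold per subject: every instance of the held-out
#' subject is predicted by per-stream classifiers trained on all other
#' subjects, and the per-stream votes are fused by [majority_vote()].
#' The held-out subject never contributes to training, so the evaluation
#' is subject-independent. A fold whose training labels collapse to a
#' single class is skipped with a warning and reported. Overall accuracy
#' is pooled over instances; the AUC is computed from the fused signed
#' confidence scores.
#'
#' @param instances List of [pain_instance()] objects.
#' @param streams Character vector of stream names to fuse (subset of the
#'   names present in each instance's `streams`).
#' @param config Per-stream classifier configuration (see
#'   [train_stream()]).
#' @param feature_subset Optional named list (per stream) of integer
#'   positions to keep, e.g. from [hemiface_select()].
#' @return An object of class `painface_loso`: a list with `predictions`
#'   (data frame: subject_id, epoch_id, label, predicted, confidence,
#'   per-stream vote columns), `accuracy`, `auc`, `skipped_folds`.
#' @export
loso_evaluate <- function(instances, streams = c("dface", "dpose", "lbptop"),
                          config = list(), feature_subset = NULL) {
  stopifnot(length(instances) >= 2L)
  subj <- vapply(instances, function(x) x$subject$subject_id, character(1))
  labels <- vapply(instances, function(x) x$label, character(1))
  if (length(unique(subj)) < 2L) stop("LOSO needs at least 2 subjects")
  missing <- setdiff(streams, names(instances[[1]]$streams))
  if (length(missing)) {
    stop("instances lack stream(s): ", paste(missing, collapse = ", "))
  }
  mats <- lapply(streams, function(sn) {
    m <- do.call(rbind, lapply(instances, function(x) x$streams[[sn]]))
    if (!is.null(feature_subset[[sn]])) m <- m[, feature_subset[[sn]], drop = FALSE]
    m
  })
  names(mats) <- streams

  rows <- list(); skipped <- character(0)
  for (held in unique(subj)) {
    train_idx <- which(subj != held)
    test_idx <- which(subj == held)
    if (length(unique(labels[train_idx])) < 2L) {
      warning("fold '", held, "' skipped: single-class training set")
      skipped <- c(skipped, held)
      next
    }
    preds <- lapply(streams, function(sn) {
      clf <- train_stream(mats[[sn]][train_idx, , drop = FALSE],
                          labels[train_idx], config, stream_name = sn)
      predict_stream(clf, mats[[sn]][test_idx, , drop = FALSE])
    })
    names(preds) <- streams
    for (j in seq_along(test_idx)) {
      i <- test_idx[j]
      votes <- vapply(preds, function(p) p$label[j], character(1))
      confs <- vapply(preds, function(p) p$confidence[j], numeric(1))
      row <- data.frame(
        subject_id = subj[i],
        epoch_id = instances[[i]]$epoch_id,
        label = labels[i],
        predicted = majority_vote(votes, confs),
        confidence = fused_score(votes, confs),
        stringsAsFactors = FALSE)
      for (sn in streams) row[[paste0("vote_", sn)]] <- votes[[sn]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("all LOSO folds were skipped")
  pred <- do.call(rbind, rows)
  acc <- mean(pred$predicted == pred$label)
  auc <- if (length(unique(pred$label)) == 2L) {
    roc_auc(pred$confidence, pred$label)
  } else {
    NA_real_
  }
  structure(list(predictions = pred, accuracy = acc, auc = auc,
                 skipped_folds = skipped, streams = streams),
            class = "painface_loso")
}

#' @export
print.painface_loso <- function(x, ...) {
  cat(sprintf("<LOSO evaluation: %d instances, %d subjects, streams %s>\n",
              nrow(x$predictions), length(unique(x$predictions$subject_id)),
              paste(x$streams, collapse = "+")))
  cat(sprintf("  overall accuracy: %.4f\n", x$accuracy))
  if (!is.na(x$auc)) cat(sprintf("  AUC: %.4f\n", x$auc))
  if (length(x$skipped_folds)) {
    cat("  skipped folds:", paste(x$skipped_folds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Filter a dataset by an individual-variable subgroup
#'
#' Restricts a list of instances to one subgroup of an individual
#' variable: gender (`"male"`, `"female"`), gestational age class
#' (`"preterm"` < 37 weeks, `"fullterm"` 37-42 weeks) or race
#' (`"white"`, `"black"`, `"asian"`). Used to contrast subgroup-specific
#' models with the general model. Idempotent; an empty result triggers a
#' warning.
#'
#' @param instances List of [pain_instance()] objects.
#' @param criterion Subgroup name (one of the values above, or
#'   `"unknown_gender"` / `"unknown_race"`).
#' @return The filtered list of instances.
#' @export
subgroup_filter <- function(instances,
                            criterion = c("male", "female", "unknown_gender",
                                          "preterm", "fullterm",
                                          "white", "black", "asian",
                                          "unknown_race")) {
  criterion <- match.arg(criterion)
  keep <- vapply(instances, function(x) {
    s <- x$subject
    switch(criterion,
      male = s$gender == "male",
      female = s$gender == "female",
      unknown_gender = s$gender == "unknown",
      preterm = age_class(s) == "preterm",
      fullterm = age_class(s) == "fullterm",
      white = s$race == "white",
      black = s$race == "black",
      asian = s$race == "asian",
      unknown_race = s$race == "unknown")
  }, logical(1))
  if (!any(keep)) warning("subgroup '", criterion, "' is empty")
  instances[keep]
}
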