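#' Leave-one-person-out folds of a feature table
#'
#' One fold per subject: all of that subject's epochs form the test set and
#' every other subject's epochs the training set, so train and test never
#' share a subject and the folds partition the table.
#'
#' @param tab A `feature_table`.
#' @return List of folds, each `list(subject, train, test)` with row
#'   indices into `tab`.
#' @export
lopo_split <- function(tab) {
  subjects <- unique(tab$subject_id)
  if (length(subjects) < 2)
    stop("leave-one-person-out needs at least 2 subjects")
  lapply(subjects, function(s) {
    test <- which(tab$subject_id == s)
    list(subject = s, train = setdiff(seq_len(nrow(tab)), test),
         test = test)
  })
}

#' Classifier hyperparameters
#'
#' @param rf_ntree Random-forest tree count (100).
#' @param svm_cost SVM soft-margin cost (1).
#' @param svm_gamma RBF bandwidth; `"median"` (default) sets
#'   `gamma = 1 / (2 * median pairwise squared distance)` on the (subsampled)
#'   training fold — the median heuristic — or pass a fixed numeric.
#' @param tree_control [rpart::rpart.control()] options for the decision
#'   tree (Gini impurity, default growth/pruning settings).
#' @return A list of settings for [evaluate_lopo()].
#' @export
classifier_params <- function(rf_ntree = 100, svm_cost = 1,
                              svm_gamma = "median",
                              tree_control = rpart::rpart.control()) {
  list(rf_ntree = rf_ntree, svm_cost = svm_cost, svm_gamma = svm_gamma,
       tree_control = tree_control)
}

# Median heuristic for the RBF bandwidth: gamma = 1 / (2 * median ||x-y||^2)
# over a deterministic subsample of at most 300 training rows.
median_gamma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 300) round(seq(1, n, length.out = 300)) else seq_len(n)
  d2 <- as.numeric(stats::dist(x[idx, , drop = FALSE]))^2
  med <- median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) return(1 / ncol(x))
  1 / (2 * med)
}

fit_predict <- function(classifier, xtr, ytr, xte, params, fold_seed) {
  with_seed(fold_seed, switch(
    classifier,
    decision_tree = {
      d <- data.frame(xtr, .y = ytr)
      fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                          control = params$tree_control)
      predict(fit, data.frame(xte), type = "class")
    },
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytr,
                                        ntree = params$rf_ntree)
      predict(fit, xte)
    },
    svm = {
      gamma <- if (identical(params$svm_gamma, "median"))
        median_gamma(xtr) else params$svm_gamma
      fit <- e1071::svm(xtr, ytr, kernel = "radial",
                        cost = params$svm_cost, gamma = gamma,
                        scale = FALSE)
      predict(fit, xte)
    },
    stop("unknown classifier '", classifier,
         "'; options: decision_tree, random_forest, svm")))
}

#' Leave-one-person-out evaluation of one classifier
#'
#' Per fold, the 18 features are standardized with the training fold's
#' means and SDs only (no leakage), the classifier is fit on the training
#' epochs and every held-out epoch of the test subject is predicted.
#' Confusion counts (case group = positive) are accumulated over folds and
#' summarized as accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`.
#'
#' @param tab A `feature_table` with a two-group `group` column.
#' @param classifier One of `"decision_tree"`, `"random_forest"`, `"svm"`.
#' @param seed Integer seed; per-fold seeds are derived from it, so results
#'   are reproducible.
#' @param positive Label of the positive (case) class, default `"AD"`.
#' @param params [classifier_params()].
#' @return An `eeg_lopo` object: per-fold confusion counts, aggregate
#'   counts and the three rates (also as percentages via `print`).
#' @export
evaluate_lopo <- function(tab, classifier = c("decision_tree",
                                              "random_forest", "svm"),
                          seed = 1, positive = "AD",
                          params = classifier_params()) {
  if (length(classifier) == 1 && !classifier %in%
      c("decision_tree", "random_forest", "svm"))
    stop("unknown classifier '", classifier,
         "'; options: decision_tree, random_forest, svm")
  classifier <- match.arg(classifier)
  levels <- c(setdiff(unique(tab$group), positive), positive)
  if (length(levels) != 2)
    stop("classification needs exactly two groups")
  y <- factor(tab$group, levels = levels)
  x <- as.matrix(tab[, feature_names])
  folds <- lopo_split(tab)

  per_fold <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    mu <- colMeans(x[f$train, , drop = FALSE])
    sig <- apply(x[f$train, , drop = FALSE], 2, sd)
    sig[sig == 0] <- 1
    xtr <- scale(x[f$train, , drop = FALSE], center = mu, scale = sig)
    xte <- scale(x[f$test, , drop = FALSE], center = mu, scale = sig)
    pred <- fit_predict(classifier, xtr, y[f$train], xte, params,
                        fold_seed = derive_seed(seed, i))
    truth <- y[f$test]
    per_fold[[i]] <- data.frame(
      subject = f$subject,
      TP = sum(pred == positive & truth == positive),
      FP = sum(pred == positive & truth != positive),
      TN = sum(pred != positive & truth != positive),
      FN = sum(pred != positive & truth == positive),
      stringsAsFactors = FALSE)
  }
  per_fold <- do.call(rbind, per_fold)
  tot <- colSums(per_fold[, c("TP", "FP", "TN", "FN")])
  structure(list(classifier = classifier, positive = positive,
                 folds = per_fold, confusion = as.list(tot),
                 accuracy = unname((tot["TP"] + tot["TN"]) / sum(tot)),
                 sensitivity = unname(tot["TP"] / (tot["TP"] + tot["FN"])),
                 specificity = unname(tot["TN"] / (tot["TN"] + tot["FP"])),
                 seed = seed),
            class = "eeg_lopo")
}

#' @export
print.eeg_lopo <- function(x, ...) {
  cat(sprintf("Leave-one-person-out CV, classifier: %s (positive class %s)\n",
              x$classifier, x$positive))
  cat(sprintf("  %d folds, %d test epochs (TP %d, FP %d, TN %d, FN %d)\n",
              nrow(x$folds), sum(unlist(x$confusion)),
              x$confusion$TP, x$confusion$FP, x$confusion$TN,
              x$confusion$FN))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' @export
summary.eeg_lopo <- function(object, ...) {
  f <- object$folds
  f$accuracy <- (f$TP + f$TN) / (f$TP + f$TN + f$FP + f$FN)
  f
}

#' Subject-level majority vote
#'
#' Aggregates an epoch-level LOPO result to one prediction per held-out
#' subject (a subject is called positive when more than half of its test
#' epochs are). This subject-level view is an extension beyond the
#' epoch-level evaluation and is reported separately.
#'
#' @param x An `eeg_lopo` object.
#' @return Data frame with one row per subject: predicted and true class
#'   and the positive-epoch fraction; subject-level accuracy as attribute
#'   `accuracy`.
#' @export
majority_vote <- function(x) {
  f <- x$folds
  frac <- (f$TP + f$FP) / (f$TP + f$FP + f$TN + f$FN)
  truth_pos <- (f$TP + f$FN) > 0
  pred_pos <- frac > 0.5
  out <- data.frame(subject = f$subject,
                    true_positive = truth_pos,
                    predicted_positive = pred_pos,
                    positive_fraction = frac)
  attr(out, "accuracy") <- mean(pred_pos == truth_pos)
  out
}

#' Permute group labels across subjects
#'
#' Randomly reassigns the group labels over subjects (keeping every epoch
#' of a subject together and the group sizes fixed): the permutation
#' control for leave-one-person-out classification. A sound pipeline's
#' accuracy on a shuffled table falls to roughly the majority-class rate.
#'
#' @param tab A `feature_table`.
#' @param seed Integer seed for the permutation.
#' @return The table with permuted `group` labels.
#' @export
shuffle_subject_labels <- function(tab, seed = 1) {
  subjects <- unique(tab$subject_id)
  lab <- vapply(subjects, function(s)
    tab$group[match(s, tab$subject_id)], "")
  perm <- with_seed(as.integer(seed), sample(lab))
  tab$group <- perm[match(tab$subject_id, subjects)]
  tab
}

#' Run all three classifiers under LOPO-CV
#'
#' @inheritParams evaluate_lopo
#' @param classifiers Character vector of classifier names.
#' @return Named list of `eeg_lopo` objects, with a `summary` attribute
#'   data frame (classifier, accuracy, sensitivity, specificity in %).
#' @export
evaluate_all <- function(tab, classifiers = c("decision_tree",
                                              "random_forest", "svm"),
                         seed = 1, positive = "AD",
                         params = classifier_params()) {
  res <- lapply(classifiers, function(cl)
    evaluate_lopo(tab, cl, seed = seed, positive = positive,
                  params = params))
  names(res) <- classifiers
  attr(res, "summary") <- data.frame(
    classifier = classifiers,
    accuracy = 100 * vapply(res, `[[`, 0, "accuracy"),
    sensitivity = 100 * vapply(res, `[[`, 0, "sensitivity"),
    specificity = 100 * vapply(res, `[[`, 0, "specificity"),
    row.names = NULL)
  res
}
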