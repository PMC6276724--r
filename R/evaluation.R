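#' Round half away from zero
#'
#' Percentage reporting uses conventional half-up rounding (base `round`
#' rounds half to even).
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Create disjoint cross-validation folds
#'
#' Random partition of n subjects into k folds with sizes floor(n / k) or
#' ceiling(n / k) (n mod k folds take the larger size). With `stratify_by`,
#' members of each group are dealt into folds in shuffled order so that
#' per-group counts per fold differ by at most one.
#'
#' @param n number of subjects.
#' @param k number of folds (default 10; must satisfy k <= n).
#' @param seed integer seed.
#' @param stratify_by optional label vector of length n.
#' @return integer fold assignment of length n (values in 1..k).
#' @export
make_cv_folds <- function(n, k = 10, seed = 1, stratify_by = NULL) {
  if (k > n) stop("`k` must not exceed `n`")
  withr_seed(seed, {
    if (is.null(stratify_by)) {
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
      rep(seq_len(k), times = sizes)[sample.int(n)]
    } else {
      stopifnot(length(stratify_by) == n)
      fold <- integer(n)
      pos <- 0L
      for (g in unique(stratify_by)) {
        idx <- sample(which(stratify_by == g))
        fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
        pos <- pos + length(idx)
      }
      fold
    }
  })
}

#' Repeated k-fold cross-validated classification
#'
#' For each repetition a fresh fold assignment is drawn (seed = `seed` +
#' repetition - 1). Within each fold, preprocessing (standardization and,
#' optionally, fold-wise PCA) and the classifier are fitted on the training
#' folds only and applied to the held-out fold, so every subject receives
#' exactly one out-of-fold prediction per repetition.
#'
#' Two-group mode trains a binary SVM on the diagnosis labels with
#' class box constraints computed from the training-fold class sizes;
#' four-group mode trains a one-vs-one ensemble on the diagnosis-by-sex
#' cells.
#'
#' @param features numeric feature matrix (subjects x features).
#' @param cohort matching `cohort_table`.
#' @param mode `"two_group"` or `"four_group"`.
#' @param config classifier configuration, default [svm_config()] for the
#'   mode.
#' @param n_repetitions number of repetitions (study default 500).
#' @param k folds (default 10).
#' @param seed base integer seed.
#' @param stratify stratify folds by the class label.
#' @param pca_threshold variance-retention threshold; `NULL` disables PCA.
#' @param pca_scope `"fold"` (refit inside each training fold, default) or
#'   `"global"` (fit once on all data, mirroring the whole-sample protocol).
#' @return A `cv_run_set`: list with `predictions` (repetitions x subjects
#'   character matrix), `accuracies`, `mean_accuracy`, `sd_accuracy` (n - 1
#'   convention; 0 with `degenerate_sd = TRUE` when there is a single
#'   repetition), `truth`, `mode` and `scenario_keys`.
#' @export
run_repeated_cv <- function(features, cohort,
                            mode = c("two_group", "four_group"),
                            config = NULL,
                            n_repetitions = 500, k = 10, seed = 1,
                            stratify = FALSE,
                            pca_threshold = 0.95,
                            pca_scope = c("fold", "global")) {
  mode <- match.arg(mode)
  pca_scope <- match.arg(pca_scope)
  if (is.null(config)) config <- svm_config(mode)
  truth <- if (mode == "two_group") factor(cohort$diagnosis) else
    cohort_groups(cohort)
  n <- nrow(features)
  stopifnot(length(truth) == n)

  global_model <- NULL
  if (!is.null(pca_threshold) && pca_scope == "global") {
    global_model <- fit_pca(features, pca_threshold)
  }

  predict_fold <- function(train_idx, test_idx) {
    xtr <- features[train_idx, , drop = FALSE]
    xte <- features[test_idx, , drop = FALSE]
    if (!is.null(pca_threshold)) {
      pm <- if (is.null(global_model)) fit_pca(xtr, pca_threshold) else
        global_model
      xtr <- project(pm, xtr)
      xte <- project(pm, xte)
    } else {
      std <- standardize(xtr)
      xtr <- std$x
      xte <- sweep(sweep(xte, 2, std$center), 2, std$scale, "/")
    }
    ytr <- droplevels(truth[train_idx])
    if (mode == "two_group") {
      bc <- class_box_constraints(sum(ytr == levels(ytr)[1]),
                                  sum(ytr == levels(ytr)[2]),
                                  scheme = config$box_scheme) *
        config$penalty_scale
      m <- train_binary_svm(xtr, ytr, C = unname(bc),
                            kernel = config$kernel, tol = config$kkt_tol,
                            max_iter = config$max_iter)
      decision_value(m, xte)$label
    } else {
      ovo <- train_ovo(xtr, ytr, config)
      as.character(predict_ovo(ovo, xte))
    }
  }

  preds <- matrix(NA_character_, n_repetitions, n)
  accuracies <- numeric(n_repetitions)
  for (r in seq_len(n_repetitions)) {
    fold <- make_cv_folds(n, k, seed = seed + r - 1L,
                          stratify_by = if (stratify) truth else NULL)
    for (fk in seq_len(k)) {
      test_idx <- which(fold == fk)
      train_idx <- which(fold != fk)
      preds[r, test_idx] <- tryCatch(
        predict_fold(train_idx, test_idx),
        error = function(e) stop(sprintf("repetition %d, fold %d: %s",
                                         r, fk, conditionMessage(e))))
    }
    accuracies[r] <- mean(preds[r, ] == as.character(truth))
  }
  structure(list(
    predictions = preds, accuracies = accuracies,
    mean_accuracy = mean(accuracies),
    sd_accuracy = if (n_repetitions > 1) stats::sd(accuracies) else 0,
    degenerate_sd = n_repetitions == 1,
    truth = truth, mode = mode,
    scenario_keys = apply(preds, 1, paste, collapse = "|")
  ), class = "cv_run_set")
}

#' Most frequent classification scenario
#'
#' A scenario is the full vector of out-of-fold predicted labels over
#' subjects. Returns the modal scenario across repetitions; ties are broken
#' by the earliest repetition index at which a tied scenario first occurs.
#'
#' @param runs a `cv_run_set`.
#' @return list with `key`, `count`, `repetition` (first matching index)
#'   and `predictions` (the representative label vector).
#' @export
most_frequent_scenario <- function(runs) {
  keys <- runs$scenario_keys
  if (length(keys) == 0) stop("at least one repetition required")
  counts <- table(keys)
  top <- names(counts)[counts == max(counts)]
  first_idx <- vapply(top, function(k) which(keys == k)[1], 0L)
  key <- top[which.min(first_idx)]
  rep_idx <- which(keys == key)[1]
  list(key = key, count = as.integer(max(counts)), repetition = rep_idx,
       predictions = runs$predictions[rep_idx, ])
}

#' Confusion matrix / tensor summary with sensitivity and specificity
#'
#' Two-group mode (labels ASD / TD) reports the standard-convention counts
#' TP (ASD correctly classified), TN (TD correct), FN (ASD classified TD)
#' and FP (TD classified ASD), with sensitivity = 100 TP / (TP + FN) and
#' specificity = 100 TN / (TN + FP). Four-group mode (diagnosis-by-sex
#' cells) reports correct counts per cell and per-cell error counts, with
#' sensitivity = 100 (TP_M + TP_F) / n_ASD and specificity =
#' 100 (TN_M + TN_F) / n_TD. Percentages are of the classified total,
#' rounded half-up to 2 decimals.
#'
#' A `paper_labels` rendering is attached in which the two error count
#' labels are swapped (the study's printed tables label the ASD-to-TD
#' errors "FP" and the TD-to-ASD errors "FN"); the stored counts always
#' follow the standard convention.
#'
#' @param truth,predicted equal-length label vectors.
#' @param mode `"two_group"` or `"four_group"`.
#' @return A `confusion_summary` list with `counts`, `percent`,
#'   `sensitivity`, `specificity`, `accuracy`, `n` and `paper_labels`.
#' @export
confusion_summary <- function(truth, predicted,
                              mode = c("two_group", "four_group")) {
  mode <- match.arg(mode)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  n <- length(truth)
  if (mode == "two_group") {
    valid <- c("ASD", "TD")
    if (!all(c(truth, predicted) %in% valid)) {
      stop("two-group labels must be ASD / TD")
    }
    counts <- c(
      TP = sum(truth == "ASD" & predicted == "ASD"),
      TN = sum(truth == "TD" & predicted == "TD"),
      FN = sum(truth == "ASD" & predicted == "TD"),
      FP = sum(truth == "TD" & predicted == "ASD")
    )
    sens <- 100 * counts["TP"] / (counts["TP"] + counts["FN"])
    spec <- 100 * counts["TN"] / (counts["TN"] + counts["FP"])
    paper <- counts[c("TP", "TN", "FP", "FN")]
    names(paper) <- c("TP", "TN", "FN", "FP")  # printed labels are swapped
  } else {
    valid <- c("ASD_M", "ASD_F", "TD_M", "TD_F")
    if (!all(c(truth, predicted) %in% valid)) {
      stop("four-group labels must be ASD_M / ASD_F / TD_M / TD_F")
    }
    counts <- c(
      TP_M = sum(truth == "ASD_M" & predicted == "ASD_M"),
      TN_M = sum(truth == "TD_M" & predicted == "TD_M"),
      TP_F = sum(truth == "ASD_F" & predicted == "ASD_F"),
      TN_F = sum(truth == "TD_F" & predicted == "TD_F"),
      err_ASD_M = sum(truth == "ASD_M" & predicted != "ASD_M"),
      err_ASD_F = sum(truth == "ASD_F" & predicted != "ASD_F"),
      err_TD_M = sum(truth == "TD_M" & predicted != "TD_M"),
      err_TD_F = sum(truth == "TD_F" & predicted != "TD_F")
    )
    n_asd <- sum(truth %in% c("ASD_M", "ASD_F"))
    n_td <- sum(truth %in% c("TD_M", "TD_F"))
    sens <- 100 * (counts["TP_M"] + counts["TP_F"]) / n_asd
    spec <- 100 * (counts["TN_M"] + counts["TN_F"]) / n_td
    paper <- counts
    names(paper) <- c("TP_M", "TN_M", "TP_F", "TN_F",
                      "FP_M", "FP_F", "FN_M", "FN_F")
  }
  structure(list(
    counts = counts,
    percent = round_half_up(100 * counts / n, 2),
    sensitivity = round_half_up(unname(sens), 2),
    specificity = round_half_up(unname(spec), 2),
    accuracy = round_half_up(100 * sum(truth == predicted) / n, 2),
    n = n, mode = mode, paper_labels = paper
  ), class = "confusion_summary")
}
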