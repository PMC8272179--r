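#' SVM classifier configuration
#'
#' The classifier is fixed to a radial-basis-function (RBF) kernel
#' support vector machine to isolate the effect of the segmentation
#' windows.  Features are standardized (zero mean, unit variance) with
#' parameters fit on the training folds only.
#'
#' @param C Soft-margin cost (default 1).
#' @param gamma Optional fixed RBF width.  When `NULL` (default) it is
#'   set per training fold by the heuristic
#'   `1 / (n_features * mean variance of the standardized training
#'   features)`, which reduces to `1 / n_features` up to the population /
#'   sample variance factor.
#' @param standardize Standardize features per training fold (default
#'   `TRUE`).
#' @param stratified Stratify the cross-validation folds by class
#'   (default `FALSE`: plain random partition).
#' @return An `svm_config` list.
#' @export
svm_config <- function(C = 1, gamma = NULL, standardize = TRUE,
                       stratified = FALSE) {
  stopifnot(is.numeric(C), length(C) == 1L, C > 0)
  structure(list(C = C, kernel = "radial", gamma = gamma,
                 standardize = isTRUE(standardize),
                 stratified = isTRUE(stratified)),
            class = "svm_config")
}

#' Deterministic fold assignment
#'
#' Folds depend only on the seed and the record identifiers -- never on
#' features or labels (unless stratification is requested) -- so every
#' window configuration is evaluated on the same partition.
#'
#' @param ids Unique record identifiers.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param labels Optional class labels, used only when `stratified`.
#' @param stratified Stratify by `labels`.
#' @return Integer vector of fold numbers (1..k), aligned with `ids`.
#' @export
assign_folds <- function(ids, k, seed, labels = NULL, stratified = FALSE) {
  n <- length(ids)
  if (anyDuplicated(ids)) stop("assign_folds: ids must be unique")
  stopifnot(k >= 2, k <= n)
  ord <- order(ids)
  folds <- integer(n)
  if (stratified) {
    if (is.null(labels)) stop("assign_folds: stratified needs labels")
    withr::with_seed(as.integer(seed), {
      for (lv in unique(labels[ord])) {
        sel <- ord[labels[ord] == lv]
        folds[sel] <- sample(rep_len(seq_len(k), length(sel)))
      }
    })
  } else {
    withr::with_seed(as.integer(seed), {
      folds[ord] <- sample(rep_len(seq_len(k), n))
    })
  }
  folds
}

#' k-fold cross-validated SVM confusion counts
#'
#' Randomly partitions the records into `k` folds (seeded), trains the
#' RBF-SVM on k - 1 folds and tests on the held-out fold, repeating so
#' every fold is tested once.  Standardization parameters and the gamma
#' heuristic are fit on the training folds only and applied unchanged to
#' the test fold.  Confusion counts are summed over the folds; falls are
#' the positive class.
#'
#' @param x Numeric feature matrix (rows = records), e.g.
#'   `feature_matrix()$x`.
#' @param labels Factor or character vector of `"fall"` / `"adl"`.
#' @param svm An [svm_config()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param types Optional per-record activity types for the per-type
#'   FN/FP breakdowns.
#' @param ids Record identifiers (default: rownames of `x`), the sole
#'   input (with `seed`) to the fold assignment.
#' @param return_predictions Also return the per-record predictions.
#' @return A `confusion_counts` list: `TP`, `FP`, `FN`, `TN`,
#'   `per_type_FN`, `per_type_FP`, and optionally `predictions`.
#' @export
five_fold_cv <- function(x, labels, svm = svm_config(), k = 5, seed = 1,
                         types = NULL, ids = rownames(x),
                         return_predictions = FALSE) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("adl", "fall"))
  n <- nrow(x)
  stopifnot(length(labels) == n)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("five_fold_cv: need both classes present")
  }
  if (min(table(labels)) < k) {
    stop("five_fold_cv: need at least k = ", k, " records per class")
  }
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(types)) types <- rep("unknown", n)
  folds <- assign_folds(ids, k, seed, labels = labels,
                        stratified = svm$stratified)
  pred <- factor(rep(NA_character_, n), levels = c("adl", "fall"))
  for (f in seq_len(k)) {
    te <- folds == f
    tr <- !te
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    if (svm$standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2L, stats::sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
    }
    gamma <- svm$gamma
    if (is.null(gamma)) {
      pooled_var <- mean(apply(xtr, 2L, stats::var))
      if (!is.finite(pooled_var) || pooled_var <= 0) pooled_var <- 1
      gamma <- 1 / (ncol(xtr) * pooled_var)
    }
    fit <- e1071::svm(x = xtr, y = droplevels(labels[tr]),
                      type = "C-classification", kernel = "radial",
                      cost = svm$C, gamma = gamma, scale = FALSE)
    p <- stats::predict(fit, xte)
    pred[te] <- as.character(p)
  }
  is_fall <- labels == "fall"
  det_fall <- pred == "fall"
  counts <- confusion_counts(
    TP = sum(is_fall & det_fall),
    FP = sum(!is_fall & det_fall),
    FN = sum(is_fall & !det_fall),
    TN = sum(!is_fall & !det_fall),
    per_type_FN = table_to_named(types[is_fall & !det_fall]),
    per_type_FP = table_to_named(types[!is_fall & det_fall])
  )
  if (return_predictions) {
    counts$predictions <- data.frame(id = ids, fold = folds,
                                     truth = as.character(labels),
                                     pred = as.character(pred),
                                     stringsAsFactors = FALSE)
  }
  counts
}

table_to_named <- function(x) {
  if (!length(x)) return(integer(0))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' Construct confusion counts
#'
#' @param TP,FP,FN,TN Non-negative integer counts (falls positive).
#' @param per_type_FN Named integer vector: FN count per fall type;
#'   must sum to `FN`.
#' @param per_type_FP Named integer vector: FP count per ADL type;
#'   must sum to `FP`.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(TP, FP, FN, TN,
                             per_type_FN = integer(0),
                             per_type_FP = integer(0)) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  if (length(per_type_FN) && sum(per_type_FN) != FN) {
    stop("confusion_counts: per_type_FN does not sum to FN")
  }
  if (length(per_type_FP) && sum(per_type_FP) != FP) {
    stop("confusion_counts: per_type_FP does not sum to FP")
  }
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), TN = as.integer(TN),
                 per_type_FN = per_type_FN, per_type_FP = per_type_FP),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  FN %d  TN %d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Detection metrics from confusion counts
#'
#' * `fscore = 2 TP / (2 TP + FP + FN)` -- harmonic mean of sensitivity
#'   and precision, the study's single summary measure;
#' * `amr_by_type[t] = FN_t / (FN + TP)` -- Activity Miss Rate: the
#'   share of all falls that are both of type `t` and missed;
#' * `afpr_by_type[t] = FP_t / (FP + TN)` -- Activity False Positive
#'   Rate: the share of all ADL that are of type `t` and raise an alarm.
#'
#' A zero denominator yields `NA` (explicitly undefined), never a silent
#' zero.
#'
#' @param counts A [confusion_counts()].
#' @return A `metrics_report` list: `fscore`, `amr_by_type`,
#'   `afpr_by_type` (all fractions in \[0, 1\] or `NA`).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom_f <- 2 * counts$TP + counts$FP + counts$FN
  fscore <- if (denom_f > 0) 2 * counts$TP / denom_f else NA_real_
  denom_miss <- counts$FN + counts$TP
  amr <- if (denom_miss > 0) counts$per_type_FN / denom_miss else
    stats::setNames(rep(NA_real_, length(counts$per_type_FN)),
                    names(counts$per_type_FN))
  denom_fp <- counts$FP + counts$TN
  afpr <- if (denom_fp > 0) counts$per_type_FP / denom_fp else
    stats::setNames(rep(NA_real_, length(counts$per_type_FP)),
                    names(counts$per_type_FP))
  structure(list(fscore = fscore, amr_by_type = amr, afpr_by_type = afpr),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> Fscore %.1f%%\n", 100 * x$fscore))
  invisible(x)
}
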