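#' Cross-validated sweep over window configurations
#'
#' For every (non-degenerate) window configuration: build the feature
#' matrix over the event-centered records, run k-fold cross-validated
#' SVM classification, and record the Fscore and confusion counts.  All
#' configurations share the same seeded fold partition, so differences
#' between rows reflect the segmentation alone.
#'
#' @param ecrs List of `event_centered_record`s (from
#'   [build_event_centered()]).
#' @param configs Configuration table from [enumerate_configs()]
#'   (possibly a reduced grid for desk-scale runs).
#' @param svm An [svm_config()].
#' @param k Number of CV folds (default 5).
#' @param seed Integer seed for the fold partition.
#' @param verbose Print progress every 500 configurations.
#' @return A `sweep_result` data frame with one row per configuration:
#'   `config_id, t1..t4, window_class, fscore, TP, FP, FN, TN`, with the
#'   provenance (`seed`, `k`, `svm`) stored as attributes.
#' @export
run_sweep <- function(ecrs, configs, svm = svm_config(), k = 5, seed = 1,
                      verbose = FALSE) {
  stopifnot(length(ecrs) > 0, nrow(configs) > 0)
  if (any(configs$window_class == "degenerate")) {
    stop("run_sweep: degenerate configurations cannot be swept")
  }
  ids <- vapply(ecrs, `[[`, character(1), "event_id")
  labels <- vapply(ecrs, `[[`, character(1), "label")
  types <- vapply(ecrs, `[[`, character(1), "activity_type")
  out <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, ]
    fm_x <- do.call(rbind, lapply(ecrs, config_features, config = cfg))
    rownames(fm_x) <- ids
    cc <- five_fold_cv(fm_x, labels, svm = svm, k = k, seed = seed,
                       types = types, ids = ids)
    out[[i]] <- data.frame(cfg, fscore = compute_metrics(cc)$fscore,
                           TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
                           stringsAsFactors = FALSE)
    if (verbose && i %% 500 == 0) {
      message("run_sweep: ", i, "/", nrow(configs), " configurations")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  attr(res, "k") <- k
  attr(res, "svm") <- svm
  class(res) <- c("sweep_result", class(res))
  res
}

#' Best configuration per window class
#'
#' For each window class present in the sweep, the maximal Fscore and
#' the configuration achieving it.  Ties resolve to the smaller
#' `t1 + t2 + t3 + t4`, then lexicographically on (t1, t2, t3, t4).
#'
#' @param sweep A [run_sweep()] result.
#' @return Data frame `window_class, fscore, t1, t2, t3, t4, config_id`,
#'   ordered by window class.
#' @export
best_by_class <- function(sweep) {
  stopifnot(nrow(sweep) > 0)
  rows <- lapply(split(seq_len(nrow(sweep)), sweep$window_class), function(ix) {
    sub <- sweep[ix, , drop = FALSE]
    best <- sub$fscore == max(sub$fscore)
    sub <- sub[best, , drop = FALSE]
    o <- order(sub$t1 + sub$t2 + sub$t3 + sub$t4,
               sub$t1, sub$t2, sub$t3, sub$t4)
    sub[o[1L], c("window_class", "fscore", "t1", "t2", "t3", "t4",
                 "config_id")]
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Maximal Fscore over a pair of window parameters
#'
#' Each window's duration is fixed by a pair of the t-parameters: W1 by
#' (t3, t4), W2 by (t2, t4) and W3 by (t1, t3).  For every value pair on
#' the grid this returns the maximal Fscore over all configurations
#' matching it, as a matrix (rows = first parameter, columns = second).
#' Several sweeps (e.g. emulating several datasets) may be supplied, in
#' which case the per-sweep maxima are averaged cell-wise.
#'
#' @param sweep A [run_sweep()] result, or a list of them to average.
#' @param pair One of `"t3_t4"`, `"t2_t4"`, `"t1_t3"`.
#' @return Numeric matrix of (averaged) maximal Fscores with the
#'   parameter values as dimnames.  Cells that the grid constraints
#'   make impossible (t3 > t1 or t4 > t2 on the same side) are `NA`.
#' @export
pairwise_max_grid <- function(sweep, pair = c("t3_t4", "t2_t4", "t1_t3")) {
  pair <- match.arg(pair)
  vars <- strsplit(pair, "_", fixed = TRUE)[[1L]]
  sweeps <- if (inherits(sweep, "sweep_result")) list(sweep) else sweep
  mats <- lapply(sweeps, function(sw) {
    a <- sw[[vars[1L]]]
    b <- sw[[vars[2L]]]
    tapply(sw$fscore, list(factor(a, levels = sort(unique(a))),
                           factor(b, levels = sort(unique(b)))),
           max)
  })
  dims <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), dims), logical(1)))) {
    stop("pairwise_max_grid: sweeps cover different parameter grids")
  }
  out <- Reduce(`+`, mats) / length(mats)
  # cells ruled out by the grid itself (inner parameter exceeding its
  # outer bound on the same side) stay NA; any other gap is an error
  feasible <- matrix(TRUE, nrow(out), ncol(out))
  rv <- as.numeric(rownames(out)); cv <- as.numeric(colnames(out))
  if (pair == "t2_t4") feasible <- outer(rv, cv, `>=`)
  if (pair == "t1_t3") feasible <- outer(rv, cv, `>=`)
  if (any(is.na(out) & feasible)) {
    stop("pairwise_max_grid: some parameter pairs are absent from the sweep")
  }
  out
}

#' Per-activity-type misclassification rates at one configuration
#'
#' Runs the cross-validated classifier at a single window configuration
#' (typically the best three-window one) and reports the Activity Miss
#' Rate per fall type and Activity False Positive Rate per ADL type.
#'
#' @inheritParams run_sweep
#' @param config One configuration row.
#' @return Data frame `type, class, rate` (rates as fractions).
#' @export
per_type_rates <- function(ecrs, config, svm = svm_config(), k = 5,
                           seed = 1) {
  fm <- feature_matrix(ecrs, config)
  cc <- five_fold_cv(fm$x, fm$label, svm = svm, k = k, seed = seed,
                     types = fm$type, ids = fm$event_id)
  m <- compute_metrics(cc)
  empty <- data.frame(type = character(0), class = character(0),
                      rate = numeric(0), stringsAsFactors = FALSE)
  rbind(
    empty,
    if (length(m$amr_by_type)) {
      data.frame(type = names(m$amr_by_type), class = "fall",
                 rate = as.numeric(m$amr_by_type), stringsAsFactors = FALSE)
    },
    if (length(m$afpr_by_type)) {
      data.frame(type = names(m$afpr_by_type), class = "adl",
                 rate = as.numeric(m$afpr_by_type), stringsAsFactors = FALSE)
    }
  )
}
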