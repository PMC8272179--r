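test_that("metrics follow the confusion-count formulas", {
  m <- compute_metrics(confusion_counts(TP = 9, FP = 1, FN = 1, TN = 9))
  expect_equal(m$fscore, 0.90)
  expect_equal(compute_metrics(confusion_counts(5, 0, 0, 7))$fscore, 1)
  m2 <- compute_metrics(confusion_counts(
    TP = 16, FP = 0, FN = 4, TN = 10,
    per_type_FN = c(trip = 2, slip = 2)))
  expect_equal(m2$amr_by_type[["trip"]], 0.10)
})

test_that("zero denominators give explicit NA, never silent zero", {
  m <- compute_metrics(confusion_counts(0, 0, 0, 5))
  expect_true(is.na(m$fscore))
  m2 <- compute_metrics(confusion_counts(0, 0, 0, 0,
                                         per_type_FP = integer(0)))
  expect_true(is.na(m2$fscore))
})

test_that("per-type tallies must sum to the marginal counts", {
  expect_error(confusion_counts(1, 2, 1, 0, per_type_FP = c(a = 1)),
               "per_type_FP")
})

test_that("fold assignment depends only on seed and record ids", {
  ids <- sprintf("e%03d", 1:40)
  f1 <- assign_folds(ids, k = 5, seed = 3)
  perm <- sample(40)
  f2 <- assign_folds(ids[perm], k = 5, seed = 3)
  expect_equal(f1[perm], f2)            # same fold per id, any row order
  expect_equal(as.integer(table(f1)), rep(8L, 5))
  expect_false(identical(f1, assign_folds(ids, k = 5, seed = 4)))
})

test_that("leave-one-out folds partition the records", {
  ids <- letters[1:10]
  f <- assign_folds(ids, k = 10, seed = 1)
  expect_equal(sort(f), 1:10)
})

separable_xy <- function(n_per_class, seed, gap = 6) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * 3), ncol = 3),
               matrix(rnorm(n_per_class * 3, mean = gap), ncol = 3))
    rownames(x) <- sprintf("r%03d", seq_len(2 * n_per_class))
    list(x = x, y = rep(c("adl", "fall"), each = n_per_class))
  })
}

test_that("cross-validation is perfect on well-separated classes", {
  d <- separable_xy(30, seed = 8)
  cc <- five_fold_cv(d$x, d$y, k = 5, seed = 1)
  expect_equal(cc$FP + cc$FN, 0L)
  expect_equal(cc$TP + cc$TN, 60L)
})

test_that("cross-validation errors on degenerate class structure", {
  d <- separable_xy(30, seed = 8)
  expect_error(five_fold_cv(d$x, rep("fall", 60), k = 5, seed = 1),
               "both classes")
  expect_error(five_fold_cv(d$x[1:8, ], d$y[c(1:4, 31:34)], k = 5, seed = 1),
               "per class")
})

test_that("shuffled labels score near chance", {
  d <- separable_xy(25, seed = 15)
  fs <- withr::with_seed(99, {
    vapply(1:20, function(i) {
      y <- sample(d$y)
      compute_metrics(five_fold_cv(d$x, y, k = 5, seed = i))$fscore
    }, numeric(1))
  })
  expect_gte(mean(fs), 0.35)
  expect_lte(mean(fs), 0.65)
})

test_that("standardization is fit on training folds only", {
  d <- separable_xy(25, seed = 21, gap = 4)
  base <- five_fold_cv(d$x, d$y, k = 5, seed = 2,
                       return_predictions = TRUE)$predictions
  # corrupt one record's features massively; records sharing its test
  # fold must keep identical predictions (their scaler and model come
  # from the other folds)
  mutant <- "r005"
  x2 <- d$x
  x2[mutant, ] <- x2[mutant, ] * 1000
  after <- five_fold_cv(x2, d$y, k = 5, seed = 2,
                        return_predictions = TRUE)$predictions
  fold_m <- base$fold[base$id == mutant]
  others <- base$id[base$fold == fold_m & base$id != mutant]
  expect_identical(after$pred[match(others, after$id)],
                   base$pred[match(others, base$id)])
})

test_that("the sweep is deterministic and its summaries match brute force", {
  study <- build_study(15, 15, difficulty = 0.2, seed = 5)
  grid <- enumerate_configs(t_max = 0.5)
  sw1 <- run_sweep(study$bec$ecrs, grid, k = 3, seed = 5)
  sw2 <- run_sweep(study$bec$ecrs, grid, k = 3, seed = 5)
  expect_identical(sw1$fscore, sw2$fscore)
  expect_equal(nrow(sw1), nrow(grid))

  best <- best_by_class(sw1)
  for (i in seq_len(nrow(best))) {
    sub <- sw1[sw1$window_class == best$window_class[i], ]
    expect_equal(best$fscore[i], max(sub$fscore))
  }

  # pairwise max grid equals group-by-then-max
  pm <- pairwise_max_grid(sw1, "t3_t4")
  for (a in rownames(pm)) for (b in colnames(pm)) {
    sel <- sw1$t3 == as.numeric(a) & sw1$t4 == as.numeric(b)
    expect_equal(pm[a, b], max(sw1$fscore[sel]))
  }
  # averaging a sweep with itself changes nothing
  expect_equal(pairwise_max_grid(list(sw1, sw1), "t2_t4"),
               pairwise_max_grid(sw1, "t2_t4"))
})

test_that("degenerate configurations are refused by the sweep", {
  study <- build_study(8, 8, difficulty = 0, seed = 2)
  bad <- data.frame(config_id = "z", t1 = 0, t2 = 0, t3 = 0, t4 = 0,
                    window_class = "degenerate")
  expect_error(run_sweep(study$bec$ecrs, bad, seed = 1), "degenerate")
})
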