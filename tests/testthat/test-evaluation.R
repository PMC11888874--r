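test_that("make_folds partitions 1..n into near-equal seeded blocks", {
  cfg <- cv_config(k = 5, repeats = 3, seed = 42)
  folds <- make_folds(30, cfg)
  expect_length(folds, 3L)
  for (rep_folds in folds) {
    expect_length(rep_folds, 5L)
    expect_setequal(unlist(rep_folds), 1:30)
    expect_true(all(vapply(rep_folds, length, 1L) == 6L))
  }
  sizes45 <- vapply(make_folds(45, cv_config(seed = 1))[[1]], length, 1L)
  expect_true(all(sizes45 == 9L))
  sizes7 <- sort(vapply(make_folds(7, cv_config(k = 3, seed = 1))[[1]],
                        length, 1L))
  expect_equal(unname(sizes7), c(2L, 2L, 3L))  # sizes differ by at most one

  expect_identical(make_folds(30, cfg), make_folds(30, cfg))
  expect_false(identical(folds[[1]], folds[[2]]))
  expect_error(make_folds(4, cv_config(k = 5)), "n must be >= k")
})

test_that("confusion_matrix counts predicted x true", {
  C <- confusion_matrix(rep(c("HF", "MS", "H"), each = 15),
                        rep(c("HF", "MS", "H"), each = 15),
                        c("HF", "MS", "H"))
  expect_equal(unclass(unname(as.matrix(C))), diag(c(15, 15, 15)))
  C2 <- confusion_matrix(c("A", "B"), c("B", "B"), c("A", "B"))
  expect_equal(unname(as.matrix(C2)), rbind(c(0, 1), c(0, 1)))
  C0 <- confusion_matrix(character(0), character(0), c("A", "B"))
  expect_true(all(C0 == 0))
  expect_error(confusion_matrix("Z", "A", c("A", "B")), "not in 'classes'")
})

test_that("reduce_label implements the one-vs-rest reduction exactly", {
  C <- rbind(c(13, 2, 0), c(1, 12, 1), c(1, 1, 14))
  r <- reduce_label(C, 2)
  expect_equal(r[c("TP", "FP", "FN", "TN")],
               list(TP = 12, FP = 2, FN = 3, TN = 28))
  r1 <- reduce_label(diag(c(15, 15, 15)), 1)
  expect_equal(r1[c("TP", "FP", "FN", "TN")],
               list(TP = 15, FP = 0, FN = 0, TN = 30))
  expect_error(reduce_label(C, 4), "out of range")
})

test_that("reduce_label matches the brute-force recount on random matrices", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(2:5, 1)
    C <- random_confusion(n)
    m <- sample(n, 1)
    expect_identical(reduce_label(C, m)[c("TP", "FP", "FN", "TN", "N")],
                     brute_force_reduction(C, m))
  }
})

test_that("TP/FP/FN/TN conserve totals and the micro identity holds", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(2:5, 1)
    C <- random_confusion(n)
    reds <- lapply(seq_len(n), reduce_label, C = C)
    for (r in reds) expect_equal(r$TP + r$FP + r$FN + r$TN, sum(C))
    expect_equal(sum(vapply(reds, `[[`, 0, "TP")), sum(diag(C)))
  }
})

test_that("binary_metrics evaluates the 2x2 formulas in percent", {
  m <- binary_metrics(list(TP = 15, TN = 15, FP = 0, FN = 0))
  expect_equal(as.numeric(m), c(100, 100, 100, 100))
  m2 <- binary_metrics(list(TP = 12, FP = 2, FN = 3, TN = 28))
  expect_equal(round(as.numeric(m2), 1), c(88.9, 85.7, 80.0, 82.8))
  m3 <- binary_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_equal(as.numeric(m3[c("precision", "recall", "f1")]), c(0, 0, 0))
  expect_true(all(c("precision", "f1") %in% attr(m3, "undefined")))
})

test_that("for n = 2 the reduction reproduces the direct 2x2 computation", {
  set.seed(31)
  for (i in 1:50) {
    C <- random_confusion(2)
    if (sum(C) == 0) next
    direct <- list(TP = C[1, 1], FP = C[1, 2], FN = C[2, 1], TN = C[2, 2])
    expect_equal(binary_metrics(reduce_label(C, 1)), binary_metrics(direct))
  }
})

test_that("macro_average is the arithmetic mean per metric", {
  acc <- rbind(c(accuracy = 95), c(accuracy = 93), c(accuracy = 97))
  expect_equal(unname(macro_average(acc)), 95)
  one <- matrix(c(88, 90, 92, 91), 1,
                dimnames = list(NULL, c("accuracy", "precision", "recall", "f1")))
  expect_equal(macro_average(one), one[1, ])
  expect_equal(unname(macro_average(rbind(c(0, 0), c(0, 0)))), c(0, 0))
})

test_that("cross_validate is perfect on separable blobs, chance on noise", {
  fm <- blob_features(n_per_class = 15, sep = 10, sd = 0.5, seed = 1)
  rep_ <- cross_validate(fm, kernel_spec("linear"), cv_config(seed = 1))
  expect_equal(unname(rep_$macro[["accuracy"]]), 100)
  expect_equal(unname(rep_$macro[["recall"]]), 100)
  expect_length(rep_$confusion, 5L)
  expect_equal(sum(rep_$confusion[[1]]), 45)

  # pure-noise features: macro recall near chance over a few seeds
  set.seed(2)
  rec <- vapply(1:5, function(s) {
    Xn <- matrix(rnorm(45 * 4), 45)
    fmn <- make_features(Xn, rep(c("HF", "MS", "H"), each = 15))
    cross_validate(fmn, kernel_spec("linear"),
                   cv_config(seed = s))$macro[["recall"]]
  }, 0)
  expect_lt(abs(mean(rec) - 100 / 3), 12)
})

test_that("leave-one-out on a tiny separable set is exact", {
  X <- matrix(c(0, 0.2, 0.1, 5, 5.2, 5.1), ncol = 1)
  fm <- make_features(X, rep(c("HF", "MS"), each = 3))
  rep_ <- cross_validate(fm, kernel_spec("linear"),
                         cv_config(k = 6, repeats = 1, seed = 2))
  expect_equal(unname(rep_$macro[["accuracy"]]), 100)
})

test_that("a training split losing a class warns and skips the fold", {
  X <- matrix(rnorm(12), ncol = 2)
  fm <- make_features(X, c(rep("HF", 5), "MS"))
  expect_warning(
    rep_ <- cross_validate(fm, kernel_spec("linear"),
                           cv_config(k = 3, repeats = 1, seed = 1)),
    "lost a class")
  expect_gt(length(rep_$skipped_folds), 0L)
})

test_that("rank_models sorts by accuracy then F1 then name", {
  mk <- function(name, acc, f1) {
    structure(list(per_label = NULL,
                   macro = c(accuracy = acc, precision = acc, recall = acc,
                             f1 = f1),
                   model_name = name, classes = c("HF", "MS", "H"),
                   k = 5, repeats = 5, seed = 1, skipped_folds = list()),
              class = "cpet_metrics_report")
  }
  tab <- rank_models(list(mk("B", 92, 90), mk("A", 95, 93), mk("C", 86, 80)))
  expect_equal(tab$model, c("A", "B", "C"))
  expect_equal(tab$rank, 1:3)
  tab2 <- rank_models(list(mk("Z", 90, 90), mk("Y", 90, 90)))
  expect_equal(tab2$model, c("Y", "Z"))
  tab3 <- rank_models(list(only = mk("ONLY", 50, 50)))
  expect_equal(tab3$rank, 1L)
  expect_equal(tab3$model, "only")
})
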