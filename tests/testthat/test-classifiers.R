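test_that("kernel formulas evaluate as specified", {
  x <- matrix(c(1, 0), 1)
  z <- matrix(c(0, 1), 1)
  expect_equal(kernel_matrix(kernel_spec("rbf"), x, x)[1, 1], 1)
  expect_equal(kernel_matrix(kernel_spec("rbf", scale = 2), x, z)[1, 1],
               exp(-2 / 4))
  # degree-3 polynomial with offset 1 on x.z = 1 gives (1 + 1)^3 = 8
  xy <- matrix(1, 1)
  expect_equal(kernel_matrix(kernel_spec("polynomial"), xy, xy)[1, 1], 8)
  expect_equal(kernel_matrix(kernel_spec("linear"), x, z)[1, 1], 0)
})

test_that("linear SVM separates the symmetric toy set at x = 1.5", {
  X <- rbind(c(0, 0), c(0, 1), c(3, 0), c(3, 1))
  y <- c("A", "A", "B", "B")
  fit <- fit_binary(X, labels = y)
  expect_equal(unname(predict(fit, X)), y)
  # boundary crosses x ~ 1.5: points either side classify accordingly
  probe <- rbind(c(1.2, 0.5), c(1.8, 0.5))
  expect_equal(unname(predict(fit, probe)), c("A", "B"))
  f <- attr(predict(fit, rbind(c(1.5, 0.5)), decision = TRUE), "decision")
  expect_lt(abs(f), 1e-6)
})

test_that("one point per class flips the decision sign", {
  X <- matrix(c(-1, 1), ncol = 1)
  # "A" sorts first so it is the positive (+1) class; it sits at x = -1
  fit <- fit_binary(X, labels = c("A", "B"))
  f <- attr(predict(fit, matrix(c(-1, 1), ncol = 1), decision = TRUE),
            "decision")
  expect_equal(sign(f), c(1, -1))
  expect_equal(unname(predict(fit, X)), c("A", "B"))
})

test_that("standardizer has training mean 0 / sd 1, zero-sd features map to 0", {
  set.seed(9)
  X <- cbind(rnorm(20, 50, 9), rnorm(20, 0.1, 2), rep(7, 20))
  colnames(X) <- c("a", "b", "const")
  fit <- fit_binary(X, labels = rep(c("HF", "MS"), 10))
  Xs <- cpetwave:::apply_standardizer(fit$standardizer, X)
  expect_lt(max(abs(colMeans(Xs[, 1:2]))), 1e-8)
  expect_equal(unname(apply(Xs[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-8)
  expect_true(all(Xs[, 3] == 0))
})

test_that("fit_binary rejects degenerate inputs", {
  X <- matrix(rnorm(10), 5)
  expect_error(fit_binary(X, labels = rep("HF", 5)), "2 classes")
  expect_error(fit_binary(X, labels = c("HF", "MS", "H", "HF", "MS")),
               "2 classes")
  X[1] <- NA
  expect_error(fit_binary(X, labels = rep(c("HF", "MS"), c(2, 3))),
               "non-finite")
})

test_that("ECOC trains one machine per pair and nails separable blobs", {
  fm <- blob_features()
  fit <- fit_multiclass(fm, kernel_spec("linear"))
  expect_length(fit$learners, 3L)           # C(3,2)
  expect_equal(dim(fit$coding), c(3L, 3L))
  expect_equal(unname(predict(fit, fm)), fm$labels)
  # class centroids classify to their class
  centroids <- rbind(c(0, 0), c(8, 0), c(0, 8))
  colnames(centroids) <- colnames(fm$values)
  expect_equal(unname(predict(fit, centroids)), c("HF", "MS", "H"))
  expect_error(fit_multiclass(fm$values[1:20, ], labels = fm$labels[1:20]),
               ">= 3 classes")
})

test_that("ECOC decoding minimises mean hinge loss, ties to lowest index", {
  coding <- rbind(A = c(1, 1, 0), B = c(-1, 0, 1), C = c(0, -1, -1))
  # A wins both its pairwise machines decisively
  expect_equal(cpetwave:::ecoc_decode(coding, c(3, 3, 0.1)), 1L)
  # brute-force oracle over all classes for random scores
  set.seed(4)
  for (i in 1:50) {
    s <- rnorm(3, sd = 2)
    loss <- apply(coding, 1, function(m) {
      act <- m != 0
      sum(pmax(0, 1 - m[act] * s[act]) / 2) / sum(act)
    })
    expect_equal(cpetwave:::ecoc_decode(coding, s),
                 unname(which(loss == min(loss))[1]))
  }
  # all-zero scores tie every class -> lowest index, no crash
  expect_equal(cpetwave:::ecoc_decode(coding, c(0, 0, 0)), 1L)
})

test_that("degenerate all-identical features decode without crashing", {
  X <- matrix(1, 9, 4)
  fit <- fit_multiclass(X, labels = rep(c("HF", "MS", "H"), 3))
  pred <- predict(fit, matrix(1, 2, 4))
  expect_length(pred, 2L)
  expect_true(all(pred %in% c("HF", "MS", "H")))
})

test_that("label permutation permutes predictions identically", {
  fm <- blob_features(sd = 0.4, seed = 13)
  swap <- c(HF = "MS", MS = "HF", H = "H")
  fit1 <- fit_multiclass(fm)
  fm2 <- make_features(fm$values, unname(swap[fm$labels]))
  fit2 <- fit_multiclass(fm2)
  expect_equal(unname(swap[predict(fit1, fm)]), unname(predict(fit2, fm)))
})

test_that("row order does not change predictions on separable data", {
  fm <- blob_features(seed = 3)
  ord <- rev(seq_len(nrow(fm$values)))
  fit1 <- fit_multiclass(fm)
  fit2 <- fit_multiclass(fm$values[ord, ], labels = fm$labels[ord])
  expect_equal(predict(fit1, fm$values), predict(fit2, fm$values))
})

test_that("a single pairwise machine decodes like the plain binary fit", {
  fm <- blob_features(classes = c("HF", "MS"), sd = 1.2, seed = 21)
  bin <- fit_binary(fm)
  # hand-build the one-learner ECOC wrapper around the same machine
  ecoc <- structure(list(type = "ecoc", kernel = bin$kernel,
                         classes = bin$classes,
                         standardizer = bin$standardizer,
                         feature_names = bin$feature_names,
                         coding = rbind(1L, -1L),
                         learners = list(list(sv = bin$sv, coef = bin$coef,
                                              b = bin$b))),
                    class = "cpet_svm")
  rownames(ecoc$coding) <- bin$classes
  expect_equal(predict(ecoc, fm), predict(bin, fm), ignore_attr = TRUE)
})

test_that("models persist to JSON and predict identically after reload", {
  fm <- blob_features(n_per_class = 6, seed = 30)
  for (kern in list(kernel_spec("linear"), kernel_spec("rbf", scale = 3),
                    kernel_spec("polynomial", degree = 2))) {
    fit <- fit_multiclass(fm, kern)
    p <- tempfile(fileext = ".json")
    save_model(fit, p)
    expect_identical(predict(load_model(p), fm), predict(fit, fm))
  }
  bfm <- make_features(fm$values[1:12, ], fm$labels[1:12])
  bin <- fit_binary(bfm, kernel_spec("polynomial"))
  p <- tempfile(fileext = ".json")
  save_model(bin, p)
  expect_identical(predict(load_model(p), bfm), predict(bin, bfm))
})

test_that("column mismatch in predict is a schema error", {
  fm <- blob_features(n_per_class = 4)
  fit <- fit_multiclass(fm)
  bad <- fm$values
  colnames(bad) <- c("x", "y")
  expect_error(predict(fit, bad), "do not match")
  # same columns in different order are realigned, not rejected
  reordered <- fm$values[, c(2, 1)]
  expect_equal(predict(fit, reordered), predict(fit, fm$values))
})
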