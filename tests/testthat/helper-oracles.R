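# Shared fixtures and independent oracles, built in code at test time.

# wrap a plain matrix + labels as the feature container the evaluators expect
make_features <- function(values, labels, layout = "X") {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  structure(list(values = values, labels = labels, layout = layout,
                 config = NULL),
            class = "cpet_features")
}

# three well-separated Gaussian blobs in 2D
blob_features <- function(n_per_class = 10, sep = 8, sd = 0.5, seed = 42,
                          classes = c("HF", "MS", "H")) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))[seq_along(classes), ,
                                                  drop = FALSE]
  X <- do.call(rbind, lapply(seq_along(classes), function(i)
    cbind(rnorm(n_per_class, centers[i, 1], sd),
          rnorm(n_per_class, centers[i, 2], sd))))
  make_features(X, rep(classes, each = n_per_class))
}

# brute-force one-vs-rest recount: expand a confusion matrix into its
# underlying (pred, truth) pairs and count TP/FP/FN/TN for class m directly
brute_force_reduction <- function(C, m) {
  n <- nrow(C)
  pred <- truth <- integer(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pred <- c(pred, rep(i, C[i, j]))
    truth <- c(truth, rep(j, C[i, j]))
  }
  list(TP = sum(pred == m & truth == m),
       FP = sum(pred == m & truth != m),
       FN = sum(pred != m & truth == m),
       TN = sum(pred != m & truth != m),
       N = length(pred))
}

random_confusion <- function(n_classes, max_count = 20) {
  matrix(sample(0:max_count, n_classes^2, replace = TRUE),
         n_classes, n_classes)
}

# small synthetic cohorts used across test files
tiny_cohort <- function(n_per_class = 3, classes = c("HF", "MS", "H"),
                        delta = 1, seed = 11, ...) {
  generate_cohort(synthetic_config(n_per_class = n_per_class,
                                   classes = classes, delta = delta,
                                   n_breaths = c(120L, 200L),
                                   seed = seed, ...))
}

expect_record_equal <- function(a, b, tol = 1e-8) {
  expect_identical(a$subject_id, b$subject_id)
  expect_identical(a$condition, b$condition)
  expect_identical(sort(names(a$signals)), sort(names(b$signals)))
  for (v in names(a$signals)) {
    expect_equal(a$signals[[v]], b$signals[[v]], tolerance = tol)
  }
}
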