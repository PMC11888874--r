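#' Cross-validation configuration
#'
#' @param k number of folds (default 5).
#' @param repeats number of independent repetitions of the k-fold split
#'   (default 5).
#' @param stratified if `TRUE`, folds preserve class proportions; the default
#'   `FALSE` mirrors a plain unstratified random split.
#' @param seed integer seed controlling the fold permutations.
#' @return object of class `cpet_cv_config`.
#' @export
cv_config <- function(k = 5L, repeats = 5L, stratified = FALSE, seed = 1L) {
  k <- as.integer(k); repeats <- as.integer(repeats)
  stopifnot(k >= 2L, repeats >= 1L)
  structure(list(k = k, repeats = repeats, stratified = stratified,
                 seed = as.integer(seed)),
            class = "cpet_cv_config")
}

#' Seeded unstratified k-fold partitions
#'
#' For each repeat, a seeded random permutation of `1..n` is cut into `k`
#' contiguous blocks whose sizes differ by at most one.  With
#' `stratified = TRUE` the same is done per class and the per-class folds are
#' merged.
#'
#' @param n number of samples.
#' @param cfg a [cv_config()].
#' @param labels class labels, required when `cfg$stratified`.
#' @return list of length `repeats`; each element a list of `k` disjoint
#'   index vectors covering `1..n`.
#' @export
make_folds <- function(n, cfg = cv_config(), labels = NULL) {
  stopifnot(inherits(cfg, "cpet_cv_config"))
  if (n < cfg$k) stop("n must be >= k", call. = FALSE)
  set.seed(cfg$seed)
  cut_blocks <- function(idx, k) {
    sizes <- rep(length(idx) %/% k, k)
    extra <- length(idx) %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    split(idx, rep(seq_len(k), sizes))
  }
  lapply(seq_len(cfg$repeats), function(r) {
    if (!cfg$stratified) {
      cut_blocks(sample.int(n), cfg$k)
    } else {
      stopifnot(!is.null(labels), length(labels) == n)
      per_class <- lapply(split(seq_len(n), labels), function(ix)
        cut_blocks(sample(ix), cfg$k))
      folds <- lapply(seq_len(cfg$k), function(f)
        sort(unlist(lapply(per_class, `[[`, f), use.names = FALSE)))
      folds
    }
  })
}

#' Confusion matrix with rows = predicted, columns = true
#'
#' The orientation is fixed by the label-reduction formulas: the row-m sum
#' minus the diagonal is the false-positive count for class m, the column-m
#' sum minus the diagonal the false-negative count.
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param classes ordered class vector (index m = 1 is HF for the standard
#'   cohort).
#' @return integer matrix `C` with `C[i, j]` = number of samples predicted
#'   `classes[i]` whose true label is `classes[j]`.
#' @export
confusion_matrix <- function(pred, truth, classes) {
  stopifnot(length(pred) == length(truth))
  unknown <- setdiff(unique(c(pred, truth)), classes)
  if (length(unknown)) {
    stop("label(s) not in 'classes': ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  table(factor(pred, levels = classes), factor(truth, levels = classes),
        dnn = c("predicted", "true"))
}

#' One-vs-rest reduction of a multi-class confusion matrix
#'
#' For class index `m`: `TP = C[m, m]`; `FP` = row-m sum minus `TP`;
#' `FN` = column-m sum minus `TP`; `TN` = grand total minus the other three.
#'
#' @param C square confusion matrix (rows = predicted, columns = true).
#' @param m class index, `1 <= m <= ncol(C)`.
#' @return list with integers `TP`, `FP`, `FN`, `TN` and the total `N`.
#' @export
reduce_label <- function(C, m) {
  C <- as.matrix(C)
  n <- nrow(C)
  stopifnot(n == ncol(C))
  m <- as.integer(m)
  if (m < 1L || m > n) stop("class index out of range", call. = FALSE)
  TP <- C[m, m]
  FP <- sum(C[m, ]) - TP
  FN <- sum(C[, m]) - TP
  TN <- sum(C) - TP - FP - FN
  list(TP = TP, FP = FP, FN = FN, TN = TN, N = sum(C))
}

#' Accuracy, precision, recall and F1 from one-vs-rest counts
#'
#' Percentages in `[0, 100]`.  An undefined ratio (0/0) is reported as 0 and
#' flagged in the `"undefined"` attribute; F1 is 0 when precision + recall
#' is 0.
#'
#' @param r a [reduce_label()] result (or any list with TP/FP/FN/TN).
#' @return named numeric vector `(accuracy, precision, recall, f1)` in
#'   percent.
#' @export
binary_metrics <- function(r) {
  N <- r$TP + r$FP + r$FN + r$TN
  stopifnot(N > 0)
  undef <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) { undef <<- c(undef, what); 0 } else num / den
  }
  A <- (r$TP + r$TN) / N
  P <- safe_div(r$TP, r$TP + r$FP, "precision")
  R <- safe_div(r$TP, r$TP + r$FN, "recall")
  F1 <- if (P + R == 0) { undef <- c(undef, "f1"); 0 } else 2 * P * R / (P + R)
  out <- 100 * c(accuracy = A, precision = P, recall = R, f1 = F1)
  attr(out, "undefined") <- undef
  out
}

#' Macro average of per-label metrics
#'
#' Plain arithmetic mean, metric by metric, across labels — e.g. per-label
#' accuracies (95, 93, 97) average to 95.
#'
#' @param per_label numeric matrix (labels x metrics) or list of metric
#'   vectors.
#' @return named numeric vector of macro metrics.
#' @export
macro_average <- function(per_label) {
  if (is.list(per_label)) per_label <- do.call(rbind, per_label)
  stopifnot(nrow(per_label) >= 1L)
  colMeans(per_label)
}

metrics_from_confusion <- function(C, classes) {
  per_label <- t(vapply(seq_along(classes), function(m)
    binary_metrics(reduce_label(C, m)),
    c(accuracy = 0, precision = 0, recall = 0, f1 = 0)))
  rownames(per_label) <- classes
  per_label
}

#' Repeated k-fold cross-validation of the wavelet-SVM pipeline
#'
#' For each repeat, the held-out predictions of the k folds are pooled into a
#' single confusion matrix; per-label metrics are computed from that pooled
#' matrix via [reduce_label()] and [binary_metrics()], and the reported
#' metrics are the arithmetic mean over repeats.  Standardization is refit
#' inside every training split.  A training split that lost a class entirely
#' (possible without stratification) raises a warning and the fold is skipped
#' and recorded in the report.
#'
#' @param features a `cpet_features` object (2 or >= 3 classes).
#' @param kernel a [kernel_spec()].
#' @param cfg a [cv_config()].
#' @param model_name optional display name (e.g. `"SVM-LIN-MW3"`).
#' @return object of class `cpet_metrics_report`: list with `per_label`
#'   (labels x 4 matrix, % mean over repeats), `macro` (length-4 vector),
#'   `confusion` (list of pooled per-repeat matrices), `classes`, `k`,
#'   `repeats`, `seed`, `skipped_folds`, `model_name`.
#' @export
cross_validate <- function(features, kernel = kernel_spec("linear"),
                           cfg = cv_config(), model_name = NULL) {
  stopifnot(inherits(features, "cpet_features"),
            inherits(cfg, "cpet_cv_config"))
  X <- features$values
  labels <- features$labels
  classes <- class_order(labels)
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  n <- nrow(X)
  folds <- make_folds(n, cfg, labels = labels)

  fit_fun <- if (length(classes) == 2L) fit_binary else fit_multiclass
  per_label_reps <- vector("list", cfg$repeats)
  confusions <- vector("list", cfg$repeats)
  skipped <- list()

  for (r in seq_len(cfg$repeats)) {
    pred <- rep(NA_character_, n)
    for (f in seq_len(cfg$k)) {
      test_idx <- folds[[r]][[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      if (!all(classes %in% labels[train_idx])) {
        warning(sprintf("repeat %d fold %d: training split lost a class; fold skipped",
                        r, f), call. = FALSE)
        skipped[[length(skipped) + 1L]] <- c(repeat_ = r, fold = f)
        next
      }
      model <- fit_fun(X[train_idx, , drop = FALSE], kernel,
                       seed = cfg$seed, labels = labels[train_idx])
      pred[test_idx] <- predict(model, X[test_idx, , drop = FALSE])
    }
    keep <- !is.na(pred)
    C <- confusion_matrix(pred[keep], labels[keep], classes)
    confusions[[r]] <- C
    per_label_reps[[r]] <- metrics_from_confusion(C, classes)
  }
  per_label <- Reduce(`+`, per_label_reps) / cfg$repeats
  structure(list(per_label = per_label,
                 macro = macro_average(per_label),
                 confusion = confusions, classes = classes,
                 k = cfg$k, repeats = cfg$repeats, seed = cfg$seed,
                 stratified = cfg$stratified,
                 skipped_folds = skipped,
                 model_name = model_name %||%
                   paste0("SVM-", toupper(substr(kernel$kind, 1, 3)),
                          "-", features$layout)),
            class = "cpet_metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cpet_metrics_report <- function(x, ...) {
  cat(sprintf("<cpet_metrics_report> %s: %d-fold CV x %d repeat(s), seed %d\n",
              x$model_name, x$k, x$repeats, x$seed))
  tab <- round(rbind(x$per_label, macro = x$macro))
  print(tab)
  if (length(x$skipped_folds)) {
    cat(sprintf("  (%d fold(s) skipped: training split lost a class)\n",
                length(x$skipped_folds)))
  }
  invisible(x)
}

#' Rank models by macro accuracy
#'
#' Sorts reports descending by macro accuracy, breaking ties by macro F1 and
#' then by model name, and lays the result out as a ranking table (accuracy,
#' precision, recall, F1 per model).
#'
#' @param reports named list of `cpet_metrics_report` objects (names override
#'   the reports' `model_name`s when given).
#' @param digits rounding applied to the displayed percentages (`NULL` for
#'   full precision).
#' @return data.frame with columns `rank`, `model`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
rank_models <- function(reports, digits = NULL) {
  stopifnot(length(reports) >= 1L)
  if (inherits(reports, "cpet_metrics_report")) reports <- list(reports)
  nm <- names(reports)
  if (is.null(nm)) nm <- rep("", length(reports))
  rows <- do.call(rbind, lapply(seq_along(reports), function(i) {
    rp <- reports[[i]]
    data.frame(model = if (nzchar(nm[i])) nm[i] else rp$model_name,
               accuracy = rp$macro[["accuracy"]],
               precision = rp$macro[["precision"]],
               recall = rp$macro[["recall"]],
               f1 = rp$macro[["f1"]],
               stringsAsFactors = FALSE)
  }))
  ord <- order(-rows$accuracy, -rows$f1, rows$model)
  rows <- rows[ord, , drop = FALSE]
  rows <- cbind(rank = seq_len(nrow(rows)), rows)
  rownames(rows) <- NULL
  if (!is.null(digits)) {
    num <- c("accuracy", "precision", "recall", "f1")
    rows[num] <- lapply(rows[num], round, digits = digits)
  }
  rows
}

#' Serialize a metrics report to JSON
#'
#' @param report a `cpet_metrics_report`.
#' @param path JSON output path.
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "cpet_metrics_report"))
  obj <- list(model = report$model_name, classes = report$classes,
              k = report$k, repeats = report$repeats, seed = report$seed,
              stratified = report$stratified,
              per_label = apply(report$per_label, 1L, as.list),
              macro = as.list(report$macro),
              confusion_per_repeat = lapply(report$confusion, function(C)
                unclass(as.matrix(C))),
              skipped_folds = report$skipped_folds)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
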