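# Class ordering used throughout: HF < MS < H (label indices m = 1, 2, 3).
class_order <- function(labels) {
  known <- intersect(c("HF", "MS", "H"), unique(labels))
  c(known, sort(setdiff(unique(labels), known)))
}

#' Kernel specification for the maximum-margin classifiers
#'
#' @param kind `"linear"`, `"polynomial"` or `"rbf"`.
#' @param degree polynomial degree (>= 1, default 3).
#' @param offset polynomial additive offset (default 1):
#'   `K(x, z) = (offset + x.z)^degree`.
#' @param scale RBF kernel scale (> 0, default 1):
#'   `K(x, z) = exp(-||x - z||^2 / scale^2)`.
#' @param cost box constraint C of the soft margin (> 0, default 1).
#' @return object of class `cpet_kernel`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "rbf"),
                        degree = 3L, offset = 1, scale = 1, cost = 1) {
  kind <- match.arg(kind)
  stopifnot(degree >= 1, scale > 0, cost > 0)
  structure(list(kind = kind, degree = as.integer(degree), offset = offset,
                 scale = scale, cost = cost),
            class = "cpet_kernel")
}

# Gram matrix between row sets X (n x p) and Z (m x p)
kernel_matrix <- function(spec, X, Z = X) {
  G <- X %*% t(Z)
  switch(spec$kind,
    linear = G,
    polynomial = (spec$offset + G)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * G
      exp(-pmax(d2, 0) / spec$scale^2)
    })
}

# per-feature standardizer from training rows; zero-sd features map to 0
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  list(mean = mu, sd = sd)
}

apply_standardizer <- function(std, X) {
  Xc <- sweep(X, 2L, std$mean, "-")
  s <- ifelse(std$sd > 0, std$sd, 1)
  Xs <- sweep(Xc, 2L, s, "/")
  Xs[, std$sd == 0] <- 0
  Xs
}

# SMO dual solver for the binary soft-margin problem.
# y in {-1, +1}; returns alpha and bias b of f(x) = sum_i alpha_i y_i K(x_i, x) + b.
# Working-set selection is the maximal-KKT-violating pair; convergence when
# the duality-gap surrogate m(alpha) - M(alpha) drops below `tol`.
smo_solve <- function(K, y, cost, tol = 1e-6, max_passes = NULL) {
  n <- length(y)
  if (is.null(max_passes)) max_passes <- 50000L + 200L * n
  alpha <- numeric(n)
  Fv <- numeric(n)                       # F_i = sum_j alpha_j y_j K_ij
  for (it in seq_len(max_passes)) {
    v <- y - Fv                          # -y_i * grad_i
    up  <- (y > 0 & alpha < cost) | (y < 0 & alpha > 0)
    low <- (y < 0 & alpha < cost) | (y > 0 & alpha > 0)
    if (!any(up) || !any(low)) break
    m_up <- max(v[up]); m_low <- min(v[low])
    if (m_up - m_low < tol) break
    i <- which(up)[which.max(v[up])]
    j <- which(low)[which.min(v[low])]

    Ei <- Fv[i] - y[i]; Ej <- Fv[j] - y[j]
    s <- y[i] * y[j]
    if (s > 0) {
      gamma <- alpha[i] + alpha[j]
      L <- max(0, gamma - cost); H <- min(cost, gamma)
    } else {
      gamma <- alpha[j] - alpha[i]
      L <- max(0, gamma); H <- min(cost, cost + gamma)
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 0) eta <- 1e-12
    aj_new <- min(max(alpha[j] + y[j] * (Ei - Ej) / eta, L), H)
    d_aj <- aj_new - alpha[j]
    if (abs(d_aj) < 1e-14) break         # numerically stalled at tolerance
    d_ai <- -s * d_aj
    alpha[i] <- alpha[i] + d_ai
    alpha[j] <- aj_new
    Fv <- Fv + d_ai * y[i] * K[i, ] + d_aj * y[j] * K[j, ]
  }
  v <- y - Fv
  free <- alpha > 1e-8 & alpha < cost - 1e-8
  b <- if (any(free)) mean(v[free]) else {
    up  <- (y > 0 & alpha < cost) | (y < 0 & alpha > 0)
    low <- (y < 0 & alpha < cost) | (y > 0 & alpha > 0)
    (max(v[up]) + min(v[low])) / 2
  }
  list(alpha = alpha, b = b)
}

feature_values <- function(features) {
  if (inherits(features, "cpet_features")) features$values
  else as.matrix(features)
}

feature_labels <- function(features, labels = NULL) {
  if (inherits(features, "cpet_features")) features$labels else labels
}

#' Fit a binary soft-margin kernel classifier
#'
#' Standardizes features using statistics of the training rows only, then
#' solves the soft-margin dual with an SMO solver.  The first class in
#' canonical order (HF before MS before H; otherwise alphabetical) is coded
#' `+1` and is the positive class of the decision function.
#'
#' @param features a `cpet_features` object with exactly two label values, or
#'   a numeric matrix (then supply `labels`).
#' @param kernel a [kernel_spec()].
#' @param seed integer; retained for API stability — the solver is fully
#'   deterministic, so the seed does not influence the fit.
#' @param labels character vector of row labels when `features` is a matrix.
#' @param tol SMO convergence tolerance.
#' @return object of class `cpet_svm`.
#' @export
fit_binary <- function(features, kernel = kernel_spec("linear"), seed = 1L,
                       labels = NULL, tol = 1e-6) {
  X <- feature_values(features)
  y_lab <- feature_labels(features, labels)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  classes <- class_order(y_lab)
  if (length(classes) != 2L) {
    stop("fit_binary needs exactly 2 classes, got ", length(classes),
         call. = FALSE)
  }
  y <- ifelse(y_lab == classes[1], 1, -1)
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  K <- kernel_matrix(kernel, Xs)
  sol <- smo_solve(K, y, kernel$cost, tol = tol)
  sv <- sol$alpha > 1e-10
  structure(list(type = "binary", kernel = kernel, classes = classes,
                 standardizer = std, feature_names = colnames(X),
                 sv = Xs[sv, , drop = FALSE],
                 coef = (sol$alpha * y)[sv], b = sol$b, seed = seed),
            class = "cpet_svm")
}

decision_binary <- function(model, Xs) {
  if (nrow(model$sv) == 0L) return(rep(model$b, nrow(Xs)))
  as.vector(kernel_matrix(model$kernel, Xs, model$sv) %*% model$coef) + model$b
}

#' Fit a one-vs-one ECOC multi-class classifier
#'
#' Trains one binary machine per unordered class pair (3 machines for 3
#' classes) on the full standardized feature set and stores the one-vs-one
#' coding matrix.  Prediction decodes by minimizing the mean binary hinge
#' loss across the coding matrix; ties break to the lowest class index.
#'
#' @inheritParams fit_binary
#' @return object of class `cpet_svm` (type `"ecoc"`).
#' @export
fit_multiclass <- function(features, kernel = kernel_spec("linear"),
                           seed = 1L, labels = NULL, tol = 1e-6) {
  X <- feature_values(features)
  y_lab <- feature_labels(features, labels)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  classes <- class_order(y_lab)
  if (length(classes) < 3L) {
    stop("fit_multiclass needs >= 3 classes (use fit_binary for 2)",
         call. = FALSE)
  }
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)

  pairs <- utils::combn(length(classes), 2L)
  n_learners <- ncol(pairs)
  coding <- matrix(0L, length(classes), n_learners,
                   dimnames = list(classes, NULL))
  learners <- vector("list", n_learners)
  for (l in seq_len(n_learners)) {
    i <- pairs[1, l]; j <- pairs[2, l]
    coding[i, l] <- 1L; coding[j, l] <- -1L
    sel <- y_lab %in% classes[c(i, j)]
    y <- ifelse(y_lab[sel] == classes[i], 1, -1)
    K <- kernel_matrix(kernel, Xs[sel, , drop = FALSE])
    sol <- smo_solve(K, y, kernel$cost, tol = tol)
    sv <- sol$alpha > 1e-10
    Xp <- Xs[sel, , drop = FALSE]
    learners[[l]] <- list(sv = Xp[sv, , drop = FALSE],
                          coef = (sol$alpha * y)[sv], b = sol$b)
  }
  structure(list(type = "ecoc", kernel = kernel, classes = classes,
                 standardizer = std, feature_names = colnames(X),
                 coding = coding, learners = learners, seed = seed),
            class = "cpet_svm")
}

# ECOC decode: mean hinge loss over the learners each class participates in
ecoc_decode <- function(coding, scores) {
  n_cls <- nrow(coding)
  loss <- vapply(seq_len(n_cls), function(r) {
    m <- coding[r, ]
    active <- m != 0L
    sum(pmax(0, 1 - m[active] * scores[active]) / 2) / sum(active)
  }, numeric(1))
  which.min(loss)          # which.min takes the first (lowest index) on ties
}

#' Predict condition labels
#'
#' @param object a fitted `cpet_svm`.
#' @param newdata `cpet_features` object or numeric matrix whose columns
#'   match the training feature names.
#' @param decision also return decision values / decoding losses.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.cpet_svm <- function(object, newdata, decision = FALSE, ...) {
  X <- feature_values(newdata)
  if (!is.null(object$feature_names)) {
    if (is.null(colnames(X)) || !identical(colnames(X), object$feature_names)) {
      if (!is.null(colnames(X)) &&
          setequal(colnames(X), object$feature_names)) {
        X <- X[, object$feature_names, drop = FALSE]
      } else {
        stop("feature columns of 'newdata' do not match the training columns",
             call. = FALSE)
      }
    }
  }
  Xs <- apply_standardizer(object$standardizer, X)
  if (object$type == "binary") {
    f <- decision_binary(object, Xs)
    pred <- ifelse(f >= 0, object$classes[1], object$classes[2])
    if (decision) attr(pred, "decision") <- f
    pred
  } else {
    scores <- vapply(object$learners, function(lr) {
      if (nrow(lr$sv) == 0L) rep(lr$b, nrow(Xs))
      else as.vector(kernel_matrix(object$kernel, Xs, lr$sv) %*% lr$coef) + lr$b
    }, numeric(nrow(Xs)))
    scores <- matrix(scores, nrow = nrow(Xs))
    idx <- apply(scores, 1L, function(s) ecoc_decode(object$coding, s))
    pred <- object$classes[idx]
    if (decision) attr(pred, "scores") <- scores
    pred
  }
}

#' @export
print.cpet_svm <- function(x, ...) {
  cat(sprintf("<cpet_svm> %s, kernel %s, classes: %s\n", x$type,
              x$kernel$kind, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Save / load a fitted model as self-describing JSON
#'
#' The JSON stores the kernel specification, class order, standardizer and
#' all support vectors / dual coefficients, so a reloaded model predicts
#' identically.
#'
#' @param model a `cpet_svm`.
#' @param path JSON file path.
#' @return `load_model()` returns the restored `cpet_svm`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cpet_svm"))
  ser_learner <- function(lr) list(sv = unclass(lr$sv), coef = lr$coef,
                                   b = lr$b)
  obj <- list(package = "cpetwave", type = model$type,
              kernel = unclass(model$kernel), classes = model$classes,
              standardizer = model$standardizer,
              feature_names = model$feature_names)
  if (model$type == "binary") {
    obj <- c(obj, ser_learner(model))
  } else {
    obj$coding <- model$coding
    obj$learners <- lapply(model$learners, ser_learner)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, as.numeric, 0)
  chr <- function(x) vapply(x, as.character, "")
  fn <- chr(obj$feature_names)
  kernel <- do.call(kernel_spec, obj$kernel)
  std <- list(mean = stats::setNames(num(obj$standardizer$mean), fn),
              sd = stats::setNames(num(obj$standardizer$sd), fn))
  obj$classes <- chr(obj$classes)
  # support vectors serialize as a list of rows
  as_mat <- function(sv) {
    if (!length(sv)) return(matrix(0, 0, length(fn),
                                   dimnames = list(NULL, fn)))
    m <- do.call(rbind, lapply(sv, num))
    colnames(m) <- fn
    m
  }
  if (obj$type == "binary") {
    structure(list(type = "binary", kernel = kernel, classes = obj$classes,
                   standardizer = std, feature_names = fn,
                   sv = as_mat(obj$sv), coef = num(obj$coef),
                   b = obj$b, seed = NA_integer_),
              class = "cpet_svm")
  } else {
    coding <- do.call(rbind, lapply(obj$coding, function(r)
      vapply(r, as.integer, 0L)))
    rownames(coding) <- obj$classes
    learners <- lapply(obj$learners, function(lr) {
      list(sv = as_mat(lr$sv), coef = num(lr$coef), b = lr$b)
    })
    structure(list(type = "ecoc", kernel = kernel, classes = obj$classes,
                   standardizer = std, feature_names = fn,
                   coding = coding, learners = learners, seed = NA_integer_),
              class = "cpet_svm")
  }
}
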