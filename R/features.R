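# Default variable sets.  The binary layouts use eight of the nine tabulated
# breath-by-breath variables (Vtex is dropped as redundant with Vtin, which
# yields the documented 16/64/96 column counts); the multi-class layouts use
# the five variables available for all three cohorts.
BINARY_VARIABLES <- c("METS", "HR", "VO2", "VCO2", "RER", "VE", "RR", "Vtin")
MULTI_VARIABLES  <- c("HR", "VO2", "VCO2", "VE", "RR")

LAYOUTS <- c("X", "BW3", "BW5", "MW3", "MW5")

layout_levels <- function(layout) {
  switch(layout, X = 0L, BW3 = 3L, MW3 = 3L, BW5 = 5L, MW5 = 5L)
}

layout_default_variables <- function(layout) {
  if (layout %in% c("X", "BW3", "BW5")) BINARY_VARIABLES else MULTI_VARIABLES
}

#' Feature-extraction configuration
#'
#' Fixes a feature layout and everything needed to compute it
#' deterministically.  The five layouts are: `X` — raw-signal mean and
#' variance per variable; `BW3`/`BW5` — mean and variance of every wavelet
#' component (`d1..dL`, `ap`) of each variable at 3 or 5 levels, for the
#' two-class task; `MW3`/`MW5` — the same at 3 or 5 levels for the
#' three-class task.  Column counts are `2V` for `X` and `2V(L+1)` otherwise;
#' with the default variable sets: X = 16, BW3 = 64, BW5 = 96, MW3 = 40,
#' MW5 = 60.
#'
#' @param layout one of `"X"`, `"BW3"`, `"BW5"`, `"MW3"`, `"MW5"`.
#' @param variables canonical variable names; defaults to the 8-variable
#'   binary set for `X`/`BW*` and the 5-variable set for `MW*`.
#' @param wavelet wavelet name (db2 only).
#' @param mode DWT boundary mode, see [dwt_decompose()].
#' @param variance variance convention for coefficient statistics.
#' @return object of class `cpet_feature_config`.
#' @export
feature_config <- function(layout, variables = NULL, wavelet = "db2",
                           mode = c("symmetric", "periodization"),
                           variance = c("unbiased", "biased")) {
  layout <- match.arg(layout, LAYOUTS)
  mode <- match.arg(mode)
  variance <- match.arg(variance)
  if (is.null(variables)) variables <- layout_default_variables(layout)
  bad <- setdiff(variables, CANONICAL_VARIABLES)
  if (length(bad)) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(layout = layout, variables = variables, wavelet = wavelet,
                 levels = layout_levels(layout), mode = mode,
                 variance = variance),
            class = "cpet_feature_config")
}

# feature name grammar: <VAR>__<component>__<mean|var>,
# component in {raw, d1..d5, ap}; variable-major, then component, then stat.
feature_names_for <- function(config) {
  comps <- if (config$layout == "X") "raw" else
    c(paste0("d", seq_len(config$levels)), "ap")
  unlist(lapply(config$variables, function(v)
    unlist(lapply(comps, function(cp) paste(v, cp, c("mean", "var"),
                                            sep = "__")))))
}

#' Build a subjects-by-features matrix from a cohort
#'
#' Applies the configured summary (raw or wavelet-coefficient means and
#' variances) to every record, in cohort order.  The output is deterministic:
#' the same cohort and configuration always give a bitwise-identical matrix.
#'
#' @param cohort list of [cpet_record()]s, ordered by class block.
#' @param config a [feature_config()].
#' @return object of class `cpet_features`: list with `values`
#'   (numeric matrix, rownames = subject ids, colnames = feature names),
#'   `labels` (character vector of conditions), `layout`, and `config`.
#' @export
build_feature_matrix <- function(cohort, config) {
  stopifnot(inherits(config, "cpet_feature_config"), length(cohort) >= 1L)
  fnames <- feature_names_for(config)
  rows <- lapply(cohort, function(rec) {
    stopifnot(inherits(rec, "cpet_record"))
    missing_v <- setdiff(config$variables, names(rec$signals))
    if (length(missing_v)) {
      stop(sprintf("subject %s is missing variable(s): %s", rec$subject_id,
                   paste(missing_v, collapse = ", ")), call. = FALSE)
    }
    unlist(lapply(config$variables, function(v) {
      x <- rec$signals[[v]]
      if (config$layout == "X") {
        m <- mean(x)
        va <- if (config$variance == "unbiased") stats::var(x)
              else mean((x - m)^2)
        c(m, va)
      } else {
        dec <- tryCatch(
          dwt_decompose(x, config$levels, config$wavelet, config$mode),
          error = function(e) {
            stop(sprintf("subject %s, variable %s: %s", rec$subject_id, v,
                         conditionMessage(e)), call. = FALSE)
          })
        s <- summarize_decomposition(dec, config$variance)
        as.vector(rbind(s$mean, s$variance))
      }
    }))
  })
  values <- do.call(rbind, rows)
  dimnames(values) <- list(vapply(cohort, `[[`, "", "subject_id"), fnames)
  if (any(!is.finite(values))) {
    stop("non-finite feature value produced", call. = FALSE)
  }
  structure(list(values = values,
                 labels = vapply(cohort, `[[`, "", "condition"),
                 layout = config$layout, config = config),
            class = "cpet_features")
}

#' @export
print.cpet_features <- function(x, ...) {
  cat(sprintf("<cpet_features> layout %s: %d subjects x %d features\n",
              x$layout, nrow(x$values), ncol(x$values)))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = " "), "\n")
  invisible(x)
}

#' Persist / restore a feature matrix
#'
#' CSV with header `subject_id,label,<feature names...>` plus `#` comment
#' lines recording the layout and variable order.  `load_features()`
#' re-orders shuffled feature columns back to canonical order by name and
#' rejects unknown feature names.
#'
#' @param fm a `cpet_features` object.
#' @param path CSV path.
#' @return `load_features()` returns a `cpet_features` object.
#' @export
save_features <- function(fm, path) {
  stopifnot(inherits(fm, "cpet_features"))
  header <- c(sprintf("# layout: %s", fm$layout),
              sprintf("# variables: %s",
                      paste(fm$config$variables, collapse = ",")),
              sprintf("# mode: %s", fm$config$mode),
              sprintf("# variance: %s", fm$config$variance))
  body <- cbind(subject_id = rownames(fm$values), label = fm$labels,
                apply(fm$values, 2L, function(v) sprintf("%.17g", v)))
  lines <- c(header, paste(colnames(body), collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_features
#' @export
load_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    ln <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (!length(ln)) stop("malformed feature file: missing '# ", key,
                          ":' line", call. = FALSE)
    trimws(sub(sprintf("^#\\s*%s:", key), "", ln[1]))
  }
  layout <- grab("layout")
  variables <- strsplit(grab("variables"), ",", fixed = TRUE)[[1]]
  config <- feature_config(layout, variables, mode = grab("mode"),
                           variance = grab("variance"))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(df))) {
    stop("malformed feature file: need subject_id and label columns",
         call. = FALSE)
  }
  canon <- feature_names_for(config)
  present <- setdiff(names(df), c("subject_id", "label"))
  unknown <- setdiff(present, canon)
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(present, canon)) {
    stop("feature file is missing column(s): ",
         paste(setdiff(canon, present), collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(df[, canon, drop = FALSE])
  rownames(values) <- df$subject_id
  structure(list(values = values, labels = df$label, layout = layout,
                 config = config),
            class = "cpet_features")
}

# restrict a feature matrix to rows whose label is in `keep`
subset_features <- function(fm, keep) {
  sel <- fm$labels %in% keep
  structure(list(values = fm$values[sel, , drop = FALSE],
                 labels = fm$labels[sel], layout = fm$layout,
                 config = fm$config),
            class = "cpet_features")
}
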