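# Canonical variable vocabulary (units per source documentation):
# HR beats/min, VO2 L/min, VCO2 L/min, VE L/min, RR breaths/min,
# METS (multiples of rest), RER (dimensionless), Vtex L, Vtin L.
CANONICAL_VARIABLES <- c("HR", "VO2", "VCO2", "VE", "RR",
                         "METS", "RER", "Vtex", "Vtin")

CONDITION_LEVELS <- c("HF", "MS", "H", "UNKNOWN")

#' A single subject's CPET recording
#'
#' Container for one subject's breath-by-breath cardiopulmonary exercise test:
#' a named list of per-variable sample vectors (which may differ in length
#' after per-variable cleaning), a condition label, and optional time/metadata.
#'
#' @param subject_id character scalar.
#' @param condition one of `"HF"`, `"MS"`, `"H"`, `"UNKNOWN"`.
#' @param signals named list of numeric vectors; names must be canonical
#'   variable names (`HR`, `VO2`, `VCO2`, `VE`, `RR`, `METS`, `RER`, `Vtex`,
#'   `Vtin`). Every vector must contain at least one finite sample.
#' @param time optional numeric vector of sample times (minutes).
#' @param meta optional named list (age, sex, height_cm, weight_kg, ...).
#' @return an object of class `cpet_record`.
#' @export
cpet_record <- function(subject_id, condition, signals, time = NULL,
                        meta = list()) {
  condition <- match.arg(condition, CONDITION_LEVELS)
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id)) {
    stop("'subject_id' must be a non-empty string", call. = FALSE)
  }
  if (!is.list(signals) || is.null(names(signals)) ||
      !all(nzchar(names(signals)))) {
    stop("'signals' must be a named list", call. = FALSE)
  }
  bad <- setdiff(names(signals), CANONICAL_VARIABLES)
  if (length(bad)) {
    stop("unknown signal variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  signals <- lapply(signals, as.numeric)
  empty <- names(signals)[!vapply(signals, function(v)
    any(is.finite(v)), logical(1))]
  if (length(empty)) {
    stop("signal(s) with no finite samples: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  structure(list(subject_id = subject_id, condition = condition,
                 signals = signals,
                 time = if (is.null(time)) NULL else as.numeric(time),
                 meta = meta),
            class = "cpet_record")
}

#' @export
print.cpet_record <- function(x, ...) {
  lens <- vapply(x$signals, length, 1L)
  cat(sprintf("<cpet_record> %s [%s], %d signal(s)\n",
              x$subject_id, x$condition, length(lens)))
  cat(" ", paste(sprintf("%s(n=%d)", names(lens), lens), collapse = " "), "\n")
  invisible(x)
}

#' Column maps for the two source CSV dialects
#'
#' A column map ties source CSV headers to canonical variable names, with an
#' optional positive per-variable scale factor for unit conversion.
#' `colmap_github_mshf()` matches the MS/HF source headers
#' (e.g. `"HR(beats/min)"`); `colmap_physionet_h()` matches the treadmill
#' healthy-subject export (`HR`, `VO2`, `VCO2`, `VE`, `RR` in the same units);
#' `colmap_canonical()` reads files written by [write_cpet_csv()].
#'
#' @param dialect label recorded on the map.
#' @param mapping named character vector: names are source headers, values
#'   canonical variable names.
#' @param scale optional named numeric vector of positive factors keyed by
#'   canonical variable name.
#' @param variables canonical variables the canonical map should expect.
#' @return object of class `cpet_colmap`.
#' @export
column_map <- function(dialect, mapping, scale = NULL) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  bad <- setdiff(unname(mapping), CANONICAL_VARIABLES)
  if (length(bad)) {
    stop("mapping targets must be canonical names; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(scale)) {
    stopifnot(is.numeric(scale), !is.null(names(scale)), all(scale > 0))
  }
  structure(list(dialect = dialect, mapping = mapping, scale = scale),
            class = "cpet_colmap")
}

#' @rdname column_map
#' @export
colmap_github_mshf <- function() {
  column_map("GITHUB_MSHF", c(
    "METS"             = "METS",
    "HR(beats/min)"    = "HR",
    "VO2(L/min)"       = "VO2",
    "VCO2(L/min)"      = "VCO2",
    "RER"              = "RER",
    "VE(L/min)"        = "VE",
    "RR(breaths/min)"  = "RR",
    "Vtex(L)"          = "Vtex",
    "Vtin(L)"          = "Vtin"))
}

#' @rdname column_map
#' @export
colmap_physionet_h <- function() {
  column_map("PHYSIONET_H", c(
    "HR"   = "HR",
    "VO2"  = "VO2",
    "VCO2" = "VCO2",
    "VE"   = "VE",
    "RR"   = "RR"))
}

#' @rdname column_map
#' @export
colmap_canonical <- function(variables = CANONICAL_VARIABLES) {
  column_map("CANONICAL", stats::setNames(variables, variables))
}

#' Read one subject's CPET CSV
#'
#' Parses a comma-separated file with a header row, maps the columns named in
#' `colmap` to canonical variables and drops non-numeric or missing cells per
#' variable (so signal vectors may end up with different lengths).  Leading
#' `#`-comment lines of the canonical dialect (`# subject_id:`,
#' `# condition:`, `# meta: key=value`) are honoured unless overridden by the
#' arguments.
#'
#' @param path CSV file path.
#' @param colmap a `cpet_colmap`; default canonical.
#' @param condition condition label; `NULL` uses a `# condition:` comment if
#'   present, else `"UNKNOWN"`.
#' @param subject_id subject id; `NULL` uses a `# subject_id:` comment if
#'   present, else the file name without extension.
#' @return a [cpet_record()].
#' @export
read_cpet_csv <- function(path, colmap = colmap_canonical(),
                          condition = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(colmap, "cpet_colmap"))

  lines <- readLines(path, warn = FALSE)
  hdr_comments <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (cm in hdr_comments) {
    if (grepl("^#\\s*subject_id:", cm) && is.null(subject_id)) {
      subject_id <- trimws(sub("^#\\s*subject_id:", "", cm))
    } else if (grepl("^#\\s*condition:", cm) && is.null(condition)) {
      condition <- trimws(sub("^#\\s*condition:", "", cm))
    } else if (grepl("^#\\s*meta:", cm)) {
      kv <- strsplit(trimws(sub("^#\\s*meta:", "", cm)), "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L) {
        val <- suppressWarnings(as.numeric(kv[2]))
        meta[[trimws(kv[1])]] <- if (is.na(val)) trimws(kv[2]) else val
      }
    }
  }
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(condition)) condition <- "UNKNOWN"

  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(colmap$mapping), names(df))
  # only columns actually mapped are required
  if (length(missing_cols)) {
    if (colmap$dialect == "CANONICAL") {
      # canonical files may legitimately carry a subset of variables
      colmap$mapping <- colmap$mapping[!names(colmap$mapping) %in% missing_cols]
      if (!length(colmap$mapping)) {
        stop("no canonical variable columns found in ", path, call. = FALSE)
      }
    } else {
      stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "),
           " in ", path, call. = FALSE)
    }
  }

  signals <- list()
  for (src in names(colmap$mapping)) {
    canon <- colmap$mapping[[src]]
    v <- suppressWarnings(as.numeric(df[[src]]))
    v <- v[is.finite(v)]
    if (!length(v)) {
      stop(sprintf("variable %s has no finite samples in %s", canon, path),
           call. = FALSE)
    }
    if (!is.null(colmap$scale) && canon %in% names(colmap$scale)) {
      v <- v * colmap$scale[[canon]]
    }
    signals[[canon]] <- v
  }
  time <- NULL
  if ("time" %in% names(df)) {
    tv <- suppressWarnings(as.numeric(df[["time"]]))
    time <- tv[is.finite(tv)]
  }
  cpet_record(subject_id, condition, signals, time = time, meta = meta)
}

#' Write a record in the canonical CSV dialect
#'
#' One row per breath, comma separated, '.' decimal; signals of unequal
#' length are padded with empty cells.  Subject id, condition and metadata go
#' into leading `#` comment lines so that [read_cpet_csv()] with the canonical
#' column map round-trips the record exactly (up to float-text precision).
#'
#' @param record a [cpet_record()].
#' @param path output file path.
#' @export
write_cpet_csv <- function(record, path) {
  stopifnot(inherits(record, "cpet_record"))
  cols <- record$signals
  if ("time" %in% names(cols)) stop("'time' is a reserved column name")
  if (!is.null(record$time)) cols <- c(cols, list(time = record$time))
  nmax <- max(vapply(cols, length, 1L))
  fmt <- function(v) {
    out <- rep("", nmax)
    out[seq_along(v)] <- sprintf("%.12g", v)
    out
  }
  body <- do.call(cbind, lapply(cols, fmt))
  lines <- c(
    sprintf("# subject_id: %s", record$subject_id),
    sprintf("# condition: %s", record$condition),
    if (length(record$meta)) {
      sprintf("# meta: %s=%s", names(record$meta),
              vapply(record$meta, as.character, ""))
    },
    paste(colnames(body), collapse = ","),
    apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Load an ordered cohort of CPET records
#'
#' Reads the subjects listed in a manifest, in manifest order, so that row
#' indices of downstream feature matrices follow the fixed block layout
#' (HF block first, then MS, then H).
#'
#' @param dir directory holding the per-subject CSV files.
#' @param manifest data.frame with columns `subject_id`, `condition`,
#'   `filename`, or the path of a CSV file with those columns.
#' @param colmap column map applied to every file.
#' @param allow_duplicates keep duplicated subject ids instead of erroring.
#' @return list of [cpet_record()]s in manifest order.
#' @export
load_cohort <- function(dir, manifest, colmap = colmap_canonical(),
                        allow_duplicates = FALSE) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                                comment.char = "#")
  }
  stopifnot(is.data.frame(manifest),
            all(c("subject_id", "condition", "filename") %in% names(manifest)))
  if (!nrow(manifest)) return(list())
  dup <- duplicated(manifest$subject_id)
  if (any(dup) && !allow_duplicates) {
    stop("duplicate subject id(s) in manifest: ",
         paste(unique(manifest$subject_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  paths <- file.path(dir, manifest$filename)
  absent <- !file.exists(paths)
  if (any(absent)) {
    stop("missing subject file(s) for: ",
         paste(manifest$subject_id[absent], collapse = ", "), call. = FALSE)
  }
  Map(function(p, id, cond) {
    read_cpet_csv(p, colmap = colmap, condition = cond, subject_id = id)
  }, paths, manifest$subject_id, manifest$condition)
}
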