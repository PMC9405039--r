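#' @importFrom stats predict quantile rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# The raw-table contract: a data.frame whose columns follow the schema order,
# with NA as the single missing marker, plus an optional "class" column.
# Nominal columns may hold category labels (character) before encoding or
# numeric codes after.

normalize_label <- function(x) tolower(trimws(as.character(x)))

#' Encode nominal attributes and the class label numerically
#'
#' Replaces every nominal category label by its schema code (e.g.
#' normal -> 1, abnormal -> 0), leaves numeric columns and missing entries
#' untouched, and maps the class column to +1 (`ckd`, the disease/positive
#' class) and -1 (`notckd`). A nominal column that already holds valid
#' numeric codes passes through unchanged, so encoding is idempotent.
#' Labels are matched case-insensitively with
#' surrounding whitespace stripped, so the tab-polluted variants found in
#' the UCI file ("ckd\t", " yes") encode cleanly.
#'
#' @param raw A raw table (data frame) whose columns match `schema`, with an
#'   optional final `class` column.
#' @param schema An [attribute_schema()].
#' @return The table with nominal columns numeric-coded and the class column
#'   (if present) in \{+1, -1\}.
#' @export
encode_nominal <- function(raw, schema) {
  raw <- check_raw(raw, schema)
  for (entry in schema) {
    col <- raw[[entry$name]]
    if (!is.null(entry$encoding)) {
      # already-coded column: idempotent pass-through
      if (is.numeric(col) &&
          all(col[!is.na(col)] %in% unname(entry$encoding))) {
        next
      }
      lab <- normalize_label(col)
      lab[is.na(col) | lab == ""] <- NA
      code <- unname(entry$encoding[match(lab, normalize_label(names(entry$encoding)))])
      bad <- !is.na(lab) & is.na(code)
      if (any(bad)) {
        stop("unknown category label for attribute '", entry$name, "': '",
             col[which(bad)[1]], "'")
      }
      raw[[entry$name]] <- code
    } else {
      num <- suppressWarnings(as.numeric(as.character(col)))
      if (any(!is.na(col) & trimws(as.character(col)) != "" & is.na(num))) {
        bad <- which(!is.na(col) & is.na(num))[1]
        stop("non-numeric value for numeric attribute '", entry$name,
             "': '", col[bad], "'")
      }
      num[!is.na(col) & trimws(as.character(col)) == ""] <- NA
      raw[[entry$name]] <- num
    }
  }
  if ("class" %in% names(raw)) {
    raw[["class"]] <- encode_class(raw[["class"]])
  }
  raw
}

encode_class <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(-1, 1))) stop("numeric class labels must be +1/-1")
    return(x)
  }
  lab <- normalize_label(x)
  y <- ifelse(lab == "ckd", 1, ifelse(lab == "notckd", -1, NA_real_))
  if (anyNA(y)) {
    stop("unknown class label: '", x[which(is.na(y))[1]],
         "' (expected 'ckd' or 'notckd')")
  }
  y
}

#' Fill missing entries by per-column mean imputation
#'
#' Each missing entry is replaced by the arithmetic mean of its column's
#' observed values. For nominal columns a plain mean is generally not a
#' valid code, so by default it is snapped to the nearest valid code, with
#' ties broken toward the more frequent (majority) code; this keeps binary
#' columns binary. Set `nominal = "mean"` for plain mean imputation
#' everywhere.
#'
#' Imputation statistics are computed on the table as given. For leak-free
#' cross-validation, compute them on a training fold via `stats_from` and
#' apply to held-out rows.
#'
#' @param raw An encoded table (see [encode_nominal()]).
#' @param schema An [attribute_schema()].
#' @param nominal `"round"` (default) or `"mean"`; how nominal columns are
#'   imputed.
#' @param stats_from Optional table from which to compute the column means
#'   (fold-safe mode); defaults to `raw` itself.
#' @return The table with no missing feature entries.
#' @export
impute_mean <- function(raw, schema, nominal = c("round", "mean"),
                        stats_from = NULL) {
  nominal <- match.arg(nominal)
  if (is.null(stats_from)) stats_from <- raw
  for (entry in schema) {
    col <- raw[[entry$name]]
    if (!is.numeric(col)) {
      stop("attribute '", entry$name, "' is not numeric; run encode_nominal() first")
    }
    if (!anyNA(col)) next
    ref <- stats_from[[entry$name]]
    obs <- ref[!is.na(ref)]
    if (length(obs) == 0) {
      stop("attribute '", entry$name, "' is entirely missing; mean undefined")
    }
    fill <- mean(obs)
    codes <- schema_codes(entry)
    if (entry$role != "numeric" && nominal == "round" && !is.null(codes)) {
      fill <- nearest_code(fill, codes, obs)
    }
    col[is.na(col)] <- fill
    raw[[entry$name]] <- col
  }
  raw
}

# Snap a value to the nearest valid code; ties go to the majority code among
# the observed entries, then to the smaller code.
nearest_code <- function(value, codes, observed) {
  d <- abs(codes - value)
  cand <- codes[d <= min(d) + 1e-12]
  if (length(cand) == 1L) return(cand)
  counts <- vapply(cand, function(cc) sum(observed == cc), numeric(1))
  cand <- cand[counts == max(counts)]
  min(cand)
}

#' Min-max scale selected columns and assemble the design matrix
#'
#' Columns flagged `scaled` in the schema are mapped by
#' \eqn{(x - \min x) / (\max x - \min x)} onto \[0, 1\]; age and binary
#' attributes pass through unchanged. A constant scaled column (max = min)
#' is mapped to all zeros with a warning. The class column becomes the
#' label vector.
#'
#' @param raw An encoded, complete table (see [impute_mean()]).
#' @param schema An [attribute_schema()].
#' @param y Optional label vector in \{+1, -1\}; required if `raw` has no
#'   `class` column.
#' @return A [design_matrix()].
#' @export
scale_minmax <- function(raw, schema, y = NULL) {
  nm <- schema_names(schema)
  if (is.null(y)) {
    if (!"class" %in% names(raw)) stop("no class column and no labels supplied")
    y <- raw[["class"]]
  }
  X <- as.matrix(raw[, nm, drop = FALSE])
  if (anyNA(X)) stop("missing entries remain; run impute_mean() first")
  storage.mode(X) <- "double"
  for (j in which(schema_scaled(schema))) {
    rng <- range(X[, j])
    if (rng[1] == rng[2]) {
      warning("scaled column '", nm[j], "' is constant; mapped to 0")
      X[, j] <- 0
    } else {
      X[, j] <- (X[, j] - rng[1]) / (rng[2] - rng[1])
    }
  }
  design_matrix(X, y)
}

#' Construct a design matrix with +/-1 labels
#'
#' The common currency of the package: a fully numeric feature matrix with
#' labels +1 (disease / positive class) and -1 (negative class).
#'
#' @param X Numeric matrix, one row per instance.
#' @param y Numeric vector of labels in \{+1, -1\}, length `nrow(X)`.
#' @return An object of class `design_matrix` with elements `X`, `y` and
#'   `feature_names`.
#' @export
design_matrix <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y disagree on the number of instances")
  if (anyNA(X)) stop("design matrix must not contain missing entries")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  structure(list(X = X, y = y, feature_names = colnames(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$X), "instances x", ncol(x$X), "features;",
      sum(x$y == 1), "positive /", sum(x$y == -1), "negative\n")
  invisible(x)
}

#' Restrict a design matrix to a feature subset
#'
#' @param dm A [design_matrix()].
#' @param features Character vector of feature names to keep.
#' @return A [design_matrix()] with only those columns.
#' @export
subset_features <- function(dm, features) {
  missing <- setdiff(features, dm$feature_names)
  if (length(missing)) {
    stop("unknown features: ", paste(missing, collapse = ", "))
  }
  design_matrix(dm$X[, features, drop = FALSE], dm$y)
}

#' Run the full preprocessing pipeline
#'
#' encode -> impute -> scale, in the conventional order: categorical coding
#' first, then mean imputation, then selective min-max scaling.
#'
#' @inheritParams encode_nominal
#' @inheritParams impute_mean
#' @return A [design_matrix()].
#' @export
preprocess <- function(raw, schema, nominal = c("round", "mean")) {
  nominal <- match.arg(nominal)
  enc <- encode_nominal(raw, schema)
  imp <- impute_mean(enc, schema, nominal = nominal)
  scale_minmax(imp, schema)
}

check_raw <- function(raw, schema) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  nm <- schema_names(schema)
  missing <- setdiff(nm, names(raw))
  if (length(missing)) {
    stop("raw table is missing schema attributes: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(raw), c(nm, "class"))
  if (length(extra)) {
    stop("raw table has columns not in the schema: ",
         paste(extra, collapse = ", "))
  }
  # realign to schema order, class (if any) last
  raw[, c(nm, intersect("class", names(raw))), drop = FALSE]
}

#' Read a clinical table from ARFF or CSV
#'
#' Reads the UCI CKD file dialect: ARFF with `?` as the missing marker, or
#' headered CSV where both `?` and the empty string mark missingness.
#' Columns are realigned to the schema order by header name, so a shuffled
#' CSV still parses; a header that does not cover the schema is rejected.
#'
#' @param path File path.
#' @param schema An [attribute_schema()].
#' @param format `"arff"` or `"csv"`; guessed from the file extension when
#'   omitted.
#' @return A raw table (data frame) in schema order with NA for missing.
#' @export
read_clinical_table <- function(path, schema, format = c("auto", "arff", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "arff") {
    raw <- foreign::read.arff(path)
  } else {
    raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("?", ""),
                    strip.white = TRUE, check.names = FALSE)
  }
  for (j in seq_along(raw)) {
    if (is.factor(raw[[j]])) raw[[j]] <- as.character(raw[[j]])
    if (is.character(raw[[j]])) {
      v <- trimws(raw[[j]])
      v[v == "?" | v == ""] <- NA
      raw[[j]] <- v
    }
  }
  check_raw(raw, schema)
}

#' Write a clinical table as ARFF or CSV
#'
#' The generator's round-trip counterpart of [read_clinical_table()]:
#' missing entries are written as `?` (ARFF) or empty fields (CSV).
#'
#' @param raw A raw table in schema order.
#' @param path Output path.
#' @param format `"arff"` or `"csv"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(raw, path, format = c("auto", "arff", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "arff") {
    df <- as.data.frame(raw, stringsAsFactors = FALSE)
    for (j in seq_along(df)) {
      if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
    }
    foreign::write.arff(df, path)
  } else {
    write.csv(raw, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Export a processed design matrix as CSV
#'
#' Header = feature names, final column = label as +1/-1.
#'
#' @param dm A [design_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(dm, path) {
  out <- as.data.frame(dm$X)
  out$label <- dm$y
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
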