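#' Patient-level cohort container
#'
#' Bundles a binary outcome vector, a dummy-coded design matrix and the
#' per-patient center assignment into the validated structure every other
#' function in the package consumes. Most users never call this directly:
#' [mwg_logit()] builds one from a formula and a data frame, and
#' [load_cohort()] builds one from a delimited file.
#'
#' @param y binary outcome per patient (0/1 numeric, integer or logical).
#' @param X numeric design matrix, one row per patient, dummy/reference-coded
#'   predictors without an intercept column. May have zero columns.
#' @param center_index integer center assignment per patient in `1..J`, or
#'   `NULL` for a model without center effects.
#' @param center_labels character vector of `J` center names (defaults to
#'   `C1..CJ`).
#' @param encoding optional data frame mapping design-matrix columns to
#'   covariate/level pairs (emitted by the formula interface so column order
#'   is reproducible).
#'
#' @return An object of class `"cohort_data"`: a list with elements `y`, `X`,
#'   `center_index`, `center_labels`, `n_patients`, `n_covariates`,
#'   `n_centers` and `encoding`.
#' @export
cohort_data <- function(y, X, center_index = NULL, center_labels = NULL,
                        encoding = NULL) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("outcome must be binary 0/1 with no missing values", call. = FALSE)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n)
    stop("design matrix rows must match outcome length", call. = FALSE)
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  if (is.null(center_index)) {
    center_index <- integer(n)
    J <- 0L
    center_labels <- character(0)
  } else {
    center_index <- as.integer(center_index)
    if (length(center_index) != n)
      stop("center_index length must match outcome length", call. = FALSE)
    J <- max(center_index)
    if (anyNA(center_index) || any(center_index < 1L))
      stop("center_index must be positive integers", call. = FALSE)
    if (!all(seq_len(J) %in% center_index))
      stop("every center must have at least one patient", call. = FALSE)
    if (is.null(center_labels)) center_labels <- paste0("C", seq_len(J))
    if (length(center_labels) != J)
      stop("center_labels length must equal the number of centers", call. = FALSE)
  }
  structure(list(
    y = y, X = X, center_index = center_index,
    center_labels = as.character(center_labels),
    n_patients = n, n_covariates = ncol(X), n_centers = J,
    encoding = encoding
  ), class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d centers, %d design columns\n",
              x$n_patients, x$n_centers, x$n_covariates))
  cat(sprintf("Events: %d (%.1f%%)\n", sum(x$y), 100 * mean(x$y)))
  invisible(x)
}

# build a cohort_data from formula + data.frame (+ center column name)
build_cohort <- function(formula, data, center = NULL) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  has_int <- "(Intercept)" %in% colnames(mm)
  X <- if (has_int) mm[, -match("(Intercept)", colnames(mm)), drop = FALSE] else mm
  enc <- encoding_map(attr(mf, "terms"), mf, colnames(X))
  ci <- labels <- NULL
  if (!is.null(center)) {
    if (inherits(center, "formula")) center <- all.vars(center)
    if (is.character(center)) {
      if (!center %in% names(data))
        stop(sprintf("center column '%s' not found in data", center), call. = FALSE)
      cvec <- data[[center]]
    } else cvec <- center
    if (anyNA(cvec)) stop("missing center assignments", call. = FALSE)
    f <- factor(cvec)
    ci <- as.integer(f)
    labels <- levels(f)
  }
  cohort_data(y, X, ci, labels, encoding = enc)
}

# design-column -> covariate/level map, so exported draws are interpretable
encoding_map <- function(terms, mf, colnames_X) {
  vars <- attr(terms, "term.labels")
  enc <- data.frame(column = colnames_X, covariate = NA_character_,
                    level = NA_character_, stringsAsFactors = FALSE)
  for (v in vars) {
    if (!v %in% names(mf)) next
    x <- mf[[v]]
    if (is.factor(x)) {
      for (lv in levels(x)[-1L]) {
        cn <- paste0(v, lv)
        hit <- enc$column == cn
        enc$covariate[hit] <- v
        enc$level[hit] <- lv
      }
    } else {
      hit <- enc$column == v
      enc$covariate[hit] <- v
      enc$level[hit] <- ""
    }
  }
  enc
}

#' Read a patient-level cohort from a delimited file
#'
#' Reads a CSV or TSV file (delimiter chosen by file extension) with a header
#' row, validates the declared columns and returns a [cohort_data] object plus
#' its design-matrix encoding map. Rows with missing required fields are
#' rejected with row-numbered messages; the registry workflow this package
#' models performs no imputation.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param outcome name of the binary outcome column (values 0/1).
#' @param center name of the center identifier column, or `NULL` for a model
#'   without center effects.
#' @param covariates either a character vector of covariate column names
#'   (reference level = first level in sort order) or a named list mapping
#'   covariate name to its reference level.
#'
#' @return A [cohort_data] object. Columns named in `covariates` are treated
#'   as categorical and dummy-coded against the declared reference level.
#' @export
load_cohort <- function(path, outcome, center = NULL, covariates = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty cohort file", call. = FALSE)
  refs <- NULL
  if (is.list(covariates) && !is.null(names(covariates))) {
    refs <- covariates
    covariates <- names(covariates)
  }
  need <- c(outcome, center, covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  bad <- which(rowSums(is.na(df[, need, drop = FALSE]) |
                         df[, need, drop = FALSE] == "") > 0)
  if (length(bad))
    stop(sprintf("missing values in required fields at row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  yv <- df[[outcome]]
  badY <- which(!(yv %in% c(0, 1, "0", "1")))
  if (length(badY))
    stop(sprintf("outcome must be 0/1; invalid value at row(s): %s",
                 paste(utils::head(badY, 10), collapse = ", ")), call. = FALSE)
  df[[outcome]] <- as.integer(as.character(yv))
  for (v in covariates) {
    x <- as.character(df[[v]])
    lv <- sort(unique(x))
    if (!is.null(refs)) {
      ref <- as.character(refs[[v]])
      if (!ref %in% lv)
        stop(sprintf("declared reference level '%s' not present in covariate '%s'",
                     ref, v), call. = FALSE)
      lv <- c(ref, setdiff(lv, ref))
    }
    df[[v]] <- factor(x, levels = lv)
  }
  if (!is.null(center)) {
    tab <- table(df[[center]])
    if (any(tab == 1L))
      warning(sprintf("center(s) with a single patient: %s",
                      paste(names(tab)[tab == 1L], collapse = ", ")), call. = FALSE)
  }
  fml <- stats::reformulate(if (length(covariates)) covariates else "1",
                            response = as.name(outcome))
  build_cohort(fml, df, center = center)
}

#' Write a cohort data frame to a delimited file
#'
#' @param data a data frame (e.g. the `data` element of [simulate_cohort()]).
#' @param path output path; `.csv` writes comma-separated, otherwise
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
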