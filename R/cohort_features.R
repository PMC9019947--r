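#' Truncate an ICD-10 code to its 3-character category
#'
#' ICD-10 category codes are canonically three alphanumeric characters
#' (e.g. `"J44"`), optionally followed by a dot and a sub-classification
#' (`"J44.9"`). Featurization works at category granularity, so codes are
#' uppercased, stripped of whitespace, and cut at the third character; any
#' dot separator and suffix are discarded.
#'
#' @param code character vector of ICD-10 codes.
#' @return character vector of 3-character category strings.
#' @examples
#' truncate_icd10(c("J44.9", "R05", "e11.65"))
#' @export
truncate_icd10 <- function(code) {
  if (length(code) == 0) return(character(0))
  if (!is.character(code)) stop("'code' must be a character vector", call. = FALSE)
  out <- toupper(trimws(code))
  out <- sub("\\..*$", "", out)
  bad <- is.na(out) | nchar(out) < 3L
  if (any(bad)) {
    stop(sprintf("malformed ICD-10 code(s): %s",
                 paste(unique(code[bad]), collapse = ", ")), call. = FALSE)
  }
  substr(out, 1L, 3L)
}

#' Apply the chronic-cough temporal labeling rule
#'
#' A patient qualifies as chronic cough (CC) when some contiguous calendar
#' window of `window_days` days contains at least `min_instances` cough
#' instances on distinct visit dates whose first and last dates are at least
#' `min_span_days` apart (eight weeks by default). Candidate windows are
#' anchored at each cough date; any qualifying window can be shifted to
#' start at a cough date, so this anchoring is sufficient. Distinct calendar
#' dates stand in for separate visits.
#'
#' @param dates `Date` vector (or coercible) of cough-instance dates; one
#'   entry per visit. Duplicated dates are collapsed.
#' @param window_days window length in days (default 120).
#' @param min_instances minimum number of cough instances in the window.
#' @param min_span_days minimum first-to-last span, in days, inside the
#'   window (default 56 = 8 weeks, inclusive comparison).
#' @return list with `chronic` (logical), and when `TRUE` also
#'   `window_start`/`window_end` (`Date`), the earliest qualifying window,
#'   anchored at its first qualifying cough date. An empty `dates` vector
#'   returns `chronic = FALSE`.
#' @examples
#' d0 <- as.Date("2012-01-01")
#' label_chronic_cough(d0 + c(0, 30, 60))$chronic   # TRUE: span 60 >= 56
#' label_chronic_cough(d0 + c(0, 10, 20))$chronic   # FALSE: span 20
#' label_chronic_cough(d0 + c(0, 70))$chronic       # FALSE: two instances
#' @export
label_chronic_cough <- function(dates, window_days = 120L, min_instances = 3L,
                                min_span_days = 56L) {
  if (window_days < min_span_days) {
    stop("'window_days' must be >= 'min_span_days'", call. = FALSE)
  }
  if (length(dates) == 0) return(list(chronic = FALSE))
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("cough dates contain unparseable entries", call. = FALSE)
  days <- sort(unique(as.integer(dates)))
  n <- length(days)
  if (n < min_instances) return(list(chronic = FALSE))
  for (i in seq_len(n - min_instances + 1L)) {
    inside <- days[days >= days[i] & days <= days[i] + window_days - 1L]
    if (length(inside) >= min_instances &&
        (inside[length(inside)] - inside[1L]) >= min_span_days) {
      return(list(chronic = TRUE,
                  window_start = as.Date(days[i], origin = "1970-01-01"),
                  window_end = as.Date(days[i] + window_days - 1L,
                                       origin = "1970-01-01")))
    }
  }
  list(chronic = FALSE)
}

#' Read a long-format coded patient event table
#'
#' Expects delimited text (comma or tab, auto-detected from the header line)
#' with columns `patient_id`, `event_date` (ISO-8601), `code`, and optionally
#' `domain` (one of `diagnosis`, `medication_category`, `lab_category`;
#' missing column means all rows are diagnoses).
#'
#' @param path file path.
#' @return data.frame with columns `patient_id` (character), `event_date`
#'   (`Date`), `code` (character), `domain` (character).
#' @export
read_event_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("patient_id", "event_date", "code")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tab$domain)) tab$domain <- "diagnosis"
  tab$event_date <- as.Date(tab$event_date)
  if (anyNA(tab$event_date)) stop("unparseable event_date values", call. = FALSE)
  if (any(!nzchar(tab$patient_id))) stop("empty patient_id values", call. = FALSE)
  tab[, c("patient_id", "event_date", "code", "domain")]
}

#' Build the bag-of-words term-frequency feature matrix
#'
#' Each patient's coded record is treated as a text document and each
#' truncated 3-digit ICD-10 category as a word; cell (i, j) is the number of
#' occurrences of code j for patient i (raw term frequency, no idf and no
#' binarization). Patients are ordered lexicographically by id and the
#' vocabulary lexicographically by code, so the construction is independent
#' of input row order.
#'
#' @param events event table as returned by [read_event_table()] (or any
#'   data.frame with `patient_id`, `code`, and optionally `domain`).
#' @param domain which event domain to featurize (default `"diagnosis"`).
#' @param vocabulary optional fixed character vector of 3-character codes;
#'   when supplied, codes outside it are dropped and column order follows it.
#' @return object of class `feature_matrix`: list with `values` (N x d
#'   integer matrix), `row_ids`, `vocabulary`.
#' @export
build_feature_matrix <- function(events, domain = "diagnosis",
                                 vocabulary = NULL) {
  stopifnot(is.data.frame(events))
  if (!is.null(events$domain)) events <- events[events$domain == domain, , drop = FALSE]
  if (nrow(events) == 0) {
    stop(sprintf("no events left after filtering to domain '%s'", domain),
         call. = FALSE)
  }
  codes <- truncate_icd10(events$code)
  ids <- as.character(events$patient_id)
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(codes))
  } else {
    keep <- codes %in% vocabulary
    codes <- codes[keep]
    ids <- ids[keep]
    if (length(codes) == 0) stop("no events match the supplied vocabulary", call. = FALSE)
  }
  row_ids <- sort(unique(ids))
  values <- as.matrix(table(factor(ids, levels = row_ids),
                            factor(codes, levels = vocabulary)))
  dimnames(values) <- list(row_ids, vocabulary)
  structure(list(values = values, row_ids = row_ids, vocabulary = vocabulary),
            class = "feature_matrix")
}

#' @exportS3Method print feature_matrix
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d patients x %d codes (total events %d)\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' @exportS3Method dim feature_matrix
dim.feature_matrix <- function(x) dim(x$values)

#' Persist / load a feature matrix as plain-text sparse triplets
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format), `vocabulary.txt`
#' (one code per line) and `row_ids.txt` under `dir`.
#'
#' @param fm a `feature_matrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (`write`); the `feature_matrix` (`read`).
#' @export
write_feature_matrix <- function(fm, dir) {
  stopifnot(inherits(fm, "feature_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(fm$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(fm$vocabulary, file.path(dir, "vocabulary.txt"))
  writeLines(fm$row_ids, file.path(dir, "row_ids.txt"))
  invisible(dir)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(dir) {
  values <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  vocabulary <- readLines(file.path(dir, "vocabulary.txt"))
  row_ids <- readLines(file.path(dir, "row_ids.txt"))
  dimnames(values) <- list(row_ids, vocabulary)
  structure(list(values = values, row_ids = row_ids, vocabulary = vocabulary),
            class = "feature_matrix")
}

#' Randomly match non-CC controls to the CC cohort
#'
#' Draws a uniformly random subset of the control pool of the same size as
#' the case list, so the combined analysis cohort has exactly twice as many
#' patients as there are cases. Reproducible given `seed`.
#'
#' @param cc_ids character vector of case identifiers.
#' @param non_cc_ids character vector of candidate control identifiers.
#' @param seed integer seed.
#' @return character vector of selected control ids (length `length(cc_ids)`).
#' @export
match_controls <- function(cc_ids, non_cc_ids, seed = 1L) {
  n <- length(cc_ids)
  if (length(non_cc_ids) < n) {
    stop(sprintf("need %d controls but only %d available",
                 n, length(non_cc_ids)), call. = FALSE)
  }
  if (n == 0) return(character(0))
  withr::with_seed(seed, sample(non_cc_ids, n))
}
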