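#' Construct a repeated-readings dataset
#'
#' A repeated-readings dataset holds one diameter measurement per
#' (lesion, reader, session, phase) and is the input to outlier trimming and
#' model fitting. Solid-organ lesions are measured on the long axis and lymph
#' nodes on the short axis; a dataset is fit per axis, so all records must
#' share one axis.
#'
#' @param records data frame with columns `lesion_id`, `patient_id`,
#'   `reader_id`, `session` (integer), `phase` (`"baseline"` or `"post"`),
#'   `axis` (`"long"` or `"short"`), `organ` (`"solid"` or `"lymph"`),
#'   `diameter_mm` (positive, millimetres).
#' @return An object of class `reading_dataset`: the validated data frame
#'   with an `axis_kind` attribute.
#' @seealso [read_readings_csv()], [generate_readings()]
#' @export
reading_dataset <- function(records) {
  req <- c("lesion_id", "patient_id", "reader_id", "session", "phase",
           "axis", "organ", "diameter_mm")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("readings table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) {
    stop("readings table contains no measurement rows", call. = FALSE)
  }
  records <- as.data.frame(records)[req]
  records$session <- as.integer(records$session)
  bad_phase <- !records$phase %in% c("baseline", "post")
  if (any(bad_phase)) {
    stop("invalid phase at row(s) ", paste(head(which(bad_phase)), collapse = ", "),
         ": must be 'baseline' or 'post'", call. = FALSE)
  }
  bad_axis <- !records$axis %in% c("long", "short")
  if (any(bad_axis)) {
    stop("invalid axis at row(s) ", paste(head(which(bad_axis)), collapse = ", "),
         ": must be 'long' or 'short'", call. = FALSE)
  }
  bad_organ <- !records$organ %in% c("solid", "lymph")
  if (any(bad_organ)) {
    stop("invalid organ at row(s) ", paste(head(which(bad_organ)), collapse = ", "),
         ": allowed labels are 'solid', 'lymph'", call. = FALSE)
  }
  bad_diam <- !is.finite(records$diameter_mm) | records$diameter_mm <= 0
  if (any(bad_diam)) {
    stop("non-positive diameter_mm at row(s) ",
         paste(head(which(bad_diam)), collapse = ", "), call. = FALSE)
  }
  if (length(unique(records$axis)) > 1) {
    stop("all records in a dataset must share one axis; found both ",
         "'long' and 'short' (fit the two axes separately)", call. = FALSE)
  }
  key <- paste(records$lesion_id, records$reader_id, records$session,
               records$phase, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (lesion, reader, session, phase) key at row(s) ",
         paste(head(which(dup)), collapse = ", "), call. = FALSE)
  }
  structure(records, axis_kind = records$axis[1], class = c("reading_dataset", "data.frame"))
}

#' @export
print.reading_dataset <- function(x, ...) {
  cat(sprintf("Repeated-readings dataset (%s axis): %d records, %d lesions, %d readers\n",
              attr(x, "axis_kind"), nrow(x),
              length(unique(x$lesion_id)), length(unique(x$reader_id))))
  invisible(x)
}

#' Read a repeated-readings CSV
#'
#' Comma-separated, UTF-8, header row required, decimal point. Columns:
#' `lesion_id, patient_id, reader_id, session, phase, axis, organ,
#' diameter_mm`.
#'
#' @param path path to the CSV file.
#' @return A [reading_dataset()].
#' @export
read_readings_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  reading_dataset(df)
}

#' Write a repeated-readings CSV
#'
#' @param data a [reading_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_readings_csv <- function(data, path) {
  stopifnot(inherits(data, "reading_dataset"))
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a trial dataset
#'
#' One row per target lesion with the first-reading sizes at baseline and
#' post-treatment. Patients whose progression is definitive (unequivocal
#' radiologic progression, symptomatic progression, or death) carry no
#' lesion rows; they enter denominators through `n_definitive_progression`
#' and are assigned progression probability 1 during evaluation.
#'
#' @param lesions data frame with columns `patient_id`, `organ` (`"solid"`
#'   or `"lymph"`), `baseline_mm` (> 0), `post_mm` (>= 0; 0 encodes lesion
#'   disappearance).
#' @param n_definitive_progression non-negative integer count of definitive
#'   progression patients without lesion rows.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(lesions, n_definitive_progression = 0L) {
  req <- c("patient_id", "organ", "baseline_mm", "post_mm")
  missing_cols <- setdiff(req, names(lesions))
  if (length(missing_cols) > 0) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lesions <- as.data.frame(lesions)[req]
  n_def <- as.integer(n_definitive_progression)
  if (is.na(n_def) || n_def < 0) {
    stop("n_definitive_progression must be a non-negative integer", call. = FALSE)
  }
  if (nrow(lesions) > 0) {
    bad_organ <- !lesions$organ %in% c("solid", "lymph")
    if (any(bad_organ)) {
      stop("invalid organ '", lesions$organ[which(bad_organ)[1]], "' at row ",
           which(bad_organ)[1], ": allowed labels are 'solid', 'lymph'",
           call. = FALSE)
    }
    bad_b <- !is.finite(lesions$baseline_mm) | lesions$baseline_mm <= 0
    if (any(bad_b)) {
      stop("baseline_mm must be > 0; offending row(s) ",
           paste(head(which(bad_b)), collapse = ", "), call. = FALSE)
    }
    bad_p <- !is.finite(lesions$post_mm) | lesions$post_mm < 0
    if (any(bad_p)) {
      stop("post_mm must be >= 0; offending row(s) ",
           paste(head(which(bad_p)), collapse = ", "), call. = FALSE)
    }
  }
  structure(lesions, n_definitive_progression = n_def,
            class = c("trial_dataset", "data.frame"))
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Trial dataset: %d lesions in %d patients; %d definitive-progression patients\n",
              nrow(x), length(unique(x$patient_id)),
              attr(x, "n_definitive_progression")))
  invisible(x)
}

#' Number of definitive-progression patients in a trial dataset
#' @param trial a [trial_dataset()].
#' @return Integer count.
#' @export
n_definitive_progression <- function(trial) {
  stopifnot(inherits(trial, "trial_dataset"))
  attr(trial, "n_definitive_progression")
}

#' Read a trial CSV
#'
#' Columns: `patient_id, organ, baseline_mm, post_mm`; one row per lesion.
#' The definitive-progression count is not a CSV column; pass it here (it
#' mirrors the "further information" entered alongside an uploaded table).
#'
#' @param path path to the CSV file.
#' @param n_definitive_progression see [trial_dataset()].
#' @return A [trial_dataset()].
#' @export
read_trial_csv <- function(path, n_definitive_progression = 0L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  trial_dataset(df, n_definitive_progression)
}

#' Write a trial CSV
#'
#' @param trial a [trial_dataset()].
#' @param path output path.
#' @return `path`, invisibly. The definitive-progression count is not
#'   written; it travels outside the lesion table.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_dataset"))
  write.csv(as.data.frame(trial), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-patient tumor-burden summaries
#'
#' The tumor burden is the sum of the target-lesion diameters; the percent
#' change is the relative change of the burden from baseline, in percent.
#' Downstream response thresholds operate on the fractional scale (the
#' partial-response cutoff is -0.30); this function is the single place
#' where the percent scale is produced.
#'
#' @param trial a [trial_dataset()] (definitive-progression patients have no
#'   rows and do not appear here).
#' @return Data frame with one row per patient: `patient_id`, `n_solid`,
#'   `n_lymph`, `burden_baseline_mm`, `burden_post_mm`, `percent_change`.
#' @examples
#' tr <- trial_dataset(data.frame(
#'   patient_id = c("P1", "P1"), organ = c("solid", "solid"),
#'   baseline_mm = c(30, 20), post_mm = c(21, 19)))
#' summarize_burden(tr)  # burden 50 -> 40, percent_change -20
#' @export
summarize_burden <- function(trial) {
  stopifnot(inherits(trial, "trial_dataset"))
  if (nrow(trial) == 0) {
    return(data.frame(patient_id = character(), n_solid = integer(),
                      n_lymph = integer(), burden_baseline_mm = numeric(),
                      burden_post_mm = numeric(), percent_change = numeric()))
  }
  ids <- unique(trial$patient_id)
  out <- lapply(ids, function(id) {
    les <- trial[trial$patient_id == id, , drop = FALSE]
    b <- sum(les$baseline_mm)
    p <- sum(les$post_mm)
    data.frame(patient_id = id,
               n_solid = sum(les$organ == "solid"),
               n_lymph = sum(les$organ == "lymph"),
               burden_baseline_mm = b,
               burden_post_mm = p,
               percent_change = 100 * (p - b) / b,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
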