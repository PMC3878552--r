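# Data model and I/O for multi-review binary-outcome extraction corpora.
#
# An extraction corpus holds, for each (review, study unit, outcome,
# timepoint), the four variables a review extracted: events and total for the
# index arm (arm A, total hip arthroplasty) and for the comparator arm
# (arm B, hemiarthroplasty). A cell a review did not report is stored
# explicitly with status "not_reported" so that "review omitted the study"
# is distinguishable from "row missing from the file".

OUTCOMES   <- c("dislocation", "mortality_1y", "revision")
TIMEPOINTS <- c("one_year", "thirteen_year", "unspecified")
VARIABLES  <- c("arm_a_events", "arm_a_total", "arm_b_events", "arm_b_total")
LABELS     <- c("identical", "error", "selection", "not_reported")
COUNT_COLS <- VARIABLES

#' Construct a validated extraction-audit corpus
#'
#' Bundles the extraction rows of several systematic reviews of the same
#' trials with an optional discrepancy-annotation table, the study-unit
#' register, and the identity of the reference-standard review.
#'
#' @param extractions data.frame with columns `review_id`, `study_unit_id`,
#'   `outcome_id` (one of `dislocation`, `mortality_1y`, `revision`),
#'   `timepoint` (`one_year`, `thirteen_year` or `unspecified`),
#'   `arm_a_events`, `arm_a_total`, `arm_b_events`, `arm_b_total`
#'   (non-negative integers, `NA` when not reported) and `status`
#'   (`reported` / `not_reported`).
#' @param reference_review_id review acting as the reference standard;
#'   must appear in `extractions$review_id`.
#' @param annotations optional data.frame with columns `review_id`,
#'   `study_unit_id`, `outcome_id`, `variable` (one of the four count
#'   variables), `label` (`identical`, `error`, `selection`,
#'   `not_reported`), logical `adjudicated` and free-text `rationale`.
#'   `adjudicated = TRUE` marks a judgement made against the primary trial
#'   publications rather than against the reference extraction; it is the
#'   only way a variable whose value equals the reference (or whose
#'   reference cell is not reported) can carry an `error` or `selection`
#'   label.
#' @param study_units optional data.frame with columns `unit_id`,
#'   `member_publications`, `notes`; derived from `extractions` if omitted.
#'
#' @return An object of class `audit_corpus`: a list with elements
#'   `extractions`, `annotations`, `study_units`, `reviews`,
#'   `reference_review_id`.
#' @export
audit_corpus <- function(extractions, reference_review_id,
                         annotations = NULL, study_units = NULL) {
  extractions <- validate_extractions(extractions)
  if (is.null(study_units)) {
    study_units <- data.frame(unit_id = unique(extractions$study_unit_id),
                              member_publications = "",
                              notes = "",
                              stringsAsFactors = FALSE)
  }
  study_units <- validate_study_units(study_units)
  if (is.null(annotations)) annotations <- empty_annotations()
  annotations <- validate_annotations(annotations)

  reviews <- unique(extractions$review_id)
  if (nrow(extractions) == 0L) reviews <- as.character(reference_review_id)
  if (length(reference_review_id) != 1L || !reference_review_id %in% reviews)
    stop("unknown reference_review_id: ",
         paste(reference_review_id, collapse = ", "), call. = FALSE)
  bad <- setdiff(extractions$study_unit_id, study_units$unit_id)
  if (length(bad))
    stop("extractions reference undeclared study units: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(annotations$study_unit_id, study_units$unit_id)
  if (length(bad))
    stop("annotations reference undeclared study units: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(annotations$review_id, reviews)
  if (length(bad))
    stop("annotations reference unknown reviews: ",
         paste(bad, collapse = ", "), call. = FALSE)

  structure(list(extractions = extractions,
                 annotations = annotations,
                 study_units = study_units,
                 reviews = reviews,
                 reference_review_id = reference_review_id),
            class = "audit_corpus")
}

empty_annotations <- function() {
  data.frame(review_id = character(), study_unit_id = character(),
             outcome_id = character(), variable = character(),
             label = character(), adjudicated = logical(),
             rationale = character(), stringsAsFactors = FALSE)
}

validate_extractions <- function(x) {
  need <- c("review_id", "study_unit_id", "outcome_id", "timepoint",
            COUNT_COLS, "status")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("extractions: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)[need]
  for (cc in COUNT_COLS) x[[cc]] <- as.integer(x[[cc]])
  if (nrow(x) == 0L) return(x)

  bad_row <- function(i, why)
    stop(sprintf("extractions row %d (%s/%s/%s): %s", i, x$review_id[i],
                 x$study_unit_id[i], x$outcome_id[i], why), call. = FALSE)
  for (i in seq_len(nrow(x))) {
    if (!x$outcome_id[i] %in% OUTCOMES) bad_row(i, "unknown outcome_id")
    if (!x$timepoint[i] %in% TIMEPOINTS) bad_row(i, "unknown timepoint")
    if (!x$status[i] %in% c("reported", "not_reported"))
      bad_row(i, "status must be 'reported' or 'not_reported'")
    cnt <- unlist(x[i, COUNT_COLS])
    if (x$status[i] == "reported") {
      if (anyNA(cnt)) bad_row(i, "reported row with missing counts")
      if (any(cnt < 0)) bad_row(i, "negative count")
      if (cnt["arm_a_total"] <= 0 || cnt["arm_b_total"] <= 0)
        bad_row(i, "arm totals must be positive")
      if (cnt["arm_a_events"] > cnt["arm_a_total"] ||
          cnt["arm_b_events"] > cnt["arm_b_total"])
        bad_row(i, "events exceed total")
    } else if (!all(is.na(cnt))) {
      bad_row(i, "not_reported row must have all counts absent")
    }
  }
  key <- paste(x$review_id, x$study_unit_id, x$outcome_id, x$timepoint)
  if (anyDuplicated(key))
    stop("duplicate extraction rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  x
}

validate_study_units <- function(x) {
  need <- c("unit_id", "member_publications", "notes")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("study_units: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)[need]
  x$member_publications[is.na(x$member_publications)] <- ""
  x$notes[is.na(x$notes)] <- ""
  if (anyDuplicated(x$unit_id))
    stop("duplicate study unit ids", call. = FALSE)
  x
}

validate_annotations <- function(x) {
  need <- c("review_id", "study_unit_id", "outcome_id", "variable", "label",
            "adjudicated", "rationale")
  if (!"adjudicated" %in% names(x)) x$adjudicated <- FALSE
  if (!"rationale" %in% names(x)) x$rationale <- ""
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("annotations: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)[need]
  x$adjudicated <- as.logical(x$adjudicated)
  x$adjudicated[is.na(x$adjudicated)] <- FALSE
  x$rationale[is.na(x$rationale)] <- ""
  if (nrow(x)) {
    if (!all(x$variable %in% VARIABLES))
      stop("annotations: unknown variable names", call. = FALSE)
    if (!all(x$label %in% LABELS))
      stop("annotations: unknown labels", call. = FALSE)
    if (!all(x$outcome_id %in% OUTCOMES))
      stop("annotations: unknown outcome_id", call. = FALSE)
    key <- paste(x$review_id, x$study_unit_id, x$outcome_id, x$variable)
    if (anyDuplicated(key))
      stop("duplicate annotations for: ",
           paste(unique(key[duplicated(key)]), collapse = "; "),
           call. = FALSE)
  }
  x
}

#' @export
print.audit_corpus <- function(x, ...) {
  cat("<audit_corpus>\n")
  cat("  reviews:    ", paste(x$reviews, collapse = ", "),
      " (reference: ", x$reference_review_id, ")\n", sep = "")
  cat("  study units:", nrow(x$study_units), "\n")
  cat("  extractions:", nrow(x$extractions),
      sprintf("(%d not reported)", sum(x$extractions$status == "not_reported")),
      "\n")
  cat("  annotations:", nrow(x$annotations), "\n")
  invisible(x)
}

companion_paths <- function(path) {
  stem <- sub("\\.csv$", "", path)
  list(extractions = path,
       annotations = paste0(stem, "_annotations.csv"),
       study_units = paste0(stem, "_units.csv"))
}

#' Read an extraction corpus from disk
#'
#' Two on-disk layouts are supported. `format = "csv"` reads the extraction
#' table from `path` and, when present, the companion files
#' `<stem>_annotations.csv` and `<stem>_units.csv`; the literal token `NR`
#' (or an empty cell) in a count column marks a not-reported value and
#' `reference_review_id` must be supplied. `format = "json"` reads a single
#' file with keys `extractions`, `annotations`, `study_units` and
#' `reference_review_id`.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @param reference_review_id reference review (csv only; json stores it).
#' @return An [audit_corpus()].
#' @export
read_corpus <- function(path, format = c("auto", "csv", "json"),
                        reference_review_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    ext <- decode_nr(as.data.frame(doc$extractions, stringsAsFactors = FALSE))
    ann <- if (!is.null(doc$annotations) && length(doc$annotations))
      as.data.frame(doc$annotations, stringsAsFactors = FALSE) else NULL
    units <- if (!is.null(doc$study_units) && length(doc$study_units))
      as.data.frame(doc$study_units, stringsAsFactors = FALSE) else NULL
    ref <- doc$reference_review_id
    if (!is.null(reference_review_id)) ref <- reference_review_id
    return(audit_corpus(ext, ref, annotations = ann, study_units = units))
  }

  paths <- companion_paths(path)
  ext <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  ext <- decode_nr(ext)
  ann <- if (file.exists(paths$annotations))
    utils::read.csv(paths$annotations, stringsAsFactors = FALSE) else NULL
  units <- if (file.exists(paths$study_units))
    utils::read.csv(paths$study_units, stringsAsFactors = FALSE,
                    colClasses = "character") else NULL
  if (is.null(reference_review_id))
    stop("reference_review_id must be supplied for csv corpora", call. = FALSE)
  audit_corpus(ext, reference_review_id, annotations = ann,
               study_units = units)
}

decode_nr <- function(ext) {
  for (cc in intersect(COUNT_COLS, names(ext))) {
    v <- as.character(ext[[cc]])
    v[v %in% c("NR", "")] <- NA_character_
    suppressWarnings(num <- as.integer(v))
    if (any(!is.na(v) & is.na(num)))
      stop("malformed count in column ", cc, ": ",
           paste(unique(v[!is.na(v) & is.na(num)]), collapse = ", "),
           call. = FALSE)
    ext[[cc]] <- num
  }
  ext
}

#' Write an extraction corpus to disk
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(corpus, path))`
#' restores every field including not-reported markers. The csv layout
#' writes the extraction table to `path` plus `<stem>_annotations.csv` and
#' `<stem>_units.csv`; not-reported counts are written as the literal `NR`.
#'
#' @param corpus an [audit_corpus()].
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(corpus, "audit_corpus"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"

  if (format == "json") {
    doc <- list(reference_review_id = jsonlite::unbox(corpus$reference_review_id),
                extractions = encode_nr(corpus$extractions),
                annotations = corpus$annotations,
                study_units = corpus$study_units)
    jsonlite::write_json(doc, path, dataframe = "rows", na = "null",
                         pretty = TRUE)
    return(invisible(path))
  }
  paths <- companion_paths(path)
  utils::write.csv(encode_nr(corpus$extractions), paths$extractions,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(corpus$annotations, paths$annotations,
                   row.names = FALSE)
  utils::write.csv(corpus$study_units, paths$study_units,
                   row.names = FALSE)
  invisible(path)
}

encode_nr <- function(ext) {
  for (cc in COUNT_COLS) {
    v <- as.character(ext[[cc]])
    v[is.na(v)] <- "NR"
    ext[[cc]] <- v
  }
  ext
}

#' Load the packaged hip-arthroplasty extraction corpus
#'
#' The corpus records the binary event data (events/total per arm) that
#' three systematic reviews of total hip arthroplasty versus
#' hemiarthroplasty for displaced intracapsular hip fracture ("BMJ",
#' "Cochrane" and the reference-standard "HTA" review) extracted from the
#' same randomised trials, for three outcomes: dislocation, one-year
#' mortality and revision. The Skinner 1989 / Ravikumar 2000 publications
#' are one study unit with one-year and thirteen-year timepoints. The
#' annotation table classifies every discrepant variable as an extraction
#' error or a selection difference; adjudicated annotations record
#' judgements made against the primary trial publications.
#'
#' @return An [audit_corpus()] with 3 reviews, 7 study units and 3 outcomes.
#' @export
load_fixture_corpus <- function() {
  dir <- system.file("extdata", package = "extractaudit", mustWork = TRUE)
  read_corpus(file.path(dir, "hip_extractions.csv"), format = "csv",
              reference_review_id = "HTA")
}

# Reported extraction rows of one review for one outcome, optionally at one
# timepoint ("unspecified" rows match any requested timepoint).
review_rows <- function(corpus, review_id, outcome_id, timepoint = NULL,
                        reported_only = TRUE) {
  e <- corpus$extractions
  sel <- e$review_id == review_id & e$outcome_id == outcome_id
  if (!is.null(timepoint) && timepoint != "unspecified")
    sel <- sel & e$timepoint %in% c(timepoint, "unspecified")
  if (reported_only) sel <- sel & e$status == "reported"
  e[sel, , drop = FALSE]
}

# Single extraction record (or NULL) for review/unit/outcome/timepoint.
find_extraction <- function(corpus, review_id, study_unit_id, outcome_id,
                            timepoint = NULL) {
  e <- corpus$extractions
  sel <- e$review_id == review_id & e$study_unit_id == study_unit_id &
    e$outcome_id == outcome_id
  if (!is.null(timepoint)) sel <- sel & e$timepoint == timepoint
  out <- e[sel, , drop = FALSE]
  if (nrow(out) == 0L) NULL else out
}
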