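#' @title Beat-to-beat blood pressure series
#'
#' @description Container for raw per-beat noninvasive arterial pressure as
#' produced by a finger-cuff monitor: per-beat time stamps plus systolic
#' (SAP), mean (MAP) and diastolic (DAP) pressure in mmHg, an optional heart
#' reference system (HRS) height channel in cm, and a per-beat validity flag
#' set by the preprocessing rules.
#'
#' Raw device output may violate SAP >= MAP >= DAP; such beats are candidates
#' for elimination, not construction errors.
#'
#' @param t numeric, seconds since record start, strictly increasing.
#' @param sap,map,dap numeric, pressures in mmHg, finite and positive.
#' @param hrs optional numeric, HRS height in cm; `NULL` when the channel is
#'   absent.
#' @param valid logical validity flags; defaults to all `TRUE`.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(t, sap, map, dap, hrs = NULL, valid = NULL) {
  t <- as.numeric(t); sap <- as.numeric(sap)
  map <- as.numeric(map); dap <- as.numeric(dap)
  n <- length(t)
  if (length(sap) != n || length(map) != n || length(dap) != n)
    stop("beat_series: t, sap, map, dap must have equal length", call. = FALSE)
  if (n > 1 && any(diff(t) <= 0))
    stop("beat_series: beat times must be strictly increasing", call. = FALSE)
  for (nm in c("sap", "map", "dap")) {
    v <- get(nm)
    if (n > 0 && (anyNA(v) || any(!is.finite(v)) || any(v <= 0)))
      stop(sprintf("beat_series: %s must be finite and > 0 (row %d)",
                   nm, which(!is.finite(v) | v <= 0)[1]), call. = FALSE)
  }
  if (!is.null(hrs)) {
    hrs <- as.numeric(hrs)
    if (length(hrs) != n)
      stop("beat_series: hrs must match beat count", call. = FALSE)
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  structure(list(t = t, sap = sap, map = map, dap = dap,
                 hrs = hrs, valid = as.logical(valid)),
            class = "beat_series")
}

#' @export
length.beat_series <- function(x) length(x$t)

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s; %d flagged invalid; HRS %s\n",
              length(x$t),
              if (length(x$t)) diff(range(x$t)) else 0,
              sum(!x$valid), if (is.null(x$hrs)) "absent" else "present"))
  invisible(x)
}

#' One patient's induction blood-pressure record
#'
#' Bundles a [beat_series()] with the induction time (administration of the
#' first induction agent, the origin of all analysis windows), annotated drug
#' events, and — for simulated records only — the generating ground-truth
#' class. A record is expected to span at least 5 minutes before to 15
#' minutes after induction; shorter records are admitted with a warning and
#' are normally removed later by the missing-data exclusion rules.
#'
#' @param patient_id character scalar identifier.
#' @param beats a [beat_series()].
#' @param t_induction induction time in seconds since record start.
#' @param events data frame with columns `drug`, `dose`, `units`, `time`
#'   (seconds since record start); may have zero rows.
#' @param ground_truth optional `"stable"`/`"unstable"` flag (synthetic data
#'   only; never consumed by the analysis pipeline).
#' @return An object of class `induction_record`.
#' @export
induction_record <- function(patient_id, beats, t_induction,
                             events = empty_events(), ground_truth = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats) == 0) stop("empty record", call. = FALSE)
  t_induction <- as.numeric(t_induction)
  if (!is.finite(t_induction))
    stop("induction_record: t_induction must be a finite number", call. = FALSE)
  if (t_induction < min(beats$t) || t_induction > max(beats$t))
    stop("induction_record: t_induction outside record span", call. = FALSE)
  if (min(beats$t) > t_induction - 300 || max(beats$t) < t_induction + 900)
    warning(sprintf(
      "record '%s' does not span [-300, +900] s around induction; it will likely fail the coverage check",
      patient_id), call. = FALSE)
  events <- as.data.frame(events)
  needed <- c("drug", "dose", "units", "time")
  if (!all(needed %in% names(events)))
    stop("induction_record: events need columns drug, dose, units, time", call. = FALSE)
  if (!is.null(ground_truth))
    ground_truth <- match.arg(ground_truth, c("stable", "unstable"))
  structure(list(patient_id = as.character(patient_id), beats = beats,
                 t_induction = t_induction, events = events[needed],
                 ground_truth = ground_truth),
            class = "induction_record")
}

#' @export
print.induction_record <- function(x, ...) {
  cat(sprintf("<induction_record> '%s': %d beats, induction at %.1f s, %d events%s\n",
              x$patient_id, length(x$beats), x$t_induction, nrow(x$events),
              if (is.null(x$ground_truth)) "" else paste0(" [truth: ", x$ground_truth, "]")))
  invisible(x)
}

#' @rdname induction_record
#' @export
empty_events <- function() {
  data.frame(drug = character(), dose = numeric(),
             units = character(), time = numeric())
}

#' Expert rating matrix
#'
#' Subjects-by-raters binary votes (1 = hemodynamically unstable), with an
#' optional second block of repeat sessions by the same raters for
#' intra-rater reliability.
#'
#' @param votes integer matrix in \{0, 1\}, rows = subjects, columns = raters.
#'   Dimnames supply subject and rater ids (generated when absent).
#' @param repeats optional matrix of identical shape: the same raters'
#'   second-session votes on the same subjects.
#' @return An object of class `rating_matrix`.
#' @export
rating_matrix <- function(votes, repeats = NULL) {
  votes <- as.matrix(votes)
  check_binary <- function(m, what) {
    bad <- which(!(m %in% c(0, 1)) | is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("%s: non-binary cell at subject %d, rater %d", what,
                   bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  check_binary(votes, "rating_matrix")
  if (is.null(rownames(votes))) rownames(votes) <- paste0("s", seq_len(nrow(votes)))
  if (is.null(colnames(votes))) colnames(votes) <- paste0("r", seq_len(ncol(votes)))
  if (anyDuplicated(rownames(votes)))
    stop("rating_matrix: duplicated subject id", call. = FALSE)
  if (anyDuplicated(colnames(votes)))
    stop("rating_matrix: duplicated rater id", call. = FALSE)
  if (!is.null(repeats)) {
    repeats <- as.matrix(repeats)
    if (!all(dim(repeats) == dim(votes)))
      stop("rating_matrix: repeats block must match votes dimensions", call. = FALSE)
    check_binary(repeats, "rating_matrix repeats")
    dimnames(repeats) <- dimnames(votes)
  }
  structure(list(votes = votes, repeats = repeats,
                 subjects = rownames(votes), raters = colnames(votes)),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> %d subjects x %d raters%s\n",
              nrow(x$votes), ncol(x$votes),
              if (is.null(x$repeats)) "" else " (+ repeat sessions)"))
  invisible(x)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path, ignore.case = TRUE)

#' Read an induction record from beat CSV + JSON sidecar
#'
#' The on-disk dialect is one CSV row per beat (columns `t`, `sap`, `map`,
#' `dap`, optional `hrs`) plus a JSON sidecar of the same basename holding
#' `patient_id`, `t_induction`, the annotated drug `events`, and the optional
#' synthetic `ground_truth`. The format is this package's own interchange
#' convention; unknown optional columns are ignored.
#'
#' @param path path to the beat CSV; the sidecar is `<path minus .csv>.json`.
#' @return An [induction_record()].
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing sidecar: ", side, call. = FALSE)
  df <- utils::read.csv(path)
  for (nm in c("t", "sap", "map", "dap"))
    if (!nm %in% names(df)) stop("missing channel: ", nm, call. = FALSE)
  num <- lapply(df[c("t", "sap", "map", "dap")], function(x) suppressWarnings(as.numeric(x)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad) > 0)
    stop("malformed beat row ", bad[1], " in ", path, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$t_induction)) stop("missing induction time in ", side, call. = FALSE)
  if (length(df$t) > 1 && any(diff(num$t) <= 0))
    stop("non-monotone beat times at row ",
         which(diff(num$t) <= 0)[1] + 1L, call. = FALSE)
  hrs <- if ("hrs" %in% names(df)) as.numeric(df$hrs) else NULL
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else NULL
  ev <- if (is.null(meta$events) || NROW(meta$events) == 0) empty_events() else
    as.data.frame(meta$events)
  induction_record(
    patient_id = if (is.null(meta$patient_id)) "unknown" else meta$patient_id,
    beats = beat_series(num$t, num$sap, num$map, num$dap, hrs = hrs, valid = valid),
    t_induction = meta$t_induction,
    events = ev,
    ground_truth = meta$ground_truth)
}

#' Write an induction record as beat CSV + JSON sidecar
#'
#' @param record an [induction_record()].
#' @param path destination CSV path; the JSON sidecar is written alongside.
#' @return Invisibly, `path`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "induction_record"))
  b <- record$beats
  if (length(b) == 0) stop("empty record", call. = FALSE)
  df <- data.frame(t = b$t, sap = b$sap, map = b$map, dap = b$dap)
  if (!is.null(b$hrs)) df$hrs <- b$hrs
  if (any(!b$valid)) df$valid <- b$valid
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("unwritable path: ", path, call. = FALSE)
  meta <- list(patient_id = record$patient_id,
               t_induction = record$t_induction,
               events = record$events,
               ground_truth = record$ground_truth)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)], sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read an expert rating matrix from CSV
#'
#' Expects subjects as rows (first column `subject`) and one column of 0/1
#' votes per rater.
#'
#' @param path ratings CSV path.
#' @return A [rating_matrix()].
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2) stop("ratings table needs subject column plus raters", call. = FALSE)
  subj <- as.character(df[[1]])
  if (anyDuplicated(subj))
    stop("duplicated subject id: ", subj[duplicated(subj)][1], call. = FALSE)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "numeric"
  rownames(m) <- subj
  rating_matrix(m)
}

#' @rdname read_ratings
#' @param ratings a [rating_matrix()] to serialize (repeat block not written).
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(inherits(ratings, "rating_matrix"))
  df <- data.frame(subject = ratings$subjects, ratings$votes,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read/write a feature table (one row per patient, named feature columns)
#'
#' @param x data frame with an `id` column and one numeric column per
#'   feature, as produced by [featurize_cohort()].
#' @param path CSV path.
#' @return `read_feature_table` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(is.data.frame(x), "id" %in% names(x))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, check.names = FALSE)
}
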