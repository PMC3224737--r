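#' Trial recordings, file dialect, and cohort loading
#'
#' One trial is the two-receiver 6-DOF stream of a single fast axial head
#' rotation: forehead and Th2 receivers, each contributing ZYX cardan angles
#' (degrees) and Cartesian position, nominally sampled at 60 Hz. Trials are
#' stored one per CSV file with header
#' `t,haz,hel,hro,hx,hy,hz,taz,tel,tro,tx,ty,tz`; a JSON manifest ties trial
#' files to a subject table.
#'
#' @name trial-io
NULL

.trial_channels <- c(
  "t", "haz", "hel", "hro", "hx", "hy", "hz",
  "taz", "tel", "tro", "tx", "ty", "tz"
)

#' Declare the CSV dialect of trial files
#'
#' The tracker's Euler sign conventions are not universal, so the dialect lets
#' users declare per-axis sign flips applied at read time. Angles are always
#' ZYX cardan (azimuth-elevation-roll) in degrees after normalisation.
#'
#' @param angle_signs Length-3 numeric of +/-1 multiplying
#'   (azimuth, elevation, roll) on both receivers at read time.
#' @param columns Channel names, in file order. Defaults to the package
#'   dialect; reordered files are normalised to the canonical order.
#' @return A `trial_dialect` list.
#' @export
trial_dialect <- function(angle_signs = c(1, 1, 1), columns = .trial_channels) {
  stopifnot(length(angle_signs) == 3L, all(angle_signs %in% c(-1, 1)))
  if (!setequal(columns, .trial_channels)) {
    stop("dialect columns must be a permutation of: ", paste(.trial_channels, collapse = ","))
  }
  structure(list(angle_signs = angle_signs, columns = columns), class = "trial_dialect")
}

#' Construct and validate a raw trial recording
#'
#' @param data Data frame with the 13 channels of `trial_dialect()`: time `t`
#'   (s), head Euler angles `haz,hel,hro` (deg), head position `hx,hy,hz`,
#'   thorax Euler angles `taz,tel,tro` (deg), thorax position `tx,ty,tz`.
#' @param subject_id Subject identifier string.
#' @param trial_index Trial number 1..6 within a session.
#' @param direction `"left"` or `"right"` (instructed outward direction).
#' @param session `"test1"` or `"test2"`.
#' @param sample_rate_hz Nominal sampling rate (Hz).
#' @param practice Logical; practice trials are retained but excluded from
#'   analysis.
#' @return A `trial_recording` object.
#' @export
trial_recording <- function(data, subject_id, trial_index = 1L,
                            direction = c("left", "right"),
                            session = c("test1", "test2"),
                            sample_rate_hz = 60, practice = FALSE) {
  direction <- match.arg(direction)
  session <- match.arg(session)
  data <- tibble::as_tibble(data)
  missing_ch <- setdiff(.trial_channels, names(data))
  if (length(missing_ch) > 0L) {
    stop("recording is missing channel(s): ", paste(missing_ch, collapse = ", "))
  }
  data <- data[, .trial_channels]
  n <- nrow(data)
  if (n < 2L) stop("recording must have at least 2 samples")
  if (!all(vapply(data, function(x) all(is.finite(x)), logical(1L)))) {
    stop("recording channels must be finite")
  }
  dt <- diff(data$t)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (any(abs(dt - 1 / sample_rate_hz) > 0.01 / sample_rate_hz)) {
    stop("sample spacing deviates more than 1% from 1/sample_rate_hz")
  }
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            trial_index >= 1L, sample_rate_hz > 0)
  structure(
    list(
      data = data, subject_id = subject_id, trial_index = as.integer(trial_index),
      direction = direction, session = session,
      sample_rate_hz = sample_rate_hz, practice = isTRUE(practice)
    ),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> subject %s, %s trial %d (%s rotation%s): %d samples @ %g Hz\n",
    x$subject_id, x$session, x$trial_index, x$direction,
    if (x$practice) ", practice" else "", nrow(x$data), x$sample_rate_hz
  ))
  invisible(x)
}

#' @method tidy trial_recording
#' @export
tidy.trial_recording <- function(x, ...) x$data

#' Read one trial recording from CSV
#'
#' @param path Path to a trial CSV.
#' @param dialect A [trial_dialect()].
#' @param subject_id,trial_index,direction,session,practice Trial metadata
#'   (normally supplied by the manifest via [load_cohort()]).
#' @param sample_rate_hz Nominal sampling rate.
#' @return A validated [trial_recording()].
#' @export
read_recording <- function(path, dialect = trial_dialect(), subject_id = "unknown",
                           trial_index = 1L, direction = "left", session = "test1",
                           sample_rate_hz = 60, practice = FALSE) {
  if (!file.exists(path)) stop("no such trial file: ", path)
  # base read.csv: correctly-rounded float parsing, so the shortest-round-trip
  # decimals written by write_recording() come back bit-identical
  raw <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  missing_ch <- setdiff(dialect$columns, names(raw))
  if (length(missing_ch) > 0L) {
    stop("trial file ", basename(path), " is missing channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  raw <- raw[, .trial_channels]
  sg <- dialect$angle_signs
  for (k in 1:3) {
    raw[[c("haz", "hel", "hro")[k]]] <- sg[k] * raw[[c("haz", "hel", "hro")[k]]]
    raw[[c("taz", "tel", "tro")[k]]] <- sg[k] * raw[[c("taz", "tel", "tro")[k]]]
  }
  trial_recording(raw, subject_id = subject_id, trial_index = trial_index,
                  direction = direction, session = session,
                  sample_rate_hz = sample_rate_hz, practice = practice)
}

#' Write one trial recording to CSV
#'
#' Values round-trip at full decimal precision: reading the file back yields
#' bitwise-equal channels.
#'
#' @param rec A [trial_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "trial_recording"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  readr::write_csv(rec$data, path, progress = FALSE)
  invisible(path)
}

#' Load a cohort from a JSON manifest
#'
#' The manifest lists the subject table (CSV) and one entry per trial file:
#' `{"subjects": "subjects.csv", "recordings": [{"path", "subject_id",
#' "session", "trial_index", "direction", "practice"}, ...]}`. Paths are
#' resolved relative to the manifest. Every recording must link to a subject;
#' at most six non-practice trials are allowed per subject and session, in
#' alternating directions.
#'
#' @param manifest Path to the manifest JSON.
#' @param dialect A [trial_dialect()].
#' @return A `cohort_dataset`: list with `subjects` (tibble) and `recordings`
#'   (list of [trial_recording()]).
#' @export
load_cohort <- function(manifest, dialect = trial_dialect()) {
  if (!file.exists(manifest)) stop("no such manifest: ", manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  root <- dirname(manifest)
  subjects <- readr::read_csv(file.path(root, m$subjects),
                              show_col_types = FALSE, progress = FALSE)
  if (!all(c("subject_id", "group") %in% names(subjects))) {
    stop("subject table must have subject_id and group columns")
  }
  if (!all(subjects$group %in% c("NS", "CON"))) stop("group must be NS or CON")
  recs <- lapply(m$recordings, function(e) {
    read_recording(
      file.path(root, e$path), dialect = dialect,
      subject_id = e$subject_id, trial_index = e$trial_index,
      direction = e$direction, session = e$session %||% "test1",
      practice = isTRUE(e$practice)
    )
  })
  cohort_dataset(subjects, recs)
}

#' Assemble and cross-validate a cohort dataset
#'
#' @param subjects Tibble with at least `subject_id` and `group` (`NS`/`CON`);
#'   typically also `age_years`, `low_back_pain` and questionnaire columns.
#' @param recordings List of [trial_recording()] objects.
#' @param schema_version Dataset schema tag.
#' @return A `cohort_dataset` object.
#' @export
cohort_dataset <- function(subjects, recordings, schema_version = "1") {
  subjects <- tibble::as_tibble(subjects)
  orphans <- setdiff(
    vapply(recordings, function(r) r$subject_id, character(1L)),
    subjects$subject_id
  )
  if (length(orphans) > 0L) {
    stop("recording(s) reference unknown subject_id: ", paste(unique(orphans), collapse = ", "))
  }
  idx <- tibble::tibble(
    subject_id = vapply(recordings, function(r) r$subject_id, character(1L)),
    session = vapply(recordings, function(r) r$session, character(1L)),
    trial_index = vapply(recordings, function(r) r$trial_index, integer(1L)),
    direction = vapply(recordings, function(r) r$direction, character(1L)),
    practice = vapply(recordings, function(r) r$practice, logical(1L))
  )
  real <- idx[!idx$practice, ]
  if (nrow(real) > 0L) {
    counts <- dplyr::count(real, .data$subject_id, .data$session)
    if (any(counts$n > 6L)) {
      bad <- counts[counts$n > 6L, ]
      stop("more than 6 non-practice trials for subject ", bad$subject_id[1L],
           " session ", bad$session[1L])
    }
    alt_ok <- real |>
      dplyr::arrange(.data$subject_id, .data$session, .data$trial_index) |>
      dplyr::group_by(.data$subject_id, .data$session) |>
      dplyr::summarise(
        ok = dplyr::n() < 2L || all(diff(match(.data$direction, c("left", "right"))) != 0L),
        .groups = "drop"
      )
    if (!all(alt_ok$ok)) {
      bad <- alt_ok[!alt_ok$ok, ]
      stop("trial directions do not alternate for subject ", bad$subject_id[1L])
    }
  }
  structure(
    list(subjects = subjects, recordings = recordings, schema_version = schema_version),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset> %d subjects (%d NS / %d CON), %d recordings\n",
    nrow(x$subjects), sum(x$subjects$group == "NS"), sum(x$subjects$group == "CON"),
    length(x$recordings)
  ))
  invisible(x)
}

#' Write a cohort to disk (trial CSVs + manifest + subject table)
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest JSON, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- vector("list", length(cohort$recordings))
  for (i in seq_along(cohort$recordings)) {
    r <- cohort$recordings[[i]]
    fn <- sprintf("%s_%s_trial%d.csv", r$subject_id, r$session, r$trial_index)
    write_recording(r, file.path(dir, fn))
    entries[[i]] <- list(
      path = fn, subject_id = r$subject_id, session = r$session,
      trial_index = r$trial_index, direction = r$direction, practice = r$practice
    )
  }
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"), progress = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(subjects = "subjects.csv", recordings = entries),
    manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
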