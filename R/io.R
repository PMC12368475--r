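#' Convert video frames to seconds
#'
#' @param frames Non-negative frame count (vectorized).
#' @param fps Frames per second (> 0); the study videos were recorded at 30.
#' @return `frames / fps`, in seconds.
#' @export
#' @examples
#' frames_to_seconds(45)        # 1.5 s at 30 fps
frames_to_seconds <- function(frames, fps = 30) {
  if (any(fps <= 0)) stop("fps must be > 0", call. = FALSE)
  if (any(frames < 0)) stop("frames must be non-negative", call. = FALSE)
  frames / fps
}

#' Read event-level ethogram data into a validated dataset
#'
#' The events file has one row per coded behavior with columns
#' `animal_id, food, trial, behavior, start_frame, end_frame, n_chews`
#' (`n_chews` empty for bites).  Behavior labels may use common shorthand
#' ("ant. bite", "post_bite", "AB", ...); unknown labels are a parse error
#' reported with their row number.  Rows are grouped into feeding sequences
#' by (animal, food, trial) and ordered by start frame; every sequence must
#' resolve against the roster and food table.
#'
#' @param path Path to `events.csv`.
#' @param roster_path Path to `animals.csv`
#'   (`animal_id, age_class, sex, body_mass_kg, origin`).
#' @param foods_path Path to `foods.csv`
#'   (`food, volume_cm3, toughness_Jm2, elastic_modulus_MPa`).
#' @param fps Frames per second of the source video.
#' @return An `ethogram_dataset`.
#' @export
read_events <- function(path, roster_path, foods_path, fps = 30) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal_id = "character",
                                       food = "character",
                                       trial = "character"))
  need <- c("animal_id", "food", "trial", "behavior",
            "start_frame", "end_frame", "n_chews")
  if (!all(need %in% names(ev))) {
    stop("events file must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  animals <- utils::read.csv(roster_path, stringsAsFactors = FALSE,
                             colClasses = c(animal_id = "character",
                                            sex = "character"))
  foods <- utils::read.csv(foods_path, stringsAsFactors = FALSE,
                           colClasses = c(food = "character"))

  if (nrow(ev) == 0L) {
    return(ethogram_dataset(list(), animals, foods))
  }

  lab <- canonical_label(ev$behavior)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1]
    stop("parse error at row ", bad, ": unknown behavior label '",
         ev$behavior[bad], "' (closed set: ",
         paste(behavior_labels(), collapse = ", "), ")", call. = FALSE)
  }
  ev$behavior <- lab
  n_chews <- suppressWarnings(as.integer(ev$n_chews))
  chew_missing <- ev$behavior == "CHEW" & (is.na(n_chews) | n_chews < 1)
  if (any(chew_missing)) {
    stop("parse error at row ", which(chew_missing)[1],
         ": CHEW event lacks n_chews >= 1", call. = FALSE)
  }

  key <- paste(ev$animal_id, ev$food, ev$trial, sep = "|")
  sequences <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    idx <- idx[order(ev$start_frame[idx])]
    feeding_sequence(
      animal_id = ev$animal_id[idx[1]],
      food_name = ev$food[idx[1]],
      trial_id  = ev$trial[idx[1]],
      events = data.frame(
        label       = ev$behavior[idx],
        start_frame = as.integer(ev$start_frame[idx]),
        end_frame   = as.integer(ev$end_frame[idx]),
        n_chews     = ifelse(ev$behavior[idx] == "CHEW", n_chews[idx], NA_integer_)
      ),
      fps = fps
    )
  })
  names(sequences) <- NULL
  ethogram_dataset(sequences, animals, foods)
}

#' Write event-level ethogram data
#'
#' Writes the sequences of a dataset back to the `events.csv` layout with
#' canonical behavior labels.  `write_dataset()` additionally writes the
#' roster and food tables so that `read_dataset()` round-trips the full
#' object field-for-field.
#'
#' @param dataset An `ethogram_dataset`.
#' @param path Output path for the events file.
#' @return `path`, invisibly.
#' @export
write_events <- function(dataset, path) {
  rows <- lapply(dataset$sequences, function(s) {
    data.frame(
      animal_id   = s$animal_id,
      food        = s$food_name,
      trial       = s$trial_id,
      behavior    = s$events$label,
      start_frame = s$events$start_frame,
      end_frame   = s$events$end_frame,
      n_chews     = s$events$n_chews
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = character(), food = character(),
               trial = character(), behavior = character(),
               start_frame = integer(), end_frame = integer(),
               n_chews = integer())
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @param dir Directory receiving `events.csv`, `animals.csv`, `foods.csv`.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_events(dataset, file.path(dir, "events.csv"))
  utils::write.csv(dataset$animals, file.path(dir, "animals.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$foods, file.path(dir, "foods.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_events
#' @param fps Frames per second used when reading back.
#' @export
read_dataset <- function(dir, fps = 30) {
  read_events(file.path(dir, "events.csv"),
              file.path(dir, "animals.csv"),
              file.path(dir, "foods.csv"),
              fps = fps)
}

#' Bundled study tables
#'
#' `default_foods()` returns the five experimental foods with their measured
#' volume (cm^3, by water displacement), toughness (J m^-2) and elastic
#' modulus (MPa).  `default_roster()` returns the 29-animal study roster
#' (age class, sex, body mass, origin) together with the per-food trial
#' counts observed in the study; rejected trials are simply absent.
#'
#' @return A data.frame.
#' @export
default_foods <- function() {
  utils::read.csv(system.file("extdata", "foods.csv", package = "oralproc"),
                  stringsAsFactors = FALSE)
}

#' @rdname default_foods
#' @export
default_roster <- function() {
  utils::read.csv(system.file("extdata", "animals.csv", package = "oralproc"),
                  stringsAsFactors = FALSE,
                  colClasses = c(animal_id = "character",
                                 sex = "character"))
}
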