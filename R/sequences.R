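#' @title Domain objects: feeding sequences, animals, foods, datasets
#' @description
#' A feeding sequence is the ordered list of coded behaviors from the moment
#' a food item enters the oral cavity to the last swallow or discard of that
#' item, for one trial of one animal on one food.  Event times are stored as
#' integer video frames (default 30 frames per second) and converted to
#' seconds only when metrics are computed, so no float drift accumulates in
#' the stored data.
#' @name oralproc-objects
NULL

.age_classes <- c("INFANT", "JUVENILE", "OLDER_JUVENILE", "SUBADULT_ADULT")
.sexes       <- c("F", "M")
.origins     <- c("CAPTIVE", "SEMI_WILD")

#' Age class, sex and origin level sets
#'
#' Closed factor level sets used across the package.  Age classes follow
#' molar eruption stages: infant (no permanent molars in occlusion),
#' juvenile (M1), older juvenile (M2), subadult/adult (M3).
#'
#' @return Character vector of levels.
#' @export
age_classes <- function() .age_classes

#' @rdname age_classes
#' @export
sex_levels <- function() .sexes

#' Construct a feeding sequence
#'
#' @param animal_id,food_name,trial_id Identifiers (coerced to character).
#' @param events A data.frame with columns `label` (canonical behavior
#'   label), `start_frame`, `end_frame` (non-negative integers,
#'   `end_frame >= start_frame`), and `n_chews` (positive integer for
#'   `CHEW` events, `NA` for bites).
#' @param fps Frames per second of the source video (default 30).
#' @return An object of class `feeding_sequence`.
#' @export
feeding_sequence <- function(animal_id, food_name, trial_id, events, fps = 30) {
  seq <- structure(
    list(
      animal_id = as.character(animal_id),
      food_name = as.character(food_name),
      trial_id  = as.character(trial_id),
      events    = as.data.frame(events),
      fps       = fps
    ),
    class = "feeding_sequence"
  )
  validate_sequence(seq)
  seq
}

#' Validate a feeding sequence
#'
#' Checks every structural invariant of the event list: closed label set,
#' non-negative integer frames with `end >= start`, events non-decreasing in
#' start frame, and `n_chews` present (>= 1) exactly for `CHEW` events.
#'
#' @param seq A `feeding_sequence`.
#' @return `seq`, invisibly; signals an error naming the violated rule.
#' @export
validate_sequence <- function(seq) {
  ev <- seq$events
  req <- c("label", "start_frame", "end_frame", "n_chews")
  if (!all(req %in% names(ev))) {
    stop("events must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ev) < 1L) {
    stop("feeding sequence must contain at least one event (animal ",
         seq$animal_id, ", food ", seq$food_name, ", trial ", seq$trial_id,
         ")", call. = FALSE)
  }
  if (!is.numeric(seq$fps) || length(seq$fps) != 1L || seq$fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  bad <- !ev$label %in% .age_set_labels()
  if (any(bad)) {
    stop("unknown behavior label(s): ",
         paste(unique(ev$label[bad]), collapse = ", "),
         " (closed set: ", paste(behavior_labels(), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(ev$start_frame < 0) || any(ev$start_frame != floor(ev$start_frame))) {
    stop("start_frame must be a non-negative integer", call. = FALSE)
  }
  if (any(ev$end_frame < ev$start_frame)) {
    stop("end_frame must be >= start_frame", call. = FALSE)
  }
  if (is.unsorted(ev$start_frame)) {
    stop("events must be non-decreasing in start_frame", call. = FALSE)
  }
  is_chew <- ev$label == "CHEW"
  if (any(is_chew & (is.na(ev$n_chews) | ev$n_chews < 1))) {
    stop("CHEW events must carry n_chews >= 1", call. = FALSE)
  }
  if (any(!is_chew & !is.na(ev$n_chews) & ev$n_chews != 0)) {
    stop("n_chews must be absent (NA or 0) for bite events", call. = FALSE)
  }
  invisible(seq)
}

.age_set_labels <- function() behavior_labels()

#' @export
print.feeding_sequence <- function(x, ...) {
  cat("<feeding_sequence> animal", x$animal_id, "| food", x$food_name,
      "| trial", x$trial_id, "|", nrow(x$events), "events @", x$fps, "fps\n")
  invisible(x)
}

#' Number of events in a feeding sequence
#' @param seq A `feeding_sequence`.
#' @return Integer event count.
#' @export
n_events <- function(seq) nrow(seq$events)

#' Assemble a validated dataset
#'
#' Binds feeding sequences to their covariate tables and checks referential
#' integrity: every sequence's animal and food must resolve, and
#' (animal, food, trial) keys must be unique.  Empty animal-by-food cells
#' are permitted (e.g., infants that never consumed popcorn).
#'
#' @param sequences List of `feeding_sequence` objects.
#' @param animals Roster data.frame with columns `animal_id`, `age_class`,
#'   `sex`, `body_mass_kg`, `origin`.
#' @param foods Food-property data.frame with columns `food`, `volume_cm3`,
#'   `toughness_Jm2`, `elastic_modulus_MPa` (all three properties > 0).
#' @return An object of class `ethogram_dataset`.
#' @export
ethogram_dataset <- function(sequences, animals, foods) {
  animals <- as.data.frame(animals)
  foods <- as.data.frame(foods)
  rownames(animals) <- NULL
  rownames(foods) <- NULL
  ds <- structure(
    list(sequences = sequences, animals = animals, foods = foods),
    class = "ethogram_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate an `ethogram_dataset`
#'
#' @param ds An `ethogram_dataset`.
#' @return `ds`, invisibly; errors name the offending key.
#' @export
validate_dataset <- function(ds) {
  an <- ds$animals
  fo <- ds$foods
  need_an <- c("animal_id", "age_class", "sex", "body_mass_kg", "origin")
  need_fo <- c("food", "volume_cm3", "toughness_Jm2", "elastic_modulus_MPa")
  if (!all(need_an %in% names(an))) {
    stop("animals table must have columns ", paste(need_an, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_fo %in% names(fo))) {
    stop("foods table must have columns ", paste(need_fo, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(an$animal_id)) {
    stop("duplicate animal_id in roster: ",
         paste(unique(an$animal_id[duplicated(an$animal_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(an$age_class %in% .age_classes)) {
    stop("age_class must be one of ", paste(.age_classes, collapse = ", "),
         call. = FALSE)
  }
  if (!all(an$sex %in% .sexes)) {
    stop("sex must be F or M", call. = FALSE)
  }
  if (!all(an$origin %in% .origins)) {
    stop("origin must be CAPTIVE or SEMI_WILD", call. = FALSE)
  }
  if (any(an$body_mass_kg <= 0)) {
    stop("body_mass_kg must be positive", call. = FALSE)
  }
  prop <- as.matrix(fo[, c("volume_cm3", "toughness_Jm2", "elastic_modulus_MPa")])
  if (any(prop <= 0)) {
    stop("food volume, toughness and elastic modulus must all be positive",
         call. = FALSE)
  }
  for (s in ds$sequences) {
    validate_sequence(s)
    if (!s$animal_id %in% an$animal_id) {
      stop("referential integrity: animal '", s$animal_id,
           "' in events is not in the roster", call. = FALSE)
    }
    if (!s$food_name %in% fo$food) {
      stop("referential integrity: food '", s$food_name,
           "' in events is not in the food table", call. = FALSE)
    }
  }
  keys <- vapply(ds$sequences, sequence_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (animal, food, trial) key: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "),
         call. = FALSE)
  }
  invisible(ds)
}

#' Unique key of a feeding sequence
#' @param seq A `feeding_sequence`.
#' @return `"animal|food|trial"` string.
#' @export
sequence_key <- function(seq) {
  paste(seq$animal_id, seq$food_name, seq$trial_id, sep = "|")
}

#' @export
print.ethogram_dataset <- function(x, ...) {
  cat("<ethogram_dataset>", length(x$sequences), "feeding sequences |",
      nrow(x$animals), "animals |", nrow(x$foods), "foods\n")
  invisible(x)
}
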