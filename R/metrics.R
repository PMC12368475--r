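#' Feeding sequence duration
#'
#' Total duration of time (in seconds) of a feeding sequence.  By default
#' this is the span from the start of the first event to the end of the
#' last event, so pauses in handling between coded behaviors count toward
#' the total.  `mode = "sum_of_events"` instead sums the durations of the
#' coded events only, for sensitivity analysis.
#'
#' @param seq A `feeding_sequence`.
#' @param mode `"span"` (default) or `"sum_of_events"`.
#' @return Duration in seconds (>= 0).
#' @export
#' @examples
#' s <- feeding_sequence("a", "f", 1, data.frame(
#'   label = c("ANTERIOR_INGESTION", "CHEW"),
#'   start_frame = c(0L, 60L), end_frame = c(30L, 90L),
#'   n_chews = c(NA, 4L)))
#' duration(s)  # 3 s: the 1 s gap is part of the sequence
duration <- function(seq, mode = c("span", "sum_of_events")) {
  mode <- match.arg(mode)
  ev <- seq$events
  if (nrow(ev) < 1L) stop("empty sequence has no duration", call. = FALSE)
  frames <- switch(mode,
    span          = ev$end_frame[nrow(ev)] - ev$start_frame[1],
    sum_of_events = sum(ev$end_frame - ev$start_frame)
  )
  frames_to_seconds(frames, seq$fps)
}

#' Behavioral frequency
#'
#' The number of times a food processing behavior (anterior ingestion,
#' posterior ingestion, or chew) occurs within a feeding sequence.  A chew
#' bout counts once regardless of how many individual chews it contains.
#'
#' @param seq A `feeding_sequence`.
#' @param label One of [behavior_labels()].
#' @return Integer count.
#' @export
behavioral_frequency <- function(seq, label) {
  label <- match.arg(label, behavior_labels())
  sum(seq$events$label == label)
}

#' Total chew number
#'
#' Total number of individual chews in a feeding sequence, summed over chew
#' bouts.  This differs from chew (bout) frequency: chewing may occur twice
#' in a sequence yet consist of ten chews.
#'
#' @param seq A `feeding_sequence`.
#' @return Integer count (0 when the sequence has no chew events).
#' @export
chew_number <- function(seq) {
  is_chew <- seq$events$label == "CHEW"
  if (!any(is_chew)) return(0L)
  as.integer(sum(seq$events$n_chews[is_chew]))
}

#' Unique behavior patterns
#'
#' Sequential behaviors are grouped into ordered sets of three (sliding
#' windows of width 3, stride 1 by default) and the number of distinct
#' patterns is counted.  Sequences with fewer than three events contain no
#' complete pattern and score 0.  `stride = 3` tiles the sequence into
#' disjoint triplets and `count = "tokens"` counts windows rather than
#' distinct types; both are provided for sensitivity analysis.
#'
#' @param seq A `feeding_sequence`, or a character vector of labels.
#' @param stride Window stride (default 1, overlapping windows).
#' @param count `"distinct"` (default) or `"tokens"`.
#' @return Integer count.
#' @export
#' @examples
#' unique_patterns(c("ANTERIOR_INGESTION", "CHEW", "POSTERIOR_INGESTION",
#'                   "CHEW", "ANTERIOR_INGESTION", "ANTERIOR_INGESTION",
#'                   "CHEW"))  # 5 distinct trigrams
unique_patterns <- function(seq, stride = 1L, count = c("distinct", "tokens")) {
  count <- match.arg(count)
  labels <- if (inherits(seq, "feeding_sequence")) seq$events$label else seq
  n <- length(labels)
  if (n < 3L) return(0L)
  starts <- seq.int(1L, n - 2L, by = stride)
  tri <- paste(labels[starts], labels[starts + 1L], labels[starts + 2L],
               sep = ">")
  if (count == "distinct") length(unique(tri)) else length(tri)
}

#' Compute all efficiency measures for one sequence
#'
#' @param seq A `feeding_sequence`.
#' @param duration_mode Passed to [duration()].
#' @return One-row data.frame with the six response columns.
#' @export
efficiency_measures <- function(seq, duration_mode = "span") {
  data.frame(
    duration_s      = duration(seq, mode = duration_mode),
    freq_ant        = behavioral_frequency(seq, "ANTERIOR_INGESTION"),
    freq_post       = behavioral_frequency(seq, "POSTERIOR_INGESTION"),
    freq_chew       = behavioral_frequency(seq, "CHEW"),
    chew_number     = chew_number(seq),
    unique_patterns = unique_patterns(seq)
  )
}

#' Names of the six response measures
#' @return Character vector of response column names.
#' @export
response_measures <- function() {
  c("duration_s", "freq_ant", "freq_post", "freq_chew",
    "chew_number", "unique_patterns")
}

#' Per-sequence measures table with covariates
#'
#' One row per feeding sequence: the six efficiency measures joined with
#' the animal covariates (age class, sex) and food properties (volume,
#' toughness, elastic modulus).  This is the response table for the mixed
#' model battery.
#'
#' @param dataset An `ethogram_dataset`.
#' @param duration_mode Passed to [duration()].
#' @return A data.frame with one row per sequence.
#' @export
measures_table <- function(dataset, duration_mode = "span") {
  empty <- data.frame(
    animal_id = character(), food = character(), trial = character(),
    duration_s = numeric(), freq_ant = integer(), freq_post = integer(),
    freq_chew = integer(), chew_number = integer(),
    unique_patterns = integer(), age_class = character(), sex = character(),
    volume_cm3 = numeric(), toughness_Jm2 = numeric(),
    elastic_modulus_MPa = numeric()
  )
  if (length(dataset$sequences) == 0L) return(empty)
  sq <- dataset$sequences
  tab <- data.frame(
    animal_id = vapply(sq, function(s) s$animal_id, character(1)),
    food = vapply(sq, function(s) s$food_name, character(1)),
    trial = vapply(sq, function(s) s$trial_id, character(1)),
    duration_s = vapply(sq, duration, numeric(1), mode = duration_mode),
    freq_ant = vapply(sq, function(s)
      sum(s$events$label == "ANTERIOR_INGESTION"), integer(1)),
    freq_post = vapply(sq, function(s)
      sum(s$events$label == "POSTERIOR_INGESTION"), integer(1)),
    freq_chew = vapply(sq, function(s)
      sum(s$events$label == "CHEW"), integer(1)),
    chew_number = vapply(sq, chew_number, integer(1)),
    unique_patterns = vapply(sq, unique_patterns, integer(1))
  )
  tab <- merge(tab, dataset$animals[, c("animal_id", "age_class", "sex")],
               by = "animal_id", sort = FALSE)
  tab <- merge(tab, dataset$foods, by.x = "food", by.y = "food", sort = FALSE)
  tab <- tab[order(tab$animal_id, tab$food, tab$trial), ]
  rownames(tab) <- NULL
  tab[, names(empty)]
}
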