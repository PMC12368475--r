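# Shared fixtures: tiny sequences, covariate tables and independent oracles.

# Build an event table from shorthand labels ("AB", "C", "PB"), laying
# events end to end (10 frames each, 5-frame gaps).  CHEW events get
# n_chews from `chews` (recycled).
mk_events <- function(labels, chews = 3L) {
  labels <- canonical_label(labels)
  n <- length(labels)
  start <- (0:(n - 1)) * 15L
  n_chews <- rep(NA_integer_, n)
  is_chew <- which(labels == "CHEW")
  n_chews[is_chew] <- rep_len(as.integer(chews), length(is_chew))
  data.frame(label = labels, start_frame = start, end_frame = start + 10L,
             n_chews = n_chews)
}

mk_seq <- function(labels, chews = 3L, animal = "a1", food = "peanut",
                   trial = "1", fps = 30) {
  feeding_sequence(animal, food, trial, mk_events(labels, chews), fps = fps)
}

# The worked seven-behavior example: anterior bite, chew, posterior bite,
# chew, anterior bite, anterior bite, chew.
example7 <- function(chews = c(4L, 6L, 2L)) {
  mk_seq(c("AB", "C", "PB", "C", "AB", "AB", "C"), chews = chews)
}

toy_roster <- function(ids = "a1") {
  data.frame(animal_id = ids, age_class = "JUVENILE", sex = "F",
             body_mass_kg = 1.5, origin = "SEMI_WILD")
}

toy_foods <- function() {
  data.frame(food = "peanut", volume_cm3 = 0.43, toughness_Jm2 = 255.5,
             elastic_modulus_MPa = 23.9)
}

toy_dataset <- function(seqs) {
  ids <- unique(vapply(seqs, function(s) s$animal_id, character(1)))
  ethogram_dataset(seqs, toy_roster(ids), toy_foods())
}

# Independent brute-force oracle for distinct trigram counting: walks every
# window and accumulates a set, never touching the vectorized code path.
trigram_oracle <- function(labels) {
  if (length(labels) < 3L) return(0L)
  seen <- new.env(parent = emptyenv())
  for (i in 1:(length(labels) - 2L)) {
    key <- paste0(labels[i], "\r", labels[i + 1L], "\r", labels[i + 2L])
    assign(key, TRUE, envir = seen)
  }
  length(ls(seen))
}

random_labels <- function(n) sample(behavior_labels(), n, replace = TRUE)

# A measures-style table for model-level tests, bypassing the generator:
# balanced one-way layout in age class with a nested animal grouping.
oneway_frame <- function(k_animals_per_class = 3L, trials = 4L,
                         group_effects = c(0, 0, 0, 0),
                         zero_animal_variance = FALSE, sd = 1) {
  ages <- age_classes()
  tab <- expand.grid(animal = seq_len(4L * k_animals_per_class),
                     trial = seq_len(trials))
  tab$animal_id <- sprintf("a%02d", tab$animal)
  tab$age_class <- ages[(tab$animal - 1L) %/% k_animals_per_class + 1L]
  tab$trial <- as.character(tab$trial)
  tab$food <- "peanut"
  tab$sex <- "F"
  tab$volume_cm3 <- 0.43
  tab$toughness_Jm2 <- 255.5
  tab$elastic_modulus_MPa <- 23.9
  e <- stats::rnorm(nrow(tab), 0, sd)
  if (zero_animal_variance) e <- e - stats::ave(e, tab$animal_id)
  tab$duration_s <- group_effects[match(tab$age_class, ages)] + e
  tab$freq_ant <- tab$freq_post <- tab$freq_chew <- 1L
  tab$chew_number <- tab$unique_patterns <- 1L
  tab
}

# Minimal stand-in for a fitted-battery result, for decision-level tests.
fake_result <- function(hypothesis = "H2", response = "duration_s",
                        scope = "pooled", p = 0.5, term = "age_class",
                        converged = TRUE) {
  structure(
    list(hypothesis = hypothesis, response = response, scope = scope,
         converged = converged, singular = FALSE, n_obs = 10L,
         omnibus = data.frame(term = term, statistic = 1, df1 = 1, df2 = 8,
                              p = p),
         contrasts = NULL, fit = NULL, messages = character()),
    class = "hypothesis_result"
  )
}

# Small generator config used wherever paper-scale n is not needed.
small_config <- function(...) {
  preset("paper_like",
         n_animals = c(JUVENILE = 4, SUBADULT_ADULT = 4),
         foods = default_foods()[c(3, 4), ],
         trials = 3, ...)
}
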