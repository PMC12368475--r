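#' Synthetic feeding-sequence generator
#'
#' Generates `ethogram_dataset`s with the statistical structure the
#' analysis pipeline assumes: 29 animals in four age classes and two sexes
#' consuming five foods with known volume, toughness and elastic modulus,
#' with expected total chews following a multiplicative (log-scale) model
#'
#' \deqn{\lambda = b \cdot (v/v_0)^{\beta_v} (E/E_0)^{\beta_E}
#'       (R/R_0)^{\beta_R} \cdot m_{age} \cdot m_{sex} \cdot
#'       e^{a_i + f_j + \epsilon}}
#'
#' where \eqn{a_i, f_j, \epsilon} are Gaussian animal, food and residual
#' effects (a mean correction keeps the configured multipliers on the
#' arithmetic-mean scale).  Events are emitted by a bite-chew bout grammar:
#' an ingestion bite, then chew bouts of Poisson size, with optional
#' further bites between bouts; frame times accumulate at 30 fps with
#' per-behavior mean durations scaled by an age-specific tempo multiplier.
#'
#' @param n_animals Named integer vector of animals per age class (split
#'   as evenly as possible between sexes); ignored when `roster` is given.
#' @param roster Roster data.frame (default [default_roster()], the
#'   29-animal study roster).  Needs `trials_*` columns when
#'   `trials = "table2"`.
#' @param foods Food-property table (default [default_foods()]).
#' @param trials `"table2"` to reproduce the study's observed per-cell
#'   trial counts, a single integer for a fixed count, or a length-2 range
#'   for uniform draws.  Infants never receive popcorn.
#' @param baseline_chews Expected chews for a subadult/adult female on a
#'   geometric-mean food.
#' @param volume_exponent,modulus_exponent,toughness_exponent Power-law
#'   exponents on food volume, elastic modulus and toughness.
#' @param age_chew_mult,age_time_mult Named multipliers per age class on
#'   expected chew count and on behavior tempo (event durations).
#' @param sex_chew_mult Named multipliers per sex on expected chew count.
#' @param age_effect_scale Scales all log age effects (0 = none, 1 =
#'   configured, 2 = doubled); used for power/recovery studies.
#' @param animal_sd,food_sd,residual_sd Log-scale SDs of the random animal
#'   intercept, random food intercept, and per-sequence residual.
#' @param p_anterior_first Probability the opening ingestion bite is
#'   anterior.
#' @param p_rebite Probability of a further bite between chew bouts.
#' @param p_anterior_rebite Probability such a later bite is anterior.
#' @param mean_chews_per_bout Mean chews per chew bout.
#' @param bite_s,chew_cycle_s,gap_s Mean bite duration, per-chew cycle
#'   time, and inter-event gap, in seconds (subadult/adult tempo).
#' @param fps Frames per second.
#' @param seed Optional integer seed; `generate()` is deterministic given
#'   the config (the caller's RNG state is preserved).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_animals = NULL,
    roster = NULL,
    foods = default_foods(),
    trials = "table2",
    baseline_chews = 48.26,
    volume_exponent = 0.6409,
    modulus_exponent = 0.0911,
    toughness_exponent = -0.0257,
    age_chew_mult = c(INFANT = 1.22, JUVENILE = 1.12,
                      OLDER_JUVENILE = 1.05, SUBADULT_ADULT = 1.00),
    age_time_mult = c(INFANT = 1.45, JUVENILE = 1.25,
                      OLDER_JUVENILE = 1.10, SUBADULT_ADULT = 1.00),
    sex_chew_mult = c(F = 1.00, M = 0.97),
    age_effect_scale = 1,
    animal_sd = 0.10,
    food_sd = 0.02,
    residual_sd = 0.20,
    p_anterior_first = 0.85,
    p_rebite = 0.35,
    p_anterior_rebite = 0.40,
    mean_chews_per_bout = 6,
    bite_s = 0.6,
    chew_cycle_s = 0.35,
    gap_s = 0.25,
    fps = 30,
    seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$roster) && is.null(cfg$n_animals)) {
    cfg$roster <- default_roster()
  }
  stopifnot(animal_sd >= 0, food_sd >= 0, residual_sd >= 0,
            all(age_chew_mult > 0), all(age_time_mult > 0),
            p_anterior_first >= 0, p_anterior_first <= 1,
            p_rebite >= 0, p_rebite <= 1,
            mean_chews_per_bout >= 1, baseline_chews > 0)
  structure(cfg, class = "generator_config")
}

# Reference food properties (geometric means of the five study foods);
# frozen so that subsetting foods does not shift the calibration.
.ref_props <- c(volume = 0.4420506, modulus = 8.525394, toughness = 475.1513)

#' Generator presets
#'
#' \describe{
#'   \item{null}{No age, sex or food effects and zero animal/food variance
#'     (residual noise only) — for type-I-error calibration.}
#'   \item{paper_like}{Defaults of [generator_config()]: power-law food
#'     effects and age multipliers calibrated so that per-food mean chew
#'     numbers for the juvenile and subadult/adult groups fall inside the
#'     observed ranges (sunflower seed 16.9–21.8 up to almond 83.5–149).}
#'   \item{strong_effects}{paper_like with all log-scale age effects
#'     doubled — for parameter-recovery and power studies.}
#' }
#'
#' @param name Preset name.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
preset <- function(name = c("null", "paper_like", "strong_effects"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    null = list(
      volume_exponent = 0, modulus_exponent = 0, toughness_exponent = 0,
      age_chew_mult = c(INFANT = 1, JUVENILE = 1,
                        OLDER_JUVENILE = 1, SUBADULT_ADULT = 1),
      age_time_mult = c(INFANT = 1, JUVENILE = 1,
                        OLDER_JUVENILE = 1, SUBADULT_ADULT = 1),
      sex_chew_mult = c(F = 1, M = 1),
      animal_sd = 0, food_sd = 0),
    paper_like = list(),
    strong_effects = list(age_effect_scale = 2)
  )
  do.call(generator_config, utils::modifyList(args, list(...)))
}

# Build a synthetic roster from per-age-class counts.
.make_roster <- function(n_animals) {
  stopifnot(all(names(n_animals) %in% .age_classes))
  mass <- c(INFANT = 1.1, JUVENILE = 1.5, OLDER_JUVENILE = 1.8,
            SUBADULT_ADULT = 3.0)
  rows <- lapply(names(n_animals), function(ac) {
    n <- n_animals[[ac]]
    if (n == 0L) return(NULL)
    data.frame(
      animal_id = paste0(substr(ac, 1, 2), seq_len(n)),
      age_class = ac,
      sex = rep_len(c("F", "M"), n),
      body_mass_kg = mass[[ac]],
      origin = "SEMI_WILD"
    )
  })
  do.call(rbind, rows)
}

#' Generate a synthetic dataset
#'
#' @param config A `generator_config` (default: the paper_like preset).
#' @return An `ethogram_dataset`.
#' @export
#' @examples
#' d <- generate(preset("paper_like", seed = 1))
#' length(d$sequences)
generate <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  run <- function() .generate_impl(config)
  if (is.null(config$seed)) run() else with_local_seed(config$seed, run())
}

.generate_impl <- function(cfg) {
  roster <- if (!is.null(cfg$roster)) as.data.frame(cfg$roster)
            else .make_roster(cfg$n_animals)
  foods <- as.data.frame(cfg$foods)

  scale <- cfg$age_effect_scale
  age_chew <- cfg$age_chew_mult ^ scale
  age_time <- cfg$age_time_mult ^ scale

  a_i <- stats::rnorm(nrow(roster), 0, cfg$animal_sd)
  names(a_i) <- roster$animal_id
  f_j <- stats::rnorm(nrow(foods), 0, cfg$food_sd)
  names(f_j) <- foods$food
  mean_corr <- (cfg$animal_sd^2 + cfg$food_sd^2 + cfg$residual_sd^2) / 2

  n_trials <- function(animal, food) {
    if (roster$age_class[roster$animal_id == animal] == "INFANT" &&
        food == "popcorn") return(0L)
    if (identical(cfg$trials, "table2")) {
      col <- paste0("trials_", food)
      if (!col %in% names(roster)) {
        stop("trials = 'table2' needs a '", col, "' roster column",
             call. = FALSE)
      }
      return(as.integer(roster[[col]][roster$animal_id == animal]))
    }
    rng <- cfg$trials
    if (length(rng) == 1L) return(as.integer(rng))
    sample(rng[1]:rng[2], 1L)
  }

  sequences <- list()
  for (ai in seq_len(nrow(roster))) {
    animal <- roster$animal_id[ai]
    ac <- roster$age_class[ai]
    sx <- roster$sex[ai]
    for (fi in seq_len(nrow(foods))) {
      food <- foods$food[fi]
      k <- n_trials(animal, food)
      if (k < 1L) next
      lam_base <- cfg$baseline_chews *
        (foods$volume_cm3[fi]          / .ref_props[["volume"]])   ^ cfg$volume_exponent *
        (foods$elastic_modulus_MPa[fi] / .ref_props[["modulus"]])  ^ cfg$modulus_exponent *
        (foods$toughness_Jm2[fi]       / .ref_props[["toughness"]])^ cfg$toughness_exponent *
        age_chew[[ac]] * cfg$sex_chew_mult[[sx]]
      for (tr in seq_len(k)) {
        eps <- stats::rnorm(1, 0, cfg$residual_sd)
        lam <- lam_base * exp(a_i[[animal]] + f_j[[food]] + eps - mean_corr)
        sequences[[length(sequences) + 1L]] <- .emit_sequence(
          animal, food, tr, lam, age_time[[ac]], cfg)
      }
    }
  }
  ethogram_dataset(sequences, roster[, c("animal_id", "age_class", "sex",
                                         "body_mass_kg", "origin")], foods)
}

# Bite-chew bout grammar for one sequence.  Every sequence starts with an
# ingestion bite; total chews are partitioned into Poisson-sized bouts with
# optional further bites in between.
.emit_sequence <- function(animal, food, trial, lam, time_mult, cfg) {
  n_chews_total <- stats::rpois(1, lam)
  labels <- character()
  chews <- integer()
  bite <- function(p_ant) {
    if (stats::runif(1) < p_ant) "ANTERIOR_INGESTION" else "POSTERIOR_INGESTION"
  }
  labels <- bite(cfg$p_anterior_first)
  chews <- NA_integer_
  remaining <- n_chews_total
  while (remaining > 0L) {
    bout <- min(remaining, 1L + stats::rpois(1, max(cfg$mean_chews_per_bout - 1, 0)))
    labels <- c(labels, "CHEW")
    chews <- c(chews, bout)
    remaining <- remaining - bout
    if (remaining > 0L && stats::runif(1) < cfg$p_rebite) {
      labels <- c(labels, bite(cfg$p_anterior_rebite))
      chews <- c(chews, NA_integer_)
    }
  }
  n <- length(labels)
  dur_s <- numeric(n)
  for (i in seq_len(n)) {
    dur_s[i] <- if (labels[i] == "CHEW") {
      chews[i] * cfg$chew_cycle_s * time_mult * exp(stats::rnorm(1, 0, 0.10))
    } else {
      cfg$bite_s * time_mult * exp(stats::rnorm(1, 0, 0.25))
    }
  }
  gaps <- stats::rexp(n, 1 / (cfg$gap_s * time_mult))
  gaps[1] <- 0
  t <- 0
  start_f <- integer(n)
  end_f <- integer(n)
  for (i in seq_len(n)) {
    t <- t + gaps[i]
    start_f[i] <- as.integer(round(t * cfg$fps))
    t <- t + dur_s[i]
    end_f[i] <- max(as.integer(round(t * cfg$fps)), start_f[i])
  }
  feeding_sequence(animal, food, trial,
                   data.frame(label = labels, start_frame = start_f,
                              end_frame = end_f, n_chews = chews),
                   fps = cfg$fps)
}
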