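test_that("duration spans first start to last end, gaps included", {
  one <- feeding_sequence("a1", "peanut", "1", data.frame(
    label = "ANTERIOR_INGESTION", start_frame = 0L, end_frame = 30L,
    n_chews = NA_integer_))
  expect_equal(duration(one), 1.0)

  gapped <- feeding_sequence("a1", "peanut", "1", data.frame(
    label = c("ANTERIOR_INGESTION", "CHEW"),
    start_frame = c(0L, 60L), end_frame = c(30L, 90L),
    n_chews = c(NA, 5L)))
  expect_equal(duration(gapped), 3.0)               # 1 s gap counts
  expect_equal(duration(gapped, mode = "sum_of_events"), 2.0)

  degenerate <- feeding_sequence("a1", "peanut", "1", data.frame(
    label = "CHEW", start_frame = 10L, end_frame = 10L, n_chews = 1L))
  expect_equal(duration(degenerate), 0.0)
})

test_that("behavioral frequency counts bouts on the worked example", {
  s <- example7()
  expect_equal(behavioral_frequency(s, "ANTERIOR_INGESTION"), 3L)
  expect_equal(behavioral_frequency(s, "POSTERIOR_INGESTION"), 1L)
  expect_equal(behavioral_frequency(s, "CHEW"), 3L)

  chews5 <- mk_seq(rep("C", 5))
  expect_equal(behavioral_frequency(chews5, "ANTERIOR_INGESTION"), 0L)
  expect_equal(behavioral_frequency(mk_seq("PB"), "POSTERIOR_INGESTION"), 1L)
})

test_that("chew number sums chews over bouts, distinct from bout count", {
  two_bouts <- mk_seq(c("C", "C"), chews = c(4L, 6L))
  expect_equal(chew_number(two_bouts), 10L)
  expect_equal(behavioral_frequency(two_bouts, "CHEW"), 2L)
  expect_equal(chew_number(mk_seq(c("AB", "PB"))), 0L)
  expect_equal(chew_number(mk_seq(rep("C", 7), chews = 1L)), 7L)
})

test_that("unique patterns counts distinct sliding trigrams", {
  expect_equal(unique_patterns(example7()), 5L)
  expect_equal(unique_patterns(mk_seq(rep("C", 10))), 1L)
  expect_equal(unique_patterns(mk_seq(c("AB", "C"))), 0L)
  # alternative readings exposed for sensitivity analysis
  expect_equal(unique_patterns(example7(), count = "tokens"), 5L)
  expect_equal(unique_patterns(mk_seq(rep("C", 10)), count = "tokens"), 8L)
  expect_equal(unique_patterns(example7(), stride = 3, count = "tokens"), 2L)
})

test_that("unique patterns agrees with the brute-force set oracle", {
  set.seed(42)
  for (i in 1:250) {
    labs <- random_labels(sample(0:12, 1))
    expect_identical(unique_patterns(labs), trigram_oracle(labs))
    n <- length(labs)
    if (n >= 3L) {
      expect_lte(unique_patterns(labs), n - 2L)
      all_distinct <- trigram_oracle(labs) == n - 2L
      expect_identical(unique_patterns(labs) == n - 2L, all_distinct)
    } else {
      expect_identical(unique_patterns(labs), 0L)
    }
  }
})

test_that("measures are invariant to identifier relabeling", {
  s <- example7()
  relabeled <- s
  relabeled$animal_id <- "zzz"
  relabeled$trial_id <- "99"
  expect_equal(efficiency_measures(s), efficiency_measures(relabeled))
})

test_that("chew number dominates bout frequency, equal iff single-chew bouts", {
  set.seed(1)
  for (i in 1:50) {
    labs <- random_labels(sample(1:10, 1))
    chews <- sample(1:4, sum(labs == "CHEW"), replace = TRUE)
    if (!any(labs == "CHEW")) chews <- 1L
    s <- mk_seq(labs, chews = chews)
    expect_gte(chew_number(s), behavioral_frequency(s, "CHEW"))
    if (behavioral_frequency(s, "CHEW") > 0) {
      expect_identical(chew_number(s) == behavioral_frequency(s, "CHEW"),
                       all(s$events$n_chews[s$events$label == "CHEW"] == 1L))
    }
  }
})

test_that("measures table joins covariates, one row per sequence", {
  gen <- generate(small_config(seed = 7))
  tab <- measures_table(gen)
  expect_equal(nrow(tab), length(gen$sequences))
  expect_true(all(c("age_class", "sex", "volume_cm3", "toughness_Jm2",
                    "elastic_modulus_MPa") %in% names(tab)))
  expect_false(anyNA(tab$volume_cm3))

  empty <- ethogram_dataset(list(), toy_roster(), toy_foods())
  etab <- measures_table(empty)
  expect_equal(nrow(etab), 0L)
  expect_true(all(response_measures() %in% names(etab)))

  single <- toy_dataset(list(example7()))
  stab <- measures_table(single)
  expect_equal(stab$duration_s, duration(example7()))
  expect_equal(stab$chew_number, chew_number(example7()))
  expect_equal(stab$unique_patterns, unique_patterns(example7()))
})
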