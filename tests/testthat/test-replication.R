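test_that("decisions use strict inequality at alpha and flag failures", {
  res <- list(fake_result(p = 0.04), fake_result(response = "chew_number",
                                                 p = 0.05),
              fake_result(response = "freq_ant", converged = FALSE))
  v <- significance_vector(res, alpha = 0.05)
  expect_equal(v$status[v$response == "duration_s"], "sig")
  expect_equal(v$status[v$response == "chew_number"], "nonsig")  # p == alpha
  expect_equal(v$status[v$response == "freq_ant"], "failed")
})

test_that("replication rate identities hold for arbitrary vectors", {
  set.seed(9)
  v <- significance_vector(lapply(seq_len(12), function(i) {
    fake_result(hypothesis = sample(hypothesis_ids(), 1),
                response = response_measures()[1 + i %% 6],
                scope = as.character(i), p = runif(1))
  }))
  self <- replication_rate(v, v)
  expect_equal(self$overall, 100)

  flipped <- v
  flipped$status <- ifelse(v$status == "sig", "nonsig", "sig")
  expect_equal(replication_rate(v, flipped)$overall, 0)

  shuffled <- v[sample(nrow(v)), ]
  expect_equal(replication_rate(v, shuffled)$overall, 100)
})

test_that("a 10-key vector with 5 matches scores 50 percent", {
  mk <- function(ps) significance_vector(lapply(seq_along(ps), function(i) {
    fake_result(scope = as.character(i), p = ps[i])
  }))
  cont <- mk(rep(0.01, 10))
  disc <- mk(c(rep(0.01, 5), rep(0.9, 5)))
  rep <- replication_rate(cont, disc)
  expect_equal(rep$overall, 50)
  expect_equal(rep$n_scored, 10L)
})

test_that("failed keys leave the denominator and are listed", {
  mk <- function(ps, fail = integer()) {
    significance_vector(lapply(seq_along(ps), function(i) {
      fake_result(scope = as.character(i), p = ps[i],
                  converged = !(i %in% fail))
    }))
  }
  cont <- mk(rep(0.01, 4))
  disc <- mk(c(0.01, 0.01, 0.9, 0.01), fail = 4)
  rep <- replication_rate(cont, disc)
  expect_equal(rep$n_scored, 3L)
  expect_equal(rep$overall, 100 * 2 / 3)
  expect_equal(nrow(rep$excluded), 1L)

  mismatched <- mk(rep(0.01, 3))
  expect_error(replication_rate(cont, mismatched), "share keys")
})

test_that("overall rate is the key-count weighted mean of per-hypothesis rates", {
  set.seed(13)
  mk <- function(ps, hyp) {
    significance_vector(mapply(function(p, h, i) {
      fake_result(hypothesis = h, scope = as.character(i), p = p)
    }, ps, hyp, seq_along(ps), SIMPLIFY = FALSE))
  }
  hyp <- rep(c("H1", "H2", "H3"), times = c(2, 5, 3))
  cont <- mk(rep(0.01, 10), hyp)
  disc <- mk(c(0.01, 0.9, 0.01, 0.01, 0.9, 0.9, 0.01, 0.01, 0.01, 0.9), hyp)
  rep <- replication_rate(cont, disc)
  w <- rep$per_hypothesis
  expect_equal(rep$overall,
               sum(w$percent_replicated * w$n_keys) / sum(w$n_keys))
})

test_that("iteration summaries report percent significant per key", {
  mk <- function(p, converged = TRUE) {
    significance_vector(list(fake_result(p = p, converged = converged)))
  }
  sum1 <- random_iteration_summary(list(mk(0.01), mk(0.9), mk(0.9), mk(0.9)))
  expect_equal(sum1$percent_significant, 25)

  sum2 <- random_iteration_summary(list(mk(0.5, FALSE), mk(0.5, FALSE)))
  expect_true(is.na(sum2$percent_significant[sum2$key == "<all>"][1]))
  expect_equal(sum2$n_converged[1], 0)

  sum3 <- random_iteration_summary(list(mk(0.01), mk(0.02)))
  expect_equal(sum3$percent_significant, 100)
})

test_that("half-sequence analyses replicate better than random windows,
           over an ensemble of generator seeds", {
  per_seed <- vapply(c(101, 202, 303), function(sd) {
    d <- generate(preset("strong_effects",
                         n_animals = c(JUVENILE = 6, SUBADULT_ADULT = 6),
                         foods = default_foods()[c(3, 4), ], trials = 4,
                         seed = sd))
    m <- measures_table(d)
    bat <- function(tab) suppressWarnings(run_battery(
      tab, hypotheses = "H2",
      responses = c("duration_s", "chew_number", "unique_patterns"),
      scope = "pooled", contrasts = FALSE))
    vc <- significance_vector(bat(m), level = "term")
    rate_of <- function(kind, i = 1L) {
      dd <- make_discontinuous_dataset(d, split_scheme(kind),
                                       base_seed = sd, iteration = i)
      replication_rate(
        vc, significance_vector(bat(measures_table(dd)),
                                level = "term"))$overall
    }
    rnd <- mean(vapply(1:4, function(i) rate_of("random", i), numeric(1)))
    rate_of("first_half") >= rnd && rate_of("last_half") >= rnd
  }, logical(1))
  expect_gte(mean(per_seed), 0.5)   # majority of seeds, not every seed
})
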