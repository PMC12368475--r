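test_that("zero variance components reduce the mixed fit to least squares", {
  set.seed(11)
  tab <- oneway_frame(group_effects = c(0, 1, 2, 3),
                      zero_animal_variance = TRUE)
  r <- fit_lme(tab, "H2", response = "duration_s", scope = "per_food")
  expect_true(r$converged)
  expect_true(r$singular)
  tab2 <- tab
  tab2$age_class <- factor(tab2$age_class)
  contrasts(tab2$age_class) <- contr.sum(4)
  ols <- lm(duration_s ~ age_class, data = tab2)
  expect_equal(unname(lme4::fixef(r$fit)), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("Tukey-adjusted contrasts match the studentized-range oracle", {
  set.seed(11)
  k <- 4L; na <- 3L; nt <- 4L
  tab <- oneway_frame(k_animals_per_class = na, trials = nt,
                      group_effects = c(0, 1, 2, 3),
                      zero_animal_variance = TRUE)
  r <- fit_lme(tab, "H2", response = "duration_s", scope = "per_food")
  expect_true(r$singular)   # oracle premise: animal variance at zero
  npg <- na * nt
  mns <- tapply(tab$duration_s, tab$age_class, mean)
  mse <- sum((tab$duration_s - ave(tab$duration_s, tab$age_class))^2) /
    (nrow(tab) - k)
  cmb <- utils::combn(names(mns), 2)
  oracle <- vapply(seq_len(ncol(cmb)), function(j) {
    q <- abs(mns[cmb[1, j]] - mns[cmb[2, j]]) / sqrt(mse / npg)
    stats::ptukey(q, k, nrow(tab) - k, lower.tail = FALSE)
  }, numeric(1))
  got <- r$contrasts[r$contrasts$factor == "age_class", ]
  key <- paste(cmb[1, ], "-", cmb[2, ])
  expect_equal(got$adj_p[match(key, got$contrast)], oracle,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("with two levels the Tukey adjustment is the identity", {
  set.seed(2)
  tab <- oneway_frame(group_effects = c(0, 0.8, 0, 0))
  tab <- tab[tab$age_class %in% c("JUVENILE", "SUBADULT_ADULT"), ]
  r <- fit_lme(tab, "H2", response = "duration_s", scope = "per_food")
  ct <- r$contrasts[r$contrasts$factor == "age_class", ]
  expect_equal(nrow(ct), 1L)
  unadjusted <- 2 * stats::pt(abs(ct$estimate / ct$se), ct$df,
                              lower.tail = FALSE)
  expect_equal(ct$adj_p, unadjusted, tolerance = 1e-10)
})

test_that("a factor with four levels yields all six pairwise contrasts", {
  set.seed(3)
  tab <- oneway_frame()
  r <- fit_lme(tab, "H2", response = "duration_s", scope = "per_food")
  ct <- r$contrasts[r$contrasts$factor == "age_class", ]
  expect_equal(nrow(ct), choose(4, 2))
  expect_true(all(ct$adj_p >= 0 & ct$adj_p <= 1))
})

test_that("contrast estimates are antisymmetric under group relabeling", {
  set.seed(4)
  tab <- oneway_frame(group_effects = c(0, 2, 0, 1))
  swapped <- tab
  swapped$age_class[tab$age_class == "JUVENILE"] <- "SUBADULT_ADULT"
  swapped$age_class[tab$age_class == "SUBADULT_ADULT"] <- "JUVENILE"
  a <- fit_lme(tab, "H2", response = "duration_s", scope = "per_food")
  b <- fit_lme(swapped, "H2", response = "duration_s", scope = "per_food")
  pick <- function(r) {
    ct <- r$contrasts
    ct[ct$contrast == "JUVENILE - SUBADULT_ADULT", ]
  }
  expect_equal(pick(a)$estimate, -pick(b)$estimate, tolerance = 1e-8)
  expect_equal(pick(a)$adj_p, pick(b)$adj_p, tolerance = 1e-8)
})

test_that("degenerate designs raise structured errors naming the cause", {
  tab <- oneway_frame()
  solo <- tab[tab$age_class == "JUVENILE", ]
  expect_error(fit_lme(solo, "H2", response = "duration_s",
                       scope = "per_food"),
               class = "oralproc_degenerate_design")
  expect_error(fit_lme(solo, "H2", response = "duration_s",
                       scope = "per_food"),
               "age_class")
  # a food property is constant within a single food
  expect_error(fit_lme(tab, "H3", response = "duration_s",
                       scope = "per_food"),
               class = "oralproc_degenerate_design")
})

test_that("the battery enumerates hypothesis-by-response cells", {
  gen <- generate(small_config(seed = 31))
  tab <- measures_table(gen)
  res <- run_battery(tab, hypotheses = "H1",
                     responses = response_measures(),
                     scope = "pooled", contrasts = FALSE)
  expect_length(res, 6L)
  expect_setequal(vapply(res, `[[`, "", "response"), response_measures())

  # per-food scope: H2 fits within each food, H3 is degenerate and skipped
  w <- capture_warnings(
    res_pf <- run_battery(tab, hypotheses = c("H2", "H3"),
                          responses = "chew_number",
                          scope = "per_food", contrasts = FALSE))
  expect_length(w, 2L)   # one skipped H3 cell per food
  expect_match(w, "degenerate", all = TRUE)
  expect_setequal(vapply(res_pf, `[[`, "", "scope"), unique(tab$food))
  expect_true(all(vapply(res_pf, `[[`, "", "hypothesis") == "H2"))
})

test_that("interaction hypotheses report joint cell contrasts", {
  gen <- generate(preset("paper_like",
                         n_animals = c(JUVENILE = 6, SUBADULT_ADULT = 6),
                         foods = default_foods()[c(3, 4), ],
                         trials = 3, seed = 17))
  tab <- measures_table(gen)
  r <- fit_lme(tab, "H1", response = "chew_number")
  expect_true(all(c("age_class", "sex", "age_class:sex") %in%
                    r$contrasts$factor))
  joint <- r$contrasts[r$contrasts$factor == "age_class:sex", ]
  expect_equal(nrow(joint), choose(4, 2))  # 2 ages x 2 sexes -> 4 cells
  expect_true(all(c("age_class", "sex", "age_class:sex") %in%
                    r$omnibus$term))
})
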