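#' Hypothesis specifications for the mixed-model battery
#'
#' Each hypothesis fixes the fixed-effect structure of a linear mixed model
#' fitted separately to each efficiency measure:
#' \describe{
#'   \item{H1}{`age_class * sex` — sex differences within age classes.}
#'   \item{H2}{`age_class` — ontogenetic variation.}
#'   \item{H3}{`age_class * volume` — food geometric properties.}
#'   \item{H4a}{`age_class * toughness` — food toughness.}
#'   \item{H4b}{`age_class * elastic modulus` — food stiffness.}
#' }
#' Pooled models carry crossed random intercepts for food type and animal
#' identity; within-food models keep the animal intercept only.
#'
#' @param id One of `"H1"`, `"H2"`, `"H3"`, `"H4a"`, `"H4b"`.
#' @return An object of class `hypothesis_spec`.
#' @export
hypothesis_spec <- function(id = c("H1", "H2", "H3", "H4a", "H4b")) {
  id <- match.arg(id)
  fixed <- switch(id,
    H1  = "age_class * sex",
    H2  = "age_class",
    H3  = "age_class * volume_z",
    H4a = "age_class * toughness_z",
    H4b = "age_class * modulus_z"
  )
  covariate <- switch(id,
    H3  = "volume_cm3",
    H4a = "toughness_Jm2",
    H4b = "elastic_modulus_MPa",
    NULL
  )
  factors <- if (id == "H1") c("age_class", "sex") else "age_class"
  structure(list(id = id, fixed = fixed, covariate = covariate,
                 factors = factors, alpha = 0.05),
            class = "hypothesis_spec")
}

#' @rdname hypothesis_spec
#' @export
hypothesis_ids <- function() c("H1", "H2", "H3", "H4a", "H4b")

# Map spec covariates to the z-scored model column.
.z_col <- c(volume_cm3 = "volume_z", toughness_Jm2 = "toughness_z",
            elastic_modulus_MPa = "modulus_z")

# Prepare a measures table for model fitting: factor coding (sum contrasts,
# so type-III omnibus tests are meaningful) and z-scored food properties.
# Continuous food properties are standardized to aid optimizer convergence;
# raw-scale values stay in the table.
prepare_model_frame <- function(table, standardize = TRUE) {
  tab <- as.data.frame(table)
  tab$age_class <- factor(tab$age_class,
                          levels = intersect(.age_classes, tab$age_class))
  tab$sex <- factor(tab$sex, levels = intersect(.sexes, tab$sex))
  if (nlevels(tab$age_class) > 1L) {
    contrasts(tab$age_class) <- stats::contr.sum(nlevels(tab$age_class))
  }
  if (nlevels(tab$sex) > 1L) {
    contrasts(tab$sex) <- stats::contr.sum(nlevels(tab$sex))
  }
  zscore <- function(x) {
    s <- stats::sd(x)
    if (!standardize) return(x)
    if (is.na(s) || s == 0) return(x - mean(x)) else (x - mean(x)) / s
  }
  tab$volume_z    <- zscore(tab$volume_cm3)
  tab$toughness_z <- zscore(tab$toughness_Jm2)
  tab$modulus_z   <- zscore(tab$elastic_modulus_MPa)
  tab$animal_id <- factor(tab$animal_id)
  tab$food <- factor(tab$food)
  tab
}

#' Fit the linear mixed model for one hypothesis and one response
#'
#' Fits a REML linear mixed model with the hypothesis fixed effects and
#' random intercepts for food type and animal identity (animal only for
#' within-food fits), then extracts type-III omnibus F tests per fixed
#' term.  Count responses are modeled as Gaussian, matching the study
#' design this package operationalizes.  Optimizer non-convergence is
#' caught and flagged, never raised; models whose tested factor or
#' covariate is constant raise a structured degenerate-design error.
#'
#' @param table A measures table ([measures_table()]).
#' @param spec A `hypothesis_spec` (or its id string).
#' @param response One of [response_measures()].
#' @param scope `"pooled"` or `"per_food"`; per-food fits drop the food
#'   random intercept and are meant to be applied to a single-food table.
#' @param df_method Denominator degrees of freedom for the type-III F
#'   tests and contrasts: `"residual"` (default; containment-style
#'   residual df, the convention of the nlme family) or
#'   `"satterthwaite"`.
#' @param standardize Z-score continuous food properties before fitting.
#' @param contrasts Also compute Tukey-adjusted pairwise contrasts.
#' @return An object of class `hypothesis_result` with elements
#'   `hypothesis`, `response`, `scope`, `converged`, `singular`, `n_obs`,
#'   `omnibus` (term-level F tests) and `contrasts`.
#' @export
fit_lme <- function(table, spec, response = "duration_s",
                    scope = c("pooled", "per_food"),
                    df_method = c("residual", "satterthwaite"),
                    standardize = TRUE, contrasts = TRUE) {
  scope <- match.arg(scope)
  df_method <- match.arg(df_method)
  if (is.character(spec)) spec <- hypothesis_spec(spec)
  response <- match.arg(response, response_measures())
  tab <- prepare_model_frame(table, standardize = standardize)

  for (f in spec$factors) {
    if (nlevels(droplevels(tab[[f]])) < 2L) {
      stop(errorCondition(
        paste0("degenerate design: factor '", f, "' has fewer than 2 levels"),
        class = "oralproc_degenerate_design"))
    }
  }
  if (!is.null(spec$covariate) &&
      stats::sd(tab[[spec$covariate]]) == 0) {
    stop(errorCondition(
      paste0("degenerate design: covariate '", spec$covariate,
             "' is constant"),
      class = "oralproc_degenerate_design"))
  }

  random <- if (scope == "pooled") "(1 | food) + (1 | animal_id)"
            else "(1 | animal_id)"
  form <- stats::as.formula(paste(response, "~", spec$fixed, "+", random))

  converged <- TRUE
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(form, data = tab, REML = TRUE),
      error = function(e) {
        converged <<- FALSE
        msgs <<- c(msgs, conditionMessage(e))
        NULL
      }
    ),
    warning = function(w) {
      m <- conditionMessage(w)
      if (grepl("failed to converge|convergence code|unable to evaluate",
                m, ignore.case = TRUE)) {
        converged <<- FALSE
      }
      msgs <<- c(msgs, m)
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  if (!is.null(fit) && !is.null(fit@optinfo$conv$opt) &&
      fit@optinfo$conv$opt != 0) {
    converged <- FALSE
  }

  omnibus <- data.frame(term = character(), statistic = numeric(),
                        df1 = numeric(), df2 = numeric(), p = numeric())
  singular <- NA
  if (!is.null(fit)) {
    singular <- lme4::isSingular(fit)
    omnibus <- .omnibus_table(fit, df_method)
  }

  res <- structure(
    list(hypothesis = spec$id, response = response, scope = scope,
         converged = converged, singular = singular,
         n_obs = nrow(tab), omnibus = omnibus,
         contrasts = .empty_contrasts(), fit = fit, df_method = df_method,
         messages = msgs),
    class = "hypothesis_result"
  )
  if (contrasts && converged && !is.null(fit)) {
    res$contrasts <- pairwise_contrasts(fit, spec$factors,
                                        df_method = df_method)
  }
  res
}

.residual_df <- function(fit) {
  nrow(fit@frame) - ncol(lme4::getME(fit, "X"))
}

.omnibus_table <- function(fit, df_method) {
  a <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  out <- data.frame(term = rownames(a), statistic = a[["F value"]],
                    df1 = a$NumDF, df2 = a$DenDF, p = a[["Pr(>F)"]],
                    row.names = NULL)
  if (df_method == "residual") {
    out$df2 <- .residual_df(fit)
    out$p <- stats::pf(out$statistic, out$df1, out$df2, lower.tail = FALSE)
  }
  out
}

.empty_contrasts <- function() {
  data.frame(factor = character(), contrast = character(),
             estimate = numeric(), se = numeric(), df = numeric(),
             adj_p = numeric())
}

#' Tukey-adjusted pairwise contrasts of estimated marginal means
#'
#' Computes estimated marginal means for each requested factor (averaged
#' over the other model terms at balanced weights) and all pairwise
#' differences with Tukey's studentized-range adjustment.  When two
#' factors are given, joint cell-by-cell contrasts (e.g.
#' "SUBADULT_ADULT M - JUVENILE F") are appended under the keyed factor
#' `"age_class:sex"`, so both within- and cross-level comparisons are
#' available.
#'
#' @param fit A fitted `lmerMod`/`lmerModLmerTest` model, or a
#'   `hypothesis_result` (its stored fit is used; a non-converged result
#'   yields an empty contrast table).
#' @param factors Character vector of model factor names.
#' @param df_method Contrast degrees of freedom: `"residual"` (default,
#'   matching the omnibus tests) or `"satterthwaite"`.
#' @return Data.frame with columns `factor`, `contrast`, `estimate`, `se`,
#'   `df`, `adj_p`.
#' @export
pairwise_contrasts <- function(fit, factors = "age_class",
                               df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  if (inherits(fit, "hypothesis_result")) {
    if (!isTRUE(fit$converged) || is.null(fit$fit)) return(.empty_contrasts())
    fit <- fit$fit
  }
  one <- function(spec_formula, key) {
    # marginal means over a factor involved in an interaction are emitted
    # on purpose (both conventions are keyed); silence emmeans' note
    em <- suppressMessages(
      emmeans::emmeans(fit, spec_formula, lmer.df = "satterthwaite"))
    if (df_method == "residual") {
      em <- update(em, df = .residual_df(fit))
    }
    pr <- as.data.frame(suppressMessages(
      emmeans::contrast(em, method = "pairwise", adjust = "tukey")))
    data.frame(factor = key, contrast = pr$contrast, estimate = pr$estimate,
               se = pr$SE, df = pr$df, adj_p = pr$p.value)
  }
  out <- lapply(factors, function(f) one(stats::as.formula(paste("~", f)), f))
  if (length(factors) == 2L) {
    joint <- paste(factors, collapse = ":")
    out <- c(out, list(one(stats::as.formula(
      paste("~", paste(factors, collapse = " * "))), joint)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.hypothesis_result <- function(x, ...) {
  cat("<hypothesis_result>", x$hypothesis, "|", x$response, "|", x$scope,
      "| n =", x$n_obs,
      if (!x$converged) "| FAILED TO CONVERGE" else "", "\n")
  if (nrow(x$omnibus)) print(x$omnibus, digits = 4)
  invisible(x)
}

#' Run the full hypothesis battery over a measures table
#'
#' Fits every requested hypothesis for every response, across all food
#' types (pooled, crossed food and animal random intercepts) and/or within
#' each individual food (animal intercept only).  Within-food cells whose
#' design is degenerate for a hypothesis (e.g. a food property that is
#' constant within one food) are skipped with a warning rather than
#' failing the battery.
#'
#' @param table A measures table.
#' @param hypotheses Character vector of hypothesis ids.
#' @param responses Character vector of response measures.
#' @param scope `"pooled"`, `"per_food"`, or both.
#' @param ... Passed to [fit_lme()] (`df_method`, `contrasts`, ...).
#' @return List of `hypothesis_result` objects; per-food results carry the
#'   food name as their `scope`.
#' @export
run_battery <- function(table, hypotheses = hypothesis_ids(),
                        responses = response_measures(),
                        scope = "pooled", ...) {
  results <- list()
  add <- function(r) results[[length(results) + 1L]] <<- r
  fit_cell <- function(tab, h, resp, sc, label) {
    tryCatch({
      r <- fit_lme(tab, h, response = resp, scope = sc, ...)
      r$scope <- label
      add(r)
    },
    oralproc_degenerate_design = function(e) {
      warning("skipping ", h, "/", resp, "/", label, ": ",
              conditionMessage(e), call. = FALSE)
    })
  }
  if ("pooled" %in% scope) {
    for (h in hypotheses) for (resp in responses) {
      fit_cell(table, h, resp, "pooled", "pooled")
    }
  }
  if ("per_food" %in% scope) {
    for (fd in unique(table$food)) {
      sub <- table[table$food == fd, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (h in hypotheses) for (resp in responses) {
        fit_cell(sub, h, resp, "per_food", fd)
      }
    }
  }
  results
}
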