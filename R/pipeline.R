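#' Configuration for a full pipeline run
#'
#' @param generator A `generator_config` used to simulate the input
#'   dataset, or `NULL` when `input_dir` is given.
#' @param input_dir Directory with `events.csv`, `animals.csv`,
#'   `foods.csv` to analyze instead of simulating.
#' @param schemes Discontinuity schemes to run, any of
#'   `"first_half"`, `"last_half"`, `"random"` (possibly none).
#' @param n_random_iterations Random-subsample iterations (study design:
#'   10,000; scale down for interactive use).
#' @param hypotheses,responses Subsets of [hypothesis_ids()] and
#'   [response_measures()] to fit.
#' @param scope Battery scope for the continuous / first-half / last-half
#'   analyses (`"pooled"`, `"per_food"` or both).  Random iterations are
#'   always reduced to pooled omnibus decisions, so the 10,000 fits per
#'   cell are never held in memory.
#' @param alpha Significance level.
#' @param df_method Passed to [fit_lme()].
#' @param seed Integer seed driving generation and random subsampling.
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = preset("paper_like"),
                       input_dir = NULL,
                       schemes = c("first_half", "last_half", "random"),
                       n_random_iterations = 200L,
                       hypotheses = hypothesis_ids(),
                       responses = response_measures(),
                       scope = "pooled",
                       alpha = 0.05,
                       df_method = "residual",
                       seed = 1L) {
  stopifnot(n_random_iterations >= 1L)
  if (length(schemes)) {
    schemes <- match.arg(schemes,
                         c("first_half", "last_half", "random"),
                         several.ok = TRUE)
  }
  structure(as.list(environment())[c(
    "generator", "input_dir", "schemes", "n_random_iterations",
    "hypotheses", "responses", "scope", "alpha", "df_method", "seed")],
    class = "run_config")
}

.write_results_csv <- function(results, path_results, path_contrasts) {
  omni <- do.call(rbind, lapply(results, function(r) {
    if (nrow(r$omnibus) == 0L) {
      return(data.frame(hypothesis = r$hypothesis, response = r$response,
                        scope = r$scope, term = NA_character_,
                        statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                        p = NA_real_, converged = r$converged))
    }
    cbind(data.frame(hypothesis = r$hypothesis, response = r$response,
                     scope = r$scope), r$omnibus,
          data.frame(converged = r$converged))
  }))
  utils::write.csv(omni, path_results, row.names = FALSE, na = "")
  ctr <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$contrasts) || nrow(r$contrasts) == 0L) return(NULL)
    cbind(data.frame(hypothesis = r$hypothesis, response = r$response,
                     scope = r$scope), r$contrasts)
  }))
  if (is.null(ctr)) {
    ctr <- data.frame(hypothesis = character(), response = character(),
                      scope = character(), factor = character(),
                      contrast = character(), estimate = numeric(),
                      se = numeric(), df = numeric(), adj_p = numeric())
  }
  utils::write.csv(ctr, path_contrasts, row.names = FALSE, na = "")
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a dataset, computes the per-sequence measures
#' table, fits the hypothesis battery on the continuous data, repeats it
#' on each requested discontinuous scheme, scores replication against the
#' continuous baseline, and summarizes random-iteration significance
#' rates.  All tables are written as CSV under `out_dir` together with a
#' JSON manifest recording the seed, a config hash and package versions;
#' re-running with an identical config reproduces the bundle byte for
#' byte.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the dataset, measures table, battery
#'   results, decision vectors, replication reports and random-iteration
#'   summary.
#' @export
run_all <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("stage: input")
  dataset <- if (!is.null(config$input_dir)) {
    read_dataset(config$input_dir)
  } else {
    gen <- config$generator
    gen$seed <- config$seed
    generate(gen)
  }

  say("stage: measures (", length(dataset$sequences), " sequences)")
  measures <- measures_table(dataset)
  utils::write.csv(measures, file.path(out_dir, "measures.csv"),
                   row.names = FALSE)

  battery <- function(tab) {
    suppressWarnings(run_battery(
      tab, hypotheses = config$hypotheses, responses = config$responses,
      scope = config$scope, df_method = config$df_method))
  }

  say("stage: continuous battery")
  res_cont <- battery(measures)
  .write_results_csv(res_cont, file.path(out_dir, "results_continuous.csv"),
                     file.path(out_dir, "contrasts_continuous.csv"))
  vec_cont <- significance_vector(res_cont, alpha = config$alpha,
                                  level = "both")
  n_failed <- sum(!vapply(res_cont, `[[`, TRUE, "converged"))
  say("  fits: ", length(res_cont), " (", n_failed, " failed to converge)")

  reports <- list()
  for (scheme_kind in setdiff(config$schemes, "random")) {
    say("stage: ", scheme_kind, " battery")
    disc <- make_discontinuous_dataset(dataset, split_scheme(scheme_kind))
    res <- battery(measures_table(disc))
    tag <- sub("_half", "", scheme_kind)
    .write_results_csv(res,
                       file.path(out_dir, paste0("results_", tag, ".csv")),
                       file.path(out_dir, paste0("contrasts_", tag, ".csv")))
    vec <- significance_vector(res, alpha = config$alpha, level = "both")
    reports[[scheme_kind]] <- replication_rate(vec_cont, vec)
  }

  random_summary <- NULL
  if ("random" %in% config$schemes) {
    say("stage: random batteries (", config$n_random_iterations,
        " iterations, pooled omnibus)")
    cont_term <- vec_cont[vec_cont$kind == "term" &
                          vec_cont$scope == "pooled", , drop = FALSE]
    iter_vecs <- iterate_random(
      dataset, config$n_random_iterations, base_seed = config$seed,
      fun = function(d, i) {
        res <- suppressWarnings(run_battery(
          measures_table(d), hypotheses = config$hypotheses,
          responses = config$responses, scope = "pooled",
          df_method = config$df_method, contrasts = FALSE))
        significance_vector(res, alpha = config$alpha, level = "term")
      })
    random_summary <- random_iteration_summary(iter_vecs)
    utils::write.csv(random_summary,
                     file.path(out_dir, "random_summary.csv"),
                     row.names = FALSE)
    rates <- vapply(iter_vecs, function(v) {
      replication_rate(cont_term, v)$overall
    }, numeric(1))
    reports[["random"]] <- list(
      mean_overall = mean(rates, na.rm = TRUE),
      per_iteration = rates
    )
  }

  say("stage: replication summary")
  key_tabs <- list()
  sum_rows <- list()
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    if (inherits(rep, "replication_report")) {
      key_tabs[[nm]] <- cbind(data.frame(scheme = nm), rep$table)
      sum_rows[[nm]] <- data.frame(scheme = nm, level = "overall",
                                   percent_replicated = rep$overall,
                                   n_keys = rep$n_scored)
      sum_rows[[paste0(nm, "_h")]] <- data.frame(
        scheme = nm, level = rep$per_hypothesis$hypothesis,
        percent_replicated = rep$per_hypothesis$percent_replicated,
        n_keys = rep$per_hypothesis$n_keys)
    } else if (!is.null(rep)) {
      sum_rows[[nm]] <- data.frame(scheme = nm, level = "overall",
                                   percent_replicated = rep$mean_overall,
                                   n_keys = length(rep$per_iteration))
    }
  }
  if (length(key_tabs)) {
    utils::write.csv(do.call(rbind, key_tabs),
                     file.path(out_dir, "replication.csv"),
                     row.names = FALSE)
  }
  if (length(sum_rows)) {
    summ <- do.call(rbind, sum_rows)
    rownames(summ) <- NULL
    utils::write.csv(summ, file.path(out_dir, "replication_summary.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_sequences = length(dataset$sequences),
    schemes = config$schemes,
    n_random_iterations = if ("random" %in% config$schemes)
      config$n_random_iterations else 0L,
    versions = list(
      oralproc = as.character(utils::packageVersion("oralproc")),
      lme4 = as.character(utils::packageVersion("lme4")),
      emmeans = as.character(utils::packageVersion("emmeans")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = dataset, measures = measures,
                 continuous = res_cont, continuous_vector = vec_cont,
                 reports = reports, random_summary = random_summary))
}

#' Deterministic hash of a run configuration
#' @param config A `run_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
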