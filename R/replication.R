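#' Three-state significance decisions for a battery of model fits
#'
#' Reduces a list of [fit_lme()] results to one decision per key, where a
#' key is (hypothesis, response, scope, kind, term-or-contrast).  Decisions
#' are `"sig"` (p < alpha, strictly: p equal to alpha counts as
#' non-significant), `"nonsig"`, or `"failed"` for fits that did not
#' converge.  Failed keys stay in the table so that replication scoring
#' can exclude them from its denominator and list them.
#'
#' @param results List of `hypothesis_result` objects ([run_battery()]).
#' @param alpha Significance level (default 0.05).
#' @param level Score omnibus `"term"`s, `"contrast"`s, or `"both"`.
#' @return Data.frame with columns `hypothesis`, `response`, `scope`,
#'   `kind`, `key`, `p`, `status`.
#' @export
significance_vector <- function(results, alpha = 0.05,
                                level = c("term", "contrast", "both")) {
  level <- match.arg(level)
  rows <- lapply(results, function(r) {
    out <- list()
    if (level %in% c("term", "both")) {
      if (!r$converged || nrow(r$omnibus) == 0L) {
        out$term <- data.frame(
          hypothesis = r$hypothesis, response = r$response, scope = r$scope,
          kind = "term", key = "<all>", p = NA_real_, status = "failed")
      } else {
        out$term <- data.frame(
          hypothesis = r$hypothesis, response = r$response, scope = r$scope,
          kind = "term", key = r$omnibus$term, p = r$omnibus$p,
          status = ifelse(is.na(r$omnibus$p), "failed",
                          ifelse(r$omnibus$p < alpha, "sig", "nonsig")))
      }
    }
    if (level %in% c("contrast", "both")) {
      cf <- r$contrasts
      if (!r$converged || is.null(cf) || nrow(cf) == 0L) {
        out$contrast <- data.frame(
          hypothesis = r$hypothesis, response = r$response, scope = r$scope,
          kind = "contrast", key = "<all>", p = NA_real_, status = "failed")
      } else {
        out$contrast <- data.frame(
          hypothesis = r$hypothesis, response = r$response, scope = r$scope,
          kind = "contrast", key = paste(cf$factor, cf$contrast, sep = ": "),
          p = cf$adj_p,
          status = ifelse(is.na(cf$adj_p), "failed",
                          ifelse(cf$adj_p < alpha, "sig", "nonsig")))
      }
    }
    do.call(rbind, out)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.vec_id <- function(v) {
  paste(v$hypothesis, v$response, v$scope, v$kind, v$key, sep = "||")
}

.cell_id <- function(v) {
  paste(v$hypothesis, v$response, v$scope, v$kind, sep = "||")
}

#' Replication rate of discontinuous-data decisions
#'
#' A key is replicated when its three-state significance decision from the
#' discontinuous analysis matches the continuous one (both significant or
#' both non-significant).  Keys that failed to converge in either analysis
#' are excluded from the denominator and listed, mirroring how failed fits
#' are reported separately rather than counted as non-replications.
#' Direction agreement of the underlying decisions is not scored.
#'
#' @param continuous,discontinuous Decision tables from
#'   [significance_vector()]; they must contain the same key set.
#' @return An object of class `replication_report`: the key-level table,
#'   per-hypothesis percentages, the overall percentage (100 x replicated /
#'   scored keys), and the excluded (failed) keys.
#' @export
replication_rate <- function(continuous, discontinuous) {
  # a fit that failed on either side voids its whole
  # (hypothesis, response, scope, kind) cell: the term/contrast keys of an
  # unfitted model are unknowable, so the cell leaves the denominator
  failed_cells <- union(
    .cell_id(continuous)[continuous$status == "failed"],
    .cell_id(discontinuous)[discontinuous$status == "failed"])
  excluded <- continuous[.cell_id(continuous) %in% failed_cells, ,
                         drop = FALSE]
  cont <- continuous[!.cell_id(continuous) %in% failed_cells, , drop = FALSE]
  disc <- discontinuous[!.cell_id(discontinuous) %in% failed_cells, ,
                        drop = FALSE]

  ck <- .vec_id(cont)
  dk <- .vec_id(disc)
  if (length(setdiff(ck, dk)) || length(setdiff(dk, ck))) {
    stop("decision vectors do not share keys; difference: ",
         paste(c(setdiff(ck, dk), setdiff(dk, ck)), collapse = "; "),
         call. = FALSE)
  }
  disc <- disc[match(ck, dk), ]
  tab <- cont[, c("hypothesis", "response", "scope", "kind", "key")]
  tab$continuous_status <- cont$status
  tab$discontinuous_status <- disc$status
  tab$scored <- TRUE
  tab$replicated <- tab$continuous_status == tab$discontinuous_status

  scored <- tab
  per_h <- do.call(rbind, lapply(split(scored, scored$hypothesis), function(g) {
    data.frame(hypothesis = g$hypothesis[1], n_keys = nrow(g),
               percent_replicated = 100 * mean(g$replicated))
  }))
  rownames(per_h) <- NULL
  structure(
    list(table = tab,
         per_hypothesis = per_h,
         overall = if (nrow(scored)) 100 * mean(scored$replicated) else NA_real_,
         n_scored = nrow(scored),
         excluded = excluded),
    class = "replication_report"
  )
}

#' @export
print.replication_report <- function(x, ...) {
  cat("<replication_report> overall", format(x$overall, digits = 4),
      "% replicated over", x$n_scored, "keys;",
      nrow(x$excluded), "excluded (failed fits)\n")
  print(x$per_hypothesis, digits = 4)
  invisible(x)
}

#' Percent of random iterations significant, per key
#'
#' Summarizes the decision tables of repeated random-subsample analyses:
#' for each key, the percentage of iterations in which the test was
#' significant, out of the iterations in which the model converged.  Keys
#' that failed in every iteration are reported as `NA` with denominator 0.
#'
#' @param iteration_vectors List of decision tables from
#'   [significance_vector()], one per iteration.
#' @return Data.frame with key columns plus `n_iterations`, `n_converged`,
#'   `percent_significant`.
#' @export
random_iteration_summary <- function(iteration_vectors) {
  stopifnot(length(iteration_vectors) >= 1L)
  combined <- do.call(rbind, iteration_vectors)
  conv <- combined[combined$status != "failed", , drop = FALSE]
  # keys seen in at least one converged iteration; cells that failed in
  # every iteration keep their sentinel row so they surface as NA
  all_failed <- setdiff(.cell_id(combined), .cell_id(conv))
  keep <- rbind(conv,
                combined[.cell_id(combined) %in% all_failed &
                           !duplicated(.vec_id(combined)), , drop = FALSE])
  ids <- .vec_id(keep)
  out <- keep[!duplicated(ids), c("hypothesis", "response", "scope",
                                  "kind", "key")]
  uid <- ids[!duplicated(ids)]
  conv_ids <- .vec_id(conv)
  n_conv <- vapply(uid, function(k) sum(conv_ids == k), integer(1))
  n_sig <- vapply(uid, function(k) {
    sum(conv_ids == k & conv$status == "sig")
  }, integer(1))
  out$n_iterations <- length(iteration_vectors)
  out$n_converged <- unname(n_conv)
  out$percent_significant <- unname(
    ifelse(n_conv > 0, 100 * n_sig / n_conv, NA_real_))
  rownames(out) <- NULL
  out
}
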