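#' Observation-discontinuity schemes
#'
#' Discontinuous observations mimic interrupted visibility in the field.
#' Three schemes are supported: the first half of each feeding sequence,
#' the last half, and a random subsample of at least `min_behaviors`
#' consecutive behaviors.  Halves are defined by event count; an odd-length
#' sequence gives its extra event to the first half.
#'
#' @param kind `"first_half"`, `"last_half"`, or `"random"`.
#' @param min_behaviors Minimum events in a random subsample (default 4).
#' @param contiguous Draw contiguous runs (default) or arbitrary
#'   order-preserving subsets.
#' @param seed Optional integer seed making a single random draw
#'   reproducible.
#' @return An object of class `split_scheme`.
#' @export
split_scheme <- function(kind = c("first_half", "last_half", "random"),
                         min_behaviors = 4L, contiguous = TRUE, seed = NULL) {
  kind <- match.arg(kind)
  if (min_behaviors < 1L) stop("min_behaviors must be >= 1", call. = FALSE)
  structure(list(kind = kind, min_behaviors = as.integer(min_behaviors),
                 contiguous = isTRUE(contiguous), seed = seed),
            class = "split_scheme")
}

.subset_events <- function(seq, idx) {
  ev <- seq$events[idx, , drop = FALSE]
  rownames(ev) <- NULL
  out <- seq
  out$events <- ev
  out
}

#' First half of a feeding sequence
#'
#' Returns the first `ceiling(n/2)` events with metadata retained, e.g. a
#' 7-behavior sequence keeps its first 4 behaviors.
#'
#' @param seq A `feeding_sequence` with at least one event.
#' @return A `feeding_sequence`.
#' @export
first_half <- function(seq) {
  n <- n_events(seq)
  if (n < 1L) stop("empty sequence", call. = FALSE)
  .subset_events(seq, seq_len(ceiling(n / 2)))
}

#' Last half of a feeding sequence
#'
#' Returns the last `floor(n/2)` events, the exact complement of
#' [first_half()].  A single-event sequence returns that event rather than
#' an empty sequence, so downstream metrics never see empty input.
#'
#' @param seq A `feeding_sequence` with at least one event.
#' @return A `feeding_sequence`.
#' @export
last_half <- function(seq) {
  n <- n_events(seq)
  if (n < 1L) stop("empty sequence", call. = FALSE)
  if (n == 1L) return(.subset_events(seq, 1L))
  .subset_events(seq, (ceiling(n / 2) + 1L):n)
}

#' Random subsample of a feeding sequence
#'
#' Draws a random-length, random-position slice of at least
#' `min_behaviors` events (the whole sequence when it is shorter than
#' that).  Contiguous runs are the default; with `contiguous = FALSE` an
#' arbitrary order-preserving subset is drawn instead.  Draws use the
#' current RNG state unless the scheme carries a seed, in which case the
#' draw is reproducible and the caller's RNG state is untouched.
#'
#' @param seq A `feeding_sequence` with at least one event.
#' @param scheme A `split_scheme` with `kind = "random"`.
#' @return A `feeding_sequence`.
#' @export
random_subsample <- function(seq, scheme = split_scheme("random")) {
  stopifnot(inherits(scheme, "split_scheme"), scheme$kind == "random")
  n <- n_events(seq)
  if (n < 1L) stop("empty sequence", call. = FALSE)
  draw <- function() {
    lo <- min(scheme$min_behaviors, n)
    len <- if (lo >= n) n else sample(lo:n, 1L)
    if (scheme$contiguous) {
      start <- if (len >= n) 1L else sample(seq_len(n - len + 1L), 1L)
      start:(start + len - 1L)
    } else {
      sort(sample.int(n, len))
    }
  }
  idx <- if (is.null(scheme$seed)) draw() else with_local_seed(scheme$seed, draw())
  .subset_events(seq, idx)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit seed from (base seed, iteration, sequence key), so
# random draws do not depend on iteration order or parallel layout.
derive_seed <- function(base_seed, iteration, key) {
  s <- paste(base_seed, iteration, key, sep = "/")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

#' Apply a discontinuity scheme to every sequence of a dataset
#'
#' Produces a dataset with the same number of sequences, each transformed
#' by the scheme.  For the random scheme, each sequence gets an independent
#' draw seeded by `hash(base_seed, iteration, sequence_key)`, so a fixed
#' `(dataset, scheme, base_seed, iteration)` always yields an identical
#' result.
#'
#' @param dataset An `ethogram_dataset`.
#' @param scheme A `split_scheme`.
#' @param base_seed Integer seed for the random scheme (ignored otherwise).
#' @param iteration Iteration index folded into per-sequence seeds.
#' @return An `ethogram_dataset`.
#' @export
make_discontinuous_dataset <- function(dataset, scheme,
                                       base_seed = 1L, iteration = 1L) {
  f <- switch(scheme$kind,
    first_half = function(s, key) first_half(s),
    last_half  = function(s, key) last_half(s),
    random     = function(s, key) {
      sch <- scheme
      sch$seed <- derive_seed(base_seed, iteration, key)
      random_subsample(s, sch)
    }
  )
  sequences <- lapply(dataset$sequences, function(s) f(s, sequence_key(s)))
  out <- dataset
  out$sequences <- sequences
  out
}

#' Stream random-subsample iterations through a function
#'
#' Repeats the random-subsampling experiment `n_iter` times, calling
#' `fun(dataset_i, iteration)` on each freshly drawn discontinuous dataset
#' and collecting only the (typically small) return values.  Datasets are
#' built one at a time and discarded, so the full set of iterations is
#' never held in memory; the study design used 10,000 iterations.
#'
#' @param dataset An `ethogram_dataset`.
#' @param n_iter Number of iterations (>= 1).
#' @param base_seed Integer base seed; iteration-indexed seeds are derived
#'   from it, so results do not depend on evaluation order.
#' @param fun Function of `(dataset, iteration)`; defaults to returning the
#'   dataset itself (only sensible for small `n_iter`).
#' @param scheme Random `split_scheme` to apply.
#' @return List of `fun` results, one per iteration.
#' @export
iterate_random <- function(dataset, n_iter, base_seed = 1L,
                           fun = function(d, i) d,
                           scheme = split_scheme("random")) {
  stopifnot(n_iter >= 1L)
  lapply(seq_len(n_iter), function(i) {
    fun(make_discontinuous_dataset(dataset, scheme,
                                   base_seed = base_seed, iteration = i), i)
  })
}
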