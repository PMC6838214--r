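# Convergence-controlled subsampled approximation of summary distributions,
# and the unbiased batched variant for nearest-neighbor distances.

#' Approximation configuration
#'
#' Defaults follow the method's stated tuning: batch size 30, convergence
#' tolerance 0.001 for generic summaries and 1e-4 for the nearest-neighbor
#' distribution.  `max_iterations` caps the otherwise unbounded loop.
#'
#' @param batch_size number of records drawn per batch (m).
#' @param tolerance convergence tolerance on the JSD between successive
#'   iterates.
#' @param nn_tolerance tolerance used by [approximate_nn_distribution()].
#' @param max_iterations safety cap on the number of batches.
#' @param seed optional integer seed; fixed seeds give identical output.
#' @return a list of class `approx_config`.
#' @export
approx_config <- function(batch_size = 30, tolerance = 1e-3,
                          nn_tolerance = 1e-4, max_iterations = 1e4,
                          seed = NULL) {
  stopifnot(batch_size >= 1, tolerance > 0, nn_tolerance > 0,
            max_iterations >= 1)
  structure(list(batch_size = as.integer(batch_size), tolerance = tolerance,
                 nn_tolerance = nn_tolerance,
                 max_iterations = as.integer(max_iterations), seed = seed),
            class = "approx_config")
}

with_config_seed <- function(config, code) {
  if (is.null(config$seed)) return(code)
  withr::with_seed(config$seed, code)
}

#' Approximate a summary distribution by batched subsampling
#'
#' Draws batches of `batch_size` records (without replacement within a
#' batch; with replacement only when the batch exceeds the table), applies
#' the summary to each batch, appends the values to a rolling vector, and
#' stops when the JSD between successive iterates falls below the tolerance.
#' At least two batches are always drawn.  On small tables
#' (`n <= 2 * batch_size`) the exact summary is returned instead and the
#' mode is recorded.
#'
#' @param tbl repertoire data frame.
#' @param summary a summary name from [list_summaries()] (of kind `dist`) or
#'   a function `table -> numeric vector`.
#' @param config an [approx_config()].
#' @return a `rep_dist` tibble with attributes `mode`
#'   (`"approximate"`/`"exact"`), `iterations` and `final_jsd`.
#' @export
approximate_distribution <- function(tbl, summary, config = approx_config()) {
  if (nrow(tbl) == 0) abort("empty table")
  fun <- resolve_dist_summary(summary)
  name <- if (is.character(summary)) summary else "custom_summary"
  if (nrow(tbl) <= 2 * config$batch_size) {
    vals <- fun(tbl)
    out <- new_rep_dist(vals, name, nrow(tbl))
    attr(out, "mode") <- "exact"
    attr(out, "iterations") <- 0L
    attr(out, "final_jsd") <- NA_real_
    return(out)
  }
  with_config_seed(config, {
    draw <- function() tbl[sample.int(nrow(tbl), config$batch_size), , drop = FALSE]
    d_prev <- fun(draw())
    it <- 1L
    err <- Inf
    repeat {
      d_new <- c(d_prev, fun(draw()))
      it <- it + 1L
      err <- jsd(d_prev, d_new)
      d_prev <- d_new
      if (err < config$tolerance || it >= config$max_iterations) break
    }
    out <- new_rep_dist(d_prev, name, nrow(tbl))
    attr(out, "mode") <- "approximate"
    attr(out, "iterations") <- it
    attr(out, "final_jsd") <- err
    out
  })
}

resolve_dist_summary <- function(summary) {
  if (is.function(summary)) return(function(tbl) dist_values(summary(tbl)))
  reg <- summary_registry()
  i <- match(summary, reg$name)
  if (is.na(i)) abort(paste0("unknown summary: ", summary))
  if (reg$kind[i] != "dist")
    abort(sprintf("summary '%s' is not distribution-valued (kind %s)",
                  summary, reg$kind[i]))
  f <- reg$fun[[i]]
  function(tbl) dist_values(f(tbl))
}

#' Unbiased approximate nearest-neighbor distance distribution
#'
#' A subsample-only nearest-neighbor estimate is biased upward: dropping
#' sequences can only leave each minimum unchanged or larger.  This batched
#' variant instead samples `batch_size` sequences per batch and computes each
#' one's exact nearest-neighbor distance against the full repertoire, so
#' every emitted value is a member of the exact distribution; batches are
#' appended until the JSD between successive iterates drops below
#' `nn_tolerance`.  On small inputs (`n <= 2 * batch_size`) the exact
#' distribution is returned.
#'
#' @param x repertoire data frame or character vector of sequences.
#' @param field column holding the sequences.
#' @param k which order statistic (default 1, the nearest neighbor).
#' @param metric `"levenshtein"` or `"hamming"`.
#' @param config an [approx_config()]; the `nn_tolerance` element is used.
#' @return a `rep_dist` tibble with `mode`, `iterations`, `final_jsd`
#'   attributes.
#' @export
approximate_nn_distribution <- function(x, field = "sequence_alignment",
                                        k = 1, metric = "levenshtein",
                                        config = approx_config()) {
  seqs <- degap(resolve_seqs(x, field))
  n <- length(seqs)
  if (n < 2) abort("need at least 2 sequences")
  if (n <= 2 * config$batch_size) {
    out <- new_rep_dist(kth_nn_distances(seqs, k = k, metric = metric),
                        "nearest_neighbor_distance", n)
    attr(out, "mode") <- "exact"
    attr(out, "iterations") <- 0L
    attr(out, "final_jsd") <- NA_real_
    return(out)
  }
  with_config_seed(config, {
    batch <- function() {
      idx <- sample.int(n, config$batch_size)
      kth_nn_query(idx, seqs, k = k, metric = metric)
    }
    d_prev <- batch()
    it <- 1L
    err <- Inf
    repeat {
      d_new <- c(d_prev, batch())
      it <- it + 1L
      err <- jsd(d_prev, d_new)
      d_prev <- d_new
      if (err < config$nn_tolerance || it >= config$max_iterations) break
    }
    out <- new_rep_dist(d_prev, "nearest_neighbor_distance", n)
    attr(out, "mode") <- "approximate"
    attr(out, "iterations") <- it
    attr(out, "final_jsd") <- err
    out
  })
}
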