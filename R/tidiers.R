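# broom-style tidiers for the fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a summary ranking
#'
#' @param x a `summary_ranking` from [rank_summaries()].
#' @param ... unused.
#' @return a tibble with one row per (class, summary) pair: the per-class
#'   branch-off lambda and rank, plus the final rank.
#' @export
tidy.summary_ranking <- function(x, ...) {
  pc <- x$per_class_ranks
  bl <- x$branch_lambdas
  out <- tidyr::expand_grid(class_label = rownames(pc),
                            summary = colnames(pc)) %>%
    mutate(rank = as.vector(t(pc)),
           branch_lambda = as.vector(t(bl))) %>%
    left_join(x$ranks, by = "summary")
  as_tibble(out)
}

#' @rdname tidy.summary_ranking
#' @export
glance.summary_ranking <- function(x, ...) {
  tibble(n_classes = nrow(x$per_class_ranks),
         n_summaries = ncol(x$per_class_ranks),
         n_lambda = length(x$lambdas),
         lambda_max = max(x$lambdas),
         lambda_min = min(x$lambdas))
}

#' Tidy LRAD scores
#'
#' @param x an `lrad_scores` tibble from [score_report()].
#' @param ... unused.
#' @return a long tibble: `summary`, `mode` (data/sim), `value`,
#'   `numerator_mean`, `denominator_mean`.
#' @export
tidy.lrad_scores <- function(x, ...) {
  bind_rows(
    tibble(summary = x$summary, mode = "data", value = x$lrad_data,
           numerator_mean = x$numerator_data,
           denominator_mean = x$denominator),
    tibble(summary = x$summary, mode = "sim", value = x$lrad_sim,
           numerator_mean = x$numerator_sim,
           denominator_mean = x$denominator)
  )
}

#' @rdname tidy.lrad_scores
#' @export
glance.lrad_scores <- function(x, ...) {
  skip <- attr(x, "skipped")
  tibble(n_scored = nrow(x),
         n_skipped = if (is.null(skip)) 0L else nrow(skip),
         n_positive_data = sum(x$lrad_data > 0, na.rm = TRUE),
         n_positive_sim = sum(x$lrad_sim > 0, na.rm = TRUE))
}

#' Tidy a divergence matrix
#'
#' @param x a `rep_divmat` from [divergence_matrix()].
#' @param ... unused.
#' @return a long tibble of unordered pairs: `label1`, `label2`,
#'   `divergence`.
#' @export
tidy.rep_divmat <- function(x, ...) {
  m <- unclass(x)
  labs <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(label1 = labs[idx[, 1]], label2 = labs[idx[, 2]],
         divergence = m[idx], summary = attr(x, "summary"))
}
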