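# Plotting: frequency polygons and ECDFs for univariate summary
# distributions, plus companion plots for rankings, LRAD scores and MDS
# embeddings.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a summary distribution
#'
#' @param object a `rep_dist` tibble.
#' @param type `"freqpoly"` (frequency polygon, default) or `"ecdf"`.
#' @param bins number of bins for the frequency polygon.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rep_dist <- function(object, type = c("freqpoly", "ecdf"),
                              bins = 30, ...) {
  type <- arg_match(type)
  name <- attr(object, "summary")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = value))
  p <- if (type == "freqpoly") {
    p + ggplot2::geom_freqpoly(bins = bins)
  } else {
    p + ggplot2::stat_ecdf()
  }
  p + ggplot2::labs(x = name, y = if (type == "freqpoly") "count" else "ECDF",
                    title = name)
}

#' Gridded univariate distribution plots for a repertoire
#'
#' Computes every distribution-valued summary available at the table's
#' capability and facets them into one figure.
#'
#' @param tbl repertoire data frame.
#' @param trees optional `clone_trees`.
#' @param type `"freqpoly"` or `"ecdf"`.
#' @param summaries `"all"` or a character vector of summary names.
#' @return a ggplot.
#' @export
plot_univariate_distributions <- function(tbl, trees = NULL,
                                          type = c("freqpoly", "ecdf"),
                                          summaries = "all") {
  type <- arg_match(type)
  long <- summarize_repertoire(tbl, trees = trees, summaries = summaries)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = value))
  p <- if (type == "freqpoly") p + ggplot2::geom_freqpoly(bins = 30)
       else p + ggplot2::stat_ecdf()
  p + ggplot2::facet_wrap(~summary, scales = "free") +
    ggplot2::labs(x = NULL, y = if (type == "freqpoly") "count" else "ECDF")
}

#' All distribution-valued summaries of a repertoire, long form
#'
#' @inheritParams plot_univariate_distributions
#' @return a tibble `summary`, `value` covering every distribution-valued
#'   summary computable at the table's capability.
#' @export
summarize_repertoire <- function(tbl, trees = NULL, summaries = "all") {
  reg <- summary_registry() %>% filter(kind == "dist")
  if (!identical(summaries, "all")) reg <- reg[reg$name %in% summaries, ]
  cap <- airr_capability(tbl, trees)
  cap_rank <- match(as.character(cap),
                    c("alignment_only", "annotated", "clustered", "phylogenetic"))
  rows <- purrr::pmap(reg, function(name, kind, level, sequence_level,
                                    factor_scale, fun, row_fun) {
    if (match(level, c("alignment_only", "annotated", "clustered",
                       "phylogenetic")) > cap_rank) return(NULL)
    vals <- tryCatch(dist_values(fun(tbl, trees = trees)),
                     error = function(e) NULL)
    if (is.null(vals)) return(NULL)
    tibble(summary = name, value = vals)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("no distribution-valued summary computable")
  out
}

#' Plot per-class informativeness ranks
#'
#' Boxplots of the per-class ranks of each summary, ordered by final rank
#' (most informative first).
#'
#' @param object a `summary_ranking`.
#' @param ... unused.
#' @export
autoplot.summary_ranking <- function(object, ...) {
  long <- tidy(object)
  ord <- object$ranks$summary
  long$summary <- factor(long$summary, levels = rev(ord))
  ggplot2::ggplot(long, ggplot2::aes(x = summary, y = rank)) +
    ggplot2::geom_boxplot() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "per-class branch-off rank")
}

#' Plot LRAD scores
#'
#' Bar chart of per-summary log relative average divergences.
#'
#' @param object an `lrad_scores` tibble.
#' @param mode `"data"` or `"sim"`.
#' @param ... unused.
#' @export
autoplot.lrad_scores <- function(object, mode = c("data", "sim"), ...) {
  mode <- arg_match(mode)
  val <- if (mode == "data") object$lrad_data else object$lrad_sim
  df <- tibble(summary = factor(object$summary, levels = rev(object$summary)),
               value = val)
  ggplot2::ggplot(df, ggplot2::aes(x = summary, y = value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("LRAD-", mode))
}

#' Plot an MDS embedding
#'
#' @param object a `rep_mds` tibble from [mds_embed()].
#' @param ... unused.
#' @export
autoplot.rep_mds <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = dim1, y = dim2, label = label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2")
}
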