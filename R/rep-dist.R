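# Lightweight containers for summary outputs.
#
# A summary distribution is a one-column tibble of finite scalar values with
# the summary name and the number of contributing records as attributes.
# Categorical counts are a two-column tibble (category, count).

new_rep_dist <- function(values, name, n_source) {
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    abort(sprintf("summary '%s' produced non-finite values", name))
  structure(
    tibble(value = values),
    class = c("rep_dist", "tbl_df", "tbl", "data.frame"),
    summary = name,
    n_source = as.integer(n_source)
  )
}

#' @export
print.rep_dist <- function(x, ...) {
  cat(sprintf("<summary distribution '%s': %d values from %d records>\n",
              attr(x, "summary"), nrow(x), attr(x, "n_source")))
  NextMethod()
}

#' Extract the values of a summary distribution
#'
#' @param x a `rep_dist` object (or anything with a `value` column).
#' @return numeric vector.
#' @export
dist_values <- function(x) {
  if (is.numeric(x)) return(x)
  x$value
}

new_rep_counts <- function(counts, name) {
  # counts: named numeric/integer vector or tibble(category, count)
  if (!is.data.frame(counts)) {
    counts <- tibble(category = names(counts), count = as.numeric(unname(counts)))
  }
  if (any(counts$count < 0)) abort("counts must be nonnegative")
  structure(
    as_tibble(counts),
    class = c("rep_counts", "tbl_df", "tbl", "data.frame"),
    summary = name
  )
}

#' @export
print.rep_counts <- function(x, ...) {
  cat(sprintf("<categorical counts '%s': %d categories, total %g>\n",
              attr(x, "summary"), nrow(x), sum(x$count)))
  NextMethod()
}

# named numeric vector view of rep_counts (categories -> counts)
counts_vector <- function(x) {
  if (is.data.frame(x)) {
    key_cols <- setdiff(names(x), "count")
    keys <- do.call(paste, c(x[key_cols], sep = "|"))
    return(setNames(as.numeric(x$count), keys))
  }
  x
}
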