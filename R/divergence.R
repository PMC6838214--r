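# Divergences between summary outputs: Jensen-Shannon divergence for scalar
# distributions (computed on a shared discretization) and l1 divergence for
# categorical counts and matrices.

#' Shared discretization of two scalar samples
#'
#' Both samples are binned on the same `B = max(min(m, n), 2)` equal-width
#' bins spanning the pooled range, where `m` and `n` are the numbers of
#' distinct values (support sizes) of the two samples.  Bins are
#' left-closed/right-open with the last bin closed.  Bins in which exactly
#' one of the two densities is zero would give an infinite KL divergence;
#' they are discarded from both sides and the remaining masses renormalized.
#'
#' @param p_values,q_values non-empty numeric samples.
#' @return a list with `bin_edges`, `p` and `q` (probabilities over retained
#'   bins, each summing to 1), and `dropped` (number of one-sided bins
#'   removed).  When every occupied bin is one-sided, `p` and `q` are empty.
#' @export
discretize_samples <- function(p_values, q_values) {
  p_values <- dist_values(p_values)
  q_values <- dist_values(q_values)
  if (length(p_values) == 0 || length(q_values) == 0)
    abort("cannot discretize an empty sample")
  m <- length(unique(p_values))
  n <- length(unique(q_values))
  B <- max(min(m, n), 2)
  lo <- min(p_values, q_values)
  hi <- max(p_values, q_values)
  if (lo == hi) {
    # all mass at a single point in both samples: one shared bin
    return(list(bin_edges = c(lo, hi), p = 1, q = 1, dropped = 0L))
  }
  edges <- seq(lo, hi, length.out = B + 1)
  bin_of <- function(x) findInterval(x, edges, rightmost.closed = TRUE)
  p_counts <- tabulate(bin_of(p_values), nbins = B)
  q_counts <- tabulate(bin_of(q_values), nbins = B)
  p <- p_counts / sum(p_counts)
  q <- q_counts / sum(q_counts)
  one_sided <- xor(p > 0, q > 0)
  keep <- !one_sided & (p > 0 | q > 0)
  p <- p[keep]; q <- q[keep]
  if (sum(p) > 0) p <- p / sum(p)
  if (sum(q) > 0) q <- q / sum(q)
  list(bin_edges = edges, p = p, q = q, dropped = sum(one_sided))
}

#' Jensen-Shannon divergence between two scalar samples
#'
#' `JSD(P, Q) = KLD(P, M)/2 + KLD(Q, M)/2` with `M = (P + Q)/2`, computed in
#' natural log on the shared discretization of [discretize_samples()], so
#' `0 <= JSD <= ln 2`.  When the two samples share no occupied bin they are
#' maximally divergent and `ln 2` is returned with a warning.
#'
#' @param p,q non-empty numeric samples (or `rep_dist` objects).
#' @return nonnegative scalar, at most `log(2)`.
#' @export
#' @examples
#' jsd(rnorm(100), rnorm(100))
jsd <- function(p, q) {
  d <- discretize_samples(p, q)
  if (length(d$p) == 0) {
    warn("samples share no occupied bin; reporting the maximal divergence log(2)")
    return(log(2))
  }
  m <- (d$p + d$q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  v <- (kl(d$p) + kl(d$q)) / 2
  min(max(v, 0), log(2))  # clamp floating-point noise at the bounds
}

#' l1 divergence between two sets of categorical counts
#'
#' Sum of absolute differences of counts over the union of categories;
#' categories missing from one side count as zero.  With `normalize = TRUE`
#' the counts are first converted to relative frequencies, which makes
#' repertoires of different sizes comparable.
#'
#' @param c1,c2 `rep_counts` tibbles or named numeric vectors.
#' @param normalize compare relative frequencies instead of raw counts.
#' @return nonnegative scalar.
#' @export
#' @examples
#' l1_divergence(c(A = 3, B = 1), c(A = 1, B = 2))        # 3
#' l1_divergence(c(A = 3, B = 1), c(A = 1, B = 2), TRUE)  # 5/6
l1_divergence <- function(c1, c2, normalize = FALSE) {
  v1 <- counts_vector(c1)
  v2 <- counts_vector(c2)
  if (length(v1) == 0 && length(v2) == 0) abort("both count sets are empty")
  if (normalize) {
    if (sum(v1) > 0) v1 <- v1 / sum(v1)
    if (sum(v2) > 0) v2 <- v2 / sum(v2)
  }
  cats <- union(names(v1), names(v2))
  a <- setNames(rep(0, length(cats)), cats)
  b <- a
  a[names(v1)] <- v1
  b[names(v2)] <- v2
  sum(abs(a - b))
}

# divergence between the outputs of one registry summary on two repertoires
summary_divergence <- function(s1, s2, kind, normalize_counts = TRUE) {
  switch(kind,
    dist = jsd(s1, s2),
    counts = l1_divergence(s1, s2, normalize = normalize_counts),
    matrix = sum(abs(transition_matrix(s1) - transition_matrix(s2))),
    profile = l1_divergence(s1, s2, normalize = FALSE),
    scalar = abs(s1 - s2),
    abort(paste0("unknown summary kind: ", kind))
  )
}

divergence_method <- function(kind) {
  switch(kind, dist = "jsd", counts = "l1", matrix = "l1", profile = "l1",
         scalar = "l1")
}

summary_size <- function(s) {
  if (inherits(s, "rep_dist")) return(attr(s, "n_source"))
  if (is.data.frame(s)) return(nrow(s))
  length(s)
}

#' Compare two repertoires across summaries
#'
#' Computes every requested summary on both tables and the divergence
#' appropriate to its type: JSD for scalar distributions, l1 for categorical
#' counts (as relative frequencies), matrices, and profiles.  Summaries not
#' supported at the shared capability level of the two tables are reported
#' as skipped rather than raising errors.
#'
#' @param t1,t2 repertoire data frames.
#' @param summaries `"all"` or a character vector of summary names
#'   (see [list_summaries()]).
#' @param trees1,trees2 optional `clone_trees` lists enabling the
#'   phylogenetic summaries.
#' @param normalize_counts compare categorical counts as relative
#'   frequencies (default TRUE).
#' @return a tibble with one row per requested summary: `summary`, `method`,
#'   `divergence` (NA when skipped), `n_left`, `n_right`, `skipped`,
#'   `reason`.
#' @export
compare_repertoires <- function(t1, t2, summaries = "all",
                                trees1 = NULL, trees2 = NULL,
                                normalize_counts = TRUE) {
  reg <- summary_registry()
  if (!identical(summaries, "all")) {
    unknown <- setdiff(summaries, reg$name)
    if (length(unknown) > 0)
      abort(paste0("unknown summaries: ", paste(unknown, collapse = ", ")))
    reg <- reg[reg$name %in% summaries, , drop = FALSE]
  }
  cap <- min(airr_capability(t1, trees1), airr_capability(t2, trees2))
  cap_rank <- match(as.character(cap),
                    c("alignment_only", "annotated", "clustered", "phylogenetic"))
  rows <- purrr::pmap(reg, function(name, kind, level, sequence_level,
                                    factor_scale, fun, row_fun) {
    lvl_rank <- match(level, c("alignment_only", "annotated", "clustered",
                               "phylogenetic"))
    base <- tibble(summary = name, method = divergence_method(kind),
                   divergence = NA_real_, n_left = NA_integer_,
                   n_right = NA_integer_, skipped = TRUE, reason = NA_character_)
    if (lvl_rank > cap_rank) {
      base$reason <- paste0("requires capability ", level, ", tables have ", cap)
      return(base)
    }
    res <- tryCatch({
      s1 <- fun(t1, trees = trees1)
      s2 <- fun(t2, trees = trees2)
      tibble(summary = name, method = divergence_method(kind),
             divergence = summary_divergence(s1, s2, kind, normalize_counts),
             n_left = as.integer(summary_size(s1)),
             n_right = as.integer(summary_size(s2)),
             skipped = FALSE, reason = NA_character_)
    }, error = function(e) {
      base$reason <- conditionMessage(e)
      base
    })
    res
  })
  out <- bind_rows(rows)
  if (all(out$skipped)) abort("no summary computable on the two tables")
  out
}
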