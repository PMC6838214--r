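# Rearrangement-statistic summaries: gene usage, deletion/insertion length
# distributions, and insertion transition matrices.

#' Germline gene usage counts
#'
#' Counts of observed gene tuples over the requested axes.  Calls are
#' normalized first ([normalize_gene_calls()]): comma-separated lists keep
#' their first entry and alleles collapse to the gene level.  Marginal counts
#' equal the axis-sums of the joint counts by construction.
#'
#' @param x repertoire data frame.
#' @param axes subset of `c("v", "d", "j")` (default all three present).
#' @param collapse_alleles strip allele suffixes (default TRUE).
#' @return a `rep_counts` tibble with one column per axis plus `count`.
#' @export
gene_usage_counts <- function(x, axes = c("v", "d", "j"),
                              collapse_alleles = TRUE) {
  axes <- tolower(axes)
  if (!all(axes %in% c("v", "d", "j"))) abort("axes must be a subset of v, d, j")
  cols <- paste0(axes, "_call")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0)
    abort(paste0("requested axis column(s) absent: ",
                 paste(missing_cols, collapse = ", ")))
  genes <- as_tibble(lapply(setNames(cols, paste0(axes, "_gene")), function(f) {
    normalize_gene_calls(x[[f]], collapse_alleles = collapse_alleles)
  }))
  genes <- genes[stats::complete.cases(genes), , drop = FALSE]
  counted <- genes %>%
    dplyr::count(dplyr::across(dplyr::everything()), name = "count") %>%
    arrange(dplyr::across(dplyr::everything()))
  new_rep_counts(counted, paste0(paste(axes, collapse = ""), "_gene_usage"))
}

#' Rearrangement length distribution
#'
#' One nonnegative integer per record for one of the six exonucleolytic
#' deletion fields or the two non-templated insertion lengths.  `np1_length`
#' and `np2_length` fall back to the length of the `np1`/`np2` string when
#' the explicit length column is absent.
#'
#' @param x repertoire data frame.
#' @param field one of `v_3p_deletion`, `v_5p_deletion`, `d_3p_deletion`,
#'   `d_5p_deletion`, `j_3p_deletion`, `j_5p_deletion`, `np1_length`,
#'   `np2_length`.
#' @export
rearrangement_length_distribution <- function(x, field) {
  field <- arg_match0(field, c(
    "v_3p_deletion", "v_5p_deletion", "d_3p_deletion", "d_5p_deletion",
    "j_3p_deletion", "j_5p_deletion", "np1_length", "np2_length"))
  vals <- NULL
  if (field %in% names(x)) {
    vals <- x[[field]]
  } else if (field %in% c("np1_length", "np2_length")) {
    src <- sub("_length$", "", field)
    if (src %in% names(x)) vals <- nchar(x[[src]])
  }
  if (is.null(vals)) abort(sprintf("field '%s' (or its source column) is absent", field))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) abort(sprintf("field '%s' is missing for all records", field))
  if (any(vals < 0)) abort(sprintf("field '%s' has negative stored lengths", field))
  new_rep_dist(vals, field, length(vals))
}

#' Insertion transition matrix
#'
#' Nucleotide transition frequencies of the non-templated insertions: counts
#' of adjacent (from, to) base pairs pooled over all insertion strings, with
#' row-normalized frequencies.  Insertions of length <= 1 contribute no
#' transitions.
#'
#' @param x repertoire data frame.
#' @param which `"np1"` (VD or VJ insertion) or `"np2"` (DJ insertion).
#' @return a `rep_transitions` tibble with columns `from`, `to`, `count`,
#'   `prob`; rows with zero counts have `prob` 0.  Use
#'   [transition_matrix()] for the 4x4 matrix form.
#' @export
insertion_transition_matrix <- function(x, which = c("np1", "np2")) {
  which <- arg_match(which)
  seqs <- resolve_seqs(x, which)
  seqs <- seqs[nchar(seqs) >= 2]
  if (length(seqs) == 0)
    abort(sprintf("no %s insertion of length >= 2; no transitions observed", which))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (s in seqs) {
    v <- strsplit(s, "")[[1]]
    keep <- v %in% bases
    # ambiguous bases break adjacency: only count pairs of unambiguous bases
    for (i in seq_len(length(v) - 1)) {
      if (keep[i] && keep[i + 1]) counts[v[i], v[i + 1]] <- counts[v[i], v[i + 1]] + 1
    }
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  out <- tibble(
    from = rep(bases, each = 4),
    to = rep(bases, times = 4),
    count = as.vector(t(counts)),
    prob = as.vector(t(probs))
  )
  structure(out,
            class = c("rep_transitions", "tbl_df", "tbl", "data.frame"),
            summary = paste0(which, "_transition_matrix"),
            n_source = length(seqs))
}

#' Matrix form of a transition-frequency table
#'
#' @param x a `rep_transitions` tibble.
#' @param what `"prob"` (row-stochastic frequencies) or `"count"`.
#' @return a 4x4 matrix over A, C, G, T.
#' @export
transition_matrix <- function(x, what = c("prob", "count")) {
  what <- arg_match(what)
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, 4, 4, dimnames = list(bases, bases))
  m[cbind(x$from, x$to)] <- x[[what]]
  m
}

#' V/J in-frame percentage
#'
#' `100 * #(junction length divisible by 3) / #(records with a junction)`,
#' the annotation-tool-independent in-frame criterion.
#'
#' @param x repertoire data frame.
#' @return scalar percentage in \[0, 100\].
#' @export
in_frame_percentage <- function(x) {
  j <- resolve_seqs(x, "junction")
  if (length(j) == 0) abort("no non-missing junctions")
  100 * mean(nchar(j) %% 3 == 0)
}
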