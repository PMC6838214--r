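# String-metric engine.  The Levenshtein kernel is a blocked bit-parallel
# (Myers) implementation in src/distances.cpp; Hamming requires equal lengths.

check_metric <- function(metric) {
  arg_match0(metric, c("levenshtein", "hamming"))
}

#' String distance between two sequences
#'
#' @param a,b single character strings.
#' @param metric `"levenshtein"` (default) or `"hamming"` (equal lengths only).
#' @return integer distance.
#' @export
#' @examples
#' string_distance("AAAA", "AAAT")
string_distance <- function(a, b, metric = "levenshtein") {
  metric <- check_metric(metric)
  if (metric == "hamming") {
    if (nchar(a) != nchar(b))
      abort("hamming distance requires equal-length sequences")
    return(.cpp_hamming_pair(a, b))
  }
  .cpp_lev_pair(a, b)
}

# all pairwise distances i < j as an integer vector of length n(n-1)/2
pairwise_string_distances <- function(seqs, metric = "levenshtein") {
  metric <- check_metric(metric)
  if (length(seqs) < 2) abort("need at least 2 sequences")
  if (metric == "hamming") {
    if (length(unique(nchar(seqs))) > 1)
      abort("hamming distance requires equal-length sequences")
    return(.cpp_hamming_condensed(seqs))
  }
  .cpp_lev_condensed(seqs)
}

# k-th nearest-neighbor distance of every sequence against the rest
kth_nn_distances <- function(seqs, k = 1, metric = "levenshtein") {
  metric <- check_metric(metric)
  n <- length(seqs)
  if (k < 1) abort("k must be >= 1")
  if (k >= n) abort(sprintf("k (%d) must be smaller than the number of sequences (%d)", k, n))
  if (metric == "hamming") {
    if (length(unique(nchar(seqs))) > 1)
      abort("hamming distance requires equal-length sequences")
    d <- as.matrix(stats::as.dist(condensed_to_matrix(.cpp_hamming_condensed(seqs), n)))
    return(vapply(seq_len(n), function(i) sort(d[i, -i], partial = k)[k], numeric(1)))
  }
  as.numeric(.cpp_lev_kth_nn(seqs, as.integer(k)))
}

# k-th NN distance of the selected positions (1-based) against the full set
kth_nn_query <- function(idx, seqs, k = 1, metric = "levenshtein") {
  metric <- check_metric(metric)
  if (metric == "hamming") {
    return(vapply(idx, function(i) {
      d <- vapply(seqs[-i], function(s) .cpp_hamming_pair(seqs[[i]], s), integer(1))
      sort(d, partial = k)[k]
    }, numeric(1)))
  }
  as.numeric(.cpp_lev_nn_query(as.integer(idx) - 1L, seqs, as.integer(k)))
}

condensed_to_matrix <- function(d, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- NA  # filled below
  k <- 1L
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    m[i, j] <- d[k:(k + length(j) - 1L)]
    m[j, i] <- m[i, j]
    k <- k + length(j)
  }
  m
}
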