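# Somatic-hypermutation summaries from aligned sequence/germline pairs.

# paired, consistently degapped (seq, germ) strings for records where both
# fields are present
aligned_pairs <- function(x) {
  need <- c("sequence_alignment", "germline_alignment")
  if (!all(need %in% names(x)))
    abort("sequence_alignment and germline_alignment are both required")
  keep <- !is.na(x$sequence_alignment) & !is.na(x$germline_alignment)
  if (!any(keep)) abort("no records with both sequence_alignment and germline_alignment")
  degap_pair(x$germline_alignment[keep], x$sequence_alignment[keep])
}

#' Distance from germline to sequence distribution
#'
#' One value per record: the string distance between the germline and
#' observed alignments after pairwise-consistent degapping.
#'
#' @param x repertoire data frame.
#' @param metric `"levenshtein"` (default) or `"hamming"`.
#' @export
germline_distance_distribution <- function(x, metric = "levenshtein") {
  metric <- check_metric(metric)
  p <- aligned_pairs(x)
  d <- vapply(seq_along(p$a), function(i) {
    string_distance(p$a[i], p$b[i], metric)
  }, integer(1))
  new_rep_dist(d, "germline_distance", length(d))
}

# 1-based mutated positions of one degapped germline/sequence pair; both
# bases must be unambiguous (A, C, G, T)
mutated_positions <- function(germ, seq) {
  g <- strsplit(germ, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  n <- min(length(g), length(s))
  g <- g[seq_len(n)]; s <- s[seq_len(n)]
  ok <- g %in% c("A", "C", "G", "T") & s %in% c("A", "C", "G", "T")
  which(ok & g != s)
}

#' Positional distances between mutations
#'
#' For each record, the differences between consecutive sorted mutated
#' positions (positions where aligned germline and observed bases are both
#' unambiguous and differ).  Records with fewer than two mutations contribute
#' nothing; all emitted values are >= 1.
#'
#' @param x repertoire data frame.
#' @export
positional_mutation_distances <- function(x) {
  p <- aligned_pairs(x)
  gaps <- unlist(lapply(seq_along(p$a), function(i) {
    pos <- mutated_positions(p$a[i], p$b[i])
    if (length(pos) < 2) return(numeric(0))
    diff(pos)
  }))
  new_rep_dist(gaps, "positional_mutation_distances", length(p$a))
}

#' Per-gene (and per-position) substitution rates
#'
#' For each normalized V gene: total mismatched positions over total compared
#' positions, pooled over the records assigned to that gene.  With
#' `per_position = TRUE`, the positional mismatch frequency along the
#' alignment is returned instead (position index over the degapped
#' alignment).
#'
#' @param x repertoire data frame with gene calls and aligned pairs.
#' @param per_position return per-position rates (default FALSE).
#' @return a tibble `gene`, `rate` (plus `position` when per-position).
#' @export
per_gene_substitution_rates <- function(x, per_position = FALSE) {
  if (!"v_call" %in% names(x)) abort("v_call is required")
  keep <- !is.na(x$v_call) & !is.na(x$sequence_alignment) &
    !is.na(x$germline_alignment)
  if (!any(keep)) abort("no records with gene call and aligned pair")
  x <- x[keep, , drop = FALSE]
  p <- degap_pair(x$germline_alignment, x$sequence_alignment)
  gene <- normalize_gene_calls(x$v_call)
  per_rec <- lapply(seq_along(gene), function(i) {
    g <- strsplit(p$a[i], "")[[1]]
    s <- strsplit(p$b[i], "")[[1]]
    n <- min(length(g), length(s))
    g <- g[seq_len(n)]; s <- s[seq_len(n)]
    ok <- g %in% c("A", "C", "G", "T") & s %in% c("A", "C", "G", "T")
    tibble(gene = gene[i], position = which(ok), mismatch = (g != s)[ok])
  })
  rec <- bind_rows(per_rec)
  if (per_position) {
    rec %>%
      group_by(gene, position) %>%
      summarise(rate = mean(mismatch), .groups = "drop")
  } else {
    rec %>%
      group_by(gene) %>%
      summarise(rate = mean(mismatch), .groups = "drop")
  }
}
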