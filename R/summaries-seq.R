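# Sequence-level summaries that only need aligned reads.

# resolve a character vector of sequences from a table column or pass a
# character vector through; drops missing values
resolve_seqs <- function(x, field) {
  if (is.character(x)) return(x[!is.na(x)])
  if (!field %in% names(x))
    abort(sprintf("column '%s' is not present in the table", field))
  v <- x[[field]]
  v[!is.na(v)]
}

#' GC-content distribution
#'
#' One value per record: (G + C) / (A + C + G + T) over the degapped
#' sequence.  Ambiguous bases (N) are excluded from the denominator; records
#' with zero unambiguous bases are skipped.
#'
#' @param x repertoire data frame (or character vector of sequences).
#' @param field column holding the sequences (default `sequence_alignment`).
#' @return a `rep_dist` tibble of per-record GC fractions.
#' @export
#' @examples
#' gc_content_distribution(c("GGCC", "ATAT"))
gc_content_distribution <- function(x, field = "sequence_alignment") {
  seqs <- degap(resolve_seqs(x, field))
  gc <- stringr::str_count(seqs, "[GC]")
  acgt <- stringr::str_count(seqs, "[ACGT]")
  keep <- acgt > 0
  if (!any(keep)) abort("no sequences with unambiguous bases")
  new_rep_dist(gc[keep] / acgt[keep], "gc_content", sum(keep))
}

#' Pairwise distance distribution
#'
#' The multiset of string distances `d(s_i, s_j)` over all unordered pairs
#' `i < j`, of size `n (n - 1) / 2`.
#'
#' @inheritParams gc_content_distribution
#' @param metric `"levenshtein"` (default) or `"hamming"`.
#' @export
#' @examples
#' pairwise_distance_distribution(c("AAAA", "AAAT"))
pairwise_distance_distribution <- function(x, field = "sequence_alignment",
                                           metric = "levenshtein") {
  seqs <- degap(resolve_seqs(x, field))
  if (length(seqs) < 2) abort("need at least 2 sequences for pairwise distances")
  d <- pairwise_string_distances(seqs, metric)
  new_rep_dist(d, paste0("pairwise_distance_", field), length(seqs))
}

#' k-th nearest-neighbor distance distribution
#'
#' For each sequence, the k-th smallest distance to the other members of the
#' repertoire (multiset semantics: only the sequence's own position is
#' excluded, so duplicated sequences have nearest-neighbor distance 0).
#'
#' @inheritParams pairwise_distance_distribution
#' @param k which order statistic (default 1, the nearest neighbor).
#' @export
#' @examples
#' nearest_neighbor_distribution(c("AAAA", "AAAT", "TTTT"))
nearest_neighbor_distribution <- function(x, field = "sequence_alignment",
                                          k = 1, metric = "levenshtein") {
  seqs <- degap(resolve_seqs(x, field))
  if (length(seqs) <= k)
    abort(sprintf("need more than k = %d sequences, got %d", k, length(seqs)))
  d <- kth_nn_distances(seqs, k = k, metric = metric)
  new_rep_dist(d, "nearest_neighbor_distance", length(seqs))
}

# --- IUPAC motif counting ---------------------------------------------------

iupac_ok <- function(motifs) {
  ok <- grepl("^[ACGTUWSMKRYBDHVN]+$", motifs)
  if (!all(ok))
    abort(paste0("invalid IUPAC character in motif(s): ",
                 paste(motifs[!ok], collapse = ", ")))
  motifs
}

#' Default somatic-hypermutation hotspot and coldspot motifs
#'
#' The canonical AID targeting motifs: hotspots WRC, GYW, WA, TW and
#' coldspots SYC, GRS (IUPAC codes W = A/T, R = A/G, S = G/C, Y = C/T).
#'
#' @return character vector of IUPAC motifs.
#' @export
hotspot_motifs <- function() c("WRC", "GYW", "WA", "TW")

#' @rdname hotspot_motifs
#' @export
coldspot_motifs <- function() c("SYC", "GRS")

#' Motif count distribution
#'
#' One value per record: the total number of (possibly overlapping) matches
#' of any of the given IUPAC motifs in the degapped sequence.  Matching is
#' on the given strand; an ambiguous N in a read matches nothing.
#'
#' @inheritParams gc_content_distribution
#' @param motifs non-empty character vector of IUPAC patterns.
#' @export
#' @examples
#' motif_count_distribution(c("TACTAC"), motifs = "WRC")
motif_count_distribution <- function(x, motifs = hotspot_motifs(),
                                     field = "sequence_alignment") {
  if (length(motifs) == 0) abort("motif list must be non-empty")
  motifs <- iupac_ok(toupper(motifs))
  seqs <- degap(resolve_seqs(x, field))
  if (length(seqs) == 0) abort("no usable sequences")
  subj <- Biostrings::DNAStringSet(seqs)
  counts <- rep(0L, length(seqs))
  for (m in motifs) {
    counts <- counts + Biostrings::vcountPattern(
      Biostrings::DNAString(m), subj,
      fixed = c(pattern = FALSE, subject = TRUE))
  }
  new_rep_dist(counts, "motif_count", length(seqs))
}

#' CDR3 length distribution
#'
#' One length per record with a non-missing junction; summaries labeled CDR3
#' operate on the AIRR `junction`/`junction_aa` fields as provided (the
#' junction includes the conserved anchor residues).
#'
#' @param x repertoire data frame.
#' @param unit `"nt"` (junction) or `"aa"` (junction_aa).
#' @export
cdr3_length_distribution <- function(x, unit = c("nt", "aa")) {
  unit <- arg_match(unit)
  field <- if (unit == "nt") "junction" else "junction_aa"
  seqs <- resolve_seqs(x, field)
  if (length(seqs) == 0) abort(sprintf("no non-missing %s values", field))
  new_rep_dist(nchar(seqs), paste0("cdr3_length_", unit), length(seqs))
}

#' Amino-acid k-mer counts
#'
#' Counts of all overlapping length-k windows of `junction_aa`, pooled over
#' records.  The total count equals the sum over records of
#' `max(len - k + 1, 0)`.
#'
#' @param x repertoire data frame (or character vector of peptides).
#' @param k window length (default 2).
#' @param field column holding the peptides.
#' @return a `rep_counts` tibble (category, count).
#' @export
#' @examples
#' aa_kmer_counts(c("CAR"), k = 2)
aa_kmer_counts <- function(x, k = 2, field = "junction_aa") {
  if (k < 1) abort("k must be >= 1")
  seqs <- resolve_seqs(x, field)
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    stringr::str_sub(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  }))
  tab <- table(kmers)
  new_rep_counts(setNames(as.numeric(tab), names(tab)),
                 paste0("aa_", k, "mer_counts"))
}
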