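# Central registry of supported summaries: the capability level each one
# assumes, its output kind (which decides the divergence used to compare two
# repertoires), whether it is a sequence-level covariate for the
# informativeness ranking, and how to compute it.
#
# kind: "dist"    -> scalar summary distribution, compared by JSD
#       "counts"  -> categorical counts, compared by normalized l1
#       "matrix"  -> row-stochastic transition matrix, l1 over the 16 cells
#       "profile" -> named numeric vector (rates, Hill numbers), raw l1
#       "scalar"  -> single number, absolute difference

summary_registry <- function() {
  entry <- function(name, kind, level, seq_level, fun, row_fun = NULL,
                    factor_scale = FALSE) {
    tibble(name = name, kind = kind, level = level,
           sequence_level = seq_level, factor_scale = factor_scale,
           fun = list(fun), row_fun = list(row_fun))
  }
  aa_prop_entry <- function(prop, factor_scale = FALSE) {
    entry(prop, "dist", "annotated", TRUE,
          function(tbl, ...) aa_property_distribution(tbl, prop),
          row_fun = function(tbl) row_aa_property(tbl, prop),
          factor_scale = factor_scale)
  }
  len_entry <- function(field) {
    entry(field, "dist", "annotated", TRUE,
          function(tbl, ...) rearrangement_length_distribution(tbl, field),
          row_fun = function(tbl) row_length_field(tbl, field))
  }
  rows <- list(
    # --- alignment-only group ---
    entry("gc_content", "dist", "alignment_only", TRUE,
          function(tbl, ...) gc_content_distribution(tbl),
          row_fun = row_gc_content),
    entry("pairwise_distance", "dist", "alignment_only", FALSE,
          function(tbl, ...) pairwise_distance_distribution(tbl)),
    entry("nearest_neighbor_distance", "dist", "alignment_only", FALSE,
          function(tbl, ...) nearest_neighbor_distribution(tbl)),
    entry("hotspot_count", "dist", "alignment_only", TRUE,
          function(tbl, ...) motif_count_distribution(tbl, hotspot_motifs()),
          row_fun = function(tbl) row_motif_count(tbl, hotspot_motifs())),
    entry("coldspot_count", "dist", "alignment_only", TRUE,
          function(tbl, ...) motif_count_distribution(tbl, coldspot_motifs()),
          row_fun = function(tbl) row_motif_count(tbl, coldspot_motifs())),
    # --- annotated group ---
    entry("cdr3_length", "dist", "annotated", TRUE,
          function(tbl, ...) cdr3_length_distribution(tbl, "nt"),
          row_fun = function(tbl) as.numeric(nchar(tbl$junction))),
    entry("cdr3_pairwise_distance", "dist", "annotated", FALSE,
          function(tbl, ...) pairwise_distance_distribution(tbl, field = "junction")),
    entry("v_gene_usage", "counts", "annotated", FALSE,
          function(tbl, ...) gene_usage_counts(tbl, "v")),
    entry("d_gene_usage", "counts", "annotated", FALSE,
          function(tbl, ...) gene_usage_counts(tbl, "d")),
    entry("j_gene_usage", "counts", "annotated", FALSE,
          function(tbl, ...) gene_usage_counts(tbl, "j")),
    entry("vdj_gene_usage", "counts", "annotated", FALSE,
          function(tbl, ...) gene_usage_counts(tbl, c("v", "d", "j"))),
    entry("aa_frequencies", "counts", "annotated", FALSE,
          function(tbl, ...) aa_kmer_counts(tbl, k = 1)),
    entry("aa_2mer_frequencies", "counts", "annotated", FALSE,
          function(tbl, ...) aa_kmer_counts(tbl, k = 2)),
    aa_prop_entry("gravy"),
    aa_prop_entry("polarity"),
    aa_prop_entry("bulkiness"),
    aa_prop_entry("basicity"),
    aa_prop_entry("acidity"),
    aa_prop_entry("aromaticity"),
    aa_prop_entry("charge"),
    aa_prop_entry("aliphatic"),
    len_entry("v_3p_deletion"),
    len_entry("v_5p_deletion"),
    len_entry("d_3p_deletion"),
    len_entry("d_5p_deletion"),
    len_entry("j_3p_deletion"),
    len_entry("j_5p_deletion"),
    len_entry("np1_length"),
    len_entry("np2_length"),
    entry("np1_transition_matrix", "matrix", "annotated", FALSE,
          function(tbl, ...) insertion_transition_matrix(tbl, "np1")),
    entry("np2_transition_matrix", "matrix", "annotated", FALSE,
          function(tbl, ...) insertion_transition_matrix(tbl, "np2")),
    entry("germline_distance", "dist", "annotated", TRUE,
          function(tbl, ...) germline_distance_distribution(tbl),
          row_fun = row_germline_distance),
    entry("positional_mutation_distances", "dist", "annotated", FALSE,
          function(tbl, ...) positional_mutation_distances(tbl)),
    entry("per_gene_substitution_rates", "profile", "annotated", FALSE,
          function(tbl, ...) {
            r <- per_gene_substitution_rates(tbl)
            setNames(r$rate, r$gene)
          }),
    entry("in_frame_percentage", "scalar", "annotated", FALSE,
          function(tbl, ...) in_frame_percentage(tbl)),
    # --- clustered group ---
    entry("cluster_size", "dist", "clustered", FALSE,
          function(tbl, ...) cluster_size_distribution(tbl)),
    entry("hill_numbers", "profile", "clustered", FALSE,
          function(tbl, ...) {
            q <- c(0, 1, 2, 3, 4)
            setNames(vapply(q, function(qq) hill_diversity(tbl, qq), numeric(1)),
                     paste0("q", q))
          }),
    # --- phylogenetic group ---
    entry("sackin_index", "dist", "phylogenetic", FALSE,
          function(tbl, trees = NULL, ...) tree_shape_indices(trees, "sackin")),
    entry("colless_like_index", "dist", "phylogenetic", FALSE,
          function(tbl, trees = NULL, ...) tree_shape_indices(trees, "colless_like")),
    entry("cophenetic_index", "dist", "phylogenetic", FALSE,
          function(tbl, trees = NULL, ...) tree_shape_indices(trees, "cophenetic"))
  )
  for (f in 1:5) rows <- c(rows, list(aa_prop_entry(paste0("atchley_f", f), factor_scale = TRUE)))
  for (f in 1:10) rows <- c(rows, list(aa_prop_entry(paste0("kidera_f", f), factor_scale = TRUE)))
  bind_rows(rows)
}

# per-row covariate extractors (length nrow(tbl), NA where unusable) --------

row_gc_content <- function(tbl) {
  s <- degap(tbl$sequence_alignment)
  gc <- stringr::str_count(s, "[GC]")
  acgt <- stringr::str_count(s, "[ACGT]")
  ifelse(!is.na(s) & acgt > 0, gc / acgt, NA_real_)
}

row_motif_count <- function(tbl, motifs) {
  out <- rep(NA_real_, nrow(tbl))
  ok <- !is.na(tbl$sequence_alignment)
  if (any(ok))
    out[ok] <- dist_values(motif_count_distribution(tbl$sequence_alignment[ok],
                                                    motifs = motifs))
  out
}

row_aa_property <- function(tbl, prop) {
  out <- rep(NA_real_, nrow(tbl))
  ok <- !is.na(tbl$junction_aa) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", tbl$junction_aa)
  if (any(ok))
    out[ok] <- dist_values(aa_property_distribution(tbl$junction_aa[ok], prop))
  out
}

row_length_field <- function(tbl, field) {
  if (field %in% names(tbl)) return(as.numeric(tbl[[field]]))
  src <- sub("_length$", "", field)
  if (field %in% c("np1_length", "np2_length") && src %in% names(tbl))
    return(as.numeric(nchar(tbl[[src]])))
  rep(NA_real_, nrow(tbl))
}

row_germline_distance <- function(tbl) {
  out <- rep(NA_real_, nrow(tbl))
  ok <- !is.na(tbl$sequence_alignment) & !is.na(tbl$germline_alignment)
  if (any(ok))
    out[ok] <- dist_values(germline_distance_distribution(tbl[ok, , drop = FALSE]))
  out
}

#' List supported summaries
#'
#' @return a tibble with one row per summary: its name, output kind, the
#'   post-processing level it assumes, and whether it is a sequence-level
#'   covariate usable in [rank_summaries()].
#' @export
list_summaries <- function() {
  summary_registry() %>% select(name, kind, level, sequence_level, factor_scale)
}

#' Compute one named summary on a repertoire
#'
#' Dispatches to the summary's implementation; see [list_summaries()] for
#' the available names.
#'
#' @param tbl repertoire data frame.
#' @param name summary name.
#' @param trees optional `clone_trees` list, required by the phylogenetic
#'   summaries.
#' @return the summary's native output (`rep_dist`, `rep_counts`,
#'   `rep_transitions`, named vector, or scalar).
#' @export
compute_summary <- function(tbl, name, trees = NULL) {
  reg <- summary_registry()
  i <- match(name, reg$name)
  if (is.na(i)) abort(paste0("unknown summary: ", name))
  reg$fun[[i]](tbl, trees = trees)
}
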