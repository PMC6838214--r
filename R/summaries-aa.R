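# Physicochemical summaries of the CDR3 amino-acid sequence.

#' Amino-acid property distribution
#'
#' One value per usable record of `junction_aa`.  Records containing
#' anything other than the 20 standard letters (X, stop `*`, gaps) are
#' skipped.  Aggregation follows the property's rule:
#' * mean of per-residue weights for `gravy`, `polarity`, `bulkiness`,
#'   `basicity`, `acidity`, `aromaticity` and each `atchley_f*` /
#'   `kidera_f*` factor (see [aa_property_scales]);
#' * Ikai's mole-percent formula for `aliphatic` ([aliphatic_index()]);
#' * Henderson--Hasselbalch net charge at pH 7.4 for `charge`
#'   ([peptide_charge()]).
#'
#' @param x repertoire data frame (or character vector of peptides).
#' @param property a property name (see Details) or a named numeric vector of
#'   per-residue weights covering the 20 standard amino acids.
#' @param field column holding the peptides.
#' @return a `rep_dist` tibble.
#' @export
#' @examples
#' aa_property_distribution(c("A"), "gravy")  # Kyte-Doolittle Ala = 1.8
aa_property_distribution <- function(x, property, field = "junction_aa") {
  seqs <- resolve_seqs(x, field)
  usable <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
  seqs <- seqs[usable]
  if (length(seqs) == 0) abort("no usable amino-acid sequences")
  if (is.numeric(property)) {
    missing_aa <- setdiff(names(aa_property_scales$gravy), names(property))
    if (length(missing_aa) > 0)
      abort(paste0("property weights missing amino acids: ",
                   paste(missing_aa, collapse = ", ")))
    vals <- mean_of_weights(seqs, property)
    return(new_rep_dist(vals, "aa_property", length(seqs)))
  }
  property <- arg_match0(property, c(names(aa_property_scales),
                                     "aliphatic", "charge"))
  vals <- switch(property,
    aliphatic = aliphatic_index(seqs),
    charge = peptide_charge(seqs),
    mean_of_weights(seqs, aa_property_scales[[property]])
  )
  new_rep_dist(vals, property, length(seqs))
}

mean_of_weights <- function(seqs, weights) {
  vapply(seqs, function(s) {
    mean(weights[strsplit(s, "")[[1]]])
  }, numeric(1), USE.NAMES = FALSE)
}
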