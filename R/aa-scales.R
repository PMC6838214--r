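#' Per-residue amino-acid property scales
#'
#' Named constant tables used by [aa_property_distribution()].  Each scale is
#' a numeric vector indexed by the 20 standard one-letter amino-acid codes.
#'
#' Sources:
#' * `gravy` — Kyte & Doolittle (1982) hydropathy.
#' * `polarity` — Grantham (1974) polarity.
#' * `bulkiness` — Zimmerman, Eliezer & Simha (1968).
#' * `basicity` — indicator weights for the basic residues R, K, H; the
#'   per-sequence mean is the basic-residue fraction.
#' * `acidity` — indicator weights for the acidic residues D, E.
#' * `aromaticity` — indicator weights for F, W, Y; the mean is the aromatic
#'   fraction (Lobry & Gautier 1994).
#' * `atchley_f1` … `atchley_f5` — Atchley et al. (2005) factor solution.
#' * `kidera_f1` … `kidera_f10` — Kidera et al. (1985) factors.
#'
#' The aliphatic index and net charge are not mean-of-weights scales; they are
#' computed by dedicated rules (Ikai 1980 formula; Henderson--Hasselbalch at
#' pH 7.4 with the EMBOSS pKa set) inside [aa_property_distribution()].
#'
#' @format A named list of named numeric vectors (one value per standard
#'   amino acid).
#' @export
aa_property_scales <- local({
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  sc <- function(x) setNames(x, aa)
  atchley <- matrix(c(
    # f1      f2      f3      f4      f5
    -0.591, -1.302, -0.733,  1.570, -0.146,  # A
     1.538, -0.055,  1.502,  0.440,  2.897,  # R
     0.945,  0.828,  1.299, -0.169,  0.933,  # N
     1.050,  0.302, -3.656, -0.259, -3.242,  # D
    -1.343,  0.465, -0.862, -1.020, -0.255,  # C
     0.931, -0.179, -3.005, -0.503, -1.853,  # Q
     1.357, -1.453,  1.477,  0.113, -0.837,  # E
    -0.384,  1.652,  1.330,  1.045,  2.064,  # G
     0.336, -0.417, -1.673, -1.474, -0.078,  # H
    -1.239, -0.547,  2.131,  0.393,  0.816,  # I
    -1.019, -0.987, -1.505,  1.266, -0.912,  # L
     1.831, -0.561,  0.533, -0.277,  1.648,  # K
    -0.663, -1.524,  2.219, -1.005,  1.212,  # M
    -1.006, -0.590,  1.891, -0.397,  0.412,  # F
     0.189,  2.081, -1.628,  0.421, -1.392,  # P
    -0.228,  1.399, -4.760,  0.670, -2.647,  # S
    -0.032,  0.326,  2.213,  0.908,  1.313,  # T
    -0.595,  0.009,  0.672, -2.128, -0.184,  # W
     0.260,  0.830,  3.097, -0.838,  1.512,  # Y
    -1.337, -0.279, -0.544,  1.242, -1.262   # V
  ), nrow = 20, byrow = TRUE, dimnames = list(aa, NULL))
  kidera <- matrix(c(
    -1.56,-1.67,-0.97,-0.27,-0.93,-0.78,-0.20,-0.08, 0.21,-0.48,  # A
     0.22, 1.27, 1.37, 1.87,-1.70, 0.46, 0.92,-0.39, 0.23, 0.93,  # R
     1.14,-0.07,-0.12, 0.81, 0.18, 0.37,-0.09, 1.23, 1.10,-1.73,  # N
     0.58,-0.22,-1.58, 0.81,-0.92, 0.15,-1.52, 0.47, 0.76, 0.70,  # D
     0.12,-0.89, 0.45,-1.05,-0.71, 2.41, 1.52,-0.69, 1.13, 1.10,  # C
    -0.47, 0.24, 0.07, 1.10, 1.10, 0.59, 0.84,-0.71,-0.03,-2.33,  # Q
    -1.45, 0.19,-1.61, 1.17,-1.31, 0.40, 0.04, 0.38,-0.35,-0.12,  # E
     1.46,-1.96,-0.23,-0.16, 0.10,-0.11, 1.32, 2.36,-1.66, 0.46,  # G
    -0.41, 0.52,-0.28, 0.28, 1.61, 1.01,-1.85, 0.47, 1.13, 1.63,  # H
    -0.73,-0.16, 1.79,-0.77,-0.54, 0.03,-0.83, 0.51, 0.66,-1.78,  # I
    -1.04, 0.00,-0.24,-1.10,-0.55,-2.05, 0.96,-0.76, 0.45, 0.93,  # L
    -0.34, 0.82,-0.23, 1.70, 1.54,-1.62, 1.15,-0.08,-0.48, 0.60,  # K
    -1.40, 0.18,-0.42,-0.73, 2.00, 1.52, 0.26, 0.11,-1.27, 0.27,  # M
    -0.21, 0.98,-0.36,-1.43, 0.22,-0.81, 0.67, 1.10, 1.71,-0.44,  # F
     2.06,-0.33,-1.15,-0.75, 0.88,-0.45, 0.30,-2.30, 0.74,-0.28,  # P
     0.81,-1.08, 0.16, 0.42,-0.21,-0.43,-1.89,-1.15,-0.97,-0.23,  # S
     0.26,-0.70, 1.21, 0.63,-0.10, 0.21, 0.24,-1.15,-0.56, 0.19,  # T
     0.30, 2.10,-0.72,-1.57,-1.16, 0.57,-0.48,-0.40,-2.30,-0.60,  # W
     1.38, 1.48, 0.80,-0.56, 0.00,-0.68,-0.31, 1.03,-0.05, 0.53,  # Y
    -0.74,-0.71, 2.04,-0.40, 0.50,-0.81,-1.07, 0.06,-0.46, 0.65   # V
  ), nrow = 20, byrow = TRUE, dimnames = list(aa, NULL))
  out <- list(
    gravy = sc(c( 1.8,-4.5,-3.5,-3.5, 2.5,-3.5,-3.5,-0.4,-3.2, 4.5,
                  3.8,-3.9, 1.9, 2.8,-1.6,-0.8,-0.7,-0.9,-1.3, 4.2)),
    polarity = sc(c( 8.1,10.5,11.6,13.0, 5.5,10.5,12.3, 9.0,10.4, 5.2,
                     4.9,11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9)),
    bulkiness = sc(c(11.50,14.28,12.82,11.68,13.46,14.45,13.57, 3.40,13.69,21.40,
                     21.40,15.71,16.25,19.80,17.43, 9.47,15.77,21.67,18.03,21.57)),
    basicity = sc(as.numeric(aa %in% c("R","K","H"))),
    acidity = sc(as.numeric(aa %in% c("D","E"))),
    aromaticity = sc(as.numeric(aa %in% c("F","W","Y")))
  )
  for (f in 1:5)  out[[paste0("atchley_f", f)]] <- setNames(atchley[, f], aa)
  for (f in 1:10) out[[paste0("kidera_f", f)]]  <- setNames(kidera[, f], aa)
  out
})

# EMBOSS pKa values for ionizable groups, used by the net-charge rule.
emboss_pka <- c(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

#' Net charge of a peptide at a given pH
#'
#' Henderson--Hasselbalch net charge using the EMBOSS pKa set, summing the
#' fractional positive charge of the basic groups (N-terminus, R, K, H) and
#' the fractional negative charge of the acidic groups (C-terminus, D, E, C,
#' Y).
#'
#' @param seq character vector of amino-acid sequences (standard 20 letters).
#' @param pH numeric, defaults to physiological 7.4.
#' @param termini include the terminal amine/carboxyl groups (default TRUE).
#' @return numeric vector of net charges.
#' @export
#' @examples
#' peptide_charge(c("K", "D"))
peptide_charge <- function(seq, pH = 7.4, termini = TRUE) {
  pos_frac <- function(pka) 1 / (1 + 10^(pH - pka))
  neg_frac <- function(pka) -1 / (1 + 10^(pka - pH))
  vapply(seq, function(s) {
    letters1 <- strsplit(s, "")[[1]]
    tab <- table(factor(letters1, levels = names(aa_property_scales$gravy)))
    z <- tab[["R"]] * pos_frac(emboss_pka[["R"]]) +
      tab[["K"]] * pos_frac(emboss_pka[["K"]]) +
      tab[["H"]] * pos_frac(emboss_pka[["H"]]) +
      tab[["D"]] * neg_frac(emboss_pka[["D"]]) +
      tab[["E"]] * neg_frac(emboss_pka[["E"]]) +
      tab[["C"]] * neg_frac(emboss_pka[["C"]]) +
      tab[["Y"]] * neg_frac(emboss_pka[["Y"]])
    if (termini)
      z <- z + pos_frac(emboss_pka[["Nterm"]]) + neg_frac(emboss_pka[["Cterm"]])
    z
  }, numeric(1), USE.NAMES = FALSE)
}

#' Aliphatic index of a peptide
#'
#' Ikai (1980) aliphatic index in mole-percent form:
#' `AI = X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu)` where `X` are mole
#' percentages of each residue.
#'
#' @param seq character vector of amino-acid sequences.
#' @return numeric vector.
#' @export
aliphatic_index <- function(seq) {
  vapply(seq, function(s) {
    letters1 <- strsplit(s, "")[[1]]
    n <- length(letters1)
    x <- function(a) 100 * sum(letters1 == a) / n
    x("A") + 2.9 * x("V") + 3.9 * (x("I") + x("L"))
  }, numeric(1), USE.NAMES = FALSE)
}
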