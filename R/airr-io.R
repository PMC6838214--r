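# Reading, validating and writing AIRR Rearrangement tables, plus the
# capability ladder that decides which summaries a table supports.

# Recognized AIRR Rearrangement fields and their types.
airr_fields <- function() {
  tibble::tribble(
    ~field,               ~type,
    "sequence_id",        "character",
    "sequence_alignment", "character",
    "germline_alignment", "character",
    "junction",           "character",
    "junction_aa",        "character",
    "v_call",             "character",
    "d_call",             "character",
    "j_call",             "character",
    "v_3p_deletion",      "integer",
    "v_5p_deletion",      "integer",
    "d_3p_deletion",      "integer",
    "d_5p_deletion",      "integer",
    "j_3p_deletion",      "integer",
    "j_5p_deletion",      "integer",
    "np1",                "character",
    "np2",                "character",
    "np1_length",         "integer",
    "np2_length",         "integer",
    "clone_id",           "character",
    "productive",         "logical",
    "locus",              "character"
  )
}

airr_loci <- c("IGH", "IGK", "IGL", "TRA", "TRB", "TRD", "TRG")

#' Read an AIRR Rearrangement TSV
#'
#' Reads a tab-separated rearrangement table with a header row.  Recognized
#' AIRR fields are mapped by exact name and coerced to their schema types;
#' unrecognized columns are preserved untouched.  Empty strings become `NA`,
#' sequences are uppercased.
#'
#' @param path path to a TSV file.
#' @param locus expected locus code (one of IGH, IGK, IGL, TRA, TRB, TRD,
#'   TRG) or `NULL` to accept whatever the table declares.
#' @return a validated repertoire tibble.
#' @export
read_airr <- function(path, locus = NULL) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0 || !nzchar(header))
    abort(paste0("file has no header row: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE,
                         comment = "#")
  if (nrow(tbl) == 0) abort(paste0("file has a header but zero data rows: ", path))
  tbl <- coerce_airr_types(tbl)
  if (!is.null(locus)) {
    locus <- arg_match0(locus, airr_loci)
    if (!"locus" %in% names(tbl)) tbl$locus <- locus
    else if (!all(is.na(tbl$locus) | tbl$locus == locus))
      abort(sprintf("table locus does not match requested locus %s", locus))
  }
  validate_repertoire(tbl)
}

coerce_airr_types <- function(tbl) {
  spec <- airr_fields()
  for (i in seq_len(nrow(spec))) {
    f <- spec$field[i]
    if (!f %in% names(tbl)) next
    tbl[[f]] <- switch(spec$type[i],
      integer = as.integer(tbl[[f]]),
      logical = parse_airr_logical(tbl[[f]]),
      character = as.character(tbl[[f]])
    )
  }
  seq_cols <- intersect(c("sequence_alignment", "germline_alignment",
                          "junction", "np1", "np2"), names(tbl))
  for (f in seq_cols) tbl[[f]] <- toupper(tbl[[f]])
  if ("junction_aa" %in% names(tbl)) tbl$junction_aa <- toupper(tbl$junction_aa)
  tbl
}

parse_airr_logical <- function(x) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("t", "true", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("f", "false", "0", "no")] <- FALSE
  out
}

#' Validate a repertoire table
#'
#' Checks the schema invariants: deletion and insertion lengths are
#' nonnegative, `sequence_alignment`/`germline_alignment` have equal lengths
#' whenever both are present in a record, and `locus` is uniform.
#'
#' @param tbl a repertoire data frame.
#' @return the table, invisibly returned as a tibble, or an error.
#' @export
validate_repertoire <- function(tbl) {
  tbl <- as_tibble(tbl)
  len_cols <- intersect(c("v_3p_deletion", "v_5p_deletion", "d_3p_deletion",
                          "d_5p_deletion", "j_3p_deletion", "j_5p_deletion",
                          "np1_length", "np2_length"), names(tbl))
  for (f in len_cols) {
    bad <- !is.na(tbl[[f]]) & tbl[[f]] < 0
    if (any(bad))
      abort(sprintf("column %s has %d negative length value(s)", f, sum(bad)))
  }
  if (all(c("sequence_alignment", "germline_alignment") %in% names(tbl))) {
    both <- !is.na(tbl$sequence_alignment) & !is.na(tbl$germline_alignment)
    neq <- both & nchar(tbl$sequence_alignment) != nchar(tbl$germline_alignment)
    if (any(neq))
      abort(sprintf(
        "%d record(s) have sequence_alignment and germline_alignment of unequal length",
        sum(neq)))
  }
  if ("locus" %in% names(tbl)) {
    loc <- unique(tbl$locus[!is.na(tbl$locus)])
    if (length(loc) > 1)
      abort(paste0("locus is not uniform within the table: ",
                   paste(loc, collapse = ", ")))
  }
  invisible(tbl)
}

#' Write an AIRR Rearrangement TSV
#'
#' Round-trip companion to [read_airr()]: re-reading the written file
#' reproduces all recognized fields exactly.  Missing values are written as
#' empty strings.
#'
#' @param tbl a repertoire data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(tbl, path) {
  validate_repertoire(tbl)
  out <- as_tibble(tbl)
  if ("productive" %in% names(out))
    out$productive <- ifelse(is.na(out$productive), NA,
                             ifelse(out$productive, "T", "F"))
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Post-processing capability of a repertoire table
#'
#' Summaries assume increasing degrees of post-processing: aligned
#' sequences, then standard rearrangement annotations, then clonal-family
#' assignments, then per-clone phylogenies.  The capability of a table is the
#' highest level whose required columns are present and non-missing for at
#' least one record; each level implies all lower levels.
#'
#' @param tbl a repertoire data frame.
#' @param trees optional named list of per-clone trees (see
#'   [read_clone_trees()]); supplying one or more trees grants the
#'   `phylogenetic` level.
#' @return an ordered factor with levels
#'   `alignment_only < annotated < clustered < phylogenetic`.
#' @export
airr_capability <- function(tbl, trees = NULL) {
  levels <- c("alignment_only", "annotated", "clustered", "phylogenetic")
  has <- function(cols) {
    all(cols %in% names(tbl)) &&
      all(vapply(cols, function(f) any(!is.na(tbl[[f]])), logical(1)))
  }
  lvl <- "alignment_only"
  if (has(c("v_call", "j_call")) || has("junction") ||
      has(c("np1")) || has(c("v_3p_deletion"))) {
    # annotated needs the standard annotation block: gene calls or junction
    if (has(c("v_call", "j_call"))) lvl <- "annotated"
  }
  if (lvl == "annotated" && has("clone_id")) lvl <- "clustered"
  if (lvl == "clustered" && !is.null(trees) && length(trees) > 0)
    lvl <- "phylogenetic"
  factor(lvl, levels = levels, ordered = TRUE)
}

#' Normalize gene calls
#'
#' When a call is a comma-separated list, only the first entry is kept; the
#' `*NN` allele suffix is stripped so that usage is counted at the gene level
#' (comparable across annotation tools).
#'
#' @param calls character vector of gene calls.
#' @param collapse_alleles strip the allele suffix (default TRUE).
#' @return character vector of normalized gene names.
#' @export
#' @examples
#' normalize_gene_calls("IGHV1-2*02,IGHV1-2*04")
normalize_gene_calls <- function(calls, collapse_alleles = TRUE) {
  first <- stringr::str_split_i(calls, stringr::fixed(","), 1)
  first <- stringr::str_trim(first)
  if (collapse_alleles) first <- stringr::str_remove(first, "\\*[0-9A-Za-z]+$")
  first
}

#' Read per-clone Newick trees
#'
#' Accepts either a two-column tab-separated file (`clone_id`, `newick`) or a
#' directory of `<clone_id>.nwk` files, and returns a named list of `phylo`
#' objects parsed with \pkg{ape}.
#'
#' @param path file or directory path.
#' @return named list of `phylo` trees (class `clone_trees`).
#' @export
read_clone_trees <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.nwk$", full.names = TRUE)
    if (length(files) == 0) abort(paste0("no .nwk files in ", path))
    trees <- lapply(files, ape::read.tree)
    names(trees) <- sub("\\.nwk$", "", basename(files))
  } else {
    if (!file.exists(path)) abort(paste0("file does not exist: ", path))
    tbl <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
    if (!all(c("clone_id", "newick") %in% names(tbl)))
      abort("tree table must have columns clone_id and newick")
    trees <- lapply(tbl$newick, function(s) ape::read.tree(text = s))
    names(trees) <- tbl$clone_id
  }
  structure(trees, class = c("clone_trees", "list"))
}

# --- gap handling -----------------------------------------------------------

# strip IMGT gap characters from a single set of sequences
degap <- function(x) stringr::str_remove_all(x, "[.\\-]")

# pairwise-consistent degapping: positions gapped in either sequence are
# dropped from both, preserving positional correspondence
degap_pair <- function(a, b) {
  sa <- strsplit(a, "")
  sb <- strsplit(b, "")
  out_a <- character(length(a))
  out_b <- character(length(a))
  for (i in seq_along(a)) {
    va <- sa[[i]]; vb <- sb[[i]]
    keep <- !(va %in% c(".", "-")) & !(vb %in% c(".", "-"))
    out_a[i] <- paste(va[keep], collapse = "")
    out_b[i] <- paste(vb[keep], collapse = "")
  }
  list(a = out_a, b = out_b)
}
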