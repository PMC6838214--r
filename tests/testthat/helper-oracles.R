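# Independent naive re-implementations used as oracles.  These deliberately
# avoid the package's code paths: distances come from utils::adist, counting
# is done with plain loops, and the JSD oracle bins with cut().

o_lev <- function(a, b) as.integer(utils::adist(a, b))

o_degap <- function(s) gsub("[.\\-]", "", s)

o_degap_pair <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  keep <- !(va %in% c(".", "-")) & !(vb %in% c(".", "-"))
  c(paste(va[keep], collapse = ""), paste(vb[keep], collapse = ""))
}

o_gc <- function(seqs) {
  out <- numeric(0)
  for (s in o_degap(seqs)) {
    v <- strsplit(s, "")[[1]]
    denom <- sum(v %in% c("A", "C", "G", "T"))
    if (denom == 0) next
    out <- c(out, sum(v %in% c("G", "C")) / denom)
  }
  out
}

o_pairwise <- function(seqs) {
  seqs <- o_degap(seqs)
  n <- length(seqs)
  out <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) out <- c(out, o_lev(seqs[i], seqs[j]))
  out
}

o_kth_nn <- function(seqs, k = 1) {
  seqs <- o_degap(seqs)
  n <- length(seqs)
  vapply(seq_len(n), function(i) {
    d <- vapply(setdiff(seq_len(n), i), function(j) o_lev(seqs[i], seqs[j]), integer(1))
    sort(d)[k]
  }, integer(1))
}

iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           W = "[AT]", S = "[GC]", M = "[AC]", K = "[GT]", R = "[AG]",
           Y = "[CT]", B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
           N = "[ACGT]")
  paste(map[strsplit(motif, "")[[1]]], collapse = "")
}

# total over motifs of per-motif overlapping match counts (a window matching
# two motifs counts once per motif)
o_motif_count <- function(seqs, motifs) {
  seqs <- o_degap(seqs)
  vapply(seqs, function(s) {
    total <- 0L
    for (mo in motifs) {
      m <- gregexpr(paste0("(?=", iupac_regex(mo), ")"), s, perl = TRUE)[[1]]
      total <- total + sum(m > 0)
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

o_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) out <- c(out, substr(s, i, i + k - 1))
  }
  tab <- table(out)
  setNames(as.numeric(tab), names(tab))
}

o_first_gene <- function(calls) {
  first <- vapply(strsplit(calls, ","), `[`, character(1), 1)
  sub("\\*[0-9A-Za-z]+$", "", trimws(first))
}

o_usage <- function(tbl, axes) {
  cols <- paste0(axes, "_call")
  keys <- apply(do.call(cbind, lapply(cols, function(f) o_first_gene(tbl[[f]]))),
                1, paste, collapse = "|")
  keys <- keys[!grepl("NA", keys, fixed = TRUE)]
  tab <- table(keys)
  setNames(as.numeric(tab), names(tab))
}

o_transitions <- function(seqs) {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (s in seqs[!is.na(seqs) & nchar(seqs) >= 2]) {
    v <- strsplit(s, "")[[1]]
    for (i in seq_len(length(v) - 1)) {
      if (v[i] %in% bases && v[i + 1] %in% bases)
        counts[v[i], v[i + 1]] <- counts[v[i], v[i + 1]] + 1
    }
  }
  counts
}

o_germline_dist <- function(tbl) {
  out <- integer(0)
  for (i in seq_len(nrow(tbl))) {
    if (is.na(tbl$sequence_alignment[i]) || is.na(tbl$germline_alignment[i])) next
    p <- o_degap_pair(tbl$germline_alignment[i], tbl$sequence_alignment[i])
    out <- c(out, o_lev(p[1], p[2]))
  }
  out
}

o_mutation_gaps <- function(tbl) {
  out <- integer(0)
  for (i in seq_len(nrow(tbl))) {
    if (is.na(tbl$sequence_alignment[i]) || is.na(tbl$germline_alignment[i])) next
    p <- o_degap_pair(tbl$germline_alignment[i], tbl$sequence_alignment[i])
    g <- strsplit(p[1], "")[[1]]
    s <- strsplit(p[2], "")[[1]]
    n <- min(length(g), length(s))
    pos <- integer(0)
    for (j in seq_len(n)) {
      if (g[j] %in% c("A","C","G","T") && s[j] %in% c("A","C","G","T") && g[j] != s[j])
        pos <- c(pos, j)
    }
    if (length(pos) >= 2) out <- c(out, diff(pos))
  }
  out
}

o_aa_mean <- function(seqs, weights) {
  vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    mean(vapply(v, function(a) weights[[a]], numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

o_hill <- function(counts, q) {
  p <- counts[counts > 0] / sum(counts[counts > 0])
  if (q == 0) length(p)
  else if (q == 1) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

# independent JSD: same binning contract, but implemented with cut()
o_jsd <- function(x, y) {
  B <- max(min(length(unique(x)), length(unique(y))), 2)
  lo <- min(c(x, y)); hi <- max(c(x, y))
  if (lo == hi) return(0)
  br <- seq(lo, hi, length.out = B + 1)
  bx <- cut(x, breaks = br, include.lowest = TRUE, right = FALSE)
  # cut(right=FALSE) makes the last bin open at hi; close it manually
  bx[x == hi] <- levels(bx)[B]
  by <- cut(y, breaks = br, include.lowest = TRUE, right = FALSE)
  by[y == hi] <- levels(by)[B]
  p <- as.numeric(table(bx)) / length(x)
  q <- as.numeric(table(by)) / length(y)
  keep <- (p > 0) == (q > 0) & (p > 0 | q > 0)
  p <- p[keep]; q <- q[keep]
  if (length(p) == 0) return(log(2))
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a) sum(ifelse(a > 0, a * log(a / m), 0))
  (kl(p) + kl(q)) / 2
}

# rep_counts -> named numeric vector sorted by category key, for comparison
# with the oracle count vectors
counts_sorted <- function(x) {
  key_cols <- setdiff(names(x), "count")
  keys <- do.call(paste, c(x[key_cols], sep = "|"))
  v <- setNames(as.numeric(x$count), keys)
  v[order(names(v))]
}

# a small handcrafted table exercising gaps, Ns, allele lists and clones
fixture_table <- function() {
  tibble::tibble(
    sequence_id = paste0("f", 1:6),
    sequence_alignment = c("ATGGCCAAT", "AT.GCCAAT", "ATGGCCTAT",
                           "GANTGGCCA", "ATGGCCAAT", "TTGGCCAAA"),
    germline_alignment = c("ATGGCCAAT", "ATGG.CAAT", "ATGGCCAAT",
                           "GAATGGCCA", "ATGGCCAAT", "ATGGCCAAA"),
    junction            = c("TGTGCGAAA", "TGTGCGAAA", "TGTAAA",
                            "TGTGCGTGGAAA", "TGTGCGAAA", "TGTGCGAA"),
    junction_aa         = c("CAK", "CAK", "CK", "CAWK", "CAK", NA),
    v_call = c("IGHV1-2*02,IGHV1-2*04", "IGHV1-2*02", "IGHV3-23*01",
               "IGHV1-2*02", "IGHV3-23*01", "IGHV1-2*02"),
    d_call = c("IGHD3-10*01", "IGHD3-10*01", "IGHD2-2*01",
               "IGHD3-10*01", "IGHD2-2*01", "IGHD3-10*01"),
    j_call = c("IGHJ4*02", "IGHJ4*02", "IGHJ6*01",
               "IGHJ4*02", "IGHJ6*01", "IGHJ4*02"),
    v_3p_deletion = c(0L, 2L, 2L, 1L, 0L, 3L),
    v_5p_deletion = 0L,
    d_3p_deletion = c(1L, 0L, 2L, 0L, 1L, 0L),
    d_5p_deletion = c(0L, 1L, 0L, 2L, 0L, 1L),
    j_3p_deletion = 0L,
    j_5p_deletion = c(2L, 2L, 0L, 1L, 1L, 0L),
    np1 = c("AAG", "", "GC", "TACT", "A", "CGCG"),
    np2 = c("", "T", "GG", "A", "", "TT"),
    np1_length = c(3L, 0L, 2L, 4L, 1L, 4L),
    np2_length = c(0L, 1L, 2L, 1L, 0L, 2L),
    clone_id = c("1", "1", "2", "3", "2", "3"),
    productive = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    locus = "IGH"
  )
}
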