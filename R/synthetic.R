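# Synthetic AIRR-schema repertoire generator with a fully specified
# generative model, so every summary can be tested against known ground
# truth without any external download.

draw_lengths <- function(dist, n) {
  if (!is.null(dist$fixed)) return(rep(as.integer(dist$fixed), n))
  pmin(rgeom(n, dist$p), dist$cap)
}

check_prob_vec <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    abort(paste0(what, " must be a probability vector summing to 1"))
  p
}

random_germline <- function(n, len, prefix) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  tibble(name = paste0(prefix, seq_len(n)), seq = seqs)
}

#' Specify a synthetic repertoire generative model
#'
#' The model draws, per clonal family: a (V, D, J) gene triple from the
#' usage probabilities, exonucleolytic deletion lengths per end (geometric
#' with parameter `p` capped at `cap`, or degenerate via `fixed`),
#' non-templated np1/np2 insertions from a first-order nucleotide Markov
#' chain, and a clone size; descendants then receive i.i.d. point mutations
#' at `mutation_rate` per site (star genealogy: one naive ancestor per
#' clone, descendants mutated independently).  Germline gene sequences are
#' synthetic random sequences of realistic lengths (V ~ 300 nt, D ~ 20 nt,
#' J ~ 50 nt), generated reproducibly from `pool_seed`.
#'
#' @param n_sequences target number of rearrangement records.
#' @param seed integer seed driving all sampling in
#'   [generate_repertoire()].
#' @param n_v,n_d,n_j pool sizes.
#' @param v_length,d_length,j_length germline segment lengths (nt).
#' @param v_probs,d_probs,j_probs usage probabilities (default: fixed
#'   geometric-decay weights, so usage is non-uniform but known).
#' @param deletion_dists named list over `v_3p`, `d_5p`, `d_3p`, `j_5p`
#'   of `list(p =, cap =)` or `list(fixed =)`.
#' @param insertion_length_dists named list over `np1`, `np2` of the same
#'   form.
#' @param insertion_init initial base distribution of the insertion chain.
#' @param insertion_matrix 4x4 row-stochastic transition matrix (A, C, G,
#'   T) of the insertion chain.
#' @param mutation_rate per-site substitution probability in descendants.
#' @param clone_size_p clone sizes are `1 + Geometric(clone_size_p)`.
#' @param pool_seed seed for the germline pools (kept separate from `seed`
#'   so different repertoires can share identical germlines).
#' @return a validated list of class `generative_spec`.
#' @export
generative_spec <- function(n_sequences = 500,
                            seed = 1,
                            n_v = 10, n_d = 5, n_j = 6,
                            v_length = 300, d_length = 20, j_length = 50,
                            v_probs = NULL, d_probs = NULL, j_probs = NULL,
                            deletion_dists = NULL,
                            insertion_length_dists = NULL,
                            insertion_init = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2),
                            insertion_matrix = NULL,
                            mutation_rate = 0.03,
                            clone_size_p = 0.5,
                            pool_seed = 42) {
  decay_probs <- function(n) {
    w <- 2^(-(seq_len(n) - 1) / 2)
    w / sum(w)
  }
  if (is.null(v_probs)) v_probs <- decay_probs(n_v)
  if (is.null(d_probs)) d_probs <- decay_probs(n_d)
  if (is.null(j_probs)) j_probs <- decay_probs(n_j)
  check_prob_vec(v_probs, "v_probs"); check_prob_vec(d_probs, "d_probs")
  check_prob_vec(j_probs, "j_probs")
  if (length(v_probs) != n_v || length(d_probs) != n_d || length(j_probs) != n_j)
    abort("usage probability vectors must match the pool sizes")
  if (is.null(deletion_dists))
    deletion_dists <- list(v_3p = list(p = 0.2, cap = 12),
                           d_5p = list(p = 0.2, cap = 8),
                           d_3p = list(p = 0.2, cap = 8),
                           j_5p = list(p = 0.2, cap = 12))
  if (is.null(insertion_length_dists))
    insertion_length_dists <- list(np1 = list(p = 0.2, cap = 15),
                                   np2 = list(p = 0.2, cap = 15))
  if (is.null(insertion_matrix))
    insertion_matrix <- matrix(c(
      0.35, 0.20, 0.30, 0.15,
      0.15, 0.35, 0.30, 0.20,
      0.20, 0.30, 0.35, 0.15,
      0.15, 0.30, 0.20, 0.35
    ), 4, 4, byrow = TRUE, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  check_prob_vec(insertion_init, "insertion_init")
  apply(insertion_matrix, 1, check_prob_vec, what = "insertion_matrix rows")
  if (mutation_rate < 0 || mutation_rate > 1) abort("mutation_rate must be in [0, 1]")
  pools <- withr::with_seed(pool_seed, list(
    v = dplyr::mutate(random_germline(n_v, v_length, "IGHV"), prob = v_probs),
    d = dplyr::mutate(random_germline(n_d, d_length, "IGHD"), prob = d_probs),
    j = dplyr::mutate(random_germline(n_j, j_length, "IGHJ"), prob = j_probs)
  ))
  structure(list(
    n_sequences = as.integer(n_sequences), seed = seed,
    gene_pools = pools,
    deletion_dists = deletion_dists,
    insertion_length_dists = insertion_length_dists,
    insertion_init = insertion_init,
    insertion_matrix = insertion_matrix,
    mutation_rate = mutation_rate,
    clone_size_p = clone_size_p,
    anchor = 3L  # junction spans the last/first `anchor` nt of V/J
  ), class = "generative_spec")
}

draw_insertion <- function(len, init, mat) {
  if (len == 0) return("")
  bases <- c("A", "C", "G", "T")
  out <- character(len)
  out[1] <- sample(bases, 1, prob = init)
  if (len > 1) {
    for (i in 2:len) out[i] <- sample(bases, 1, prob = mat[out[i - 1], ])
  }
  paste(out, collapse = "")
}

mutate_sequence <- function(seq, rate) {
  if (rate == 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1), character(1))
  }
  paste(v, collapse = "")
}

translate_inframe <- function(junctions) {
  out <- rep(NA_character_, length(junctions))
  ok <- !is.na(junctions) & nchar(junctions) > 0 & nchar(junctions) %% 3 == 0
  if (any(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(junctions[ok]),
                                if.fuzzy.codon = "X")
    out[ok] <- as.character(aa)
  }
  out
}

#' Generate a synthetic AIRR repertoire
#'
#' Draws clonal families from the generative model of [generative_spec()]
#' and records all AIRR fields: gene calls (with `*01` allele suffixes),
#' deletion lengths, np1/np2 strings and lengths, the junction (spanning
#' the V-end anchor through the J-start anchor), its translation for
#' in-frame records, clone labels, and productivity flags.  With
#' `mutation_rate = 0` every `sequence_alignment` equals its
#' `germline_alignment`.
#'
#' @param spec a `generative_spec`.
#' @return a validated repertoire tibble.
#' @export
generate_repertoire <- function(spec) {
  if (!inherits(spec, "generative_spec")) abort("spec must be a generative_spec")
  withr::with_seed(spec$seed, {
    rows <- list()
    total <- 0L
    clone <- 0L
    while (total < spec$n_sequences) {
      clone <- clone + 1L
      p <- spec$gene_pools
      vi <- sample.int(nrow(p$v), 1, prob = p$v$prob)
      di <- sample.int(nrow(p$d), 1, prob = p$d$prob)
      ji <- sample.int(nrow(p$j), 1, prob = p$j$prob)
      del <- lapply(spec$deletion_dists, draw_lengths, n = 1)
      vlen <- nchar(p$v$seq[vi]); dlen <- nchar(p$d$seq[di]); jlen <- nchar(p$j$seq[ji])
      del$v_3p <- min(del$v_3p, vlen - spec$anchor)
      del$j_5p <- min(del$j_5p, jlen - spec$anchor)
      if (del$d_5p + del$d_3p > dlen) {  # over-trimmed D vanishes
        del$d_5p <- min(del$d_5p, dlen)
        del$d_3p <- dlen - del$d_5p
      }
      vtrim <- stringr::str_sub(p$v$seq[vi], 1, vlen - del$v_3p)
      dtrim <- if (del$d_5p + del$d_3p >= dlen) "" else
        stringr::str_sub(p$d$seq[di], del$d_5p + 1, dlen - del$d_3p)
      jtrim <- stringr::str_sub(p$j$seq[ji], del$j_5p + 1, jlen)
      ins_len <- lapply(spec$insertion_length_dists, draw_lengths, n = 1)
      np1 <- draw_insertion(ins_len$np1, spec$insertion_init, spec$insertion_matrix)
      np2 <- draw_insertion(ins_len$np2, spec$insertion_init, spec$insertion_matrix)
      germ <- paste0(vtrim, np1, dtrim, np2, jtrim)
      j_start <- nchar(vtrim) - spec$anchor + 1L       # junction start in germ
      j_end <- nchar(vtrim) + nchar(np1) + nchar(dtrim) + nchar(np2) + spec$anchor
      size <- 1L + min(rgeom(1, spec$clone_size_p), 20L)
      seqs <- vapply(seq_len(size), function(mi) {
        mutate_sequence(germ, spec$mutation_rate)
      }, character(1))
      rows[[clone]] <- list(
        sequence_alignment = seqs,
        germline_alignment = rep(germ, size),
        junction = stringr::str_sub(seqs, j_start, j_end),
        v_call = rep(paste0(p$v$name[vi], "*01"), size),
        d_call = rep(paste0(p$d$name[di], "*01"), size),
        j_call = rep(paste0(p$j$name[ji], "*01"), size),
        v_3p_deletion = rep(as.integer(del$v_3p), size),
        v_5p_deletion = rep(0L, size),
        d_3p_deletion = rep(as.integer(del$d_3p), size),
        d_5p_deletion = rep(as.integer(del$d_5p), size),
        j_3p_deletion = rep(0L, size),
        j_5p_deletion = rep(as.integer(del$j_5p), size),
        np1 = rep(np1, size), np2 = rep(np2, size),
        np1_length = rep(nchar(np1), size), np2_length = rep(nchar(np2), size),
        clone_id = rep(as.character(clone), size)
      )
      total <- total + size
    }
    cols <- names(rows[[1]])
    out <- as_tibble(lapply(setNames(cols, cols), function(f) {
      unlist(lapply(rows, `[[`, f), use.names = FALSE)
    }))
    out <- out[seq_len(min(nrow(out), spec$n_sequences)), , drop = FALSE]
    out$sequence_id <- paste0("seq_", seq_len(nrow(out)))
    out$junction_aa <- translate_inframe(out$junction)
    out$productive <- nchar(out$junction) %% 3 == 0 &
      !is.na(out$junction_aa) & !grepl("\\*", out$junction_aa)
    out$locus <- "IGH"
    out <- dplyr::relocate(out, "sequence_id")
    validate_repertoire(out)
    out
  })
}

#' Perturb one targeted property of a repertoire
#'
#' Returns a modified copy in which only the targeted property's
#' distribution changes; `magnitude = 0` returns the input unchanged.
#' Knobs:
#' * `junction_length_shift` — inserts `magnitude` random bases at the
#'   junction center (junction and its translation only; alignments are
#'   untouched, so gene usage and mutation summaries are unaffected).
#' * `gene_shuffle` — permutes the `v_call` column entries of a fraction
#'   `magnitude` of rows among themselves (marginal usage preserved, joint
#'   usage scrambled).
#' * `mutation_boost` — extra i.i.d. point mutations in
#'   `sequence_alignment` at per-site rate `magnitude`.
#' * `junction_scramble` — replaces `junction_aa` of a fraction
#'   `magnitude` of records with uniform-random peptides of the same
#'   length (junction nucleotides untouched).
#'
#' @param tbl repertoire data frame.
#' @param knob one of the supported perturbations.
#' @param magnitude nonnegative real (see each knob).
#' @param seed integer seed.
#' @return a repertoire tibble.
#' @export
perturb_repertoire <- function(tbl, knob = c("junction_length_shift",
                                             "gene_shuffle",
                                             "mutation_boost",
                                             "junction_scramble"),
                               magnitude, seed = 1) {
  knob <- arg_match(knob)
  if (magnitude == 0) return(tbl)
  withr::with_seed(seed, {
    out <- tbl
    if (knob == "junction_length_shift") {
      shift <- as.integer(round(magnitude))
      ok <- !is.na(out$junction)
      ins <- vapply(seq_len(sum(ok)), function(i) {
        paste(sample(c("A", "C", "G", "T"), shift, replace = TRUE), collapse = "")
      }, character(1))
      j <- out$junction[ok]
      mid <- nchar(j) %/% 2
      out$junction[ok] <- paste0(stringr::str_sub(j, 1, mid), ins,
                                 stringr::str_sub(j, mid + 1))
      if ("junction_aa" %in% names(out))
        out$junction_aa[ok] <- translate_inframe(out$junction[ok])
    } else if (knob == "gene_shuffle") {
      if (!"v_call" %in% names(out)) abort("gene_shuffle needs v_call")
      n <- nrow(out)
      idx <- sample.int(n, size = max(2, round(magnitude * n)))
      out$v_call[idx] <- out$v_call[sample(idx)]
    } else if (knob == "mutation_boost") {
      ok <- !is.na(out$sequence_alignment)
      out$sequence_alignment[ok] <-
        vapply(out$sequence_alignment[ok], mutate_sequence,
               character(1), rate = magnitude, USE.NAMES = FALSE)
    } else if (knob == "junction_scramble") {
      if (!"junction_aa" %in% names(out)) abort("junction_scramble needs junction_aa")
      aa <- c("A","C","D","E","F","G","H","I","K","L",
              "M","N","P","Q","R","S","T","V","W","Y")
      # strongly hydrophilic-biased residue distribution, so physicochemical
      # CDR3 summaries shift decisively while lengths (and everything
      # outside junction_aa) stay untouched
      w <- ifelse(aa %in% c("D", "E", "K", "R", "N", "Q", "S", "H"), 6, 1)
      ok <- which(!is.na(out$junction_aa))
      idx <- sample(ok, size = round(magnitude * length(ok)))
      out$junction_aa[idx] <- vapply(nchar(out$junction_aa[idx]), function(L) {
        paste(sample(aa, L, replace = TRUE, prob = w), collapse = "")
      }, character(1))
    }
    out
  })
}
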