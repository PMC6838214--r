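# Scoring how well simulated repertoires recapitulate their observed
# counterparts (log relative average divergence), plus divergence matrices
# and their classical MDS embedding.

#' Paired observed/simulated repertoires
#'
#' @param obs,sim lists of repertoire data frames of equal length `k >= 2`;
#'   `sim[[i]]` is the simulation fitted to `obs[[i]]`.
#' @return an object of class `paired_repertoires`.
#' @export
paired_repertoires <- function(obs, sim) {
  if (length(obs) != length(sim)) abort("obs and sim must have equal length")
  if (length(obs) < 2) abort("need k >= 2 pairs (the score needs cross-pairs)")
  structure(list(obs = obs, sim = sim, k = length(obs)),
            class = "paired_repertoires")
}

#' Log relative average divergence (LRAD) of one summary
#'
#' With `D_s(R1, R2)` the divergence of summary `s` between two repertoires
#' and `k` observed/simulated pairs, the denominator is the mean within-pair
#' divergence `mean_i D_s(R_i_obs, R_i_sim)` and the numerator is the mean
#' divergence over distinct pairs of observed repertoires (`mode = "data"`)
#' or of simulated repertoires (`mode = "sim"`); the score is the natural
#' log of their ratio.  Positive scores mean simulations look more like
#' their own observations than repertoires look like each other.
#'
#' Degenerate cases: zero denominator with positive numerator gives `+Inf`;
#' zero numerator with positive denominator gives `-Inf`; both zero is
#' reported as `NA` (undefined).  The component means are always returned.
#'
#' @param pairs a [paired_repertoires()] object.
#' @param summary one summary name (see [list_summaries()]).
#' @param mode `"data"` (observed-observed numerator) or `"sim"`.
#' @param normalize_counts passed to the divergence of categorical counts.
#' @return one-row tibble: `summary`, `mode`, `value`, `numerator_mean`,
#'   `denominator_mean`.
#' @export
lrad <- function(pairs, summary, mode = c("data", "sim"),
                 normalize_counts = TRUE) {
  mode <- arg_match(mode)
  if (!inherits(pairs, "paired_repertoires"))
    abort("pairs must be a paired_repertoires object")
  reg <- summary_registry()
  i <- match(summary, reg$name)
  if (is.na(i)) abort(paste0("unknown summary: ", summary))
  kind <- reg$kind[i]
  fun <- reg$fun[[i]]
  k <- pairs$k
  obs_s <- lapply(pairs$obs, fun)
  sim_s <- lapply(pairs$sim, fun)
  denom <- mean(vapply(seq_len(k), function(i) {
    summary_divergence(obs_s[[i]], sim_s[[i]], kind, normalize_counts)
  }, numeric(1)))
  cross <- if (mode == "data") obs_s else sim_s
  num_vals <- unlist(lapply(seq_len(k - 1), function(i) {
    vapply((i + 1):k, function(j) {
      summary_divergence(cross[[i]], cross[[j]], kind, normalize_counts)
    }, numeric(1))
  }))
  num <- mean(num_vals)
  value <- if (num == 0 && denom == 0) NA_real_
           else if (denom == 0) Inf
           else if (num == 0) -Inf
           else log(num / denom)
  tibble(summary = summary, mode = mode, value = value,
         numerator_mean = num, denominator_mean = denom)
}

#' Per-summary simulator scores for a paired repertoire set
#'
#' LRAD-data and LRAD-sim for every computable summary (they share the
#' within-pair denominator), sorted descending by LRAD-data.  Summaries not
#' computable on all tables are listed in the `skipped` attribute with the
#' reason.
#'
#' @inheritParams lrad
#' @param summaries `"all"` or a character vector of summary names.
#' @return a tibble of class `lrad_scores`: `summary`, `lrad_data`,
#'   `lrad_sim`, `numerator_data`, `numerator_sim`, `denominator`.
#' @export
score_report <- function(pairs, summaries = "all", normalize_counts = TRUE) {
  reg <- summary_registry()
  if (!identical(summaries, "all")) {
    unknown <- setdiff(summaries, reg$name)
    if (length(unknown) > 0)
      abort(paste0("unknown summaries: ", paste(unknown, collapse = ", ")))
    reg <- reg[reg$name %in% summaries, , drop = FALSE]
  }
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    res <- tryCatch({
      d <- lrad(pairs, nm, "data", normalize_counts)
      s <- lrad(pairs, nm, "sim", normalize_counts)
      tibble(summary = nm, lrad_data = d$value, lrad_sim = s$value,
             numerator_data = d$numerator_mean,
             numerator_sim = s$numerator_mean,
             denominator = d$denominator_mean)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) skipped[[nm]] <- res else rows[[nm]] <- res
  }
  if (length(rows) == 0) abort("no summary computable on the paired set")
  out <- bind_rows(rows) %>% arrange(desc(lrad_data))
  structure(out, class = c("lrad_scores", class(out)),
            skipped = tibble(summary = names(skipped),
                             reason = unlist(unname(skipped))))
}

#' Pairwise divergence matrix over a collection of repertoires
#'
#' `D[i, j]` is the divergence of one summary between tables `i` and `j`,
#' computed once per unordered pair and mirrored; the diagonal is zero.
#' Stochastic (approximated) summaries should be computed with a fixed seed
#' upstream so the matrix is reproducible.
#'
#' @param tables list of two or more repertoire data frames.
#' @param summary one summary name.
#' @param labels optional repertoire identifiers.
#' @param normalize_counts passed to categorical-count divergences.
#' @return a symmetric labeled matrix of class `rep_divmat`.
#' @export
divergence_matrix <- function(tables, summary, labels = NULL,
                              normalize_counts = TRUE) {
  n <- length(tables)
  if (n < 2) abort("need at least 2 tables")
  if (is.null(labels)) labels <- paste0("repertoire_", seq_len(n))
  reg <- summary_registry()
  i <- match(summary, reg$name)
  if (is.na(i)) abort(paste0("unknown summary: ", summary))
  kind <- reg$kind[i]
  fun <- reg$fun[[i]]
  ss <- lapply(tables, fun)  # errors here propagate: summary must be computable
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      D[a, b] <- D[b, a] <- summary_divergence(ss[[a]], ss[[b]], kind,
                                               normalize_counts)
    }
  }
  structure(D, class = c("rep_divmat", "matrix", "array"), summary = summary)
}

#' Classical MDS embedding of a divergence matrix
#'
#' Torgerson (classical) multidimensional scaling: coordinates are centered
#' and their pairwise Euclidean distances approximate the divergences with
#' minimal strain; a Euclidean-realizable matrix is reproduced exactly when
#' `dims` is large enough.
#'
#' @param D a symmetric nonnegative matrix (e.g. [divergence_matrix()]).
#' @param dims embedding dimension, less than the number of labels.
#' @return a tibble: `label`, `dim1` ... `dim<dims>`, of class `rep_mds`.
#' @export
mds_embed <- function(D, dims = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (dims >= n) abort("dims must be smaller than the number of labels")
  # rank-deficient configurations legitimately span fewer than `dims`
  # dimensions; cmdscale warns, and the missing axes are padded with zeros
  coords <- suppressWarnings(cmdscale(stats::as.dist(D), k = dims))
  # degenerate configurations can return fewer columns; pad with zeros
  if (ncol(coords) < dims)
    coords <- cbind(coords, matrix(0, n, dims - ncol(coords)))
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("repertoire_", seq_len(n))
  out <- as_tibble(coords, .name_repair = ~ paste0("dim", seq_len(dims)))
  out <- dplyr::bind_cols(tibble(label = labels), out)
  structure(out, class = c("rep_mds", class(tibble())))
}
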