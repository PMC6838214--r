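# Ranking sequence-level summaries by how well they discriminate datasets,
# via the regularization path of an l1-penalized multinomial regression.

#' Build a design matrix of sequence-level summaries
#'
#' Stacks the per-sequence values of the requested summaries over two or
#' more repertoires; the response is the dataset identity of each row.  Only
#' sequence-level summaries can be covariates (a pairwise distance
#' distribution, for example, has more values than sequences and cannot fill
#' a design column).  Columns are standardized to zero mean and unit
#' variance; zero-variance columns are dropped with a warning, and rows with
#' any missing value are dropped.
#'
#' @param tables list of two or more repertoire data frames.
#' @param summaries character vector of sequence-level summary names
#'   (default: all sequence-level summaries except the Atchley/Kidera
#'   factors), see [list_summaries()].
#' @param labels optional dataset labels (default `dataset_1`, ...).
#' @param include_factors include the Atchley/Kidera factor scales when
#'   `summaries` is left at its default (default FALSE).
#' @return an object of class `rep_design`: list with standardized matrix
#'   `X`, factor response `y`, and `columns`.
#' @export
build_design_matrix <- function(tables, summaries = NULL, labels = NULL,
                                include_factors = FALSE) {
  if (length(tables) < 2) abort("need at least 2 tables")
  reg <- summary_registry()
  if (is.null(summaries)) {
    keep <- reg$sequence_level & (include_factors | !reg$factor_scale)
    summaries <- reg$name[keep]
  } else {
    i <- match(summaries, reg$name)
    if (anyNA(i))
      abort(paste0("unknown summaries: ",
                   paste(summaries[is.na(i)], collapse = ", ")))
    bad <- !reg$sequence_level[i]
    if (any(bad))
      abort(paste0(
        "only sequence-level summary statistics can be used as covariates; ",
        "not sequence-level: ", paste(summaries[bad], collapse = ", ")))
  }
  if (is.null(labels)) labels <- paste0("dataset_", seq_along(tables))
  reg <- reg[match(summaries, reg$name), , drop = FALSE]
  blocks <- map2(tables, labels, function(tbl, lab) {
    cols <- lapply(reg$row_fun, function(f) {
      tryCatch(f(tbl), error = function(e) rep(NA_real_, nrow(tbl)))
    })
    X <- do.call(cbind, cols)
    colnames(X) <- reg$name
    list(X = X, y = rep(lab, nrow(tbl)))
  })
  X <- do.call(rbind, map(blocks, "X"))
  y <- factor(unlist(map(blocks, "y")), levels = labels)
  keep_rows <- stats::complete.cases(X)
  X <- X[keep_rows, , drop = FALSE]
  y <- y[keep_rows]
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping zero-variance column(s): ",
                paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  X <- scale(X)
  design_matrix(X, y)
}

#' Construct a design object directly
#'
#' Low-level constructor for [rank_summaries()]; columns are standardized to
#' zero mean and unit variance.
#'
#' @param X numeric matrix with named columns (rows = sequences).
#' @param y dataset label per row (2 or more distinct values).
#' @return a `rep_design` object.
#' @export
design_matrix <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("s", seq_len(ncol(X)))
  y <- as.factor(y)
  if (nlevels(y) < 2) abort("need at least 2 distinct dataset labels")
  if (nrow(X) != length(y)) abort("X and y sizes differ")
  X <- scale(X)
  structure(list(X = X, y = y, columns = colnames(X)),
            class = "rep_design")
}

#' @export
print.rep_design <- function(x, ...) {
  cat(sprintf("<design matrix: %d sequences x %d summaries, %d datasets>\n",
              nrow(x$X), ncol(x$X), nlevels(x$y)))
  invisible(x)
}

#' Rank summaries by informativeness along the lasso path
#'
#' Fits the l1-penalized multinomial regression path over a decreasing
#' lambda grid (100 log-spaced values down to `1e-3 * lambda_max` by
#' default).  For each dataset class `d` and summary `s`, the branch-off
#' point `t[d, s]` is the largest grid lambda at which the coefficient
#' `beta[d, s]` is nonzero and remains nonzero for all smaller lambdas
#' (infinite if the coefficient never stays active).  Within each class,
#' summaries are ranked by branch-off order (earlier = rank 1; never-active
#' summaries rank last); the final score ranks the per-summary medians
#' across classes.  Ties are broken by seeded randomization rather than
#' alphabetically.
#'
#' @param design a `rep_design` from [build_design_matrix()] or
#'   [design_matrix()].
#' @param lambdas optional strictly decreasing positive grid.
#' @param seed integer seed for tie randomization.
#' @param nonzero_tol coefficients with `|beta|` below this are treated as
#'   zero (absorbs solver noise).
#' @return an object of class `summary_ranking` with elements `ranks` (a
#'   tibble: summary, median_rank, final_rank), `per_class_ranks`,
#'   `branch_lambdas` and `lambdas`.
#' @export
rank_summaries <- function(design, lambdas = NULL, seed = 1,
                           nonzero_tol = 1e-8) {
  if (!inherits(design, "rep_design")) abort("design must be a rep_design")
  if (!is.null(lambdas)) {
    if (any(lambdas <= 0) || any(diff(lambdas) >= 0))
      abort("lambdas must be a strictly decreasing positive grid")
  }
  # covariates are presented to the solver in seeded random order, so that
  # exactly collinear columns (which coordinate descent otherwise resolves
  # in favor of whichever comes first) are not ranked alphabetically
  perm <- withr::with_seed(seed, sample.int(ncol(design$X)))
  Xp <- design$X[, perm, drop = FALSE]
  fit <- glmnet::glmnet(Xp, design$y, family = "multinomial",
                        lambda = lambdas, nlambda = 100,
                        lambda.min.ratio = 1e-3, standardize = FALSE)
  lam <- fit$lambda
  classes <- names(fit$beta)
  S <- ncol(design$X)
  unperm <- order(perm)  # maps solver column order back to input order
  branch <- matrix(Inf, nrow = length(classes), ncol = S,
                   dimnames = list(classes, colnames(design$X)))
  for (d in classes) {
    B <- as.matrix(fit$beta[[d]])[unperm, , drop = FALSE]  # S x n_lambda
    nz <- abs(B) > nonzero_tol
    for (s in seq_len(S)) {
      act <- nz[s, ]
      if (!act[length(act)]) next  # not active at the smallest lambda
      # first index of the trailing all-active run
      zeros <- which(!act)
      start <- if (length(zeros) == 0) 1L else max(zeros) + 1L
      branch[d, s] <- lam[start]
    }
  }
  per_class <- withr::with_seed(seed, {
    t(apply(branch, 1, function(tt) {
      # earlier branch-off (larger lambda) = better rank; never-active = last
      key <- ifelse(is.finite(tt), -tt, Inf)
      rank(key, ties.method = "random")
    }))
  })
  med <- apply(per_class, 2, median)
  final <- withr::with_seed(seed + 1, rank(med, ties.method = "random"))
  structure(list(
    ranks = tibble(summary = colnames(design$X), median_rank = med,
                   final_rank = as.integer(final)) %>% arrange(final_rank),
    per_class_ranks = per_class,
    branch_lambdas = branch,
    lambdas = lam
  ), class = "summary_ranking")
}

#' @export
print.summary_ranking <- function(x, ...) {
  cat(sprintf("<summary ranking over %d classes, %d summaries>\n",
              nrow(x$per_class_ranks), ncol(x$per_class_ranks)))
  print(x$ranks, n = 10)
  invisible(x)
}
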