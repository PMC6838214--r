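# LRAD simulator scores, divergence matrices, and MDS embedding.

usage_tbl <- function(calls) {
  tibble::tibble(v_call = calls, j_call = "IGHJ4*01",
                 sequence_alignment = "ATG", junction = "TGTAAA")
}

test_that("the hand-computed k = 2 example returns ln 2 exactly", {
  # raw v-gene usage counts: obs1 = {A:2}, obs2 = {B:2},
  # sim1 = sim2 = {A:1, B:1}; cross-pair l1 = 4, both within-pair l1 = 2
  pairs <- paired_repertoires(
    obs = list(usage_tbl(c("IGHVA*01", "IGHVA*01")),
               usage_tbl(c("IGHVB*01", "IGHVB*01"))),
    sim = list(usage_tbl(c("IGHVA*01", "IGHVB*01")),
               usage_tbl(c("IGHVA*01", "IGHVB*01"))))
  r <- lrad(pairs, "v_gene_usage", mode = "data", normalize_counts = FALSE)
  expect_equal(r$numerator_mean, 4)
  expect_equal(r$denominator_mean, 2)
  expect_equal(r$value, log(2))
})

test_that("exact-copy simulations give +Inf with finite numerator components", {
  obs <- list(generate_repertoire(generative_spec(40, seed = 61)),
              generate_repertoire(generative_spec(40, seed = 62)))
  pairs <- paired_repertoires(obs, obs)
  r <- lrad(pairs, "cdr3_length", mode = "data")
  expect_equal(r$denominator_mean, 0)
  expect_gt(r$numerator_mean, 0)
  expect_equal(r$value, Inf)
  # both numerator and denominator zero is undefined, not NaN
  one <- usage_tbl(c("IGHVA*01", "IGHVA*01"))
  p0 <- paired_repertoires(list(one, one), list(one, one))
  r0 <- lrad(p0, "v_gene_usage", normalize_counts = FALSE)
  expect_true(is.na(r0$value))
})

test_that("data and sim modes share the within-pair denominator", {
  obs <- lapply(61:63, function(s) generate_repertoire(generative_spec(60, seed = s)))
  sim <- lapply(64:66, function(s) generate_repertoire(generative_spec(60, seed = s)))
  pairs <- paired_repertoires(obs, sim)
  rd <- lrad(pairs, "gc_content", mode = "data")
  rs <- lrad(pairs, "gc_content", mode = "sim")
  expect_identical(rd$denominator_mean, rs$denominator_mean)
})

test_that("lrad is invariant under relabeling of the pair indices", {
  obs <- lapply(71:73, function(s) generate_repertoire(generative_spec(50, seed = s)))
  sim <- lapply(74:76, function(s) generate_repertoire(generative_spec(50, seed = s)))
  r1 <- lrad(paired_repertoires(obs, sim), "cdr3_length")
  perm <- c(3, 1, 2)
  r2 <- lrad(paired_repertoires(obs[perm], sim[perm]), "cdr3_length")
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
})

test_that("score_report covers the computable intersection, sorted by LRAD-data", {
  obs <- lapply(81:82, function(s) generate_repertoire(generative_spec(50, seed = s)))
  sim <- lapply(83:84, function(s) generate_repertoire(generative_spec(50, seed = s)))
  rep <- score_report(paired_repertoires(obs, sim),
                      summaries = c("cdr3_length", "gc_content", "v_gene_usage",
                                    "sackin_index"))
  expect_s3_class(rep, "lrad_scores")
  expect_setequal(rep$summary, c("cdr3_length", "gc_content", "v_gene_usage"))
  expect_true(all(diff(rep$lrad_data) <= 0))
  expect_equal(attr(rep, "skipped")$summary, "sackin_index")
  td <- tidy(rep)
  expect_equal(nrow(td), 2 * nrow(rep))
  expect_equal(glance(rep)$n_skipped, 1L)
})

test_that("divergence matrices are symmetric, zero-diagonal, and match pairwise calls", {
  tabs <- lapply(91:93, function(s) generate_repertoire(generative_spec(50, seed = s)))
  D <- divergence_matrix(tabs, "cdr3_length")
  expect_equal(dim(D), c(3, 3))
  expect_equal(diag(unclass(D)), setNames(rep(0, 3), rownames(D)))
  expect_equal(unclass(D), t(unclass(D)))
  cmp <- compare_repertoires(tabs[[1]], tabs[[2]], summaries = "cdr3_length")
  expect_equal(D[1, 2], cmp$divergence[1])
  # identical tables give a zero matrix
  D0 <- divergence_matrix(list(tabs[[1]], tabs[[1]]), "cdr3_length")
  expect_true(all(D0 == 0))
})

test_that("an equidistant triple embeds as an equilateral triangle", {
  c0 <- 0.8
  D <- matrix(c0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  xy <- mds_embed(D, dims = 2)
  pts <- as.matrix(xy[, c("dim1", "dim2")])
  d12 <- sqrt(sum((pts[1, ] - pts[2, ])^2))
  d13 <- sqrt(sum((pts[1, ] - pts[3, ])^2))
  d23 <- sqrt(sum((pts[2, ] - pts[3, ])^2))
  expect_equal(c(d12, d13, d23), rep(c0, 3), tolerance = 1e-9)
  # centered at the origin
  expect_true(all(abs(colMeans(pts)) < 1e-9))
  expect_error(mds_embed(D, dims = 3), "smaller")
})

test_that("duplicated repertoires map to coincident MDS points", {
  tabs <- lapply(94:95, function(s) generate_repertoire(generative_spec(40, seed = s)))
  D <- divergence_matrix(list(tabs[[1]], tabs[[2]], tabs[[1]]), "gc_content",
                         labels = c("r1", "r2", "r1dup"))
  xy <- mds_embed(D, dims = 2)
  pts <- as.matrix(xy[, c("dim1", "dim2")])
  expect_lt(sqrt(sum((pts[1, ] - pts[3, ])^2)), 1e-9)
})

test_that("a Euclidean-realizable matrix is reproduced exactly at full rank", {
  withr::local_seed(95)
  pts <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("r", 1:4)
  xy <- mds_embed(D, dims = 3)
  got <- as.matrix(dist(as.matrix(xy[, -1])))
  expect_equal(unname(got), unname(D), tolerance = 1e-9)
})

test_that("paired sets validate their shape", {
  one <- usage_tbl("IGHVA*01")
  expect_error(paired_repertoires(list(one), list(one)), "k >= 2")
  expect_error(paired_repertoires(list(one, one), list(one)), "equal length")
})
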