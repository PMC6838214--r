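# Generator contracts: reproducibility, degenerate-parameter recovery, and
# targeted perturbations.

test_that("generation is seed-reproducible and passes schema validation", {
  spec <- generative_spec(n_sequences = 80, seed = 7)
  t1 <- generate_repertoire(spec)
  t2 <- generate_repertoire(spec)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 80)
  expect_silent(validate_repertoire(t1))
  expect_equal(as.character(airr_capability(t1)), "clustered")
  t3 <- generate_repertoire(generative_spec(n_sequences = 80, seed = 8))
  expect_false(identical(t1, t3))
})

test_that("zero mutation rate reproduces the germline exactly", {
  tbl <- generate_repertoire(generative_spec(n_sequences = 60, seed = 9,
                                             mutation_rate = 0))
  expect_identical(tbl$sequence_alignment, tbl$germline_alignment)
  expect_true(all(dist_values(germline_distance_distribution(tbl)) == 0))
})

test_that("degenerate deletion distributions are recovered exactly", {
  spec <- generative_spec(
    n_sequences = 50, seed = 10,
    deletion_dists = list(v_3p = list(fixed = 3), d_5p = list(fixed = 1),
                          d_3p = list(fixed = 2), j_5p = list(fixed = 4)))
  tbl <- generate_repertoire(spec)
  expect_equal(dist_values(rearrangement_length_distribution(tbl, "v_3p_deletion")),
               rep(3, 50))
  expect_equal(dist_values(rearrangement_length_distribution(tbl, "j_5p_deletion")),
               rep(4, 50))
})

test_that("junction fields are internally consistent with the anchors", {
  tbl <- generate_repertoire(generative_spec(n_sequences = 40, seed = 11,
                                             mutation_rate = 0))
  # junction = V anchor + np1 + trimmed D + np2 + J anchor
  dlen <- nchar(tbl$np1) + nchar(tbl$np2) +
    (20 - tbl$d_3p_deletion - tbl$d_5p_deletion) + 6
  expect_equal(nchar(tbl$junction), dlen)
  # the junction is a substring of the sequence
  expect_true(all(mapply(grepl, tbl$junction, tbl$sequence_alignment,
                         MoreArgs = list(fixed = TRUE))))
  # in-frame junctions translate; out-of-frame are missing
  inframe <- nchar(tbl$junction) %% 3 == 0
  expect_true(all(!is.na(tbl$junction_aa[inframe])))
  expect_true(all(is.na(tbl$junction_aa[!inframe])))
  expect_equal(nchar(tbl$junction_aa[inframe]) * 3,
               nchar(tbl$junction[inframe]))
})

test_that("insertion chain statistics converge to the generating matrix", {
  spec <- generative_spec(n_sequences = 3000, seed = 12, clone_size_p = 1)
  tbl <- generate_repertoire(spec)
  tm <- insertion_transition_matrix(tbl, "np1")
  expect_gt(sum(tm$count), 5000)
  est <- transition_matrix(tm)
  err <- apply(abs(est - spec$insertion_matrix), 1, sum)
  expect_true(all(err < 0.1))
})

test_that("usage and deletion parameters are recovered within sampling error", {
  spec <- generative_spec(n_sequences = 3000, seed = 13, clone_size_p = 1)
  tbl <- generate_repertoire(spec)
  u <- gene_usage_counts(tbl, "v")
  emp <- setNames(u$count / sum(u$count), u$v_gene)
  tru <- setNames(spec$gene_pools$v$prob, spec$gene_pools$v$name)
  filled <- setNames(rep(0, length(tru)), names(tru))
  filled[names(emp)] <- emp
  expect_lt(sum(abs(filled - tru)), 0.06)
  # capped-geometric mean for a deletion end
  v3 <- dist_values(rearrangement_length_distribution(tbl, "v_3p_deletion"))
  expected_mean <- sum(pmin(0:200, 12) * dgeom(0:200, 0.2))
  expect_lt(abs(mean(v3) - expected_mean), 0.25)
})

test_that("perturbations with magnitude zero are the identity", {
  tbl <- generate_repertoire(generative_spec(n_sequences = 40, seed = 14))
  for (knob in c("junction_length_shift", "gene_shuffle", "mutation_boost",
                 "junction_scramble")) {
    expect_identical(perturb_repertoire(tbl, knob, 0), tbl)
  }
})

test_that("junction-length shift moves CDR3 length but not gene usage", {
  tbl <- generate_repertoire(generative_spec(n_sequences = 100, seed = 15))
  shifted <- perturb_repertoire(tbl, "junction_length_shift", 3, seed = 2)
  expect_equal(nchar(shifted$junction), nchar(tbl$junction) + 3)
  expect_gt(jsd(dist_values(cdr3_length_distribution(shifted, "nt")),
                dist_values(cdr3_length_distribution(tbl, "nt"))), 0)
  expect_equal(l1_divergence(counts_sorted(gene_usage_counts(shifted)),
                             counts_sorted(gene_usage_counts(tbl))), 0)
  # only junction fields changed
  expect_identical(shifted$sequence_alignment, tbl$sequence_alignment)
})

test_that("gene shuffling preserves marginal usage but changes the joint", {
  tbl <- generate_repertoire(generative_spec(n_sequences = 200, seed = 16,
                                             clone_size_p = 1))
  shuf <- perturb_repertoire(tbl, "gene_shuffle", 1, seed = 3)
  expect_equal(counts_sorted(gene_usage_counts(shuf, "v")),
               counts_sorted(gene_usage_counts(tbl, "v")))
  expect_gt(l1_divergence(counts_sorted(gene_usage_counts(shuf)),
                          counts_sorted(gene_usage_counts(tbl))), 0)
})

test_that("junction scrambling shifts physicochemical summaries only", {
  tbl <- generate_repertoire(generative_spec(n_sequences = 150, seed = 17))
  scr <- perturb_repertoire(tbl, "junction_scramble", 1, seed = 4)
  expect_identical(scr$junction, tbl$junction)
  expect_identical(scr$v_call, tbl$v_call)
  expect_gt(jsd(dist_values(aa_property_distribution(scr, "gravy")),
                dist_values(aa_property_distribution(tbl, "gravy"))), 0.05)
  # lengths preserved, so the aa CDR3 length distribution is unchanged
  expect_equal(sort(dist_values(cdr3_length_distribution(scr, "aa"))),
               sort(dist_values(cdr3_length_distribution(tbl, "aa"))))
})

test_that("invalid specifications are rejected", {
  expect_error(generative_spec(v_probs = c(0.5, 0.2)), "pool sizes|sum")
  expect_error(generative_spec(n_v = 2, v_probs = c(0.7, 0.7)), "summing to 1")
  expect_error(generative_spec(mutation_rate = 1.5), "mutation_rate")
  expect_error(perturb_repertoire(fixture_table(), "not_a_knob", 1))
})
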