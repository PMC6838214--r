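# Unit tests for each summary, mixing hand-computed examples with oracle
# comparisons on the handcrafted fixture.

test_that("GC content handles pure, absent and ambiguous-base cases", {
  expect_equal(dist_values(gc_content_distribution("GGCC")), 1.0)
  expect_equal(dist_values(gc_content_distribution("ATAT")), 0.0)
  # N excluded from the denominator
  expect_equal(dist_values(gc_content_distribution("GANT")), 1 / 3)
  expect_equal(dist_values(gc_content_distribution(fixture_table())),
               o_gc(fixture_table()$sequence_alignment))
  expect_error(gc_content_distribution("NNN"), "unambiguous")
})

test_that("pairwise distances enumerate all unordered pairs", {
  expect_equal(dist_values(pairwise_distance_distribution(c("AAAA", "AAAT"))), 1)
  expect_equal(sort(dist_values(pairwise_distance_distribution(c("AC", "AC", "GT")))),
               c(0, 2, 2))
  expect_equal(dist_values(pairwise_distance_distribution(rep("ACGT", 5))),
               rep(0, 10))
  expect_error(pairwise_distance_distribution("AC"), "at least 2")
  fix <- fixture_table()
  expect_equal(dist_values(pairwise_distance_distribution(fix)),
               as.numeric(o_pairwise(fix$sequence_alignment)))
})

test_that("nearest-neighbor distances use multiset semantics and the kth order", {
  expect_equal(sort(dist_values(nearest_neighbor_distribution(
    c("AAAA", "AAAT", "TTTT")))), c(1, 1, 3))
  expect_equal(dist_values(nearest_neighbor_distribution(c("A", "A"))), c(0, 0))
  expect_error(nearest_neighbor_distribution(c("A", "A"), k = 2), "more than k")
  fix <- fixture_table()
  expect_equal(dist_values(nearest_neighbor_distribution(fix, k = 2)),
               as.numeric(o_kth_nn(fix$sequence_alignment, 2)))
})

test_that("subset property: NN distance never decreases on a subset", {
  withr::local_seed(42)
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("A","C","G","T"), 40, TRUE), collapse = "")
  }, character(1))
  full <- dist_values(nearest_neighbor_distribution(seqs))
  for (rep in 1:20) {
    idx <- sort(sample(30, sample(5:25, 1)))
    sub <- dist_values(nearest_neighbor_distribution(seqs[idx]))
    expect_true(all(sub >= full[idx]))
  }
})

test_that("IUPAC motif counts match sliding-window enumeration", {
  expect_equal(dist_values(motif_count_distribution("TACTAC", motifs = "WRC")), 2)
  expect_equal(dist_values(motif_count_distribution("GTC", motifs = "SYC")), 1)
  expect_error(motif_count_distribution("ACGT", motifs = character(0)), "non-empty")
  expect_error(motif_count_distribution("ACGT", motifs = "WXC"), "invalid IUPAC")
  fix <- fixture_table()
  for (motifs in list(hotspot_motifs(), coldspot_motifs(), "TW")) {
    expect_equal(dist_values(motif_count_distribution(fix, motifs = motifs)),
                 as.numeric(o_motif_count(fix$sequence_alignment, motifs)))
  }
  # overlapping matches all counted; N in the read matches nothing
  expect_equal(dist_values(motif_count_distribution("AAAA", motifs = "AA")), 3)
  expect_equal(dist_values(motif_count_distribution("ANA", motifs = "WA")), 0)
})

test_that("CDR3 lengths come from junction fields and skip missing records", {
  tbl <- tibble::tibble(junction = c("TGTGCG", "TGT", NA),
                        junction_aa = c("CA", "C", NA))
  expect_equal(dist_values(cdr3_length_distribution(tbl, "nt")), c(6, 3))
  expect_equal(dist_values(cdr3_length_distribution(tbl, "aa")), c(2, 1))
  d <- cdr3_length_distribution(tbl, "nt")
  expect_equal(attr(d, "n_source"), 2L)
  expect_error(cdr3_length_distribution(tibble::tibble(junction = NA_character_)))
})

test_that("gene usage counts normalized tuples with exact marginal consistency", {
  tbl <- tibble::tibble(
    v_call = c("IGHV1-2*02,IGHV1-2*04", "IGHV1-2*04"),
    d_call = c("IGHD3-10*01", "IGHD3-10*02"),
    j_call = c("IGHJ4*02", "IGHJ4*01"))
  joint <- gene_usage_counts(tbl)
  expect_equal(nrow(joint), 1)
  expect_equal(joint$count, 2)
  expect_equal(joint$v_gene, "IGHV1-2")
  fix <- fixture_table()
  joint <- gene_usage_counts(fix)
  for (ax in c("v", "d", "j")) {
    marg <- gene_usage_counts(fix, ax)
    agg <- tapply(joint$count, joint[[paste0(ax, "_gene")]], sum)
    expect_equal(marg$count,
                 as.numeric(agg[marg[[paste0(ax, "_gene")]]]))
    expect_equal(sum(marg$count), sum(joint$count))
  }
  expect_equal(counts_sorted(joint), o_usage(fix, c("v", "d", "j")))
  expect_error(gene_usage_counts(dplyr::select(fix, -d_call), c("v", "d")),
               "absent")
})

test_that("amino-acid properties follow the published scales and rules", {
  expect_equal(dist_values(aa_property_distribution("A", "gravy")), 1.8)
  expect_equal(dist_values(aa_property_distribution("FWYA", "aromaticity")), 0.75)
  expect_gt(dist_values(aa_property_distribution("K", "charge")), 0)
  expect_lt(dist_values(aa_property_distribution("D", "charge")), 0)
  # aliphatic index: mole-percent Ikai formula
  expect_equal(dist_values(aa_property_distribution("A", "aliphatic")), 100)
  expect_equal(dist_values(aa_property_distribution("V", "aliphatic")), 290)
  expect_equal(dist_values(aa_property_distribution("AILV", "aliphatic")),
               25 + 2.9 * 25 + 3.9 * 50)
  # mean-of-weights scales against a naive table-lookup oracle
  fix <- fixture_table()
  aa_ok <- fix$junction_aa[!is.na(fix$junction_aa)]
  for (prop in c("gravy", "polarity", "bulkiness", "basicity", "acidity",
                 "atchley_f1", "atchley_f3", "kidera_f1", "kidera_f7")) {
    expect_equal(dist_values(aa_property_distribution(fix, prop)),
                 o_aa_mean(aa_ok, aa_property_scales[[prop]]),
                 tolerance = 1e-12, label = prop)
  }
  # records with non-standard letters are skipped
  expect_equal(attr(aa_property_distribution(c("CAK", "CXK"), "gravy"), "n_source"), 1L)
  expect_error(aa_property_distribution("X", "gravy"), "no usable")
})

test_that("amino-acid k-mer counts enumerate overlapping windows", {
  expect_equal(counts_sorted(aa_kmer_counts("CAR", k = 2)), c(AR = 1, CA = 1))
  expect_equal(counts_sorted(aa_kmer_counts("AAA", k = 1)), c(A = 3))
  fix <- fixture_table()
  for (k in 1:3) {
    got <- aa_kmer_counts(fix, k = k)
    aa_ok <- fix$junction_aa[!is.na(fix$junction_aa)]
    expect_equal(counts_sorted(got), o_kmers(aa_ok, k))
    expect_equal(sum(got$count), sum(pmax(nchar(aa_ok) - k + 1, 0)))
  }
  expect_error(aa_kmer_counts(fix, k = 0), ">= 1")
})

test_that("rearrangement lengths copy columns and derive np lengths", {
  tbl <- tibble::tibble(v_3p_deletion = c(0L, 2L, 2L), np1 = c("", "AAG", NA))
  expect_equal(dist_values(rearrangement_length_distribution(tbl, "v_3p_deletion")),
               c(0, 2, 2))
  expect_equal(dist_values(rearrangement_length_distribution(tbl, "np1_length")),
               c(0, 3))
  bad <- tibble::tibble(v_3p_deletion = c(1L, -2L))
  expect_error(rearrangement_length_distribution(bad, "v_3p_deletion"), "negative")
  expect_error(rearrangement_length_distribution(tbl, "np2_length"), "absent")
})

test_that("insertion transition matrices count adjacent pairs and row-normalize", {
  tbl <- tibble::tibble(np1 = "AAG")
  tm <- insertion_transition_matrix(tbl, "np1")
  cm <- transition_matrix(tm, "count")
  expect_equal(cm["A", "A"], 1)
  expect_equal(cm["A", "G"], 1)
  expect_equal(sum(cm), 2)
  pm <- transition_matrix(tm, "prob")
  expect_equal(pm["A", ], c(A = 0.5, C = 0, G = 0.5, T = 0))
  expect_error(insertion_transition_matrix(tibble::tibble(np1 = c("A", "G", "")),
                                           "np1"), "length >= 2")
  fix <- fixture_table()
  for (w in c("np1", "np2")) {
    got <- transition_matrix(insertion_transition_matrix(fix, w), "count")
    expect_equal(got, o_transitions(fix[[w]]))
    probs <- transition_matrix(insertion_transition_matrix(fix, w), "prob")
    rs <- rowSums(probs)
    expect_true(all(abs(rs[rowSums(got) > 0] - 1) < 1e-12))
    expect_true(all(rs[rowSums(got) == 0] == 0))
  }
})

test_that("germline distances and mutation position gaps match the oracles", {
  tbl <- tibble::tibble(sequence_alignment = c("AAAT", "AAAA"),
                        germline_alignment = c("AAAA", "AAAA"))
  expect_equal(dist_values(germline_distance_distribution(tbl)), c(1, 0))
  fix <- fixture_table()
  expect_equal(dist_values(germline_distance_distribution(fix)),
               as.numeric(o_germline_dist(fix)))
  expect_true(all(dist_values(germline_distance_distribution(fix)) >= 0))
  # mutations at positions 2 and 4 -> one gap of 2
  tbl2 <- tibble::tibble(sequence_alignment = "ATAT",
                         germline_alignment = "AAAA")
  expect_equal(dist_values(positional_mutation_distances(tbl2)), 2)
  # a single mutation contributes nothing
  tbl3 <- tibble::tibble(sequence_alignment = "AAAT",
                         germline_alignment = "AAAA")
  expect_equal(nrow(positional_mutation_distances(tbl3)), 0)
  expect_equal(dist_values(positional_mutation_distances(fix)),
               as.numeric(o_mutation_gaps(fix)))
  expect_true(all(dist_values(positional_mutation_distances(fix)) >= 1))
})

test_that("per-gene substitution rates pool compared positions correctly", {
  tbl <- tibble::tibble(
    v_call = c("IGHV1*01", "IGHV1*01", "IGHV9*01"),
    sequence_alignment = c("AAAT", "AAAA", "ACGT"),
    germline_alignment = c("AAAA", "AAAA", "ACGT"))
  r <- per_gene_substitution_rates(tbl)
  expect_equal(r$rate[r$gene == "IGHV1"], 1 / 8)  # 1 mismatch in 8 positions
  expect_equal(r$rate[r$gene == "IGHV9"], 0)
  expect_true(all(r$rate >= 0 & r$rate <= 1))
  rp <- per_gene_substitution_rates(tbl, per_position = TRUE)
  expect_equal(rp$rate[rp$gene == "IGHV1" & rp$position == 4], 0.5)
  expect_true(all(rp$rate[rp$gene == "IGHV9"] == 0))
})

test_that("in-frame percentage is the mod-3 junction fraction", {
  expect_equal(in_frame_percentage(tibble::tibble(
    junction = c("AAAAAAAAA", "AAAAAAAAAA"))), 50)
  expect_equal(in_frame_percentage(tibble::tibble(junction = c("AAA", "TTTTTT"))), 100)
  f <- in_frame_percentage(fixture_table())
  expect_gte(f, 0); expect_lte(f, 100)
  expect_equal(f, 100 * 5 / 6)
  expect_error(in_frame_percentage(tibble::tibble(junction = NA_character_)))
})

test_that("cluster sizes conserve the number of clustered records", {
  expect_equal(sort(dist_values(cluster_size_distribution(
    tibble::tibble(clone_id = c("1", "1", "2"))))), c(1, 2))
  all_distinct <- tibble::tibble(clone_id = as.character(1:5))
  expect_equal(dist_values(cluster_size_distribution(all_distinct)), rep(1, 5))
  fix <- fixture_table()
  expect_equal(sum(dist_values(cluster_size_distribution(fix))),
               sum(!is.na(fix$clone_id)))
  expect_error(cluster_size_distribution(tibble::tibble(x = 1)), "absent")
})

test_that("Hill numbers interpolate richness, Shannon and Simpson forms", {
  expect_equal(hill_diversity(c(a = 3, b = 1), q = 2), 1.6)
  expect_equal(hill_diversity(c(a = 1, b = 1, c = 1, d = 1), q = 0), 4)
  expect_equal(hill_diversity(c(a = 1, b = 1, c = 1, d = 1), q = 1), 4)
  expect_equal(hill_diversity(c(a = 1, b = 1, c = 1, d = 1), q = 2.7), 4)
  expect_equal(hill_diversity(c(a = 5, b = 3, c = 2), q = 0), 3)
  for (q in c(0, 0.5, 1, 2)) {
    expect_equal(hill_diversity(c(a = 5, b = 3, c = 2), q = q),
                 o_hill(c(5, 3, 2), q), label = paste("q =", q))
  }
  expect_error(hill_diversity(c(a = 1), q = -1), "nonnegative")
})

test_that("tree shape indices match hand-derived values", {
  balanced <- ape::read.tree(text = "((a,b),(c,d));")
  caterpillar <- ape::read.tree(text = "(((a,b),c),d);")
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_equal(dist_values(tree_shape_indices(list(balanced), "sackin")), 8)
  expect_equal(dist_values(tree_shape_indices(list(caterpillar), "sackin")), 9)
  expect_equal(dist_values(tree_shape_indices(list(star), "cophenetic")), 0)
  # balanced 4-leaf: cherries (a,b), (c,d) have MRCA depth 1; cross pairs 0
  expect_equal(dist_values(tree_shape_indices(list(balanced), "cophenetic")), 2)
  # Colless-like, 3-leaf caterpillar ((a,b),c): by hand with f(n) = ln(n+e):
  # delta(leaf) = f(1); delta(cherry) = f(2) + 2 f(1); the root's children
  # have deltas {f(2) + 2 f(1), f(1)} with mean deviation |diff| / 2
  f <- function(n) log(n + exp(1))
  cat3 <- ape::read.tree(text = "((a,b),c);")
  expect_equal(dist_values(tree_shape_indices(list(cat3), "colless_like")),
               (f(2) + f(1)) / 2)
  # fully balanced trees have zero Colless-like imbalance
  expect_equal(dist_values(tree_shape_indices(list(balanced), "colless_like")), 0)
  # single-leaf trees are skipped; empty sets error
  expect_equal(nrow(tree_shape_indices(list(balanced, ape::read.tree(text = "(a);")),
                                       "sackin")), 1)
  expect_error(tree_shape_indices(list(), "sackin"), "empty")
})

test_that("summary distributions are invariant to record order", {
  fix <- fixture_table()
  perm <- fix[c(4, 1, 6, 3, 5, 2), ]
  for (s in c("gc_content", "cdr3_length", "germline_distance", "hotspot_count")) {
    expect_equal(sort(dist_values(compute_summary(fix, s))),
                 sort(dist_values(compute_summary(perm, s))), label = s)
  }
  expect_equal(counts_sorted(compute_summary(fix, "vdj_gene_usage")),
               counts_sorted(compute_summary(perm, "vdj_gene_usage")))
})
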