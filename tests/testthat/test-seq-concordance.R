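test_that("pairwise change counting matches hand values and the DP oracle", {
  expect_equal(pairwise_changes("ACGT", "ACGT"), list(changes = 0L, identity = 1))
  expect_equal(pairwise_changes("ACGT", "ACGA"), list(changes = 1L, identity = 0.75))
  expect_equal(pairwise_changes("ACGTA", "ACGT"), list(changes = 1L, identity = 4 / 5))
  expect_error(pairwise_changes("", "ACGT"), "empty")
  set.seed(41)
  for (k in 1:25) {
    a <- rand_seq(sample(10:40, 1)); b <- rand_seq(sample(10:40, 1))
    expect_equal(pairwise_changes(a, b)$changes, oracle_edit_distance(a, b))
  }
})

test_that("pairwise changes are symmetric and edit-triangle bounded", {
  set.seed(42)
  for (k in 1:20) {
    a <- rand_seq(30); b <- mutate_n(a, sample(1:6, 1)); c <- rand_seq(30)
    ab <- pairwise_changes(a, b)$changes
    expect_identical(ab, pairwise_changes(b, a)$changes)
    expect_lte(pairwise_changes(a, c)$changes,
               ab + pairwise_changes(b, c)$changes)
    expect_equal(pairwise_changes(a, a)$identity, 1)
  }
})

test_that("exact overlap partitions sequences and conserves reads", {
  mk <- function(id, counts, seqs) toy_set(id, counts, seqs)
  one <- function(reads, seq, id) mk(id,
    count_matrix(matrix(as.integer(reads), length(reads), 1),
                 features = paste0(id, "_f", seq_along(reads))), seq)
  # full three-way overlap
  A <- one(10, "AAAA", "A"); B <- one(20, "AAAA", "B"); C <- one(30, "AAAA", "C")
  ov <- exact_overlap(list(A, B, C))
  abc <- ov[ov$compartment == "A&B&C", ]
  expect_equal(abc$n_sequences, 1)
  expect_equal(abc$n_reads, 60)
  expect_equal(abc$pct_reads, 1)
  # disjoint pair
  ov <- exact_overlap(list(one(10, "AAAA", "A"), one(20, "CCCC", "B")))
  expect_equal(ov$n_reads[ov$compartment == "A"], 10)
  expect_equal(ov$n_reads[ov$compartment == "B"], 20)
  expect_equal(ov$n_reads[ov$compartment == "A&B"], 0)
  # chain overlap: A={x}, B={x,y}, C={y}, 5 reads each
  A <- one(5, "AAAA", "A")
  B <- mk("B", count_matrix(matrix(c(5L, 5L), 2, 1),
                            features = c("b1", "b2")), c("AAAA", "CCCC"))
  C <- one(5, "CCCC", "C")
  ov <- exact_overlap(list(A, B, C))
  expect_equal(ov$n_reads[ov$compartment == "A&B"], 10)
  expect_equal(ov$n_reads[ov$compartment == "B&C"], 10)
  expect_equal(sum(ov$n_reads), 20)
})

test_that("duplicate centroid strings are merged for accounting, with warning", {
  s <- toy_set("dup", count_matrix(matrix(c(4L, 6L, 3L), 3, 1)),
               c("AAAA", "AAAA", "CCCC"))
  t2 <- toy_set("o", count_matrix(matrix(13L, 1, 1)), "AAAA")
  expect_warning(ov <- exact_overlap(list(s, t2)), "duplicate")
  expect_equal(ov$n_reads[ov$compartment == "dup&o"], 10 + 13)
  expect_equal(sum(ov$n_reads), 26)
})

test_that("origin breakdown partitions sequences and reads exactly", {
  s <- toy_set("x", count_matrix(matrix(c(6L, 2L, 2L), 3, 1)),
               c("AAAA", "CCCC", "GGGG"),
               origin = c(f1 = "reference", f2 = "de_novo", f3 = "de_novo"))
  ob <- origin_breakdown(s)
  expect_equal(sum(ob$n_sequences), 3)
  expect_equal(sum(ob$n_reads), 10)
  expect_equal(ob$pct_reads[ob$origin == "reference"], 0.6)
  expect_equal(ob$pct_reads[ob$origin == "de_novo"], 0.4)
})

test_that("difference profile follows hand-designed neighbour structures", {
  # three equal-length sequences mutually 1 change apart
  base <- "ACGTACGTACGTACGTACGT"
  s <- toy_set("tri", count_matrix(matrix(5L, 3, 1)),
               c(base, sub("^A", "C", base), sub("^A", "G", base)))
  dp <- difference_profile(s, max_changes = 5)
  expect_equal(dp$cum_fraction[1], 1)
  # two sequences 10 changes apart: step at 10
  set.seed(9)
  a <- rand_seq(40); b <- mutate_n(a, 10)
  d <- pairwise_changes(a, b)$changes   # mutations may collide; use actual
  s <- toy_set("pair", count_matrix(matrix(5L, 2, 1)), c(a, b))
  dp <- difference_profile(s, max_changes = 15)
  expect_true(all(dp$cum_fraction[seq_len(d - 1)] == 0))
  expect_true(all(dp$cum_fraction[d:15] == 1))
  # a stratum with fewer than 2 sequences is empty and flagged
  s1 <- toy_set("one", count_matrix(matrix(5L, 1, 1)), a)
  dp <- difference_profile(s1, 5)
  expect_true(attr(dp, "empty"))
  expect_equal(nrow(dp), 0)
})

test_that("difference profiles stratify by cluster origin", {
  base <- "ACGTACGTACGTACGTACGTACGTACGTACGT"
  seqs <- c(base, sub("^A", "C", base), sub("^AC", "CA", base), rand_seq(32))
  s <- toy_set("str", count_matrix(matrix(4L, 4, 1)), seqs,
               origin = setNames(c("reference", "reference", "de_novo",
                                   "de_novo"), paste0("f", 1:4)))
  ref <- difference_profile(s, 5, stratum = "reference")
  expect_equal(attr(ref, "n_centroids"), 2)
  expect_equal(ref$cum_fraction[1], 1)   # the two references are 1 apart
  dn <- difference_profile(s, 5, stratum = "de_novo")
  expect_equal(attr(dn, "n_centroids"), 2)
})

test_that("difference profile equals the all-pairs oracle on random fixtures", {
  set.seed(13)
  for (rep in 1:3) {
    # clusters of near-identical sequences plus unrelated background, with
    # identities far from the 0.75 gate so co-optimal alignments cannot
    # flip neighbour eligibility
    core <- rand_seq(60)
    seqs <- unique(c(core,
                     vapply(1:4, function(i) mutate_n(core, sample(1:5, 1)), ""),
                     vapply(1:6, function(i) rand_seq(60), "")))
    s <- toy_set("r", count_matrix(matrix(2L, length(seqs), 1)), seqs)
    got <- difference_profile(s, max_changes = 12)$cum_fraction
    want <- oracle_difference_profile(seqs, 12, 0.75)
    expect_equal(got, want)
  }
})

test_that("cumulative difference fractions never decrease with N", {
  sets <- default_bundle()$sets
  for (s in sets) {
    dp <- difference_profile(s, max_changes = 10)
    expect_true(all(diff(dp$cum_fraction) >= 0))
    expect_true(all(dp$cum_fraction >= 0 & dp$cum_fraction <= 1))
  }
})

test_that("expected identity follows (L - N) / L", {
  expect_equal(expected_identity(135, 0), 1)
  expect_equal(expected_identity(100, 3), 0.97)
  expect_equal(expected_identity(127, 1), 126 / 127)  # ~0.992, one change in
  # the shortest V3 amplicon, i.e. roughly 99% identity
  expect_error(expected_identity(10, 11), "exceed")
})

test_that("greedy resilience clustering straddles thresholds correctly", {
  set.seed(21)
  # two sequences at 90% identity (length 50, 5 substitutions)
  a <- rand_seq(50); b <- mutate_n(a, 5)
  idn <- pairwise_changes(a, b)$identity
  s <- toy_set("two", count_matrix(matrix(c(9L, 5L), 2, 1)), c(a, b))
  rc <- resilience_curve(s, thresholds = c(0.99, idn + 0.02, idn - 0.02))
  expect_equal(rc$remaining_fraction, c(1, 1, 0.5))
  # mutually dissimilar set does not merge at high thresholds
  seqs <- vapply(1:5, function(i) rand_seq(50), "")
  s <- toy_set("far", count_matrix(matrix(3L, 5, 1)), seqs)
  rc <- resilience_curve(s, thresholds = c(1, 0.95, 0.9))
  expect_equal(rc$remaining_fraction, c(1, 1, 1))
})

test_that("resilience is monotone and matches the greedy-replay oracle", {
  set.seed(22)
  core1 <- rand_seq(60); core2 <- rand_seq(60)
  seqs <- unique(c(core1, mutate_n(core1, 2), mutate_n(core1, 6),
                   core2, mutate_n(core2, 3), rand_seq(60)))
  reads <- seq(60L, by = -10L, length.out = length(seqs))
  s <- toy_set("mix", count_matrix(matrix(reads, length(seqs), 1)), seqs)
  thresholds <- seq(1, 0.75, by = -0.02)
  rc <- resilience_curve(s, thresholds)
  expect_true(all(diff(rc$remaining_fraction) <= 0))
  expect_equal(rc$remaining_fraction[1], 1)    # distinct sequences at t = 1
  # oracle replay: same abundance-then-lexicographic order, same identities
  ord <- order(-reads, seqs)
  idn <- change_matrix(setNames(seqs[ord], seqs[ord]))$identity
  for (k in seq_along(thresholds))
    expect_equal(rc$n_centroids[k],
                 oracle_greedy_centroids(idn, thresholds[k]))
})
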