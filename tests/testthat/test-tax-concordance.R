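lin7 <- function(...) {
  labs <- c(...)
  matrix(c(labs, rep("", 7 - length(labs))), nrow = 1)
}

test_that("informativeness is the non-empty label at the level", {
  t1 <- c("Bacteria", "Proteobacteria", rep("", 5))
  expect_true(is_informative(t1, 2))
  expect_false(is_informative(t1, 3))
  full <- c("B", "P", "C", "O", "F", "G", "S")
  expect_true(is_informative(full, 7))
})

test_that("resolution profile weights reads by informative features", {
  lin <- rbind(lin7("B", "P", "C", "O", "Fam"),
               lin7("B", "P", "C", "O", "Fam", "G", "S"))
  rownames(lin) <- c("f1", "f2")
  s <- toy_set("x", count_matrix(matrix(c(10L, 30L), 2, 1)), c("AAAA", "CCCC"),
               lineages = lin)
  rp <- resolution_profile(s)
  expect_equal(rp$pct_reads_informative[5], 1)       # both have a family
  expect_equal(rp$pct_reads_informative[7], 30 / 40) # only f2 has a species
  expect_equal(rp$n_informative_taxa[7], 1)
  # fully resolved set: 100% everywhere
  s2 <- toy_set("y", count_matrix(matrix(c(10L, 30L), 2, 1)),
                c("AAAA", "CCCC"),
                lineages = rbind(lin7("B", "P", "C", "O", "F", "G", "S1"),
                                 lin7("B", "P", "C", "O", "F", "G", "S2")))
  expect_true(all(resolution_profile(s2)$pct_reads_informative == 1))
})

test_that("resolution is monotone non-increasing with depth", {
  for (s in filtered_sets()) {
    rp <- resolution_profile(s)
    expect_true(all(diff(rp$pct_reads_informative) <= 1e-12))
  }
})

test_that("LCA attribution splits species-missing reads by reference labels", {
  lin <- rbind(lin7("B", "P", "C", "O", "F", "G1"),
               lin7("B", "P", "C", "O", "F", "G2"),
               lin7("B", "P", "C", "O", "F", "G3", "S"))
  rownames(lin) <- c("f1", "f2", "f3")
  s <- toy_set("x", count_matrix(matrix(c(30L, 10L, 5L), 3, 1)),
               c("AAAA", "CCCC", "GGGG"), lineages = lin)
  refmap <- c("B; P; C; O; F; G1" = TRUE, "B; P; C; O; F; G2" = FALSE)
  at <- lca_attribution(s, refmap)
  expect_equal(at$pct_missing_due_to_lca, 0.75)      # 30 of 40 missing reads
  expect_equal(at$pct_missing_due_to_no_label, 0.25)
  expect_equal(at$n_features_missing_species, 2)
  # all-no-label and all-LCA extremes
  expect_equal(lca_attribution(s, c("B; P; C; O; F; G1" = FALSE,
                                    "B; P; C; O; F; G2" = FALSE))$
                 pct_missing_due_to_no_label, 1)
  expect_equal(lca_attribution(s, c("B; P; C; O; F; G1" = TRUE,
                                    "B; P; C; O; F; G2" = TRUE))$
                 pct_missing_due_to_lca, 1)
  # unknown lineages fall back to LCA with a warning
  expect_warning(at2 <- lca_attribution(s, c("B; P; C; O; F; G1" = FALSE)),
                 "absent")
  expect_equal(at2$pct_missing_due_to_lca, 0.25)
})

test_that("taxa overlap conserves reads per level on the synthetic bundle", {
  fs <- filtered_sets()
  total <- sum(vapply(fs, function(s) sum(s$table), 0))
  for (lv in c(2, 5, 7)) {
    ov <- taxa_overlap(fs, lv)
    expect_equal(sum(ov$n_reads), total)
  }
})

test_that("cross-set Spearman correlation matches a rank-then-Pearson oracle", {
  mk <- function(id, counts, lineages) {
    toy_set(id, counts, vapply(seq_len(nrow(counts)),
                               function(i) rand_seq(20), ""),
            lineages = lineages)
  }
  set.seed(31)
  lin <- do.call(rbind, lapply(1:4, function(i)
    lin7("B", "P", "C", "O", "F", paste0("G", i), paste0("S", i))))
  rownames(lin) <- paste0("f", 1:4)
  a <- mk("a", count_matrix(matrix(c(10L, 5L, 1L, 2L), 4, 1)), lin)
  b <- mk("b", count_matrix(matrix(c(8L, 6L, 1L, 2L), 4, 1)), lin)
  r <- cross_set_correlation(a, b, 7)
  va <- c(10, 5, 1, 2) / 18; vb <- c(8, 6, 1, 2) / 17
  expect_equal(r$rho, oracle_spearman(va, vb))
  expect_equal(r$n_taxa, 4)
  # identical vectors give rho exactly 1; self-correlation is 1
  expect_equal(cross_set_correlation(a, a, 7)$rho, 1)
  # perfectly reversed ranks give -1
  b2 <- mk("b2", count_matrix(matrix(c(1L, 2L, 10L, 5L), 4, 1)), lin)
  expect_equal(cross_set_correlation(a, b2, 7)$rho, -1)
  # under 3 taxa in the union: undefined and flagged
  lin2 <- lin[1:2, , drop = FALSE]
  small_a <- mk("sa", count_matrix(matrix(c(5L, 5L), 2, 1)), lin2)
  r2 <- cross_set_correlation(small_a, small_a, 7)
  expect_true(is.na(r2$rho))
  expect_match(r2$flagged, "fewer")
})

test_that("absent taxa enter the correlation union with zero abundance", {
  lin <- do.call(rbind, lapply(1:3, function(i)
    lin7("B", "P", "C", "O", "F", paste0("G", i), paste0("S", i))))
  rownames(lin) <- paste0("f", 1:3)
  a <- toy_set("a", count_matrix(matrix(c(6L, 3L, 1L), 3, 1)),
               c("AAAA", "CCCC", "GGGG"), lineages = lin)
  linb <- lin[1:2, , drop = FALSE]
  b <- toy_set("b", count_matrix(matrix(c(6L, 4L), 2, 1)),
               c("AAAA", "CCCC"), lineages = linb)
  r <- cross_set_correlation(a, b, 7)
  expect_equal(r$n_taxa, 3)
  expect_equal(r$rho, oracle_spearman(c(6, 3, 1) / 10, c(6, 4, 0) / 10))
})

test_that("the differential screen splits taxa at the abundance ratio", {
  lin <- do.call(rbind, lapply(1:3, function(i)
    lin7("B", "P", "C", "O", "F", paste0("G", i), paste0("S", i))))
  rownames(lin) <- paste0("f", 1:3)
  # ref: 9%, 3%, 0%; other: 1%, 3%, 5% (of 100 reads each)
  ref <- toy_set("ref", count_matrix(matrix(c(9L, 3L, 88L), 3, 1)),
                 c("AAAA", "CCCC", "GGGG"), lineages = lin)
  oth <- toy_set("oth", count_matrix(matrix(c(1L, 3L, 96L), 3, 1)),
                 c("AAAA", "CCCC", "GGGG"),
                 lineages = {
                   l <- lin
                   rownames(l) <- paste0("f", 1:3); l })
  d <- differential_taxa(ref, list(oth), 7)
  g1 <- d[grepl("G1", d$taxon), ]
  expect_equal(g1$category, "reference_predominant")  # 1% < (1/3) * 9%
  g2 <- d[grepl("G2", d$taxon), ]
  expect_equal(g2$category, "other")                  # 3% >= 1%
  # ref-absent taxon always lands in the complement list, flagged
  lin4 <- rbind(lin, lin7("B", "P", "C", "O", "F", "G4", "S4"))
  rownames(lin4) <- paste0("f", 1:4)
  oth2 <- toy_set("oth2", count_matrix(matrix(c(1L, 3L, 91L, 5L), 4, 1)),
                  c("AAAA", "CCCC", "GGGG", "TTTT"), lineages = lin4)
  d2 <- differential_taxa(ref, list(oth2), 7)
  g4 <- d2[grepl("G4", d2$taxon), ]
  expect_equal(g4$category, "other")
  expect_equal(g4$flag, "ref-absent")
})
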