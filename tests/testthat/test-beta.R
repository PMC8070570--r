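test_that("average rarefied tables keep exact column sums", {
  b <- default_bundle()
  tab <- b$sets[["03_ASV"]]$table[, 1:4]
  avg <- average_rarefied_table(tab, depth = 500, n_draws = 7, seed = 3)
  expect_equal(unname(colSums(avg)), rep(500, 4))
  # a single draw equals one rarefaction under the same seed
  a1 <- average_rarefied_table(tab, depth = 500, n_draws = 1, seed = 11)
  set.seed(11)
  manual <- vapply(seq_len(ncol(tab)),
                   function(j) rarefy_counts(tab[, j], 500), numeric(nrow(tab)))
  expect_equal(unname(a1), unname(manual))
})

test_that("average rarefied means approach the hypergeometric expectation", {
  tab <- count_matrix(matrix(c(50L, 50L), 2, 1))
  avg <- average_rarefied_table(feature_table(tab), depth = 10,
                                n_draws = 4000, seed = 5)
  se <- sqrt(10 * 0.5 * 0.5 * 90 / 99) / sqrt(4000)
  expect_lt(abs(avg[1, 1] - 5), 4 * se)
})

test_that("Bray-Curtis and Jaccard match hand values and bounds", {
  expect_equal(bray_curtis(c(6, 2, 0), c(2, 2, 0)), 1 / 3)
  expect_equal(jaccard_binary(c(6, 2, 0), c(2, 2, 0)), 0)
  x <- c(3, 0, 5); expect_equal(bray_curtis(x, x), 0)
  expect_equal(jaccard_binary(x, x), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 4)), 1)   # disjoint supports
  expect_equal(jaccard_binary(c(1, 0), c(0, 4)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("UniFrac matches hand-enumerated branch accounting", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 5, B = 0, C = 0, D = 0)
  y <- c(A = 0, B = 0, C = 3, D = 0)
  expect_equal(unifrac(tree, x, y, "unweighted"), 1)
  expect_equal(unifrac(tree, x, y, "weighted_raw"), 4)
  expect_equal(unifrac(tree, x, y, "weighted_normalized"), 1)
  # identical compositions are at distance zero in every mode
  z <- c(A = 2, B = 1, C = 1, D = 0)
  for (m in c("unweighted", "weighted_raw", "weighted_normalized"))
    expect_equal(unifrac(tree, z, z, m), 0)
  # star tree with unit branches, disjoint communities
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unifrac(star, x, y, "unweighted"), 1)
  # features absent from the tree are an error naming them
  expect_error(unifrac(tree, c(A = 1, E = 1), c(C = 1), "unweighted"), "E")
})

test_that("beta_distance builds valid symmetric hollow matrices", {
  b <- default_bundle()
  s <- b$sets[["03_ASV"]]
  avg <- average_rarefied_table(s$table[, 1:6], depth = 400, n_draws = 5,
                                seed = 2)
  for (m in c("braycurtis", "jaccard", "unweighted_unifrac",
              "weighted_unifrac")) {
    D <- beta_distance(avg, m, tree = s$tree)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
  }
  expect_error(beta_distance(avg, "weighted_unifrac", tree = NULL), "tree")
})

test_that("PCoA recovers planted geometry", {
  # three collinear points at distances 1, 1, 2
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  ord <- pcoa(D)
  got <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(got), unname(D), tolerance = 1e-9)
  expect_lt(abs(ord$eigenvalues[2]), 1e-9)
  # four corners of a square: two equal leading eigenvalues
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  Dsq <- as.matrix(dist(pts))
  dimnames(Dsq) <- list(paste0("s", 1:4), paste0("s", 1:4))
  osq <- pcoa(Dsq)
  expect_equal(osq$eigenvalues[1], osq$eigenvalues[2], tolerance = 1e-9)
  # Euclidean input embeds without negative eigenvalues
  expect_equal(osq$n_negative_eigenvalues, 0)
  expect_error(pcoa(D[1:2, 1:2]), "3")
})

test_that("ANOSIM attains R = 1 under perfect separation and is rank-invariant", {
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  r <- anosim(D, g)
  expect_equal(r$R, 1)
  expect_equal(r$method, "exhaustive")
  # monotone transform of distances leaves the rank statistic unchanged
  r2 <- anosim(D^2, g)
  expect_equal(r2$R, r$R)
  expect_equal(r2$p_value, r$p_value)
  expect_error(anosim(D, c("a", "a", "a", "a", "a", "b")), "singleton")
})

test_that("pairwise post hoc ANOSIM adjusts p-values over group pairs", {
  set.seed(8)
  pts <- c(rnorm(3), rnorm(3, 5), rnorm(3, 10))
  D <- as.matrix(dist(pts))
  ids <- paste0("s", 1:9)
  dimnames(D) <- list(ids, ids)
  g <- rep(c("a", "b", "c"), each = 3)
  ph <- anosim_pairwise(D, g, seed = 1)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adjusted >= ph$p_value - 1e-12))
  expect_true(all(ph$p_adjusted <= 1))
})
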