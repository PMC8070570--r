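# Fixtures are built in code.  The default synthetic bundle is generated
# once per test run and reused (generation is seeded and deterministic).

.fixture_env <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    truth <- generate_truth(n_taxa = 40L, seed = 7L)
    .fixture_env$bundle <- render_cluster_sets(truth, n_samples_per_group = 6L,
                                               reads_per_sample = 20000L,
                                               seed = 8L)
  }
  .fixture_env$bundle
}

filtered_sets <- function(bundle = default_bundle()) {
  lapply(bundle$sets, function(s) {
    s$table <- abundance_filter(s$table)$table
    keep <- rownames(s$table)
    s$centroids <- s$centroids[keep]
    s$origin <- s$origin[keep]
    s$taxonomy <- s$taxonomy[keep, , drop = FALSE]
    class(s$taxonomy) <- c("taxonomy_table", "matrix", "array")
    s
  })
}

# a tiny hand-built cluster set
toy_set <- function(set_id = "toy", counts, seqs, lineages = NULL,
                    origin = NULL) {
  ft <- feature_table(counts)
  if (is.null(lineages)) {
    lineages <- matrix("", nrow(counts), 7,
                       dimnames = list(rownames(counts), NULL))
    lineages[, 1] <- "Bacteria"
    lineages[, 2] <- paste0("P", seq_len(nrow(counts)))
  }
  rownames(lineages) <- rownames(counts)
  cluster_set(set_id, ft, setNames(seqs, rownames(counts)),
              taxonomy_table(lineages), origin = origin)
}

count_matrix <- function(m, features = NULL, samples = NULL) {
  if (is.null(features)) features <- paste0("f", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  m
}

# random DNA helper for oracle fixtures
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

mutate_n <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}
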