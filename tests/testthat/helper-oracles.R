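# Independent oracles used across tests.  These deliberately take different
# routes than the package code: plain DP / enumeration / reference packages.

# unit-cost edit distance by plain dynamic programming (no adist)
oracle_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  m <- length(x); n <- length(y)
  prev <- 0:n
  for (i in seq_len(m)) {
    cur <- numeric(n + 1L); cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (x[i] != y[j]),
                         prev[j + 1L] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  prev[n + 1L]
}

# alignment-based changes/identity via Biostrings (independent aligner)
oracle_alignment <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  al <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 1,
                                      type = "global")
  cols <- nchar(as.character(Biostrings::pattern(al)))
  list(changes = -Biostrings::score(al),
       identity = Biostrings::nmatch(al) / cols)
}

# all-pairs nearest-neighbour difference profile by explicit loops
oracle_difference_profile <- function(seqs, max_changes, min_identity) {
  n <- length(seqs)
  nearest <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      o <- oracle_alignment(seqs[i], seqs[j])
      if (o$identity >= min_identity)
        nearest[i] <- min(nearest[i], o$changes, na.rm = TRUE)
    }
  }
  vapply(seq_len(max_changes),
         function(k) sum(!is.na(nearest) & nearest <= k) / n, 0)
}

# greedy clustering replayed from scratch on a supplied identity matrix
oracle_greedy_centroids <- function(idn_ordered, t) {
  n <- nrow(idn_ordered)
  cent <- integer(0)
  for (i in seq_len(n)) {
    if (!length(cent) || max(idn_ordered[i, cent]) < t)
      cent <- c(cent, i)
  }
  length(cent)
}

# per-branch UniFrac by explicit descendant enumeration (phangorn route)
oracle_unifrac <- function(tree, x, y, mode) {
  feats <- union(names(x)[x > 0], names(y)[y > 0])
  tr <- if (length(setdiff(tree$tip.label, feats)))
    ape::keep.tip(tree, feats) else tree
  desc <- phangorn::Descendants(tr, tr$edge[, 2L], "tips")
  px <- py <- numeric(nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    tips <- tr$tip.label[desc[[e]]]
    px[e] <- sum(x[intersect(tips, names(x))]) / sum(x)
    py[e] <- sum(y[intersect(tips, names(y))]) / sum(y)
  }
  len <- tr$edge.length
  switch(mode,
    unweighted = sum(len[xor(px > 0, py > 0)]) / sum(len[px > 0 | py > 0]),
    weighted_raw = sum(len * abs(px - py)),
    weighted_normalized = sum(len * abs(px - py)) / sum(len * (px + py)))
}

# Spearman by explicit rank-then-Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ANOSIM R from first principles (no shared code with the implementation)
oracle_anosim_R <- function(D, groups) {
  n <- nrow(D)
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(D[lower.tri(D)])
  within <- c(); between <- c()
  for (i in 2:n) for (j in 1:(i - 1)) {
    if (groups[i] == groups[j]) within <- c(within, rk[i, j])
    else between <- c(between, rk[i, j])
  }
  (mean(between) - mean(within)) / (n * (n - 1) / 4)
}

# exhaustive ANOSIM p for two groups via combn label enumeration
oracle_anosim_exact_p <- function(D, groups) {
  n <- nrow(D)
  levs <- unique(groups)
  stopifnot(length(levs) == 2L)
  k <- sum(groups == levs[1L])
  obs <- oracle_anosim_R(D, groups)
  sel <- combn(n, k)
  Rs <- apply(sel, 2L, function(s) {
    g <- rep(levs[2L], n); g[s] <- levs[1L]
    oracle_anosim_R(D, g)
  })
  # label swaps give duplicate assignments only when group sizes are equal;
  # enumeration over choose(n, k) is the distinct-assignment set when the
  # two labels are distinguishable, which is what the implementation uses
  sum(Rs >= obs - 1e-12) / length(Rs)
}
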