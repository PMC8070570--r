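#' Count nucleotide changes between two sequences
#'
#' Global end-to-end alignment at unit cost (match 0, mismatch 1, indel 1),
#' i.e. Levenshtein edit distance.  `changes` counts mismatches plus gap
#' columns; `identity` is matching columns over alignment columns of the
#' optimal transcript.
#'
#' @param a,b non-empty A/C/G/T strings.
#' @return list with integer `changes` and fractional `identity`.
#' @export
pairwise_changes <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  d <- adist(a, b, counts = TRUE)
  cnt <- attr(d, "counts")
  ins <- cnt[1L, 1L, "ins"]; del <- cnt[1L, 1L, "del"]
  sub <- cnt[1L, 1L, "sub"]
  matches <- nchar(a) - del - sub
  cols <- matches + sub + ins + del
  list(changes = as.integer(d[1L, 1L]), identity = unname(matches / cols))
}

#' All-pairs change and identity matrices
#'
#' Vectorised [pairwise_changes()] over a set of sequences.
#'
#' @param seqs character vector of A/C/G/T strings.
#' @return list of two symmetric matrices, `changes` and `identity`.
#' @export
change_matrix <- function(seqs) {
  d <- adist(seqs, seqs, counts = TRUE)
  cnt <- attr(d, "counts")
  lens <- nchar(seqs)
  matches <- outer(lens, rep(1, length(seqs))) -
    cnt[, , "del"] - cnt[, , "sub"]
  cols <- matches + cnt[, , "sub"] + cnt[, , "ins"] + cnt[, , "del"]
  idn <- matches / cols
  dimnames(d) <- dimnames(idn) <- list(names(seqs), names(seqs))
  list(changes = d, identity = idn)
}

#' Exact centroid-sequence overlap between cluster sets
#'
#' Partitions the union of centroid sequences into Venn compartments by
#' exact string equality and weights each compartment by reads: for every
#' set containing a sequence, that set's cluster total reads are added.
#' Sequence percentages are taken against the size of the union; read
#' percentages against the grand total of reads over all sets, so
#' compartment reads sum exactly to the sum of set totals.
#'
#' @param sets list of 2-3 [cluster_set()]s.
#' @return data.frame with one row per non-empty subset of sets
#'   (`compartment`, `n_sequences`, `n_reads`, `pct_sequences`,
#'   `pct_reads`), class `overlap_partition`.
#' @export
exact_overlap <- function(sets) {
  if (length(sets) < 2L || length(sets) > 3L)
    stop("exact_overlap compares 2 or 3 sets")
  ids <- vapply(sets, function(s) s$set_id, "")
  # per set: reads per unique centroid string (duplicates merged, warned)
  per_set <- lapply(sets, function(s) {
    reads <- rowSums(s$table)
    if (anyDuplicated(s$centroids))
      warning(s$set_id, ": duplicate centroid strings merged for accounting",
              call. = FALSE)
    tapply(reads, s$centroids, sum)
  })
  overlap_partition(per_set, ids)
}

overlap_partition <- function(per_set, ids) {
  union_keys <- unique(unlist(lapply(per_set, names), use.names = FALSE))
  member <- vapply(per_set, function(r) union_keys %in% names(r),
                   logical(length(union_keys)))
  member <- matrix(member, nrow = length(union_keys), dimnames = list(NULL, ids))
  reads_by_key <- vapply(seq_along(per_set), function(i) {
    r <- rep(0, length(union_keys))
    r[member[, i]] <- as.numeric(per_set[[i]][union_keys[member[, i]]])
    r
  }, numeric(length(union_keys)))
  reads_by_key <- matrix(reads_by_key, nrow = length(union_keys))
  total_reads <- sum(reads_by_key)
  n_union <- length(union_keys)
  subsets <- lapply(seq_len(2L^length(ids) - 1L), function(m) {
    which(bitwAnd(m, 2L^(seq_along(ids) - 1L)) > 0L)
  })
  rows <- lapply(subsets, function(s) {
    in_comp <- rowSums(member[, s, drop = FALSE]) == length(s) &
      rowSums(member[, -s, drop = FALSE] == TRUE) == 0L
    if (length(ids) == length(s))
      in_comp <- rowSums(member) == length(s)
    nr <- sum(reads_by_key[in_comp, s, drop = FALSE])
    data.frame(compartment = paste(ids[s], collapse = "&"),
               n_sequences = sum(in_comp), n_reads = nr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pct_sequences <- if (n_union > 0) out$n_sequences / n_union else 0
  out$pct_reads <- if (total_reads > 0) out$n_reads / total_reads else 0
  class(out) <- c("overlap_partition", class(out))
  out
}

#' Per-origin breakdown of a cluster set
#'
#' Splits a set's sequences and reads by cluster origin (reference-matched
#' vs de novo vs unknown).
#'
#' @param set a [cluster_set()].
#' @return data.frame with `origin`, `n_sequences`, `n_reads`, `pct_reads`.
#' @export
origin_breakdown <- function(set) {
  reads <- rowSums(set$table)
  levs <- intersect(c("reference", "de_novo", "unknown"), unique(set$origin))
  out <- data.frame(
    origin = levs,
    n_sequences = vapply(levs, function(o) sum(set$origin == o), 0L),
    n_reads = vapply(levs, function(o) sum(reads[set$origin == o]), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  out$pct_reads <- out$n_reads / sum(reads)
  out
}

#' Nearest-neighbour nucleotide-difference profile
#'
#' For each centroid, finds the smallest number of changes to any other
#' centroid in the stratum whose pairwise identity is at least
#' `min_identity`; `cum_fraction(N)` is the fraction of stratum centroids
#' whose nearest qualifying neighbour is at most N changes away.  Centroids
#' with no qualifying neighbour are never counted.
#'
#' @param set a [cluster_set()].
#' @param max_changes largest N reported.
#' @param min_identity neighbour eligibility gate (default 75%, a lower
#'   bound close to the identity of related phyla).
#' @param stratum `"all"`, `"reference"` or `"de_novo"`.
#' @return data.frame `N`, `cum_fraction`, with attributes `n_centroids`
#'   and `empty` (TRUE when the stratum has fewer than 2 sequences).
#' @export
difference_profile <- function(set, max_changes = 20L, min_identity = 0.75,
                               stratum = c("all", "reference", "de_novo")) {
  stratum <- match.arg(stratum)
  keep <- if (stratum == "all") rep(TRUE, length(set$centroids))
          else set$origin == stratum
  seqs <- set$centroids[keep]
  if (length(seqs) < 2L) {
    out <- data.frame(N = integer(0), cum_fraction = numeric(0))
    attr(out, "empty") <- TRUE
    attr(out, "n_centroids") <- length(seqs)
    return(out)
  }
  cm <- change_matrix(seqs)
  ch <- cm$changes; idn <- cm$identity
  diag(ch) <- NA
  ch[idn < min_identity] <- NA
  nearest <- suppressWarnings(apply(ch, 1L, min, na.rm = TRUE))
  nearest[!is.finite(nearest)] <- NA
  n <- length(seqs)
  out <- data.frame(
    N = seq_len(max_changes),
    cum_fraction = vapply(seq_len(max_changes),
                          function(k) sum(!is.na(nearest) & nearest <= k) / n,
                          0))
  attr(out, "empty") <- FALSE
  attr(out, "n_centroids") <- n
  out
}

#' Expected identity after accumulating changes
#'
#' For a sequence of a given length, the identity implied by a number of
#' single-nucleotide changes: `(length - changes) / length`.
#'
#' @param length sequence length in nt.
#' @param changes number of changes, `0 <= changes <= length`.
#' @return fraction in \[0, 1\].
#' @export
expected_identity <- function(length, changes) {
  if (any(changes > length)) stop("changes exceed sequence length")
  if (any(changes < 0) || any(length <= 0)) stop("invalid length or changes")
  (length - changes) / length
}

#' Greedy-clustering resilience curve
#'
#' At each identity threshold, sequences are processed in decreasing
#' read-abundance order (ties broken lexicographically by sequence); a
#' sequence joins the first existing centroid with pairwise identity at or
#' above the threshold, otherwise it founds a new centroid.  Each threshold
#' is clustered independently.  `remaining_fraction` is centroids / inputs.
#'
#' @param set a [cluster_set()]; duplicate centroid strings are pre-merged.
#' @param thresholds identity fractions in (0, 1].
#' @return data.frame `threshold`, `n_centroids`, `remaining_fraction`,
#'   ordered by decreasing threshold.
#' @export
resilience_curve <- function(set, thresholds = seq(1, 0.75, by = -0.01)) {
  if (any(thresholds <= 0 | thresholds > 1)) stop("thresholds must be in (0,1]")
  reads <- tapply(rowSums(set$table), set$centroids, sum)
  seqs <- names(reads)
  ord <- order(-as.numeric(reads), seqs)
  seqs <- seqs[ord]
  idn <- change_matrix(setNames(seqs, seqs))$identity
  n <- length(seqs)
  thresholds <- sort(thresholds, decreasing = TRUE)
  n_cent <- vapply(thresholds, function(t) {
    cent <- integer(0)
    for (i in seq_len(n)) {
      if (!length(cent) || !any(idn[i, cent] >= t))
        cent <- c(cent, i)
    }
    length(cent)
  }, 0L)
  data.frame(threshold = thresholds, n_centroids = n_cent,
             remaining_fraction = n_cent / n)
}
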