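#' Remove sample-singletons
#'
#' A sample-singleton is a feature observed with exactly one read within a
#' sample.  Every cell equal to 1 is zeroed; features whose row becomes
#' all-zero are dropped.  With `mode = "table"` the alternative reading is
#' available: features whose total count over all samples is 1 are dropped
#' whole.
#'
#' @param table a [feature_table()].
#' @param mode `"cell"` (default, per-sample singletons) or `"table"`
#'   (whole-table singletons).
#' @return list with elements `table` (filtered, possibly empty) and
#'   `report` (a `filter_report`).
#' @export
remove_sample_singletons <- function(table, mode = c("cell", "table")) {
  mode <- match.arg(mode)
  before <- unclass(table)
  out <- before
  if (mode == "cell") {
    out[out == 1L] <- 0L
  } else {
    out[rowSums(out) == 1L, ] <- 0L
  }
  keep <- rowSums(out) > 0L
  removed <- rownames(out)[!keep]
  out <- out[keep, , drop = FALSE]
  res <- feature_table(out, allow_empty = TRUE)
  list(table = res,
       report = filter_report(before, res, removed))
}

#' Tailored relative-abundance filter
#'
#' Keeps a feature iff it reaches at least `threshold` (default 0.1%) of the
#' total reads of at least one sample.  Per-sample totals are computed once
#' on the input table; kept features retain all their counts.  The boundary
#' is inclusive and evaluated in exact integer arithmetic
#' (`count * 1/threshold >= total`), so no float artifacts occur at the
#' 0.1% boundary.
#'
#' @param table a [feature_table()].
#' @param threshold minimum per-sample relative abundance in (0,1).
#' @return list with `table` and `report` as in [remove_sample_singletons()].
#' @export
abundance_filter <- function(table, threshold = 0.001) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0,1)")
  before <- unclass(table)
  totals <- colSums(before)
  # exact comparison: count / total >= threshold  <=>  count >= threshold*total
  # done in rational arithmetic when threshold is 1/k for integer k
  k <- 1 / threshold
  if (abs(k - round(k)) < 1e-9) {
    k <- round(k)
    qual <- sweep(before * k, 2L, totals, ">=")
  } else {
    qual <- sweep(before, 2L, totals * threshold, ">=")
  }
  qual[, totals == 0L] <- FALSE      # empty sample contributes no ratio
  qual[before == 0L] <- FALSE
  keep <- rowSums(qual) > 0L
  removed <- rownames(before)[!keep]
  res <- feature_table(before[keep, , drop = FALSE], allow_empty = TRUE)
  list(table = res, report = filter_report(before, res, removed))
}

filter_report <- function(before, after, removed_feature_ids) {
  rb <- sum(before); ra <- sum(after)
  structure(list(
    reads_before = rb,
    reads_after = ra,
    features_before = nrow(before),
    features_after = nrow(after),
    removed_feature_ids = removed_feature_ids,
    percent_reads_lost = if (rb > 0) (rb - ra) / rb else 0,
    emptied = nrow(after) == 0L
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> features %d -> %d, reads %d -> %d (%.2f%% lost)%s\n",
              x$features_before, x$features_after, x$reads_before,
              x$reads_after, 100 * x$percent_reads_lost,
              if (x$emptied) " [EMPTY RESULT]" else ""))
  invisible(x)
}

#' Collapse a feature table to a taxonomic level
#'
#' Features sharing the identical lineage prefix through `level` are summed
#' into one row keyed by that prefix.  Prefixes containing empty labels form
#' their own keys, so taxa unassigned at `level` remain as distinct
#' ambiguous rows.  Total reads are conserved exactly.
#'
#' @param table a [feature_table()].
#' @param taxonomy a `taxonomy_table` covering every feature in `table`.
#' @param level rank index 1 (kingdom) .. 7 (species).
#' @return a [feature_table()] keyed by lineage prefix, with the prefix
#'   label matrix attached as attribute `lineage`.
#' @export
collapse_taxonomy <- function(table, taxonomy, level) {
  stopifnot(level %in% 1:7)
  miss <- setdiff(rownames(table), rownames(taxonomy))
  if (length(miss))
    stop("feature(s) without taxonomy: ", paste(miss, collapse = ", "))
  pref <- taxonomy[rownames(table), seq_len(level), drop = FALSE]
  key <- apply(pref, 1L, paste, collapse = "; ")
  agg <- rowsum(unclass(table), group = key, reorder = TRUE)
  out <- feature_table(agg, allow_empty = TRUE)
  lin <- unique(cbind(key, pref))
  lin <- lin[match(rownames(agg), lin[, 1L]), -1L, drop = FALSE]
  rownames(lin) <- rownames(agg)
  colnames(lin) <- RANK_NAMES[seq_len(level)]
  attr(out, "lineage") <- lin
  attr(out, "level") <- level
  out
}
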