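#' Is a lineage informative at a level?
#'
#' Informative means the label at `level` is non-empty after prefix
#' stripping and canonicalisation (no ambiguity placeholder survives
#' canonicalisation, so non-empty is sufficient).
#'
#' @param lineage character vector of 7 rank labels, or a `taxonomy_table`
#'   (then a logical vector over its rows is returned).
#' @param level rank index 1-7.
#' @return logical.
#' @export
is_informative <- function(lineage, level) {
  stopifnot(level %in% 1:7)
  if (is.matrix(lineage)) return(nzchar(lineage[, level]))
  nzchar(lineage[level])
}

#' Taxonomic resolution profile of a cluster set
#'
#' Per rank level: the fraction of reads belonging to features informative
#' at that level, and the number of distinct informative taxa.
#'
#' @param set a [cluster_set()].
#' @return data.frame `level`, `rank`, `n_informative_taxa`,
#'   `pct_reads_informative`.
#' @export
resolution_profile <- function(set) {
  reads <- rowSums(set$table)
  total <- sum(reads)
  rows <- lapply(1:7, function(lv) {
    inf <- is_informative(set$taxonomy, lv)
    keys <- apply(set$taxonomy[inf, seq_len(lv), drop = FALSE], 1L,
                  paste, collapse = "; ")
    data.frame(level = lv, rank = RANK_NAMES[lv],
               n_informative_taxa = length(unique(keys)),
               pct_reads_informative = if (total > 0) sum(reads[inf]) / total else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (total == 0 || all(out$n_informative_taxa == 0L))
    attr(out, "flagged") <- "no informative taxa"
  out
}

#' Attribute missing species labels to LCA truncation vs missing references
#'
#' Features lacking a species label either matched multiple
#' phylogenetically distant references (taxonomy truncated to the last
#' common ancestor) or matched a reference that itself carries no species
#' label.  Given a reference map from terminal lineage prefixes to whether
#' the reference carries a species label, returns the read-weighted two-way
#' attribution (fractions sum to 1 over species-missing reads).
#'
#' @param set a [cluster_set()].
#' @param reference_labels named logical vector: terminal lineage prefix
#'   (ranks joined by `"; "`) -> TRUE if the reference has a species label.
#'   Lineages absent from the map count as LCA, with a warning.
#' @return list `pct_missing_due_to_lca`, `pct_missing_due_to_no_label`,
#'   `n_features_missing_species`.
#' @export
lca_attribution <- function(set, reference_labels) {
  reads <- rowSums(set$table)
  missing <- !is_informative(set$taxonomy, 7L)
  if (!any(missing))
    return(list(pct_missing_due_to_lca = NA_real_,
                pct_missing_due_to_no_label = NA_real_,
                n_features_missing_species = 0L))
  tax <- set$taxonomy[missing, , drop = FALSE]
  depth <- apply(tax, 1L, function(r) sum(nzchar(r)))
  term <- vapply(seq_len(nrow(tax)), function(i) {
    paste(tax[i, seq_len(max(depth[i], 1L))], collapse = "; ")
  }, "")
  known <- term %in% names(reference_labels)
  if (any(!known))
    warning(sum(!known), " lineage(s) absent from reference map, counted as LCA",
            call. = FALSE)
  has_species <- rep(TRUE, length(term))          # absent -> LCA (conservative)
  has_species[known] <- reference_labels[term[known]]
  w <- reads[missing]
  lca_reads <- sum(w[has_species])                # reference could have resolved
  nolab_reads <- sum(w[!has_species])
  tot <- lca_reads + nolab_reads
  list(pct_missing_due_to_lca = lca_reads / tot,
       pct_missing_due_to_no_label = nolab_reads / tot,
       n_features_missing_species = sum(missing))
}

#' Taxa overlap between cluster sets at a taxonomic level
#'
#' Collapses each set to `level` and partitions the union of lineage-prefix
#' keys into Venn compartments with read-weighted accounting, exactly as
#' [exact_overlap()] does for centroid sequences.
#'
#' @param sets list of 2-3 [cluster_set()]s.
#' @param level rank index 1-7.
#' @return an `overlap_partition` data.frame.
#' @export
taxa_overlap <- function(sets, level) {
  ids <- vapply(sets, function(s) s$set_id, "")
  per_set <- lapply(sets, function(s) {
    coll <- collapse_taxonomy(s$table, s$taxonomy, level)
    setNames(rowSums(coll), rownames(coll))
  })
  overlap_partition(per_set, ids)
}

#' Cross-set Spearman correlation of informative taxa at a level
#'
#' Both sets are collapsed to `level`; only taxa informative at that level
#' enter.  The union of the two informative-taxa lists is used, with an
#' abundance of zero for taxa absent from one set.  Abundances are set-wide
#' relative abundances (taxon reads / set total reads); ties receive
#' average ranks.
#'
#' @param a,b [cluster_set()]s.
#' @param level rank index 1-7.
#' @return list `level`, `rank`, `set_pair`, `rho`, `n_taxa`; `rho` is NA
#'   (flagged) when the union holds fewer than 3 taxa.
#' @export
cross_set_correlation <- function(a, b, level) {
  va <- informative_rel_abund(a, level)
  vb <- informative_rel_abund(b, level)
  taxa <- sort(union(names(va), names(vb)))
  res <- list(level = level, rank = RANK_NAMES[level],
              set_pair = c(a$set_id, b$set_id), n_taxa = length(taxa))
  if (length(taxa) < 3L) {
    res$rho <- NA_real_
    res$flagged <- "fewer than 3 taxa in union"
    return(res)
  }
  xa <- setNames(rep(0, length(taxa)), taxa); xa[names(va)] <- va
  xb <- setNames(rep(0, length(taxa)), taxa); xb[names(vb)] <- vb
  res$rho <- cor(xa, xb, method = "spearman")
  res
}

informative_rel_abund <- function(set, level) {
  coll <- collapse_taxonomy(set$table, set$taxonomy, level)
  lin <- attr(coll, "lineage")
  inf <- nzchar(lin[, level])
  reads <- rowSums(coll)[inf]
  reads / sum(set$table)
}

#' Differential-taxa screen against a reference set
#'
#' Splits taxa (at a level) by whether their mean relative abundance across
#' the non-reference sets falls below `ratio` of their abundance in the
#' reference set (reference-predominant) or not (shared or
#' others-predominant).  Taxa absent from the reference are flagged.
#'
#' @param reference_set a [cluster_set()].
#' @param other_sets list of [cluster_set()]s.
#' @param level rank index 1-7.
#' @param ratio abundance ratio threshold (default 1/3, i.e. <33%).
#' @return data.frame with per-set relative abundances, `category`
#'   (`reference_predominant` / `other`) and `flag`.
#' @export
differential_taxa <- function(reference_set, other_sets, level, ratio = 1/3) {
  ra_ref <- taxon_rel_abund(reference_set, level)
  ra_others <- lapply(other_sets, taxon_rel_abund, level = level)
  taxa <- sort(unique(c(names(ra_ref), unlist(lapply(ra_others, names)))))
  fill <- function(v) { x <- setNames(rep(0, length(taxa)), taxa)
                        x[names(v)] <- v; x }
  ref <- fill(ra_ref)
  oth <- vapply(ra_others, fill, numeric(length(taxa)))
  oth <- matrix(oth, nrow = length(taxa),
                dimnames = list(taxa, vapply(other_sets, `[[`, "", "set_id")))
  mean_other <- rowMeans(oth)
  out <- data.frame(taxon = taxa, ref_abundance = ref,
                    mean_other_abundance = mean_other,
                    oth, check.names = FALSE,
                    category = ifelse(mean_other < ratio * ref,
                                      "reference_predominant", "other"),
                    flag = ifelse(ref == 0, "ref-absent", ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

taxon_rel_abund <- function(set, level) {
  coll <- collapse_taxonomy(set$table, set$taxonomy, level)
  rowSums(coll) / sum(set$table)
}
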