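#' Rarefy one sample's counts to a fixed depth
#'
#' Multivariate-hypergeometric draw: `depth` reads are subsampled without
#' replacement from the sample's reads.  Uses the current RNG state; seed
#' management belongs to the calling pipeline.
#'
#' @param counts integer vector of feature counts (named or not).
#' @param depth target depth, at most `sum(counts)`.
#' @param sample_id used in the error message when depth exceeds the total.
#' @return integer vector of the same length summing exactly to `depth`.
#' @export
rarefy_counts <- function(counts, depth, sample_id = "sample") {
  total <- sum(counts)
  if (depth > total)
    stop("rarefaction depth ", depth, " exceeds total ", total,
         " for ", sample_id)
  if (depth == total) return(counts)
  cs <- cumsum(as.numeric(counts))
  feat <- findInterval(sample.int(total, depth), cs, left.open = TRUE) + 1L
  out <- tabulate(feat, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Shannon entropy (nats)
#'
#' `H = -sum p_i ln p_i` with `p_i = count_i / total` and `0 ln 0 := 0`.
#'
#' @param counts non-negative vector with positive total.
#' @return entropy in nats.
#' @export
shannon <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("shannon undefined for an all-zero vector")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, with F1/F2 the numbers of
#' features observed exactly once/twice (the doubleton adjustment keeps the
#' estimator finite when no doubletons are observed).
#'
#' @param counts integer vector of feature counts.
#' @return estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Rarefaction-based alpha diversity with group comparisons
#'
#' For each sample, `iterations` independent rarefactions at the depth of
#' the smallest sample; observed features, Shannon entropy and
#' bias-corrected Chao1 are computed on every draw and averaged into point
#' estimates.  Samples are then compared by organ and pond (two-sided
#' Wilcoxon rank-sum) and by the organ-pond cross product (Kruskal-Wallis)
#' on the point estimates, reporting group medians and p-values; the
#' significance level alpha is reported alongside, never baked into a
#' conclusion.
#'
#' @param table a [feature_table()].
#' @param metadata data.frame from [sample_metadata()] covering every sample.
#' @param iterations rarefaction draws per sample (study default 10000).
#' @param seed optional integer; when given the whole computation is
#'   deterministic (single sequential RNG stream).
#' @param alpha significance level reported in the comparison table.
#' @return list with `depth`, `estimates` (long data.frame: sample_id,
#'   metric, estimate), `draws` (iterations x samples x metrics array),
#'   `f1f2` (singleton/doubleton counts per draw for the Chao1 audit) and
#'   `comparisons` (grouping x metric test table).
#' @export
alpha_pipeline <- function(table, metadata, iterations = 10000L, seed = NULL,
                           alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(iterations >= 1L)
  samples <- colnames(table)
  miss <- setdiff(samples, metadata$sample_id)
  if (length(miss))
    stop("sample(s) without metadata: ", paste(miss, collapse = ", "))
  meta <- metadata[match(samples, metadata$sample_id), ]
  depth <- min(colSums(table))
  metrics <- c("observed", "shannon", "chao1")
  draws <- array(NA_real_, dim = c(iterations, length(samples), 3L),
                 dimnames = list(NULL, samples, metrics))
  f1f2 <- array(NA_integer_, dim = c(iterations, length(samples), 2L),
                dimnames = list(NULL, samples, c("F1", "F2")))
  for (it in seq_len(iterations)) {
    for (j in seq_along(samples)) {
      x <- rarefy_counts(table[, j], depth, samples[j])
      draws[it, j, "observed"] <- sum(x > 0)
      draws[it, j, "shannon"] <- shannon(x)
      draws[it, j, "chao1"] <- chao1(x)
      f1f2[it, j, 1L] <- sum(x == 1)
      f1f2[it, j, 2L] <- sum(x == 2)
    }
  }
  est <- apply(draws, c(2L, 3L), mean)
  estimates <- data.frame(
    sample_id = rep(samples, times = 3L),
    metric = rep(metrics, each = length(samples)),
    estimate = as.vector(est), stringsAsFactors = FALSE)
  comparisons <- alpha_group_tests(est, meta, alpha)
  list(depth = depth, estimates = estimates, draws = draws, f1f2 = f1f2,
       comparisons = comparisons)
}

alpha_group_tests <- function(est, meta, alpha = 0.05) {
  groupings <- c("organ", "pond", "organ_pond")
  rows <- list()
  for (g in groupings) {
    fac <- meta[[g]]
    sizes <- table(fac)
    for (m in colnames(est)) {
      if (length(sizes) < 2L || any(sizes < 2L)) {
        rows[[length(rows) + 1L]] <- data.frame(
          grouping = g, metric = m, test = NA_character_,
          statistic = NA_real_, p_value = NA_real_,
          group_medians = NA_character_, alpha = alpha, skipped = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      v <- est[, m]
      if (length(sizes) == 2L) {
        ht <- suppressWarnings(wilcox.test(v ~ factor(fac)))
        test <- "wilcoxon_rank_sum"
      } else {
        ht <- kruskal.test(v ~ factor(fac))
        test <- "kruskal_wallis"
      }
      med <- tapply(v, fac, median)
      rows[[length(rows) + 1L]] <- data.frame(
        grouping = g, metric = m, test = test,
        statistic = unname(ht$statistic), p_value = ht$p.value,
        group_medians = paste(names(med), signif(med, 8), sep = "=",
                              collapse = ";"),
        alpha = alpha, skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
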