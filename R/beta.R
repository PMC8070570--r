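#' Average-rarefied standardized table
#'
#' Element-wise mean of `n_draws` independent rarefactions of every sample
#' to a common depth.  Means are kept as reals (never re-rounded), so each
#' column sums exactly to `depth`.
#'
#' @param table a [feature_table()].
#' @param depth common depth; defaults to the smallest sample total.
#' @param n_draws number of independent rarefactions averaged.
#' @param seed optional integer seed.
#' @return real-valued matrix (features x samples).
#' @export
average_rarefied_table <- function(table, depth = min(colSums(table)),
                                   n_draws = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_draws >= 1L)
  acc <- matrix(0, nrow(table), ncol(table), dimnames = dimnames(table))
  for (d in seq_len(n_draws)) {
    for (j in seq_len(ncol(table)))
      acc[, j] <- acc[, j] + rarefy_counts(table[, j], depth, colnames(table)[j])
  }
  acc / n_draws
}

#' Bray-Curtis dissimilarity
#'
#' `sum |x - y| / sum (x + y)` over equal-length non-negative vectors.
#'
#' @param x,y abundance vectors (counts or averaged counts).
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' Binary Jaccard dissimilarity
#'
#' `1 - |presence intersection| / |presence union|`; presence is any
#' abundance strictly greater than zero.
#'
#' @inheritParams bray_curtis
#' @return dissimilarity in \[0, 1\].
#' @export
jaccard_binary <- function(x, y) {
  check_pair(x, y)
  px <- x > 0; py <- y > 0
  1 - sum(px & py) / sum(px | py)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  if (sum(x) == 0 && sum(y) == 0) stop("both vectors are all-zero")
  invisible(NULL)
}

#' UniFrac dissimilarity between two samples
#'
#' The tree is pruned to the union of features observed in either sample
#' (branch lengths preserved).  Unweighted UniFrac is the branch length
#' leading exclusively to one sample's features over the branch length
#' leading to either's; weighted (raw) is `sum_b l_b |p_b(x) - p_b(y)|`
#' with `p_b` the fraction of a sample's reads descending from branch `b`;
#' the normalized variant divides by the same sum with `|.|` replaced by
#' `p_b(x) + p_b(y)`, bounding it to \[0, 1\].
#'
#' @param tree rooted `phylo` with finite non-negative branch lengths.
#' @param x,y named abundance vectors; every feature with nonzero count
#'   must be a tree leaf.
#' @param mode `"unweighted"`, `"weighted_raw"` or `"weighted_normalized"`.
#' @return dissimilarity (unweighted and normalized are in \[0, 1\]).
#' @export
unifrac <- function(tree, x, y,
                    mode = c("unweighted", "weighted_raw",
                             "weighted_normalized")) {
  mode <- match.arg(mode)
  if (is.null(names(x)) || is.null(names(y)))
    stop("UniFrac needs named abundance vectors")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  if (sum(x) == 0 || sum(y) == 0) stop("all-zero sample in UniFrac")
  feats <- union(names(x)[x > 0], names(y)[y > 0])
  miss <- setdiff(feats, tree$tip.label)
  if (length(miss))
    stop("feature(s) missing from tree: ", paste(miss, collapse = ", "))
  tr <- if (length(setdiff(tree$tip.label, feats)))
    ape::keep.tip(tree, feats) else tree
  tr <- stats::reorder(tr, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  sx <- sy <- numeric(n_node)
  sx[seq_len(n_tip)] <- ifelse(tr$tip.label %in% names(x),
                               x[tr$tip.label], 0)
  sy[seq_len(n_tip)] <- ifelse(tr$tip.label %in% names(y),
                               y[tr$tip.label], 0)
  sx[is.na(sx)] <- 0; sy[is.na(sy)] <- 0
  for (e in seq_len(nrow(tr$edge))) {
    sx[tr$edge[e, 1L]] <- sx[tr$edge[e, 1L]] + sx[tr$edge[e, 2L]]
    sy[tr$edge[e, 1L]] <- sy[tr$edge[e, 1L]] + sy[tr$edge[e, 2L]]
  }
  child <- tr$edge[, 2L]
  len <- tr$edge.length
  px <- sx[child] / sum(x)
  py <- sy[child] / sum(y)
  if (mode == "unweighted") {
    unique_b <- xor(px > 0, py > 0)
    either_b <- px > 0 | py > 0
    return(sum(len[unique_b]) / sum(len[either_b]))
  }
  raw <- sum(len * abs(px - py))
  if (mode == "weighted_raw") return(raw)
  raw / sum(len * (px + py))
}

#' Sample-by-sample dissimilarity matrix
#'
#' @param table feature x sample matrix (integer counts or an
#'   average-rarefied real table).
#' @param method `"braycurtis"`, `"jaccard"`, `"unweighted_unifrac"`,
#'   `"weighted_unifrac"` (normalized) or `"weighted_unifrac_raw"`.
#' @param tree rooted `phylo`, required for the UniFrac methods.
#' @return symmetric hollow matrix with sample ids as dimnames.
#' @export
beta_distance <- function(table,
                          method = c("braycurtis", "jaccard",
                                     "unweighted_unifrac", "weighted_unifrac",
                                     "weighted_unifrac_raw"),
                          tree = NULL) {
  method <- match.arg(method)
  if (startsWith(method, "unweighted") || startsWith(method, "weighted")) {
    if (is.null(tree)) stop("UniFrac requires a tree")
    validate_tree(tree)
  }
  n <- ncol(table)
  ids <- colnames(table)
  fun <- switch(method,
    braycurtis = function(x, y) bray_curtis(x, y),
    jaccard = function(x, y) jaccard_binary(x, y),
    unweighted_unifrac = function(x, y) unifrac(tree, x, y, "unweighted"),
    weighted_unifrac = function(x, y) unifrac(tree, x, y, "weighted_normalized"),
    weighted_unifrac_raw = function(x, y) unifrac(tree, x, y, "weighted_raw"))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    x <- setNames(table[, i], rownames(table))
    y <- setNames(table[, j], rownames(table))
    D[i, j] <- D[j, i] <- fun(x, y)
  }
  D
}

validate_distance_matrix <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (any(abs(dm - t(dm)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(dm < 0)) stop("distance matrix must be non-negative")
  dm
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-D^2 / 2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues; negative eigenvalues are counted and reported,
#' not corrected.
#'
#' @param dm symmetric hollow dissimilarity matrix (n >= 3).
#' @return list of class `pcoa_ordination` with `coordinates`,
#'   `eigenvalues`, `proportion_explained` (over positive eigenvalues) and
#'   `n_negative_eigenvalues`.
#' @export
pcoa <- function(dm) {
  D <- validate_distance_matrix(dm)
  n <- nrow(D)
  if (n < 3L) stop("PCoA needs at least 3 samples")
  A <- -0.5 * D^2
  Cn <- diag(n) - matrix(1 / n, n, n)
  B <- Cn %*% A %*% Cn
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 1e-300) * 1e-8
  pos <- which(e$values > tol)
  if (length(pos)) {
    coords <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), nrow = length(pos))
    prop <- e$values[pos] / sum(e$values[pos])
  } else {
    # fully degenerate input (e.g. an all-zero distance matrix): no axes
    coords <- matrix(0, n, 0)
    prop <- numeric(0)
  }
  dimnames(coords) <- list(rownames(D),
                           if (ncol(coords)) paste0("Axis", seq_len(ncol(coords))))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained = prop,
                 n_negative_eigenvalues = sum(e$values < -tol)),
            class = "pcoa_ordination")
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based statistic
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`
#' over all off-diagonal pairs (average ranks for ties).  The p-value comes
#' from label permutations: when the label multiset admits at most
#' `max_exhaustive` distinct assignments (and `exhaustive != "never"`) all
#' of them are enumerated and the p-value is exact
#' (`#{R* >= R} / n_assignments`, the identity included); otherwise
#' `n_permutations` random relabelings give
#' `p = (1 + #{R* >= R}) / (1 + n_permutations)`.
#'
#' @param dm symmetric hollow dissimilarity matrix.
#' @param groups group label per sample (aligned with `dm` rows; if named,
#'   reordered by the matrix dimnames).  At least 2 groups, each with at
#'   least 2 samples.
#' @param n_permutations random permutations when not exhaustive.
#' @param seed optional integer seed for the random permutations.
#' @param exhaustive `"auto"` (default), `"always"` or `"never"`.
#' @param max_exhaustive assignment-count cap for automatic enumeration.
#' @return list of class `anosim_result`: `R`, `p_value`, `n_permutations`
#'   (assignments evaluated), `method` (`"exhaustive"`/`"sampled"`).
#' @export
anosim <- function(dm, groups, n_permutations = 999L, seed = NULL,
                   exhaustive = c("auto", "always", "never"),
                   max_exhaustive = 20000L) {
  exhaustive <- match.arg(exhaustive)
  D <- validate_distance_matrix(dm)
  n <- nrow(D)
  if (!is.null(names(groups)) && !is.null(rownames(D)))
    groups <- groups[rownames(D)]
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("ANOSIM needs at least 2 groups")
  if (any(sizes < 2L))
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  low <- which(lower.tri(D))
  rk <- rank(D[low])
  pi_ <- row(D)[low]; pj_ <- col(D)[low]
  denom <- n * (n - 1) / 4
  stat <- function(g) {
    same <- g[pi_] == g[pj_]
    (mean(rk[!same]) - mean(rk[same])) / denom
  }
  R <- stat(groups)
  n_assign <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  eps <- 1e-12
  if (exhaustive == "always" ||
      (exhaustive == "auto" && n_assign <= max_exhaustive)) {
    perms <- multiset_permutations(groups)
    Rs <- vapply(perms, stat, 0)
    p <- sum(Rs >= R - eps) / length(Rs)
    res <- list(R = R, p_value = p, n_permutations = length(Rs),
                method = "exhaustive")
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_permutations))
      if (stat(sample(groups)) >= R - eps) hits <- hits + 1L
    res <- list(R = R, p_value = (1 + hits) / (1 + n_permutations),
                n_permutations = n_permutations, method = "sampled")
  }
  class(res) <- "anosim_result"
  res
}

# all distinct assignments of a multiset of labels to positions
multiset_permutations <- function(labels) {
  counts <- table(labels)
  labs <- names(counts)
  n <- length(labels)
  rec <- function(counts, prefix) {
    if (sum(counts) == 0L) return(list(prefix))
    out <- list()
    for (i in seq_along(counts)) {
      if (counts[i] > 0L) {
        c2 <- counts; c2[i] <- c2[i] - 1L
        out <- c(out, rec(c2, c(prefix, labs[i])))
      }
    }
    out
  }
  rec(as.integer(counts), character(0))
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<anosim> R = %.4f, p = %.4g (%s, %d assignments)\n",
              x$R, x$p_value, x$method, x$n_permutations))
  invisible(x)
}

#' Pairwise post hoc ANOSIM
#'
#' Runs [anosim()] on every pair of groups (subsetting the distance matrix)
#' and adjusts the p-values with Benjamini-Hochberg.
#'
#' @inheritParams anosim
#' @return data.frame `group_a`, `group_b`, `R`, `p_value`, `p_adjusted`.
#' @export
anosim_pairwise <- function(dm, groups, n_permutations = 999L, seed = NULL,
                            exhaustive = c("auto", "always", "never"),
                            max_exhaustive = 20000L) {
  exhaustive <- match.arg(exhaustive)
  D <- validate_distance_matrix(dm)
  if (!is.null(names(groups)) && !is.null(rownames(D)))
    groups <- groups[rownames(D)]
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  pairs <- combn(levs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- groups %in% pairs[, k]
    r <- anosim(D[sel, sel], groups[sel], n_permutations = n_permutations,
                seed = if (is.null(seed)) NULL else seed + k,
                exhaustive = exhaustive, max_exhaustive = max_exhaustive)
    data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k],
               R = r$R, p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
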