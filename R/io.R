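#' Read centroid sequences from FASTA
#'
#' Header tokens up to the first whitespace are taken as feature ids.
#' Sequences are uppercased and U is converted to T; any residue outside
#' A/C/G/T after normalisation is an error (centroids are expected to be
#' unambiguous representatives).
#'
#' @param path FASTA file.
#' @return named character vector, feature id -> DNA string.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
  seqs <- normalize_dna(as.character(ss), ids)
  names(seqs) <- ids
  seqs
}

normalize_dna <- function(seqs, ids = names(seqs)) {
  seqs <- chartr("u", "T", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("ambiguous base in sequence(s): ", paste(ids[bad], collapse = ", "))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read Greengenes-style taxonomy assignments
#'
#' Expects a two-column TSV (feature id, lineage) without a header; `#`
#' lines are ignored.  Lineages are semicolon-separated with rank prefixes
#' `k__` through `s__`.  Missing deeper ranks are padded with empty labels
#' and the string is canonicalised so that an empty rank truncates
#' everything below it (a warning reports dropped labels).
#'
#' @param path taxonomy TSV.
#' @return character matrix (features x 7 ranks) with feature ids as
#'   rownames; class `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy file needs two columns: ", path)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ", paste(dup, collapse = ", "))
  mat <- t(vapply(df[[2L]], parse_lineage, character(7L)))
  rownames(mat) <- ids
  taxonomy_table(mat)
}

#' Assemble a taxonomy table from parsed lineages
#'
#' @param mat character matrix with 7 columns (kingdom..species) and feature
#'   ids as rownames; canonicalised so an empty rank truncates deeper ranks.
#' @return the matrix with column names set and class `taxonomy_table`.
#' @export
taxonomy_table <- function(mat) {
  if (ncol(mat) != 7L) stop("taxonomy must have exactly 7 ranks")
  colnames(mat) <- RANK_NAMES
  mat <- t(apply(mat, 1L, canonicalize_lineage))
  colnames(mat) <- RANK_NAMES
  class(mat) <- c("taxonomy_table", class(mat))
  mat
}

parse_lineage <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  if (length(parts) > 7L) stop("lineage has more than 7 ranks: ", s)
  labs <- character(7L)
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (!nzchar(p)) next
    pref <- substr(p, 1L, 3L)
    if (!identical(pref, RANK_PREFIXES[i]))
      stop("unknown or misplaced rank prefix '", pref, "' in: ", s)
    labs[i] <- substring(p, 4L)
  }
  labs
}

canonicalize_lineage <- function(labs) {
  empty <- which(!nzchar(labs))
  if (length(empty)) {
    cut <- empty[1L]
    if (any(nzchar(labs[seq(cut, 7L)]))) {
      dropped <- labs[seq(cut, 7L)]
      dropped <- dropped[nzchar(dropped)]
      warning("labels below an empty rank dropped during canonicalization: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    labs[seq(cut, 7L)] <- ""
  }
  labs
}

format_lineage <- function(labs) {
  paste0(RANK_PREFIXES, labs, collapse = "; ")
}

#' Write taxonomy assignments as TSV
#'
#' @param taxonomy a `taxonomy_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lines <- paste(rownames(taxonomy),
                 apply(taxonomy, 1L, format_lineage), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' Every branch must carry a finite non-negative length; missing lengths are
#' an error, never silently zeroed.
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object, validated.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree has branches without a finite length")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  tree
}

#' Read sample metadata
#'
#' TSV with a header; the first column holds sample ids and columns `organ`
#' and `pond` are required.  A derived `organ_pond` cross-product column is
#' added.
#'
#' @param path metadata TSV.
#' @return data.frame with columns sample_id, organ, pond, organ_pond.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Assemble sample metadata from a data.frame
#'
#' @param df data.frame whose first column holds sample ids, with required
#'   columns `organ` and `pond`.
#' @return validated data.frame with sample_id, organ, pond, organ_pond.
#' @export
sample_metadata <- function(df) {
  need <- c("organ", "pond")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "))
  if (any(!nzchar(df$organ)) || any(!nzchar(df$pond)))
    stop("metadata has empty organ or pond categories")
  out <- data.frame(sample_id = ids,
                    organ = as.character(df$organ),
                    pond = as.character(df$pond),
                    stringsAsFactors = FALSE)
  out$organ_pond <- paste(out$organ, out$pond, sep = "_")
  out
}

#' Write sample metadata as TSV
#'
#' @param metadata data.frame from [sample_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata[, c("sample_id", "organ", "pond")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle one clustering method's outputs into a cluster set
#'
#' A cluster set is one method's view of the samples: a feature table, one
#' centroid (representative) sequence per feature, a taxonomy assignment per
#' feature and optionally the cluster origin (reference-matched vs de novo)
#' and a rooted phylogeny over the features.
#'
#' @param set_id identifier, e.g. `"01_OTU_97"`.
#' @param table a [feature_table()].
#' @param centroids named character vector feature id -> DNA string.
#' @param taxonomy a `taxonomy_table` covering every feature.
#' @param origin optional named character vector with values `reference`,
#'   `de_novo` or `unknown`; defaults to `unknown` for every feature.
#' @param tree optional rooted `phylo` whose leaves include the feature ids.
#' @return list with class `cluster_set`.
#' @export
cluster_set <- function(set_id, table, centroids, taxonomy,
                        origin = NULL, tree = NULL) {
  ids <- rownames(table)
  miss <- setdiff(ids, names(centroids))
  if (length(miss))
    stop("feature(s) without a centroid sequence: ", paste(miss, collapse = ", "))
  centroids <- normalize_dna(centroids[ids])
  names(centroids) <- ids
  if (!is.null(taxonomy)) {
    miss <- setdiff(ids, rownames(taxonomy))
    if (length(miss))
      stop("feature(s) without taxonomy: ", paste(miss, collapse = ", "))
    taxonomy <- taxonomy[ids, , drop = FALSE]
    class(taxonomy) <- c("taxonomy_table", "matrix", "array")
  }
  if (is.null(origin)) {
    origin <- setNames(rep("unknown", length(ids)), ids)
  } else {
    origin <- origin[ids]
    origin[is.na(origin)] <- "unknown"
    names(origin) <- ids
    bad <- setdiff(unique(origin), c("reference", "de_novo", "unknown"))
    if (length(bad))
      stop("invalid origin label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(tree)) {
    validate_tree(tree)
    extra <- setdiff(tree$tip.label, ids)
    if (length(extra))
      message(set_id, ": ", length(extra),
              " tree leaf/leaves without a matching feature (pruned later)")
  }
  structure(list(set_id = set_id, table = table, centroids = centroids,
                 taxonomy = taxonomy, origin = origin, tree = tree),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", x$set_id, ": ", nrow(x$table), " features x ",
      ncol(x$table), " samples, ", sum(x$table), " reads\n", sep = "")
  invisible(x)
}
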