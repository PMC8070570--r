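#' Parameters of the synthetic true community
#'
#' Defaults describe a V3-like amplicon survey: centroid lengths around
#' 150 nt (kept within the 127-168 nt V3 range), within-family sequence
#' divergence well below cross-family divergence but above typical OTU
#' cutoffs, lognormal base abundances, a 4-fold organ effect on 30% of taxa
#' and a comparable 3-fold pond effect on 30% of taxa, with lognormal
#' inter-replicate overdispersion.
#'
#' @param n_families number of bacterial families in the community.
#' @param seq_length ancestor sequence length (nt).
#' @param seq_length_range admissible centroid length range (nt).
#' @param within_family_subs substitutions between a taxon and its family
#'   ancestor.
#' @param between_family_subs substitutions between a family ancestor and
#'   the community ancestor.
#' @param lognormal_sdlog sdlog of the lognormal base abundances.
#' @param replicate_sdlog per-taxon, per-sample lognormal overdispersion of
#'   the composition, emulating inter-individual variability between
#'   replicate animals (pure multinomial resampling would make replicates
#'   unrealistically exchangeable).
#' @param min_base_abundance floor on each taxon's relative base abundance.
#'   The designed community consists of detectable taxa: every true taxon
#'   sits comfortably above the 0.1% per-sample filter threshold even after
#'   group effects dilute non-responsive taxa, so the only sub-threshold
#'   features in a rendered bundle are the designed satellite clusters.
#' @param organ_effect_fraction fraction of taxa responding to organ.
#' @param organ_fold multiplicative organ fold-change.
#' @param pond_effect_fraction fraction of taxa responding to pond.
#' @param pond_fold multiplicative pond fold-change.
#' @return list of parameters.
#' @export
truth_params <- function(n_families = 8L, seq_length = 150L,
                         seq_length_range = c(127L, 168L),
                         within_family_subs = 8L, between_family_subs = 24L,
                         lognormal_sdlog = 1.5,
                         min_base_abundance = 0.005,
                         replicate_sdlog = 0.5,
                         organ_effect_fraction = 0.3, organ_fold = 4,
                         pond_effect_fraction = 0.3, pond_fold = 3) {
  as.list(environment())
}

#' Per-set distortion design
#'
#' Controls how the three rendered cluster sets deviate from the truth:
#' the 99%-OTU-like set gains low-frequency satellite clusters 1-2 nt away
#' from abundant parents (emulating oversplitting of identity clustering at
#' a high cutoff), the 97%-OTU-like set merges near-identical taxa, swaps a
#' fraction of centroids for 1-nt private variants (representative-choice
#' differences) and truncates genus/species taxonomy labels (emulating its
#' lower taxonomic resolution); `shared_fraction` is the designed fraction
#' of true centroids identical across all three sets.
#'
#' @param shared_fraction fraction of true centroids shared by all sets.
#' @param satellite_parents number of most-abundant taxa receiving
#'   satellites in the 99%-OTU-like set.
#' @param satellite_count satellites per parent.
#' @param satellite_error_nt maximum nucleotide errors per satellite (>= 1).
#' @param satellite_read_fraction fraction of a parent's per-sample reads
#'   siphoned into each satellite, always capped strictly below the 0.1%
#'   per-sample abundance threshold.
#' @param merge_identity identity at or above which the 97%-OTU-like set
#'   merges taxa (NA disables merging).
#' @param truncation_prob named vector, probabilities of blanking the genus
#'   (and deeper) or the species label in the 97%-OTU-like set.
#' @return list of parameters.
#' @export
set_design <- function(shared_fraction = 0.8,
                       satellite_parents = 10L, satellite_count = 5L,
                       satellite_error_nt = 2L,
                       satellite_read_fraction = 0.01,
                       merge_identity = 0.97,
                       truncation_prob = c(genus = 0.3, species = 0.6)) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            satellite_error_nt >= 1)
  as.list(environment())
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# substitutions (+ optional single indel) on a DNA string, length kept in range
mutate_seq <- function(seq, n_subs, n_indels = 0L, length_range = c(1L, Inf)) {
  x <- strsplit(seq, "")[[1L]]
  if (n_subs > 0L) {
    pos <- sample(length(x), min(n_subs, length(x)))
    for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
  }
  for (k in seq_len(n_indels)) {
    if (runif(1) < 0.5 && length(x) < length_range[2L]) {
      at <- sample(length(x) + 1L, 1L)
      x <- append(x, sample(c("A", "C", "G", "T"), 1L), after = at - 1L)
    } else if (length(x) > length_range[1L]) {
      x <- x[-sample(length(x), 1L)]
    }
  }
  paste(x, collapse = "")
}

#' Generate the ground-truth community
#'
#' Builds `n_taxa` taxa with full 7-rank lineages, one V3-like centroid
#' sequence per taxon (generated by mutating a common ancestor so that
#' within-family taxa are more similar than across families, while all
#' inter-taxon identities stay below the 97% merge cutoff), lognormal base
#' abundances summing to 1, and designated organ- and pond-responsive taxa
#' with stated fold-changes.
#'
#' @param n_taxa number of true taxa (>= 5).
#' @param seed optional integer seed (fixed seed => bit-identical truth).
#' @param params community parameters, see [truth_params()].
#' @param design rendering design, see [set_design()]; stored for
#'   [render_cluster_sets()].
#' @return list of class `synthetic_truth`.
#' @export
generate_truth <- function(n_taxa = 40L, seed = NULL,
                           params = truth_params(), design = set_design()) {
  if (n_taxa < 5L) stop("n_taxa must be at least 5")
  if (params$organ_fold != 1 && params$lognormal_sdlog == 0 &&
      params$organ_effect_fraction == 0)
    stop("degenerate parameters: effects requested with zero variance")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_taxa))
  fam <- sort(rep_len(seq_len(params$n_families), n_taxa))
  tax <- cbind(
    kingdom = rep("Bacteria", n_taxa),
    phylum = sprintf("SimPhylum%02d", (fam - 1L) %/% 4L + 1L),
    class = sprintf("SimClass%02d", (fam - 1L) %/% 2L + 1L),
    order = sprintf("SimOrder%02d", fam),
    family = sprintf("SimFamily%02d", fam),
    genus = sprintf("SimGenus%03d", seq_len(n_taxa)),
    species = sprintf("sim_species_%03d", seq_len(n_taxa)))
  rownames(tax) <- ids
  tax <- taxonomy_table(tax)

  lr <- params$seq_length_range
  ancestor <- random_dna(params$seq_length)
  fam_anc <- vapply(seq_len(params$n_families), function(f)
    mutate_seq(ancestor, params$between_family_subs, n_indels = 1L,
               length_range = lr), "")
  centroids <- vapply(seq_len(n_taxa), function(i)
    mutate_seq(fam_anc[fam[i]], params$within_family_subs,
               n_indels = stats::rbinom(1L, 1L, 0.3), length_range = lr), "")
  names(centroids) <- ids
  # enforce: distinct sequences, all inter-taxon identities < merge cutoff
  for (pass in 1:25) {
    idn <- change_matrix(centroids)$identity
    diag(idn) <- 0
    bad <- which(idn >= 0.965, arr.ind = TRUE)
    if (!nrow(bad)) break
    i <- bad[1L, 1L]
    centroids[i] <- mutate_seq(centroids[i], 3L, length_range = lr)
  }
  if (any(nchar(centroids) < lr[1L]) || any(nchar(centroids) > lr[2L]))
    stop("internal: centroid length escaped the admissible range")

  base <- rlnorm(n_taxa, meanlog = 0, sdlog = params$lognormal_sdlog)
  base <- base / sum(base)
  for (k in 1:8) {                       # detectability floor, renormalised
    base <- pmax(base, params$min_base_abundance)
    base <- base / sum(base)
    if (min(base) >= params$min_base_abundance * 0.999) break
  }
  base <- setNames(base, ids)
  organ_effect <- setNames(rep(1, n_taxa), ids)
  organ_effect[sample(n_taxa, round(params$organ_effect_fraction * n_taxa))] <-
    params$organ_fold
  pond_effect <- setNames(rep(1, n_taxa), ids)
  pond_effect[sample(n_taxa, round(params$pond_effect_fraction * n_taxa))] <-
    params$pond_fold

  structure(list(taxon_ids = ids, taxonomy = tax, centroids = centroids,
                 base_abundances = base, organ_effect = organ_effect,
                 pond_effect = pond_effect, family = setNames(fam, ids),
                 params = params, design = design),
            class = "synthetic_truth")
}

# a fresh sequence `errors` nt away from `seq`, distinct from `taken`
satellite_sequence <- function(seq, max_errors, taken, length_range) {
  for (k in 1:50) {
    cand <- mutate_seq(seq, sample(max_errors, 1L), length_range = length_range)
    if (!(cand %in% taken)) return(cand)
  }
  stop("internal: could not draw a distinct satellite sequence")
}

#' Render the truth as three linked cluster sets
#'
#' Produces a fixture bundle with sample metadata (2 organs x 2 ponds x
#' `n_samples_per_group` replicates), multinomial per-sample counts from
#' the group-adjusted true abundances, and three cluster sets:
#'
#' * `03_ASV`: the true centroids and counts, full taxonomy.
#' * `02_OTU_99`: the ASV content plus `satellite_count` low-frequency
#'   satellite clusters (1-2 nt off) for each of the most abundant parents,
#'   each siphoning a small fraction of the parent's reads, always strictly
#'   below the 0.1% per-sample threshold.
#' * `01_OTU_97`: true centroids with taxa at or above `merge_identity`
#'   merged, a designed fraction of centroids swapped for 1-nt private
#'   variants (so exactly `shared_fraction` of true centroids are shared by
#'   all three sets), and genus/species labels truncated with the designed
#'   probabilities.
#'
#' Each set carries a rooted UPGMA tree built from pairwise alignment
#' identity distances.
#'
#' @param truth a [generate_truth()] result.
#' @param n_samples_per_group replicates per organ-pond group.
#' @param reads_per_sample sequencing depth per sample.
#' @param seed optional integer seed.
#' @return list of class `fixture_bundle`: `sets` (named list of
#'   [cluster_set()]s), `metadata`, `maps` (per-set feature -> true taxon,
#'   role) and `truth`.
#' @export
render_cluster_sets <- function(truth, n_samples_per_group = 6L,
                                reads_per_sample = 20000L, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  des <- truth$design
  par <- truth$params
  ids <- truth$taxon_ids
  n_taxa <- length(ids)

  grid <- expand.grid(rep = seq_len(n_samples_per_group),
                      pond = c("F3", "R2"), organ = c("I", "H"),
                      stringsAsFactors = FALSE)
  metadata <- sample_metadata(data.frame(
    sample_id = sprintf("%s%s_%02d", grid$organ, grid$pond, grid$rep),
    organ = grid$organ, pond = grid$pond, stringsAsFactors = FALSE))
  n_samples <- nrow(metadata)

  counts <- matrix(0L, n_taxa, n_samples, dimnames = list(ids, metadata$sample_id))
  for (j in seq_len(n_samples)) {
    p <- truth$base_abundances
    if (metadata$organ[j] == "H") p <- p * truth$organ_effect
    if (metadata$pond[j] == "R2") p <- p * truth$pond_effect
    p <- p * rlnorm(n_taxa, 0, par$replicate_sdlog)
    counts[, j] <- stats::rmultinom(1L, reads_per_sample, p / sum(p))
  }

  taken <- unname(truth$centroids)

  ## --- 03_ASV ---------------------------------------------------------
  asv_ids <- sprintf("asv_%03d", seq_len(n_taxa))
  asv_tab <- counts; rownames(asv_tab) <- asv_ids
  asv_tax <- truth$taxonomy; rownames(asv_tax) <- asv_ids
  asv_map <- data.frame(feature_id = asv_ids, true_taxon = ids,
                        role = "true", stringsAsFactors = FALSE)
  asv_centroids <- setNames(unname(truth$centroids), asv_ids)

  ## --- 02_OTU_99: truth + satellites ---------------------------------
  parents <- ids[order(-truth$base_abundances)][
    seq_len(min(des$satellite_parents, n_taxa))]
  cap <- ceiling(0.001 * reads_per_sample) - 1L   # strictly < 0.1% per sample
  o99_tab <- counts
  o99_centroids <- unname(truth$centroids)
  o99_tax <- unclass(truth$taxonomy)
  o99_map <- data.frame(feature_id = ids, true_taxon = ids, role = "true",
                        stringsAsFactors = FALSE)
  sat_rows <- list(); sat_meta <- list()
  dropped <- 0L
  if (des$satellite_count > 0L) {
    for (pid in parents) {
      for (s in seq_len(des$satellite_count)) {
        sseq <- satellite_sequence(truth$centroids[pid], des$satellite_error_nt,
                                   taken, par$seq_length_range)
        taken <- c(taken, sseq)
        sat <- pmin(round(des$satellite_read_fraction * counts[pid, ]),
                    cap)
        sat <- pmin(sat, o99_tab[pid, ])       # never overdraw the parent
        if (all(sat == 0L)) { dropped <- dropped + 1L; next }
        o99_tab[pid, ] <- o99_tab[pid, ] - sat
        sat_rows[[length(sat_rows) + 1L]] <- as.integer(sat)
        sat_meta[[length(sat_meta) + 1L]] <-
          list(parent = pid, seq = sseq)
      }
    }
  }
  if (dropped > 0L)
    warning(dropped, " satellite(s) dropped: reads_per_sample too small to ",
            "realize them", call. = FALSE)
  n_sat <- length(sat_rows)
  if (n_sat > 0L) {
    sat_mat <- do.call(rbind, sat_rows)
    o99_tab <- rbind(o99_tab, sat_mat)
    o99_centroids <- c(o99_centroids,
                       vapply(sat_meta, `[[`, "", "seq"))
    o99_tax <- rbind(o99_tax,
                     unclass(truth$taxonomy)[
                       vapply(sat_meta, `[[`, "", "parent"), , drop = FALSE])
    o99_map <- rbind(o99_map, data.frame(
      feature_id = rep(NA_character_, n_sat),
      true_taxon = vapply(sat_meta, `[[`, "", "parent"),
      role = "satellite", stringsAsFactors = FALSE))
  }
  o99_ids <- sprintf("otu99_%03d", seq_len(nrow(o99_tab)))
  rownames(o99_tab) <- o99_ids
  names(o99_centroids) <- o99_ids
  rownames(o99_tax) <- o99_ids
  o99_map$feature_id <- o99_ids
  o99_origin <- setNames(ifelse(o99_map$role == "satellite",
                                "de_novo", "reference"), o99_ids)

  ## --- 01_OTU_97: merges, private centroids, truncated taxonomy -------
  o97_tab <- counts
  o97_centroids <- truth$centroids
  n_private <- n_taxa - round(des$shared_fraction * n_taxa)
  private <- character(0)
  if (n_private > 0L) {
    eligible <- setdiff(ids, parents)
    if (length(eligible) < n_private) eligible <- ids
    private <- sample(eligible, n_private)
    for (pid in private) {
      v <- satellite_sequence(truth$centroids[pid], 1L, taken,
                              par$seq_length_range)
      taken <- c(taken, v)
      o97_centroids[pid] <- v
    }
  }
  # merge members reaching the identity cutoff (none under default truth,
  # which enforces inter-taxon identity < 0.965)
  keep <- rep(TRUE, n_taxa)
  merged_into <- setNames(ids, ids)
  if (!is.na(des$merge_identity)) {
    idn <- change_matrix(o97_centroids)$identity
    diag(idn) <- 0
    ord <- order(-rowSums(o97_tab))
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      for (b in seq_along(ord)) {
        j <- ord[b]
        if (i == j || !keep[j] || b < a) next
        if (idn[i, j] >= des$merge_identity) {
          o97_tab[i, ] <- o97_tab[i, ] + o97_tab[j, ]
          keep[j] <- FALSE
          merged_into[ids[j]] <- ids[i]
        }
      }
    }
  }
  o97_tab <- o97_tab[keep, , drop = FALSE]
  o97_centroids <- o97_centroids[keep]
  o97_tax <- unclass(truth$taxonomy)[keep, , drop = FALSE]
  kept_ids <- ids[keep]
  tp <- des$truncation_prob
  for (i in seq_along(kept_ids)) {
    if (stats::runif(1) < tp[["genus"]]) {
      o97_tax[i, c("genus", "species")] <- ""
    } else if (stats::runif(1) < tp[["species"]]) {
      o97_tax[i, "species"] <- ""
    }
  }
  o97_ids <- sprintf("otu97_%03d", seq_along(kept_ids))
  rownames(o97_tab) <- o97_ids
  names(o97_centroids) <- o97_ids
  rownames(o97_tax) <- o97_ids
  o97_map <- data.frame(feature_id = o97_ids, true_taxon = kept_ids,
                        role = ifelse(kept_ids %in% private,
                                      "private_variant", "true"),
                        stringsAsFactors = FALSE)
  o97_origin <- setNames(ifelse(kept_ids %in% private,
                                "de_novo", "reference"), o97_ids)

  make_set <- function(set_id, tab, centroids, tax, origin) {
    ft <- feature_table(tab)
    cluster_set(set_id, ft, centroids, taxonomy_table(tax),
                origin = origin, tree = upgma_tree(centroids))
  }
  sets <- list(
    `01_OTU_97` = make_set("01_OTU_97", o97_tab, o97_centroids, o97_tax,
                           o97_origin),
    `02_OTU_99` = make_set("02_OTU_99", o99_tab, o99_centroids, o99_tax,
                           o99_origin),
    `03_ASV` = make_set("03_ASV", asv_tab, asv_centroids,
                        unclass(asv_tax),
                        setNames(rep("reference", n_taxa), asv_ids)))
  maps <- list(`01_OTU_97` = o97_map, `02_OTU_99` = o99_map,
               `03_ASV` = asv_map)
  structure(list(sets = sets, metadata = metadata, maps = maps,
                 truth = truth),
            class = "fixture_bundle")
}

# rooted average-linkage dendrogram from alignment-identity distances
upgma_tree <- function(centroids) {
  idn <- change_matrix(centroids)$identity
  hc <- hclust(as.dist(1 - idn), method = "average")
  tree <- ape::as.phylo(hc)
  tree$edge.length[tree$edge.length < 0] <- 0
  validate_tree(tree)
}

#' Write a fixture bundle to disk
#'
#' One subdirectory per set (`table.tsv`, `centroids.fasta`,
#' `taxonomy.tsv`, `origin.tsv`, `tree.nwk`), plus `metadata.tsv` and a
#' `truth.json` with the generator's ground truth for recovery tests.  All
#' files are plain text and re-parse through the package readers.
#'
#' @param bundle a [render_cluster_sets()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(bundle$sets)) {
    s <- bundle$sets[[sid]]
    sd <- file.path(dir, sid)
    dir.create(sd, showWarnings = FALSE)
    write_feature_table(s$table, file.path(sd, "table.tsv"))
    write_fasta(s$centroids, file.path(sd, "centroids.fasta"))
    write_taxonomy(s$taxonomy, file.path(sd, "taxonomy.tsv"))
    write.table(data.frame(feature_id = names(s$origin), origin = s$origin),
                file.path(sd, "origin.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ape::write.tree(s$tree, file.path(sd, "tree.nwk"))
  }
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  tr <- bundle$truth
  truth_json <- list(
    taxon_ids = tr$taxon_ids,
    base_abundances = as.list(tr$base_abundances),
    organ_effect = as.list(tr$organ_effect),
    pond_effect = as.list(tr$pond_effect),
    centroids = as.list(tr$centroids),
    design = tr$design, params = tr$params,
    maps = bundle$maps)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read one cluster set from a directory written by [write_fixture_bundle()]
#'
#' @param dir set directory containing `table.tsv`, `centroids.fasta`,
#'   `taxonomy.tsv` and optionally `origin.tsv` and `tree.nwk`.
#' @param set_id identifier to attach (defaults to the directory name).
#' @return a [cluster_set()].
#' @export
read_cluster_set <- function(dir, set_id = basename(dir)) {
  tab <- read_feature_table(file.path(dir, "table.tsv"))
  cents <- read_fasta(file.path(dir, "centroids.fasta"))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  origin <- NULL
  op <- file.path(dir, "origin.tsv")
  if (file.exists(op)) {
    odf <- read.delim(op, colClasses = "character")
    origin <- setNames(odf$origin, odf$feature_id)
  }
  tree <- NULL
  tp <- file.path(dir, "tree.nwk")
  if (file.exists(tp)) tree <- read_newick(tp)
  cluster_set(set_id, tab, cents, tax, origin = origin, tree = tree)
}
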