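#' Assemble and validate a full-run configuration
#'
#' One flat configuration drives the whole concordance run.  Every
#' referenced path is checked at validation time, and requesting a UniFrac
#' metric for a set without a tree fails here, before any computation.
#'
#' @param sets named list; each element a list with paths `table`,
#'   `centroids`, `taxonomy` and optionally `origin`, `tree`.  Names are
#'   the set ids.
#' @param metadata path to the sample metadata TSV.
#' @param out_dir output directory.
#' @param min_frac relative-abundance filter threshold (study value 0.001).
#' @param drop_sample_singletons apply the sample-singleton filter first.
#' @param max_changes,min_identity,thresholds sequence-concordance
#'   parameters (study gate 0.75).
#' @param levels taxonomic levels (rank indices) for the taxonomy stage.
#' @param reference_set set id used by the differential-taxa screen;
#'   defaults to the first set.
#' @param alpha_iterations rarefaction draws per sample for alpha diversity
#'   (study value 10000).
#' @param rarefaction_draws draws behind the average-rarefied beta table.
#' @param beta_metrics metrics for [beta_distance()].
#' @param n_permutations ANOSIM permutations.
#' @param alpha significance level reported in test tables.
#' @param seed master seed; all stage seeds are derived from it.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(sets, metadata, out_dir,
                       min_frac = 0.001, drop_sample_singletons = TRUE,
                       max_changes = 20L, min_identity = 0.75,
                       thresholds = seq(1, 0.75, by = -0.01),
                       levels = c(2L, 5L, 6L, 7L),
                       reference_set = names(sets)[1L],
                       alpha_iterations = 10000L,
                       rarefaction_draws = 100L,
                       beta_metrics = c("jaccard", "braycurtis"),
                       n_permutations = 999L,
                       alpha = 0.05, seed = 1L) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  for (sid in names(sets)) {
    s <- sets[[sid]]
    for (f in c("table", "centroids", "taxonomy"))
      if (is.null(s[[f]]) || !file.exists(s[[f]]))
        stop("set ", sid, ": missing or nonexistent ", f, " path")
    for (f in c("origin", "tree"))
      if (!is.null(s[[f]]) && !file.exists(s[[f]]))
        stop("set ", sid, ": nonexistent ", f, " path: ", s[[f]])
    if (any(grepl("unifrac", beta_metrics)) && is.null(s[["tree"]]))
      stop("set ", sid, ": UniFrac requested but no tree provided")
  }
  if (!file.exists(metadata)) stop("nonexistent metadata path: ", metadata)
  if (!reference_set %in% names(sets))
    stop("reference_set not among set ids: ", reference_set)
  cfg <- mget(c("sets", "metadata", "out_dir", "min_frac",
                "drop_sample_singletons", "max_changes", "min_identity",
                "thresholds", "levels", "reference_set", "alpha_iterations",
                "rarefaction_draws", "beta_metrics", "n_permutations",
                "alpha", "seed"))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a flat JSON file
#'
#' Relative paths are resolved against the JSON file's directory.
#'
#' @param path JSON file mirroring [run_config()]'s arguments.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(path))
  fix <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  raw$sets <- lapply(raw$sets, function(s) lapply(s, fix))
  raw$metadata <- fix(raw$metadata)
  do.call(run_config, raw)
}

derive_seed <- function(master, offset) (master * 97L + offset) %% 2147483647L

#' Run the full concordance analysis
#'
#' Fixed stage order: read + validate, sequence concordance (on the raw
#' sets, as overlap/resilience describe the unfiltered centroids), filters
#' (sample-singletons then the tailored abundance filter), taxonomy
#' concordance, alpha diversity and beta diversity (both on the filtered
#' sets).  Every stage writes its TSV outputs under `out_dir`, a summary
#' JSON collates the machine-readable results and a MANIFEST lists every
#' file written.  Identical config + seed produce byte-identical output.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly; on-disk outputs as described.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  emit <- function(obj, rel) {
    path <- file.path(config$out_dir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <<- c(manifest, rel)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(manifest, paste0("# INCOMPLETE: failed at stage ", name)),
                 file.path(config$out_dir, "MANIFEST.tsv"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  summ <- list(schema = "ampliconcord-summary/1",
                  seed = config$seed,
                  alpha = config$alpha)

  ## stage: load
  sets <- stage("load", {
    metadata <- read_metadata(config$metadata)
    s <- lapply(names(config$sets), function(sid) {
      p <- config$sets[[sid]]
      tab <- read_feature_table(p$table)
      origin <- NULL
      if (!is.null(p$origin)) {
        odf <- read.delim(p$origin, colClasses = "character")
        origin <- setNames(odf$origin, odf$feature_id)
      }
      tree <- if (!is.null(p$tree)) read_newick(p$tree) else NULL
      miss <- setdiff(colnames(tab), metadata$sample_id)
      if (length(miss))
        stop("sample(s) without metadata in ", sid, ": ",
             paste(miss, collapse = ", "))
      cluster_set(sid, tab, read_fasta(p$centroids),
                  read_taxonomy(p$taxonomy), origin = origin, tree = tree)
    })
    names(s) <- names(config$sets)
    s
  })
  metadata <- read_metadata(config$metadata)

  ## stage: sequence concordance (raw sets)
  stage("seqcompare", {
    ov <- exact_overlap(sets)
    emit(ov, "seqcompare/overlap_partition.tsv")
    summ$overlap <- ov
    dp <- do.call(rbind, lapply(sets, function(s) {
      d <- difference_profile(s, config$max_changes, config$min_identity)
      if (nrow(d)) cbind(set_id = s$set_id, d) else NULL
    }))
    emit(dp, "seqcompare/difference_profile.tsv")
    rc <- do.call(rbind, lapply(sets, function(s)
      cbind(set_id = s$set_id, resilience_curve(s, config$thresholds))))
    emit(rc, "seqcompare/resilience.tsv")
    ob <- do.call(rbind, lapply(sets, function(s)
      cbind(set_id = s$set_id, origin_breakdown(s))))
    emit(ob, "seqcompare/origin_breakdown.tsv")
  })

  ## stage: filters
  filtered <- stage("filter", {
    reports <- list()
    out <- lapply(sets, function(s) {
      tab <- s$table
      if (config$drop_sample_singletons) {
        r1 <- remove_sample_singletons(tab)
        tab <- r1$table
      } else r1 <- NULL
      r2 <- abundance_filter(tab, config$min_frac)
      reports[[s$set_id]] <<- list(
        singleton = if (is.null(r1)) NULL else unclass(r1$report)[
          c("reads_before", "reads_after", "features_before",
            "features_after", "percent_reads_lost")],
        abundance = unclass(r2$report)[
          c("reads_before", "reads_after", "features_before",
            "features_after", "percent_reads_lost")])
      s$table <- r2$table
      s$centroids <- s$centroids[rownames(r2$table)]
      s$origin <- s$origin[rownames(r2$table)]
      s$taxonomy <- s$taxonomy[rownames(r2$table), , drop = FALSE]
      class(s$taxonomy) <- c("taxonomy_table", "matrix", "array")
      s
    })
    summ$filter_reports <- reports
    frep <- do.call(rbind, lapply(names(reports), function(sid) data.frame(
      set_id = sid,
      features_before = reports[[sid]]$abundance$features_before,
      features_after = reports[[sid]]$abundance$features_after,
      reads_before = reports[[sid]]$abundance$reads_before,
      reads_after = reports[[sid]]$abundance$reads_after,
      percent_reads_lost = reports[[sid]]$abundance$percent_reads_lost)))
    emit(frep, "filter/filter_report.tsv")
    out
  })

  ## stage: taxonomy concordance (filtered sets)
  stage("taxcompare", {
    rp <- do.call(rbind, lapply(filtered, function(s)
      cbind(set_id = s$set_id, resolution_profile(s))))
    emit(rp, "taxcompare/resolution.tsv")
    summ$resolution <- rp
    cors <- list()
    pairs <- combn(names(filtered), 2L)
    for (lv in config$levels) {
      venn <- taxa_overlap(filtered, lv)
      emit(venn, sprintf("taxcompare/venn_L%d.tsv", lv))
      for (k in seq_len(ncol(pairs))) {
        r <- cross_set_correlation(filtered[[pairs[1L, k]]],
                                   filtered[[pairs[2L, k]]], lv)
        cors[[length(cors) + 1L]] <- data.frame(
          level = lv, rank = r$rank, set_a = pairs[1L, k],
          set_b = pairs[2L, k], rho = r$rho, n_taxa = r$n_taxa)
      }
    }
    cors <- do.call(rbind, cors)
    emit(cors, "taxcompare/correlations.tsv")
    summ$correlations <- cors
    others <- filtered[setdiff(names(filtered), config$reference_set)]
    diff <- differential_taxa(filtered[[config$reference_set]], others,
                              max(config$levels))
    emit(diff, "taxcompare/differential.tsv")
  })

  ## stage: alpha diversity (filtered sets)
  stage("alpha", {
    tests <- list()
    for (s in filtered) {
      res <- alpha_pipeline(s$table, metadata,
                            iterations = config$alpha_iterations,
                            seed = derive_seed(config$seed, 101L +
                                                 match(s$set_id, names(filtered))),
                            alpha = config$alpha)
      emit(res$estimates, sprintf("alpha/estimates_%s.tsv", s$set_id))
      tests[[s$set_id]] <- cbind(set_id = s$set_id, res$comparisons)
    }
    tests <- do.call(rbind, tests)
    rownames(tests) <- NULL
    emit(tests, "alpha/tests.tsv")
    summ$alpha_tests <- tests
  })

  ## stage: beta diversity (filtered sets)
  stage("beta", {
    anosim_rows <- list()
    for (s in filtered) {
      depth <- min(colSums(s$table))
      avg <- average_rarefied_table(
        s$table, depth, n_draws = config$rarefaction_draws,
        seed = derive_seed(config$seed, 201L + match(s$set_id, names(filtered))))
      tree <- s$tree
      if (!is.null(tree)) tree <- ape::keep.tip(tree,
        intersect(tree$tip.label, rownames(avg)))
      for (m in config$beta_metrics) {
        D <- beta_distance(avg, m, tree = tree)
        emit(data.frame(sample_id = rownames(D), D, check.names = FALSE),
             sprintf("beta/dist_%s_%s.tsv", m, s$set_id))
        ord <- pcoa(D)
        emit(data.frame(sample_id = rownames(ord$coordinates),
                        ord$coordinates, check.names = FALSE),
             sprintf("beta/pcoa_%s_%s.tsv", m, s$set_id))
        groups <- setNames(metadata$organ_pond, metadata$sample_id)
        res <- list()
        for (g in c("organ", "pond", "organ_pond")) {
          gg <- setNames(metadata[[g]], metadata$sample_id)
          res[[g]] <- anosim(D, gg[rownames(D)],
                             n_permutations = config$n_permutations,
                             seed = derive_seed(config$seed, 301L))
        }
        anosim_rows[[length(anosim_rows) + 1L]] <- data.frame(
          metric = m, set_id = s$set_id,
          org_R = res$organ$R, pond_R = res$pond$R,
          org_pond_R = res$organ_pond$R,
          org_p = res$organ$p_value, pond_p = res$pond$p_value,
          org_pond_p = res$organ_pond$p_value)
        ph <- anosim_pairwise(D, setNames(metadata$organ_pond,
                                          metadata$sample_id)[rownames(D)],
                              n_permutations = config$n_permutations,
                              seed = derive_seed(config$seed, 401L))
        emit(ph, sprintf("beta/anosim_posthoc_%s_%s.tsv", m, s$set_id))
      }
    }
    anosim_tab <- do.call(rbind, anosim_rows)
    emit(anosim_tab, "beta/anosim.tsv")
    summ$anosim <- anosim_tab
  })

  jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  manifest <- c(manifest, "summary.json")
  writeLines(c("file", sort(manifest)), file.path(config$out_dir, "MANIFEST.tsv"))
  invisible(summ)
}
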