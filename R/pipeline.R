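#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates the stages end to end: depth filtering, genus collapse,
#' alpha/beta diversity with PERMANOVA and PCoA, the random-forest symptom
#' index with shadow-feature selection and covariate associations, the
#' reference-cloud dysbiosis index with 2-SD classification, the
#' logit-scale orthogonal validation and score agreement, and permutation
#' differential abundance.  Every stage output is written as TSV/JSON into
#' `out_dir` together with a run manifest.
#'
#' @param config Named list (or path to a YAML/JSON file) with entries:
#'   `counts`, `metadata`, `tree` (file paths) or `cohort` (a
#'   [generate_cohort()] result passed programmatically); optional
#'   `reference_group` (default `"healthy"`), `min_reads` (1000),
#'   `rarefy_depth` (5000), `level` (`"genus"`), `ranks` (`"genus"`),
#'   `n_perm` (1000), `n_trees` (500), `boruta_max_iter` (50),
#'   `boruta_trees` (300), `beta` (`c("braycurtis","unifrac")`),
#'   `seed` (1).
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  ref_group <- cfg$reference_group %||% "healthy"

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    md_log("stage ", name, " done in ",
           sprintf("%.1fs", as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  inputs <- stage("load", {
    if (!is.null(cfg$cohort)) {
      stopifnot(inherits(cfg$cohort, "synthetic_cohort"))
      list(table = cfg$cohort$table, metadata = cfg$cohort$metadata,
           tree = cfg$cohort$tree)
    } else {
      if (is.null(cfg$counts) || is.null(cfg$metadata))
        stop_input("config must name counts and metadata (or a cohort)")
      tab <- read_count_table(cfg$counts)
      tree <- NULL
      if (!is.null(cfg$tree))
        tree <- read_tree(cfg$tree, taxon_ids = rownames(tab$counts))
      list(table = tab, metadata = read_metadata(cfg$metadata), tree = tree)
    }
  })
  beta_metrics <- cfg$beta %||% c("braycurtis", "unifrac")
  if ("unifrac" %in% beta_metrics && is.null(inputs$tree))
    stop_input("UniFrac requested but no tree provided; ",
               "supply 'tree' in the config or drop 'unifrac' from 'beta'")

  table <- stage("filter", filter_low_depth(inputs$table,
                                            cfg$min_reads %||% 1000))
  md <- inputs$metadata[inputs$metadata$sample_id %in%
                          colnames(table$counts), ]
  genus <- stage("collapse", if (!is.null(table$taxonomy))
    collapse_to_rank(table, cfg$level %||% "genus") else table)

  alpha <- stage("alpha_diversity", alpha_diversity(
    table, tree = inputs$tree, rarefy_depth = cfg$rarefy_depth %||% 5000,
    seed = derive_seed(seed, "rarefy")))
  write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))

  beta <- stage("beta_diversity", {
    out <- list()
    if ("braycurtis" %in% beta_metrics) out$braycurtis <- bray_curtis(genus)
    if ("unifrac" %in% beta_metrics)
      out$unifrac <- unweighted_unifrac(table, inputs$tree)
    out
  })
  perm <- list()
  for (metric in names(beta)) {
    dm <- beta[[metric]]
    write_square_tsv(dm, file.path(out_dir, paste0(metric, "_distance.tsv")))
    labels <- md$group[match(rownames(dm), md$sample_id)]
    perm[[metric]] <- stage(paste0("permanova_", metric),
                            permanova(dm, labels, n_perm = cfg$n_perm %||% 999,
                                      seed = derive_seed(seed, metric)))
    ord <- pcoa(dm)
    coords <- data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates[, seq_len(min(3L,
                           ncol(ord$coordinates))), drop = FALSE])
    write_tsv(coords, file.path(out_dir, paste0(metric, "_pcoa.tsv")))
  }

  si_fit <- stage("symptom_index", {
    feats <- t(normalize_counts(genus)$normalized)
    fit_symptom_index(feats, md$group[match(rownames(feats),
                                            md$sample_id)],
                      n_trees = cfg$n_trees %||% 500,
                      seed = derive_seed(seed, "si"))
  })
  write_tsv(data.frame(sample_id = names(si_fit$si), si = si_fit$si),
            file.path(out_dir, "si.tsv"))
  jsonlite::write_json(si_fit$auc, file.path(out_dir, "auc.json"),
                       auto_unbox = TRUE, digits = NA)

  boruta <- stage("feature_selection", {
    feats <- t(normalize_counts(genus)$normalized)
    boruta_select(feats, md$group[match(rownames(feats), md$sample_id)],
                  max_iter = cfg$boruta_max_iter %||% 50,
                  n_trees = cfg$boruta_trees %||% 300,
                  seed = derive_seed(seed, "boruta"))
  })
  write_tsv(data.frame(feature = names(boruta$status),
                       status = as.character(boruta$status),
                       hits = boruta$hits, row.names = NULL),
            file.path(out_dir, "boruta.tsv"))

  assoc <- stage("associations",
                 covariate_regression(si_fit$si, md))
  write_tsv(assoc$table, file.path(out_dir, "associations.tsv"))

  cloud <- stage("cloud_dysbiosis",
                 cloud_dysbiosis(table, md, reference_group = ref_group,
                                 level = if (!is.null(table$taxonomy))
                                   cfg$level %||% "genus"))
  write_tsv(cloud$scores, file.path(out_dir, "cloud.tsv"))
  jsonlite::write_json(
    list(reference_mean = cloud$reference_mean,
         reference_sd = cloud$reference_sd, threshold = cloud$threshold),
    file.path(out_dir, "cloud_threshold.json"), auto_unbox = TRUE,
    digits = NA)

  ortho <- stage("orthogonal_validation", {
    feats <- t(normalize_counts(genus)$normalized)
    orthogonal_validation(si_fit$si,
                          md$sample_id[md$group == ref_group],
                          features = feats,
                          n_trees = cfg$n_trees %||% 500,
                          seed = derive_seed(seed, "ortho"))
  })
  agree <- stage("agreement", {
    if (is.null(ortho$probability_index)) NULL
    else agreement_correlation(
      setNames(cloud$scores$cloud_stat, cloud$scores$sample_id),
      ortho$probability_index,
      cloud_labels = setNames(cloud$scores$classification,
                              cloud$scores$sample_id),
      index_labels = ortho$labels)
  })
  if (!is.null(agree))
    jsonlite::write_json(c(agree, normality_p = ortho$normality_p),
                         file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)

  da <- stage("differential_abundance", differential_abundance(
    table, md, ranks = cfg$ranks %||% "genus",
    n_perm = cfg$n_perm %||% 1000, seed = derive_seed(seed, "da")))
  write_tsv(da, file.path(out_dir, "differential_abundance.tsv"))

  manifest <- list(
    package_version = as.character(packageVersion("microdys")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = cfg[setdiff(names(cfg), "cohort")],
    permanova = lapply(perm, function(x) x[c("f", "p")]),
    outputs = c(list.files(out_dir), "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.json$", config)) return(jsonlite::read_json(config))
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_input("YAML configs require the 'yaml' package")
    return(yaml::read_yaml(config))
  }
  stopifnot(is.list(config))
  config
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_square_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize pipeline outputs into a report
#'
#' Reads the stage files written by [run_pipeline()] and produces a
#' machine-readable JSON summary plus a short human-readable text file:
#' per-group alpha-diversity means, PERMANOVA statistics, AUC,
#' classification counts, and significant taxa per rank.  Missing stage
#' files are flagged as gaps rather than errors.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param metadata Data frame with `sample_id` and `group` used to group
#'   summaries.
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return The report list, invisibly; writes `report.json` and
#'   `report.txt` into `out_dir`.
#' @export
render_report <- function(out_dir, metadata, q_threshold = 0.05) {
  report <- list(gaps = character(0L))
  grab <- function(name) {
    path <- file.path(out_dir, name)
    if (!file.exists(path)) {
      report$gaps <<- c(report$gaps, name)
      return(NULL)
    }
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  alpha <- grab("alpha_diversity.tsv")
  if (!is.null(alpha)) {
    alpha$group <- metadata$group[match(alpha$sample_id,
                                        metadata$sample_id)]
    num <- intersect(c("observed_taxa", "shannon", "pielou_evenness",
                       "faith_pd"), colnames(alpha))
    report$alpha_by_group <- aggregate(alpha[num], list(group = alpha$group),
                                       mean)
  }
  manifest <- if (file.exists(file.path(out_dir, "manifest.json")))
    jsonlite::read_json(file.path(out_dir, "manifest.json"))
  report$permanova <- manifest$permanova
  if (file.exists(file.path(out_dir, "auc.json")))
    report$auc <- jsonlite::read_json(file.path(out_dir, "auc.json"))
  cloud <- grab("cloud.tsv")
  if (!is.null(cloud)) {
    cloud$group <- metadata$group[match(cloud$sample_id,
                                        metadata$sample_id)]
    report$classification_counts <-
      as.data.frame(table(group = cloud$group,
                          classification = cloud$classification))
  }
  da <- grab("differential_abundance.tsv")
  if (!is.null(da)) {
    sig <- da[!is.na(da$q) & da$q < q_threshold, ]
    report$n_significant_taxa <- nrow(sig)
    report$significant_taxa <- sig[, c("rank", "taxon", "t", "p", "q")]
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  lines <- c("microdys pipeline report", "========================")
  if (!is.null(report$n_significant_taxa))
    lines <- c(lines, sprintf("%d taxa significant at q < %s",
                              report$n_significant_taxa, q_threshold))
  if (!is.null(cloud))
    lines <- c(lines, sprintf("%d / %d samples classified dysbiotic",
                              sum(cloud$classification == "dysbiotic"),
                              nrow(cloud)))
  if (length(report$gaps))
    lines <- c(lines, paste("missing stage outputs:",
                            paste(report$gaps, collapse = ", ")))
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(report)
}

#' Write a synthetic cohort to disk
#'
#' Writes `counts.tsv`, `metadata.tsv`, `tree.nwk`, `truth.tsv` and a
#' `manifest.json` describing the generating specification.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$table, file.path(out_dir, "counts.tsv"))
  write_tsv(cohort$metadata, file.path(out_dir, "metadata.tsv"))
  ape::write.tree(cohort$tree, file.path(out_dir, "tree.nwk"))
  truth <- cohort$truth$sample_class
  write_tsv(truth, file.path(out_dir, "truth.tsv"))
  spec <- cohort$spec
  jsonlite::write_json(
    c(spec[setdiff(names(spec), "covariate_model")],
      list(taxon_fold_change = as.list(cohort$truth$taxon_fold_change))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}
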