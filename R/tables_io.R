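#' Construct a taxon-by-sample count table
#'
#' The central container consumed by every analysis stage: a non-negative
#' integer matrix with taxa as rows and samples as columns, plus an optional
#' taxonomy with up to seven ranks (kingdom to species).
#'
#' @param counts Non-negative integer matrix, taxa x samples, with unique
#'   row (taxon) and column (sample) names.
#' @param taxonomy Optional character matrix or data frame, one row per
#'   taxon (rownames matching `counts`), columns a prefix of
#'   `c("kingdom","phylum","class","order","family","genus","species")`.
#'   `NA` marks an unassigned rank.
#' @return An object of class `count_table` with elements `counts` and
#'   `taxonomy` (`NULL` when absent).
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_input("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_input("duplicate taxon IDs")
  if (anyDuplicated(colnames(counts)))
    stop_input("duplicate sample IDs")
  if (any(is.na(counts)))
    stop_input("counts contain missing values")
  if (any(counts < 0))
    stop_input("negative counts are not allowed")
  if (any(counts != round(counts)))
    stop_input("counts must be integers")
  storage.mode(counts) <- "double"  # keeps depths > .Machine$integer.max safe
  if (!is.null(taxonomy)) {
    taxonomy <- as.matrix(taxonomy)
    ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
    if (ncol(taxonomy) > 7L)
      stop_input("taxonomy may have at most 7 ranks")
    if (is.null(colnames(taxonomy)))
      colnames(taxonomy) <- ranks[seq_len(ncol(taxonomy))]
    if (!all(colnames(taxonomy) %in% ranks))
      stop_input("unknown taxonomy rank(s): ",
                 paste(setdiff(colnames(taxonomy), ranks), collapse = ", "))
    if (is.null(rownames(taxonomy))) rownames(taxonomy) <- rownames(counts)
    if (!setequal(rownames(taxonomy), rownames(counts)))
      stop_input("taxonomy must cover exactly the taxa of the count table")
    taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "taxa x", ncol(x$counts), "samples\n")
  cat("  read depth: median", stats::median(sample_depths(x)),
      "range", paste(range(sample_depths(x)), collapse = "-"), "\n")
  if (!is.null(x$taxonomy))
    cat("  taxonomy ranks:", paste(colnames(x$taxonomy), collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample read depths (column sums)
#' @param table A `count_table`.
#' @return Named numeric vector of per-sample totals.
#' @export
sample_depths <- function(table) {
  stopifnot(inherits(table, "count_table"))
  colSums(table$counts)
}

#' Read a count table from TSV or BIOM-JSON
#'
#' The TSV dialect is the classic OTU-table layout: taxa as rows, a first
#' column of taxon IDs (conventionally headed `#TaxonID`), samples as
#' columns, and optionally a final `taxonomy` column holding
#' semicolon-separated lineages.  Tables stored transposed are handled via
#' `orientation = "samples_rows"`.  BIOM-JSON (format 1.0) is accepted
#' read-only.
#'
#' @param path Path to a tab-separated table or a BIOM-JSON file.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @param format `"auto"` (by file extension), `"tsv"` or `"biom"`.
#' @return A [count_table].
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                             format = c("auto", "tsv", "biom")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE))
      "biom" else "tsv"
  if (format == "biom") return(read_biom_table(path))

  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop_input("count table needs an ID column plus data")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) stop_input("duplicate IDs in first column")
  lineage <- NULL
  if (tolower(colnames(raw)[ncol(raw)]) == "taxonomy") {
    lineage <- as.character(raw[[ncol(raw)]])
    raw <- raw[, -ncol(raw), drop = FALSE]
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_input("non-numeric cells in count table")
  rownames(m) <- ids
  if (orientation == "samples_rows") {
    m <- t(m)
    lineage <- NULL  # lineages only make sense attached to taxon rows
  }
  taxonomy <- if (!is.null(lineage)) parse_lineages(lineage, rownames(m))
  count_table(m, taxonomy = taxonomy)
}

read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop_input("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))
  om <- biomformat::observation_metadata(b)
  taxonomy <- NULL
  if (!is.null(om) && length(om) > 0L) {
    lin <- vapply(seq_len(nrow(m)), function(i) {
      x <- if (is.data.frame(om)) unlist(om[i, ]) else om[[i]]
      paste(x[!is.na(x) & nzchar(x)], collapse = "; ")
    }, character(1L))
    taxonomy <- parse_lineages(lin, rownames(m))
  }
  count_table(m, taxonomy = taxonomy)
}

parse_lineages <- function(lineage, taxon_ids) {
  parts <- strsplit(lineage, ";\\s*")
  depth <- max(lengths(parts))
  if (depth > 7L) stop_input("lineages deeper than 7 ranks")
  tax <- t(vapply(parts, function(p) {
    p <- sub("^[kpcofgs]__", "", p)  # tolerate greengenes-style prefixes
    p[!nzchar(p)] <- NA_character_
    c(p, rep(NA_character_, depth - length(p)))
  }, character(depth)))
  rownames(tax) <- taxon_ids
  colnames(tax) <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")[seq_len(depth)]
  tax
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()] for the TSV dialect; taxonomy, when
#' present, is written as a final semicolon-separated `taxonomy` column.
#'
#' @param table A [count_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(`#TaxonID` = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) {
    df$taxonomy <- apply(table$taxonomy, 1L, function(p)
      paste(ifelse(is.na(p), "", p), collapse = "; "))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' Tab-separated with a header; must contain `sample_id` and `group`
#' columns.  `group` may never be missing; other covariates may contain
#' `NA`, which downstream analyses drop listwise per test.
#'
#' @param path Path to a TSV file.
#' @return A data frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(md)))
    stop_input("metadata must contain sample_id and group columns")
  if (anyDuplicated(md$sample_id)) stop_input("duplicate sample_id in metadata")
  if (any(is.na(md$group) | !nzchar(md$group)))
    stop_input("group may not be missing")
  for (col in intersect(c("antibiotics_recent", "ppi", "gi_surgery"),
                        colnames(md)))
    md[[col]] <- as.logical(md[[col]])
  if ("sibo_cfu" %in% colnames(md) &&
      any(md$sibo_cfu < 0, na.rm = TRUE))
    stop_input("sibo_cfu must be non-negative")
  md
}

#' Remove samples below a read-depth threshold
#'
#' Samples with fewer than `min_reads` total reads are removed (the
#' threshold is strict: a sample with exactly `min_reads` reads is kept).
#' Removed sample IDs are reported via `message()`.
#'
#' @param table A [count_table].
#' @param min_reads Minimum acceptable depth (default 1000).
#' @return The filtered [count_table].
#' @export
filter_low_depth <- function(table, min_reads = 1000) {
  stopifnot(inherits(table, "count_table"), min_reads >= 0)
  depths <- sample_depths(table)
  drop <- depths < min_reads
  if (all(drop))
    stop_input("all samples fall below ", min_reads, " reads")
  if (any(drop))
    md_log("filter_low_depth: removed ", sum(drop), " sample(s): ",
           paste(names(depths)[drop], collapse = ", "))
  keep_samples(table, !drop)
}

keep_samples <- function(table, keep) {
  count_table(table$counts[, keep, drop = FALSE], taxonomy = table$taxonomy)
}

#' Collapse a count table to a taxonomic rank
#'
#' Counts are summed over taxa whose lineages agree up to `rank`.  Taxa
#' unassigned at any rank of the truncated lineage contribute to an
#' `"unclassified"` bin within their assigned parent lineage, so per-sample
#' depth is conserved exactly.
#'
#' @param table A [count_table] with taxonomy.
#' @param rank One of the rank names present in the taxonomy.
#' @return A [count_table] whose taxa are the distinct truncated lineages,
#'   named by their value at `rank` (disambiguated by lineage if needed).
#' @export
collapse_to_rank <- function(table, rank) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$taxonomy)) stop_input("table has no taxonomy")
  ranks <- colnames(table$taxonomy)
  if (!rank %in% ranks)
    stop_input("rank '", rank, "' absent from taxonomy (has: ",
               paste(ranks, collapse = ", "), ")")
  upto <- seq_len(match(rank, ranks))
  lin <- table$taxonomy[, upto, drop = FALSE]
  lin[is.na(lin)] <- "unclassified"
  key <- apply(lin, 1L, paste, collapse = "; ")
  agg <- rowsum(table$counts, group = key, reorder = TRUE)
  newtax <- unique(cbind(lin, key = key))
  newtax <- newtax[match(rownames(agg), newtax[, "key"]), , drop = FALSE]
  label <- newtax[, rank]
  dup <- duplicated(label) | duplicated(label, fromLast = TRUE)
  label[dup] <- rownames(agg)[dup]  # e.g. the "unclassified" bins
  rownames(agg) <- label
  tax <- newtax[, colnames(newtax) != "key", drop = FALSE]
  tax[tax == "unclassified"] <- NA_character_
  rownames(tax) <- label
  count_table(agg, taxonomy = tax)
}

#' Classify a duodenal aspirate culture result as SIBO positive or negative
#'
#' Small intestinal bacterial overgrowth is culture-defined by bacterial
#' growth of at least 1e5 CFU/mL in duodenal aspirate; the boundary is
#' inclusive.
#'
#' @param cfu Non-negative culture result(s) in CFU/mL.
#' @return Character vector, `"positive"` or `"negative"` (`NA` passed
#'   through).
#' @export
classify_sibo <- function(cfu) {
  if (any(cfu < 0, na.rm = TRUE)) stop_input("cfu must be non-negative")
  ifelse(is.na(cfu), NA_character_,
         ifelse(cfu >= 1e5, "positive", "negative"))
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Path to a Newick tree with branch lengths.
#' @param taxon_ids Optional taxon IDs to reconcile against the tip labels;
#'   a mismatch raises a warning listing the symmetric difference.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path, taxon_ids = NULL) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop_input("Newick parse error: ",
                                                  conditionMessage(e)))
  if (is.null(tree) || is.null(tree$tip.label))
    stop_input("Newick parse error: no tree read")
  if (is.null(tree$edge.length))
    stop_input("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop_input("negative branch length(s) in tree")
  if (anyDuplicated(tree$tip.label))
    stop_input("duplicate tip labels")
  if (!ape::is.rooted(tree))
    stop_input("tree must be rooted")
  if (!is.null(taxon_ids)) {
    extra <- setdiff(tree$tip.label, taxon_ids)
    missing <- setdiff(taxon_ids, tree$tip.label)
    if (length(extra) || length(missing))
      warning("tree tips and table taxa differ: ",
              paste(sort(c(extra, missing)), collapse = ", "),
              call. = FALSE)
  }
  tree
}
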