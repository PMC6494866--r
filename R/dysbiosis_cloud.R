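#' Multiplicative zero replacement on the simplex
#'
#' Zeros in each composition are replaced by `delta` and the nonzero parts
#' are scaled down by `1 - z * delta` (z = number of zeros in the row), so
#' every row still sums to 1.  Rows without zeros are returned unchanged.
#'
#' @param proportions Matrix of compositions, samples x taxa, rows on the
#'   simplex.
#' @param delta Replacement value; scalar or one value per sample.  Must be
#'   smaller than the smallest nonzero proportion of every row it touches.
#' @return Strictly positive matrix with unit row sums.
#' @export
multiplicative_replacement <- function(proportions, delta = 1e-6) {
  m <- as.matrix(proportions)
  if (any(abs(rowSums(m) - 1) > 1e-6))
    stop_input("rows must sum to 1")
  delta <- rep_len(delta, nrow(m))
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] == 0
    if (!any(z)) next
    if (all(z)) stop_input("all-zero composition in row ", i)
    if (delta[i] >= min(m[i, !z]))
      stop_input("delta (", delta[i], ") >= smallest nonzero proportion ",
                 "in row ", i)
    m[i, !z] <- m[i, !z] * (1 - sum(z) * delta[i])
    m[i, z] <- delta[i]
  }
  m
}

#' Centered log-ratio (CLR) transform
#'
#' \eqn{clr_i = \ln x_i - \frac{1}{D}\sum_j \ln x_j}: the log of each part
#' relative to the row's geometric mean.  Rows sum to zero and the
#' transform is invariant to rescaling a row by any positive constant.
#'
#' @param x Strictly positive matrix, samples x taxa (compositions or raw
#'   positive abundances).
#' @return CLR matrix of the same shape, rows summing to 0.
#' @export
clr_transform <- function(x) {
  m <- as.matrix(x)
  if (any(m <= 0))
    stop_input("CLR requires strictly positive entries; ",
               "apply multiplicative_replacement first")
  lm_ <- log(m)
  lm_ - rowMeans(lm_)
}

#' Aitchison distance matrix
#'
#' Euclidean distance between CLR-transformed compositions — the natural
#' metric of the simplex.
#'
#' @param clr A CLR matrix (samples x taxa), e.g. from [clr_transform()].
#' @return Symmetric sample x sample distance matrix.
#' @export
aitchison_distance <- function(clr) {
  m <- as.matrix(clr)
  d <- as.matrix(dist(m, method = "euclidean"))
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  new_dist_matrix(d, ids)
}

#' Reference-cloud statistic
#'
#' Each query sample is scored by its mean Aitchison distance to its `k`
#' nearest reference ("cloud") samples; `k = "all"` (default) averages
#' over the whole reference cloud.  A query that is itself a reference
#' sample (matched by row name) is excluded from its own reference set, so
#' reference samples receive leave-one-out statistics.
#'
#' @param query CLR matrix of query samples (samples x taxa).
#' @param reference CLR matrix of reference samples (>= 3), same taxa.
#' @param k Neighbour count, or `"all"`.
#' @return Named numeric vector of cloud statistics, one per query row.
#' @export
cloud_statistic <- function(query, reference, k = "all") {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  if (nrow(reference) < 3L) stop_input("reference needs >= 3 samples")
  if (ncol(query) != ncol(reference))
    stop_input("query and reference must share taxa")
  qids <- rownames(query) %||% as.character(seq_len(nrow(query)))
  rids <- rownames(reference) %||% paste0("ref", seq_len(nrow(reference)))
  stats <- vapply(seq_len(nrow(query)), function(i) {
    use <- rids != qids[i]          # leave-one-out for reference queries
    d <- sqrt(colSums((t(reference[use, , drop = FALSE]) - query[i, ])^2))
    kk <- if (identical(k, "all")) length(d) else k
    if (kk > length(d))
      stop_input("k (", kk, ") exceeds usable reference size (",
                 length(d), ")")
    mean(sort(d)[seq_len(kk)])
  }, numeric(1L))
  names(stats) <- qids
  stats
}

#' Classify samples as dysbiotic by the 2-SD reference-cloud rule
#'
#' The threshold is the mean plus two sample standard deviations (n-1
#' denominator) of the reference leave-one-out cloud statistics.  A sample
#' is dysbiotic iff its statistic is strictly greater than the threshold;
#' the rule is one-sided (an unusually central sample is still
#' healthy-like).  The dysbiosis index (DI) is the natural log of the
#' cloud statistic, a strictly monotone transform that leaves the
#' classification unchanged.
#'
#' @param stats Named cloud statistics for the samples to classify.
#' @param reference_stats Leave-one-out cloud statistics of the reference
#'   samples.
#' @param k_neighbors Neighbour count used when computing the statistics
#'   (recorded in the result; not used in the rule).
#' @return A list of class `cloud_result`: data frame `scores`
#'   (`sample_id`, `cloud_stat`, `di`, `classification`), plus
#'   `reference_mean`, `reference_sd`, `threshold`, `k_neighbors`.
#' @export
classify_dysbiosis <- function(stats, reference_stats, k_neighbors = "all") {
  ref_mean <- mean(reference_stats)
  ref_sd <- sd(reference_stats)
  if (!is.finite(ref_sd) || ref_sd == 0)
    stop_input("degenerate reference: cloud statistics have zero spread")
  threshold <- ref_mean + 2 * ref_sd
  scores <- data.frame(
    sample_id = names(stats) %||% as.character(seq_along(stats)),
    cloud_stat = unname(stats),
    di = log(unname(stats)),
    classification = ifelse(stats > threshold, "dysbiotic", "healthy-like"),
    stringsAsFactors = FALSE)
  structure(list(scores = scores, reference_mean = ref_mean,
                 reference_sd = ref_sd, threshold = threshold,
                 k_neighbors = k_neighbors),
            class = "cloud_result")
}

#' @export
print.cloud_result <- function(x, ...) {
  n <- nrow(x$scores)
  nd <- sum(x$scores$classification == "dysbiotic")
  cat(sprintf("cloud_result: %d samples, %d dysbiotic (%.1f%%)\n",
              n, nd, 100 * nd / n))
  cat(sprintf("  threshold = %.4f (ref mean %.4f + 2 x SD %.4f)\n",
              x$threshold, x$reference_mean, x$reference_sd))
  invisible(x)
}

#' Reference-cloud dysbiosis index for a cohort
#'
#' End-to-end CLOUD scoring of a count table: collapse to the requested
#' rank (genus by default), convert to proportions, multiplicative zero
#' replacement (per-sample `delta = 0.5 / depth` unless given), CLR
#' transform computed jointly over all samples, leave-one-out cloud
#' statistics for the reference group, cloud statistics for every sample,
#' and 2-SD classification.
#'
#' @param table A [count_table].
#' @param metadata Data frame with `sample_id` and `group`.
#' @param reference_group Value of `group` defining the reference cloud.
#' @param level Taxonomic rank to collapse to, or `NULL` to use the table
#'   as-is (default `"genus"` when taxonomy is present).
#' @param k Neighbour count or `"all"`.
#' @param delta Optional zero-replacement value (default `0.5 / depth` per
#'   sample).
#' @return A `cloud_result` (see [classify_dysbiosis()]).
#' @export
cloud_dysbiosis <- function(table, metadata, reference_group = "healthy",
                            level = if (!is.null(table$taxonomy)) "genus",
                            k = "all", delta = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (!is.null(level)) table <- collapse_to_rank(table, level)
  ids <- colnames(table$counts)
  md <- metadata[match(ids, metadata$sample_id), ]
  if (any(is.na(md$group)))
    stop_input("metadata missing for sample(s): ",
               paste(ids[is.na(md$group)], collapse = ", "))
  ref_ids <- ids[md$group == reference_group]
  if (length(ref_ids) < 3L)
    stop_input("reference group '", reference_group, "' has < 3 samples")
  depths <- sample_depths(table)
  props <- t(table$counts) / depths
  if (is.null(delta)) delta <- 0.5 / depths
  clr <- clr_transform(multiplicative_replacement(props, delta))
  ref_stats <- cloud_statistic(clr[ref_ids, , drop = FALSE],
                               clr[ref_ids, , drop = FALSE], k = k)
  all_stats <- cloud_statistic(clr, clr[ref_ids, , drop = FALSE], k = k)
  classify_dysbiosis(all_stats, ref_stats, k_neighbors = k)
}

#' Orthogonal validation of the dysbiosis classification from SI scores
#'
#' Healthy-control symptom-index (SI) scores are mapped to the logit scale
#' (SI clipped into (eps, 1-eps)), where they are approximately normal;
#' Shapiro-Wilk normality of the healthy logit scores is reported
#' descriptively.  The same 2-SD rule as the cloud classifier is applied
#' on the logit scale: samples with logit(SI) above the healthy mean plus
#' two SD are labelled dysbiotic.  A random forest is then refit on the
#' features with these labels and the out-of-bag probability of
#' "dysbiotic" membership is returned as a probability-based index.
#'
#' @param si Named per-sample SI scores in `[0, 1]`.
#' @param healthy_ids Sample IDs of the healthy reference group (>= 3).
#' @param features Optional numeric feature matrix (samples x features,
#'   rownames matching `si`) for the refit; when `NULL` only labels and
#'   the normality p are returned.
#' @param n_trees Trees for the refit forest (default 500).
#' @param seed Integer seed.
#' @param eps Clipping bound for the logit (default 1e-6).
#' @return List with `labels` (named character), `probability_index`
#'   (named numeric or `NULL`), `normality_p`, `threshold_logit`.
#' @export
orthogonal_validation <- function(si, healthy_ids, features = NULL,
                                  n_trees = 500, seed = 1L, eps = 1e-6) {
  ids <- names(si)
  if (is.null(ids)) stop_input("si must be named by sample")
  if (length(intersect(healthy_ids, ids)) < 3L)
    stop_input("need >= 3 healthy samples with SI scores")
  z <- pmin(pmax(si, eps), 1 - eps)
  lz <- log(z / (1 - z))
  hz <- lz[ids %in% healthy_ids]
  if (sd(hz) == 0) stop_input("degenerate: healthy SI scores identical")
  normality_p <- tryCatch(shapiro.test(hz)$p.value,
                          error = function(e) NA_real_)
  thr <- mean(hz) + 2 * sd(hz)
  labels <- setNames(ifelse(lz > thr, "dysbiotic", "healthy-like"), ids)
  prob_index <- NULL
  if (!is.null(features)) {
    features <- as.matrix(features)[ids, , drop = FALSE]
    if (length(unique(labels)) < 2L || min(table(labels)) < 3L) {
      warning("fewer than 3 samples in a class after the logit 2-SD rule; ",
              "refit skipped", call. = FALSE)
    } else {
      rf <- with_seed(seed, randomForest::randomForest(
        x = features, y = factor(labels), ntree = n_trees))
      prob_index <- setNames(rf$votes[, "dysbiotic"], ids)
    }
  }
  list(labels = labels, probability_index = prob_index,
       normality_p = normality_p, threshold_logit = thr)
}

#' Agreement between the cloud score and a probability-based index
#'
#' Pearson correlation (with two-sided p) between the two per-sample
#' scores, plus label concordance when both classifications are given.
#'
#' @param cloud_scores Named numeric cloud scores (or DI values).
#' @param probability_index Named numeric index on the same samples.
#' @param cloud_labels,index_labels Optional named classifications for
#'   concordance.
#' @return List with `pearson_r`, `p`, `n`, and `concordance` (fraction of
#'   samples with agreeing labels, or `NA`).
#' @export
agreement_correlation <- function(cloud_scores, probability_index,
                                  cloud_labels = NULL, index_labels = NULL) {
  ids <- intersect(names(cloud_scores), names(probability_index))
  ids <- ids[is.finite(cloud_scores[ids]) &
               is.finite(probability_index[ids])]
  if (length(ids) < 3L) stop_input("need >= 3 shared finite samples")
  x <- cloud_scores[ids]; y <- probability_index[ids]
  if (sd(x) == 0 || sd(y) == 0) stop_input("constant input")
  ct <- cor.test(x, y, method = "pearson")
  conc <- NA_real_
  if (!is.null(cloud_labels) && !is.null(index_labels)) {
    shared <- intersect(intersect(names(cloud_labels), names(index_labels)),
                        ids)
    conc <- mean(cloud_labels[shared] == index_labels[shared])
  }
  list(pearson_r = unname(ct$estimate), p = ct$p.value, n = length(ids),
       concordance = conc)
}
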