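#' Size-factor normalization of a count table
#'
#' Per-sample size factors from the geometric mean of pairwise count
#' ratios: for sample j and every other sample k, take the median ratio
#' over taxa with nonzero counts in both, then the geometric mean of those
#' medians over k.  Factors are rescaled to geometric mean 1 and counts
#' divided by them.  A sample sharing no taxon with any other falls back
#' to total-sum scaling with a warning; `method = "tss"` forces total-sum
#' scaling (proportions times the median depth).
#'
#' @param table A [count_table] with no all-zero samples.
#' @param method `"ratio"` (default) or `"tss"`.
#' @return List with `normalized` (taxa x samples numeric matrix) and
#'   `size_factors` (named vector).
#' @export
normalize_counts <- function(table, method = c("ratio", "tss")) {
  stopifnot(inherits(table, "count_table"))
  method <- match.arg(method)
  m <- table$counts
  depths <- colSums(m)
  if (any(depths == 0)) stop_input("all-zero sample(s) present")
  n <- ncol(m)
  if (method == "tss" || n == 1L) {
    sf <- depths / exp(mean(log(depths)))
    return(list(normalized = sweep(m, 2L, sf, "/"),
                size_factors = setNames(sf, colnames(m))))
  }
  sf <- numeric(n)
  for (j in seq_len(n)) {
    logmed <- vapply(seq_len(n)[-j], function(k) {
      shared <- m[, j] > 0 & m[, k] > 0
      if (!any(shared)) return(NA_real_)
      log(median(m[shared, j] / m[shared, k]))
    }, numeric(1L))
    if (all(is.na(logmed))) {
      warning("sample ", colnames(m)[j],
              " shares no taxa with any other; total-sum fallback",
              call. = FALSE)
      sf[j] <- NA_real_
    } else {
      # the mean pairwise log ratio estimates (m+1)/m * log s_j up to a
      # constant (the pair with the sample itself is excluded), so shrink
      # by m/(m+1) to make exact ratio data recover exact factors
      mm <- sum(!is.na(logmed))
      sf[j] <- exp(mean(logmed, na.rm = TRUE) * mm / (mm + 1))
    }
  }
  if (anyNA(sf)) {
    # total-sum fallback scaled to match the valid factors' depth ratio
    valid <- !is.na(sf)
    sf[!valid] <- depths[!valid] * mean(sf[valid] / depths[valid])
  }
  sf <- sf / exp(mean(log(sf)))
  list(normalized = sweep(m, 2L, sf, "/"),
       size_factors = setNames(sf, colnames(m)))
}

#' Prevalence and abundance filters for differential testing
#'
#' A taxon is tested iff its prevalence (fraction of samples with a
#' nonzero count) is at least `prevalence_min` and its maximum per-sample
#' proportion is at least `max_prop_min`; exclusion is strict ("<"), so
#' boundary values are tested.
#'
#' @param table A [count_table].
#' @param prevalence_min Minimum prevalence (default 0.10).
#' @param max_prop_min Minimum of the per-taxon maximum proportion
#'   (default 0.002).
#' @return Data frame with `taxon`, `prevalence`, `max_proportion`,
#'   `status` (`tested`, `excluded:prevalence`, `excluded:abundance`).
#' @export
apply_filters <- function(table, prevalence_min = 0.10,
                          max_prop_min = 0.002) {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  props <- sweep(m, 2L, colSums(m), "/")
  prevalence <- rowMeans(m > 0)
  max_prop <- apply(props, 1L, max)
  status <- rep("tested", nrow(m))
  status[max_prop < max_prop_min] <- "excluded:abundance"
  status[prevalence < prevalence_min] <- "excluded:prevalence"
  data.frame(taxon = rownames(m), prevalence = prevalence,
             max_proportion = max_prop, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized Welch t statistics, one per row of `mat`, for the two-group
# split given by logical index `g1`.  Zero within-group variance with
# distinct means gives +-Inf (perfect separation); with equal means, 0.
welch_t_rows <- function(mat, g1) {
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, !g1, drop = FALSE])
  v1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, !g1, drop = FALSE] - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / se
  zero <- se == 0
  t[zero] <- sign(m1 - m2)[zero] * Inf
  t[is.nan(t)] <- 0
  t
}

#' Two-group permutation test with the t statistic
#'
#' The observed Welch t statistic is compared with its distribution under
#' random relabelling; the two-sided p-value is
#' `(1 + #{|t_perm| >= |t_obs|}) / (1 + n_perm)`.  When the number of
#' distinct assignments `choose(n, n1)` is at most `n_perm` the test
#' enumerates all of them instead and returns the exact p
#' (`#{|t| >= |t_obs|} / #assignments`).  Zero spread in both groups
#' yields `p = 1` with a warning.
#'
#' @param values Numeric vector (e.g. sqrt of normalized abundance).
#' @param labels Two-group labels (each group >= 2 samples).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `t`, `p`, `exact`, `n_perm`.
#' @export
permutation_t_test <- function(values, labels, n_perm = 1000, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop_input("exactly 2 groups required")
  g1 <- labels == groups[1L]
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stop_input("both groups need >= 2 samples")
  res <- permutation_t_test_matrix(matrix(values, nrow = 1L), g1,
                                   n_perm = n_perm, seed = seed)
  list(t = res$t[1L], p = res$p[1L], exact = res$exact,
       n_perm = res$n_perm)
}

# Shared engine: rows of `mat` tested jointly against the same label
# permutations (one permutation stream for all taxa of a rank).
permutation_t_test_matrix <- function(mat, g1, n_perm = 1000, seed = 1L) {
  n <- ncol(mat)
  n1 <- sum(g1)
  t_obs <- welch_t_rows(mat, g1)
  constant <- apply(mat, 1L, function(x) length(unique(x)) == 1L)
  if (any(constant))
    warning("zero pooled variance for ", sum(constant),
            " taxon/taxa: p set to 1", call. = FALSE)
  n_comb <- choose(n, n1)
  exact <- n_comb <= n_perm
  if (exact) {
    combs <- combn(n, n1)
    exceed <- integer(nrow(mat))
    for (c_i in seq_len(ncol(combs))) {
      g <- rep(FALSE, n); g[combs[, c_i]] <- TRUE
      tp <- welch_t_rows(mat, g)
      exceed <- exceed + (abs(tp) >= abs(t_obs) - 1e-12)
    }
    p <- exceed / ncol(combs)
    n_used <- ncol(combs)
  } else {
    exceed <- with_seed(seed, {
      e <- integer(nrow(mat))
      for (i in seq_len(n_perm)) {
        g <- rep(FALSE, n); g[sample.int(n, n1)] <- TRUE
        tp <- welch_t_rows(mat, g)
        e <- e + (abs(tp) >= abs(t_obs) - 1e-12)
      }
      e
    })
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }
  p[constant] <- 1
  list(t = t_obs, p = p, exact = exact, n_perm = n_used)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Applied separately per taxonomic rank by the differential-abundance
#' wrapper; exposed directly for reuse.
#'
#' @param p P-values in (0, 1].
#' @return Monotone q-values of the same length (empty in, empty out).
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0L))
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Differential abundance by permutation t-test with filters and per-rank
#' FDR
#'
#' For each requested rank: collapse the table, size-factor normalize,
#' square-root transform, exclude taxa failing the prevalence/abundance
#' filters, run the two-group permutation t-test per taxon (one shared
#' permutation stream per rank), and compute BH q-values over the tested
#' taxa of that rank only.
#'
#' @param table A [count_table] with taxonomy (unless `ranks = NULL`).
#' @param metadata Data frame with `sample_id` and `group`.
#' @param ranks Character vector of ranks (default `"genus"`); `NULL`
#'   tests the table as-is under rank label `"input"`.
#' @param n_perm Permutations per rank (default 1000).
#' @param prevalence_min,max_prop_min Filter thresholds, see
#'   [apply_filters()].
#' @param normalization `"ratio"` or `"tss"`.
#' @param seed Integer seed.
#' @return Data frame with per-taxon rows: `rank`, `taxon`, `status`,
#'   group means on the sqrt-normalized scale, `t`, `p`, `q`.
#' @export
differential_abundance <- function(table, metadata, ranks = "genus",
                                   n_perm = 1000, prevalence_min = 0.10,
                                   max_prop_min = 0.002,
                                   normalization = "ratio", seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  ids <- colnames(table$counts)
  group <- metadata$group[match(ids, metadata$sample_id)]
  if (any(is.na(group))) stop_input("metadata missing for some samples")
  groups <- sort(unique(group))
  if (length(groups) != 2L) stop_input("exactly 2 groups required")
  g1 <- group == groups[1L]
  run_rank <- function(tab, rank_name) {
    filt <- apply_filters(tab, prevalence_min, max_prop_min)
    norm <- sqrt(normalize_counts(tab, method = normalization)$normalized)
    tested <- filt$status == "tested"
    out <- data.frame(rank = rank_name, taxon = filt$taxon,
                      status = filt$status,
                      mean_group1 = rowMeans(norm[, g1, drop = FALSE]),
                      mean_group2 = rowMeans(norm[, !g1, drop = FALSE]),
                      t = NA_real_, p = NA_real_, q = NA_real_,
                      stringsAsFactors = FALSE, row.names = NULL)
    if (any(tested)) {
      res <- permutation_t_test_matrix(norm[tested, , drop = FALSE], g1,
                                       n_perm = n_perm,
                                       seed = derive_seed(seed, rank_name))
      out$t[tested] <- res$t
      out$p[tested] <- res$p
      out$q[tested] <- bh_fdr(res$p)
    }
    out
  }
  if (is.null(ranks)) return(run_rank(table, "input"))
  do.call(rbind, lapply(ranks, function(r)
    run_rank(collapse_to_rank(table, r), r)))
}

#' Specification for the Monte-Carlo differential-abundance power analysis
#'
#' Defaults reproduce a post-hoc power calculation for a 38-versus-126
#' two-group design over 65 genera in which the 10 moderately abundant
#' genera at abundance ranks 6-15 are decreased by 50% in the larger
#' (symptomatic) group, tested per genus by Wilcoxon-Mann-Whitney with
#' Benjamini-Hochberg FDR control at 5%.
#'
#' @param n1,n2 Group sizes (reference, case).
#' @param n_taxa Number of genera.
#' @param differential_taxa Abundance ranks altered in group 2.
#' @param fold_change Fold change applied to those ranks (0.5 = 50%
#'   decrease).
#' @param fdr_level FDR level for detection (default 0.05).
#' @param n_replicates Monte-Carlo replicates (default 200).
#' @param base_decay,dispersion Generator parameters, see [cohort_spec()].
#' @param depth_meanlog,depth_sdlog Log-normal depth model.
#' @param seed Integer seed.
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(n1 = 38, n2 = 126, n_taxa = 65,
                       differential_taxa = 6:15, fold_change = 0.5,
                       fdr_level = 0.05, n_replicates = 200,
                       base_decay = 0.85, dispersion = 0.02,
                       depth_meanlog = log(20000), depth_sdlog = 0.5,
                       seed = 1L) {
  if (any(fold_change <= 0)) stop_input("fold change must be > 0")
  stopifnot(n1 >= 2, n2 >= 2, n_taxa >= 2, n_replicates >= 1,
            fdr_level > 0, fdr_level < 1)
  structure(list(n1 = n1, n2 = n2, n_taxa = n_taxa,
                 differential_taxa = as.integer(differential_taxa),
                 fold_change = fold_change, fdr_level = fdr_level,
                 n_replicates = n_replicates, base_decay = base_decay,
                 dispersion = dispersion, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog, seed = as.integer(seed)),
            class = "power_spec")
}

#' Monte-Carlo power analysis for differential abundance
#'
#' Per replicate: draw the two groups from the Dirichlet-multinomial
#' generator (group 2 from the effect-injected mean), convert to
#' proportions, test each genus with the Wilcoxon-Mann-Whitney test
#' (normal approximation with tie correction for n1+n2 > 25, exact
#' otherwise), and apply BH FDR at the specification's level.  Per-taxon
#' power is the fraction of replicates in which the taxon is detected;
#' average power is the mean over the truly differential taxa;
#' any-detection power is the fraction of replicates detecting at least
#' one of them.
#'
#' @param spec A [power_spec].
#' @return List of class `power_result` with `per_taxon_power`
#'   (named, differential taxa), `average_power`, `any_detection_power`,
#'   `false_positive_rate` (mean detection rate of null taxa), and `spec`.
#' @export
power_simulation <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  base <- rank_abundance_profile(spec$n_taxa, spec$base_decay)
  shifted <- inject_differential_effect(base, spec$differential_taxa,
                                        spec$fold_change)
  k <- spec$n_taxa
  diff_idx <- spec$differential_taxa
  exact <- (spec$n1 + spec$n2) <= 25
  detected <- matrix(FALSE, nrow = spec$n_replicates, ncol = k)
  for (r in seq_len(spec$n_replicates)) {
    rs <- derive_seed(spec$seed, paste0("rep", r))
    depths <- with_seed(derive_seed(rs, "depths"),
                        pmax(round(exp(rnorm(spec$n1 + spec$n2,
                                             spec$depth_meanlog,
                                             spec$depth_sdlog))), 10))
    c1 <- simulate_dirichlet_multinomial(base, spec$dispersion,
                                         depths[seq_len(spec$n1)],
                                         spec$n1, derive_seed(rs, "g1"))
    c2 <- simulate_dirichlet_multinomial(shifted, spec$dispersion,
                                         depths[spec$n1 + seq_len(spec$n2)],
                                         spec$n2, derive_seed(rs, "g2"))
    p1 <- sweep(c1, 2L, colSums(c1), "/")
    p2 <- sweep(c2, 2L, colSums(c2), "/")
    pv <- vapply(seq_len(k), function(i) {
      suppressWarnings(wilcox.test(p1[i, ], p2[i, ], exact = exact,
                                   correct = TRUE)$p.value)
    }, numeric(1L))
    pv[is.na(pv)] <- 1
    detected[r, ] <- p.adjust(pv, method = "BH") <= spec$fdr_level
  }
  per_taxon <- colMeans(detected)
  structure(list(
    per_taxon_power = setNames(per_taxon[diff_idx],
                               paste0("rank", diff_idx)),
    average_power = mean(per_taxon[diff_idx]),
    any_detection_power = mean(rowSums(detected[, diff_idx,
                                                drop = FALSE]) > 0),
    false_positive_rate = if (length(diff_idx) < k)
      mean(per_taxon[-diff_idx]) else NA_real_,
    spec = spec), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power_result (%d replicates): average power %.1f%%, any-detection %.1f%%\n",
              x$spec$n_replicates, 100 * x$average_power,
              100 * x$any_detection_power))
  invisible(x)
}
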