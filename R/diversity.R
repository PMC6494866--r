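#' Rarefy a count table to even depth
#'
#' Each sample with at least `depth` reads is subsampled without
#' replacement to exactly `depth` reads; shallower samples are dropped and
#' their IDs reported.
#'
#' @param table A [count_table].
#' @param depth Target depth (>= 1).
#' @param seed Integer seed.
#' @return The rarefied [count_table].
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"), depth >= 1)
  depths <- sample_depths(table)
  keep <- depths >= depth
  if (!any(keep)) stop_input("no samples have >= ", depth, " reads")
  if (any(!keep))
    md_log("rarefy: dropped ", sum(!keep), " sample(s) below ", depth,
           " reads: ", paste(names(depths)[!keep], collapse = ", "))
  kept <- table$counts[, keep, drop = FALSE]
  # rrarefy heuristically warns when the smallest count exceeds 1; the
  # inputs here are genuine counts, so silence that specific warning
  sub <- with_seed(seed, withCallingHandlers(
    t(vegan::rrarefy(t(kept), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  dimnames(sub) <- dimnames(kept)
  count_table(sub, taxonomy = table$taxonomy)
}

#' Shannon diversity (bits)
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} over the positive proportions of one
#' sample.  Base 2 is the package convention; pass `base = exp(1)` for
#' nats.
#'
#' @param counts Non-negative count (or proportion) vector for one sample.
#' @param base Logarithm base (default 2).
#' @return Entropy in `log(base)` units.
#' @export
shannon <- function(counts, base = 2) {
  if (all(counts == 0)) stop_input("all-zero sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Observed taxa (richness)
#' @param counts Count vector for one sample.
#' @return Number of taxa with positive count.
#' @export
observed_taxa <- function(counts) {
  if (all(counts == 0)) stop_input("all-zero sample")
  sum(counts > 0)
}

#' Pielou's evenness
#'
#' Shannon entropy divided by its maximum `log2(observed)`; defined as 1
#' for a single-taxon sample.
#'
#' @param counts Count vector for one sample.
#' @return Evenness in `[0, 1]`.
#' @export
pielou_evenness <- function(counts) {
  s <- observed_taxa(counts)
  if (s == 1L) return(1)
  shannon(counts) / log2(s)
}

# Branch-tip incidence: for each edge of a rooted tree, which tips descend
# from it.  Returned as a tips x edges logical matrix.
edge_tip_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  inc <- matrix(FALSE, nrow = n_tip, ncol = nrow(tree$edge))
  # accumulate tip sets in postorder so children are done before parents
  node_tips <- vector("list", n_node)
  for (i in seq_len(n_tip)) node_tips[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(po$edge))) {
    child <- po$edge[r, 2L]
    parent <- po$edge[r, 1L]
    node_tips[[parent]] <- c(node_tips[[parent]], node_tips[[child]])
  }
  for (r in seq_len(nrow(tree$edge)))
    inc[node_tips[[tree$edge[r, 2L]]], r] <- TRUE
  rownames(inc) <- tree$tip.label
  inc
}

check_tips <- function(taxa, tree) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop_input("taxa absent from tree: ", paste(missing, collapse = ", "))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the root and all
#' tips present in the sample.  The path to the root is included by
#' default, the common amplicon-pipeline convention.
#'
#' @param counts Named count vector (names are tip labels).
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param include_root Include branches on the path to the root (default
#'   `TRUE`).
#' @return Phylogenetic diversity in branch-length units.
#' @export
faith_pd <- function(counts, tree, include_root = TRUE) {
  present <- names(counts)[counts > 0]
  if (!length(present)) stop_input("all-zero sample")
  check_tips(present, tree)
  inc <- edge_tip_incidence(tree)
  covered <- colSums(inc[present, , drop = FALSE]) > 0
  if (!include_root) {
    # drop edges ancestral to the whole present set (the root path)
    on_all <- colSums(inc[present, , drop = FALSE]) == length(present)
    covered <- covered & !on_all
  }
  sum(tree$edge.length[covered])
}

new_dist_matrix <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}.
#'
#' @param table A [count_table] (raw counts or proportions).
#' @return Symmetric sample x sample matrix in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "count_table"), ncol(table$counts) >= 2)
  if (any(sample_depths(table) == 0))
    stop_input("Bray-Curtis undefined for all-zero samples")
  d <- vegan::vegdist(t(table$counts), method = "bray")
  new_dist_matrix(as.matrix(d), colnames(table$counts))
}

#' Unweighted UniFrac distance matrix
#'
#' For each sample pair, the branch length unique to either sample's
#' spanned subtree divided by the branch length spanned by their union,
#' using presence/absence only.
#'
#' @param table A [count_table] whose taxa are tips of `tree`.
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @return Symmetric sample x sample matrix in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "count_table"))
  taxa <- rownames(table$counts)
  check_tips(taxa, tree)
  inc <- edge_tip_incidence(tree)[taxa, , drop = FALSE]
  pres <- table$counts > 0
  # edge x sample: does the edge subtend any present tip of the sample
  span <- t(crossprod(inc, pres) > 0)  # samples x edges
  n <- nrow(span)
  len <- tree$edge.length
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- span[i, ]; b <- span[j, ]
    union_len <- sum(len[a | b])
    if (union_len == 0) stop_input("sample pair spans no branches")
    d[i, j] <- d[j, i] <- sum(len[xor(a, b)]) / union_len
  }
  new_dist_matrix(d, colnames(table$counts))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centered Gram-matrix eigendecomposition of a distance matrix.
#' Axes are sorted by eigenvalue; percent variance is relative to the sum
#' of positive eigenvalues, and negative eigenvalues are reported.
#'
#' @param dm Symmetric distance matrix with sample dimnames.
#' @return List with `coordinates` (samples x axes), `eigenvalues`, and
#'   `percent_variance` per positive axis.
#' @export
pcoa <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop_input("PCoA needs at least 3 samples")
  # cmdscale warns when fewer than k eigenvalues are positive; negative
  # eigenvalues are expected for non-Euclidean dissimilarities and are
  # reported in the result
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = eig,
       percent_variance = 100 * eig[pos] / sum(eig[pos]))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Pseudo-F from the partition of squared distances into between- and
#' within-group components; the p-value counts label permutations whose
#' pseudo-F is at least the observed one, using the add-one estimator
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.  When the number of distinct
#' two-group label assignments is at most `n_perm`, all assignments are
#' enumerated and the p-value is exact (`#{F >= F_obs} / #assignments`,
#' the identity assignment included).
#'
#' @param dm Symmetric distance matrix with sample dimnames.
#' @param labels Group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `f` (pseudo-F), `p`, `n_perm`, and `exact` (logical).
#' @export
permanova <- function(dm, labels, n_perm = 999, seed = 1L) {
  dm <- as.matrix(dm)
  labels <- as.character(labels)
  stopifnot(nrow(dm) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2L) stop_input("need at least 2 groups")
  if (any(tab < 2L)) stop_input("every group needs >= 2 samples")
  d2 <- dm^2
  n <- length(labels)
  f_stat <- function(lab) {
    ss_within <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ss_total <- sum(d2) / (2 * n)
    ss_between <- ss_total - ss_within
    g <- length(unique(lab))
    (ss_between / (g - 1)) / (ss_within / (n - g))
  }
  f_obs <- f_stat(labels)
  n_distinct <- count_label_arrangements(tab)
  if (!is.na(n_distinct) && n_distinct <= n_perm) {
    perms <- enumerate_label_arrangements(labels)
    f_all <- vapply(perms, f_stat, numeric(1L))
    p <- sum(f_all >= f_obs - 1e-12) / length(f_all)
    return(list(f = f_obs, p = p, n_perm = length(f_all), exact = TRUE))
  }
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    f_stat(sample(labels)), numeric(1L)))
  list(f = f_obs, p = (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm),
       n_perm = n_perm, exact = FALSE)
}

# Number of distinct assignments of the multiset of labels to positions
# (multinomial coefficient); NA if it overflows.
count_label_arrangements <- function(tab) {
  lg <- lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
  n <- exp(lg)
  if (n > 1e7) NA_real_ else round(n)
}

# All distinct arrangements of a label multiset (recursive; small n only).
enumerate_label_arrangements <- function(labels) {
  uniq <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = uniq)))
  n <- length(labels)
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(uniq)) {
      if (remaining[i] > 0L) {
        remaining[i] <- remaining[i] - 1L
        rec(c(prefix, uniq[i]), remaining)
        remaining[i] <- remaining[i] + 1L
      }
    }
  }
  rec(character(0L), counts)
  out
}

#' Pairwise group comparisons along an ordination axis
#'
#' Two-sided Welch t-tests on the axis values for every group pair, with
#' Benjamini-Hochberg correction across the pairs.  Pairs containing a
#' group with fewer than 2 samples are skipped with a warning.
#'
#' @param axis Numeric ordination-axis value per sample.
#' @param labels Group label per sample.
#' @return Data frame with `group1`, `group2`, `t`, `p`, `q`.
#' @export
axis_group_tests <- function(axis, labels) {
  labels <- as.character(labels)
  stopifnot(length(axis) == length(labels))
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop_input("need at least 2 groups")
  pairs <- combn(groups, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    x <- axis[labels == g1]; y <- axis[labels == g2]
    if (length(x) < 2L || length(y) < 2L) {
      warning("skipping pair ", g1, " vs ", g2, ": group with < 2 samples",
              call. = FALSE)
      return(NULL)
    }
    tt <- t.test(x, y)
    data.frame(group1 = g1, group2 = g2, t = unname(tt$statistic),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_input("no testable group pairs")
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Per-sample alpha diversity table
#'
#' Computes observed taxa, Shannon diversity (bits), Pielou evenness and
#' (when a tree is given) Faith's PD, optionally after rarefaction.
#'
#' @param table A [count_table].
#' @param tree Optional rooted [ape::phylo].
#' @param rarefy_depth Optional depth to rarefy to first.
#' @param seed Seed for rarefaction.
#' @return Data frame, one row per (retained) sample.
#' @export
alpha_diversity <- function(table, tree = NULL, rarefy_depth = NULL,
                            seed = 1L) {
  if (!is.null(rarefy_depth))
    table <- rarefy(table, rarefy_depth, seed = seed)
  m <- table$counts
  res <- data.frame(
    sample_id = colnames(m),
    observed_taxa = apply(m, 2L, observed_taxa),
    shannon = apply(m, 2L, shannon),
    pielou_evenness = apply(m, 2L, pielou_evenness),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(tree))
    res$faith_pd <- apply(m, 2L, faith_pd, tree = tree)
  res$rarefaction_depth <- if (is.null(rarefy_depth)) NA_real_
                           else rarefy_depth
  res
}
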