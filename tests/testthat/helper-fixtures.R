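# Shared fixtures, all built in code.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_table <- function() {
  m <- matrix(c(3, 0, 7,
                5, 2, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  count_table(m)
}

# A small, fast cohort for pipeline-level tests.
tiny_cohort <- function(seed = 11, ...) {
  generate_cohort(cohort_spec(
    n_reference = 12, n_case = 24, n_taxa = 25,
    depth_meanlog = log(3000), low_depth_fraction = 0.1,
    differential_taxa = 4:12, fold_change = 0.1,
    dysbiotic_fraction = 0.4, seed = seed, ...))
}

# Independent step-up FDR oracle: the definition, as a double loop.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    q[i] <- min(vapply(rank_i:m, function(j) {
      min(p[ord[j]] * m / j, 1)
    }, numeric(1L)))
  }
  q
}

# Brute-force AUC oracle: concordant pairs, ties count 1/2.
auc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Independent pseudo-F from Gower-centred inner products.
permanova_f_oracle <- function(dm, labels) {
  n <- length(labels)
  d2 <- as.matrix(dm)^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    dd <- d2[idx, idx]
    ss_within <- ss_within + sum(dd[upper.tri(dd)]) / length(idx)
  }
  g <- length(unique(labels))
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}
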