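test_that("multiplicative replacement rescales exactly onto the simplex", {
  x <- rbind(c(0.5, 0.5, 0), c(0.2, 0.3, 0.5))
  out <- multiplicative_replacement(x, 0.01)
  expect_equal(out[1, ], c(0.495, 0.495, 0.01))
  expect_equal(out[2, ], c(0.2, 0.3, 0.5))  # no zeros: unchanged
  expect_equal(rowSums(out), c(1, 1))
  expect_error(multiplicative_replacement(rbind(c(0, 0, 1)), 2),
               "delta")
  expect_error(multiplicative_replacement(rbind(c(0, 0, 0))), "sum to 1")
})

test_that("CLR rows sum to zero, match log identities, and are scale-invariant", {
  x <- rbind(c(1, 3, 9) / 13)
  clr <- clr_transform(x)
  expect_equal(clr[1, ], c(-log(3), 0, log(3)))
  expect_equal(clr_transform(rbind(rep(0.25, 4)))[1, ], rep(0, 4))
  big <- withr::with_seed(1, matrix(rexp(60) + 0.01, nrow = 5))
  expect_equal(rowSums(clr_transform(big)), rep(0, 5), tolerance = 1e-9)
  expect_equal(clr_transform(big * 1000), clr_transform(big))
  expect_error(clr_transform(rbind(c(0, 1))), "positive")
})

test_that("Aitchison distance matches the pairwise log-ratio formula", {
  props <- rbind(a = c(1, 3, 9) / 13, b = c(9, 3, 1) / 13)
  d <- aitchison_distance(clr_transform(props))
  expect_equal(d["a", "b"], 2 * sqrt(2) * log(3))
  # independent oracle: sqrt(1/(2D) * sum_ij (ln(x_i/x_j) - ln(y_i/y_j))^2)
  lr <- function(x, y) {
    s <- 0
    for (i in 1:3) for (j in 1:3)
      s <- s + (log(x[i] / x[j]) - log(y[i] / y[j]))^2
    sqrt(s / (2 * 3))
  }
  p3 <- withr::with_seed(2, {
    m <- matrix(rexp(9) + 0.05, nrow = 3)
    m / rowSums(m)
  })
  d3 <- aitchison_distance(clr_transform(p3))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(d3[i, j], lr(p3[i, ], p3[j, ]), tolerance = 1e-12)
  # permutation invariance
  perm <- c(3, 1, 2)
  expect_equal(aitchison_distance(clr_transform(p3[, perm]))[1, 2],
               d3[1, 2])
})

test_that("cloud statistics use leave-one-out for reference members", {
  # three collinear CLR points at mutual distances {1,1,2}
  ref <- cbind(x = c(0, 1, 2), y = 0, z = 0)
  rownames(ref) <- c("r1", "r2", "r3")
  stats <- cloud_statistic(ref, ref, k = "all")
  expect_equal(unname(stats), c(1.5, 1, 1.5))
  # query identical to a reference sample, k = 1, not itself a reference
  q <- ref[2, , drop = FALSE]
  rownames(q) <- "query"
  expect_equal(unname(cloud_statistic(q, ref, k = 1)), 0)
  # far outlier exceeds every leave-one-out reference statistic
  far <- matrix(c(100, 0, 0), nrow = 1,
                dimnames = list("far", colnames(ref)))
  expect_gt(cloud_statistic(far, ref)[1], max(stats))
  expect_error(cloud_statistic(q, ref, k = 5), "exceeds")
  expect_error(cloud_statistic(ref, ref[1:2, ]), ">= 3")
})

test_that("the 2-SD rule is strict and one-sided, with DI = log statistic", {
  ref_stats <- c(1, 2, 3, 2, 2)
  thr <- 2 + 2 * sd(ref_stats)  # 3.41421...
  res <- classify_dysbiosis(c(q1 = 3.5, q2 = 3.3, q3 = thr), ref_stats)
  expect_equal(res$threshold, thr)
  expect_equal(res$scores$classification,
               c("dysbiotic", "healthy-like", "healthy-like"))
  expect_equal(res$scores$di, log(c(3.5, 3.3, thr)))
  # DI ordering mirrors the statistic ordering (strict monotonicity)
  expect_equal(order(res$scores$di), order(res$scores$cloud_stat))
  expect_error(classify_dysbiosis(1:3, rep(2, 5)), "degenerate")
})

test_that("cloud_stat is invariant to per-sample count rescaling", {
  coh <- tiny_cohort(seed = 61)
  tab <- suppressMessages(filter_low_depth(coh$table))
  depths <- sample_depths(tab)
  props <- t(tab$counts) / depths
  delta <- 0.5 / depths
  clr <- clr_transform(multiplicative_replacement(props, delta))
  ref_ids <- grep("^H", rownames(clr), value = TRUE)
  s1 <- cloud_statistic(clr, clr[ref_ids, ], k = "all")
  # multiplying a sample's counts by a constant leaves proportions, hence
  # CLR and the statistic, unchanged
  scaled <- tab$counts
  scaled[, 3] <- scaled[, 3] * 7
  props2 <- t(scaled) / colSums(scaled)
  clr2 <- clr_transform(multiplicative_replacement(props2, delta))
  s2 <- cloud_statistic(clr2, clr2[ref_ids, ], k = "all")
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("null reference cohorts flag roughly the 2-SD tail", {
  base <- rank_abundance_profile(40, 0.85)
  frac <- vapply(1:50, function(r) {
    cnt <- simulate_dirichlet_multinomial(base, 0.02, 5000, 30,
                                          seed = 7000 + r)
    dimnames(cnt) <- list(paste0("G", 1:40), paste0("S", 1:30))
    props <- t(cnt) / colSums(cnt)
    clr <- clr_transform(multiplicative_replacement(props,
                                                    0.5 / colSums(cnt)))
    st <- cloud_statistic(clr, clr)
    mean(classify_dysbiosis(st, st)$scores$classification == "dysbiotic")
  }, numeric(1))
  expect_lt(mean(frac), 0.08)
})

test_that("end-to-end cloud scoring recovers injected dysbiosis", {
  coh <- tiny_cohort(seed = 71)
  tab <- suppressMessages(filter_low_depth(coh$table))
  res <- cloud_dysbiosis(tab, coh$metadata, reference_group = "healthy")
  truth <- coh$truth$sample_class
  m <- merge(res$scores, truth, by = "sample_id")
  sens <- mean(m$classification[m$latent_class == "dysbiotic"] ==
                 "dysbiotic")
  spec <- mean(m$classification[m$latent_class == "healthy-like"] ==
                 "healthy-like")
  expect_gt((sens + spec) / 2, 0.75)
  expect_error(cloud_dysbiosis(tab, coh$metadata,
                               reference_group = "nosuch"), "reference")
})

test_that("logit-scale orthogonal validation applies the 2-SD rule", {
  si <- withr::with_seed(81, {
    h <- 1 / (1 + exp(-rnorm(30, -2, 0.5)))
    c(setNames(h, paste0("H", 1:30)),
      setNames(rep(0.99, 10), paste0("P", 1:10)))
  })
  res <- orthogonal_validation(si, paste0("H", 1:30), seed = 1)
  expect_true(all(res$labels[paste0("P", 1:10)] == "dysbiotic"))
  expect_true(mean(res$labels[paste0("H", 1:30)] == "healthy-like") > 0.9)
  expect_true(res$normality_p > 0 && res$normality_p <= 1)
  expect_error(orthogonal_validation(setNames(rep(0.5, 20),
                                              paste0("H", 1:20)),
                                     paste0("H", 1:20)), "degenerate")
  expect_error(orthogonal_validation(si, c("H1", "H2")), ">= 3")
})

test_that("score agreement reports Pearson r, p, and label concordance", {
  x <- setNames(1:20 + 0, paste0("s", 1:20))
  res <- agreement_correlation(x, 2 * x + 1)
  expect_equal(res$pearson_r, 1)
  noise <- withr::with_seed(91, setNames(rnorm(2000), paste0("n", 1:2000)))
  noise2 <- withr::with_seed(92, setNames(rnorm(2000), paste0("n", 1:2000)))
  expect_lt(abs(agreement_correlation(noise, noise2)$pearson_r), 0.1)
  lab <- setNames(rep(c("dysbiotic", "healthy-like"), 10), names(x))
  res2 <- agreement_correlation(x, 2 * x, cloud_labels = lab,
                                index_labels = lab)
  expect_equal(res2$concordance, 1)
  expect_error(agreement_correlation(x, setNames(rep(1, 20), names(x))),
               "constant")
})

test_that("cloud and SI-derived classifications agree above chance on strong effects", {
  coh <- tiny_cohort(seed = 101)
  tab <- suppressMessages(filter_low_depth(coh$table))
  md <- coh$metadata
  cloud <- cloud_dysbiosis(tab, md)
  feats <- t(normalize_counts(tab)$normalized)
  si <- fit_symptom_index(feats,
                          md$group[match(rownames(feats), md$sample_id)],
                          n_trees = 300, seed = 5)$si
  ortho <- orthogonal_validation(si, md$sample_id[md$group == "healthy"],
                                 features = feats, n_trees = 300, seed = 6)
  shared <- intersect(names(ortho$labels), cloud$scores$sample_id)
  cloud_lab <- setNames(cloud$scores$classification,
                        cloud$scores$sample_id)[shared]
  conc <- mean(cloud_lab == ortho$labels[shared])
  # both classifiers track the same latent depletion class
  expect_gt(conc, 0.6)
})
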